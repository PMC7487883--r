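test_that("DNA features hit their colocalization closed forms", {
  set.seed(1)
  w <- matrix(runif(64, 0.2, 1), 8, 8)
  f <- dna_features(w, w)   # perfect colocalization
  expect_equal(unname(f[c(2, 3, 5, 6, 7)]), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(f[8]), 0, tolerance = 1e-9)
  expect_equal(unname(f[9:16]), rep(0, 8), tolerance = 1e-9)

  # disjoint blobs: no overlap
  p <- matrix(0, 8, 8); p[1:3, 1:3] <- 1
  d <- matrix(0, 8, 8); d[6:8, 6:8] <- 1
  fd <- dna_features(p, d)
  expect_equal(unname(fd[2]), 0)
  expect_equal(unname(fd[3]), 0)
})

test_that("distance statistics match a brute-force nearest-neighbor oracle", {
  p <- matrix(0, 8, 8); p[2:3, 2:3] <- 1
  d <- matrix(0, 8, 8); d[6:7, 5:8] <- 1
  f <- dna_features(p, d)
  P <- which(p > 0.5, arr.ind = TRUE); D <- which(d > 0.5, arr.ind = TRUE)
  dist_pd <- apply(P, 1, function(q)
    min(sqrt((D[, 1] - q[1])^2 + (D[, 2] - q[2])^2)))
  diag_len <- sqrt(128)
  expect_equal(unname(f[9]), mean(dist_pd) / diag_len, tolerance = 1e-9)
  expect_equal(unname(f[10]), median(dist_pd) / diag_len, tolerance = 1e-9)
  expect_equal(unname(f[11]), sd(dist_pd) / diag_len, tolerance = 1e-9)
  expect_equal(unname(f[12]), max(dist_pd) / diag_len, tolerance = 1e-9)
  dist_dp <- apply(D, 1, function(q)
    min(sqrt((P[, 1] - q[1])^2 + (P[, 2] - q[2])^2)))
  expect_equal(unname(f[13:16]),
               c(mean(dist_dp), median(dist_dp), sd(dist_dp), max(dist_dp)) / diag_len,
               tolerance = 1e-9)
})

test_that("GLCM matches hand counts and normalizes", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)       # [[0,0],[1,1]]
  G <- glcm(q, c(0L, 1L), 2L)
  expect_equal(G, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  Gc <- glcm(matrix(3L, 4, 4), c(0L, 1L), 8L)
  expect_equal(Gc[4, 4], 1)
  expect_equal(sum(Gc), 1)
  set.seed(2)
  for (i in 1:5) {
    q2 <- matrix(sample(0:7, 36, replace = TRUE), 6, 6)
    for (off in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L)))
      expect_equal(sum(glcm(q2, off, 8L)), 1, tolerance = 1e-12)
  }
  expect_error(glcm(matrix(0L, 1, 1), c(0L, 1L), 2L), "smaller than the offset")
})

test_that("Haralick statistics hit closed forms and stay finite", {
  s <- haralick_stats(diag(c(0.5, 0.5)))
  expect_equal(unname(s[c("energy", "contrast", "entropy")]), c(0.5, 0, 1))
  expect_equal(unname(s["correlation"]), 1)
  su <- haralick_stats(matrix(0.25, 2, 2))
  expect_equal(unname(su[c("energy", "entropy")]), c(0.25, 2))
  expect_equal(unname(su["correlation"]), 0)   # zero covariance
  set.seed(3)
  for (i in 1:200) {
    P <- matrix(runif(16), 4, 4); P <- (P + t(P)); P <- P / sum(P)
    expect_true(all(is.finite(haralick_stats(P))))
  }
})

test_that("haralick feature block has 576 finite values for every filter", {
  set.seed(4)
  w <- matrix(runif(32 * 32), 32, 32)
  for (filt in c("db1", "db4", "db10")) {
    v <- haralick_features(w, haralick_config(wavelet_filter = filt))
    expect_length(v, 576)
    expect_true(all(is.finite(v)))
  }
  vc <- haralick_features(matrix(5, 32, 32))
  expect_length(vc, 576)
  expect_true(all(is.finite(vc)))
  # detail subbands of a constant window carry the degenerate imputation
  expect_equal(unname(vc["har.db4.lh1.o0.energy"]), 1)
  # different filters give different textures
  v1 <- haralick_features(w, haralick_config(wavelet_filter = "db1"))
  v10 <- haralick_features(w, haralick_config(wavelet_filter = "db10"))
  expect_gt(max(abs(v1 - v10)), 0)
})

test_that("LBP histogram equals per-pixel hand enumeration", {
  hc <- lbp_features(matrix(1, 5, 5))
  expect_equal(unname(hc[256]), 1)   # constant -> code 255
  set.seed(5)
  w <- matrix(sample(0:9, 25, replace = TRUE), 5, 5)
  h <- lbp_features(w)
  expect_equal(sum(h), 1)
  # independent per-pixel enumeration
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  codes <- integer(0)
  for (r in 2:4) for (c in 2:4) {
    code <- 0
    for (b in seq_along(offs))
      if (w[r + offs[[b]][1], c + offs[[b]][2]] >= w[r, c])
        code <- code + 2^(b - 1)
    codes <- c(codes, code)
  }
  expect_equal(unname(h), as.numeric(tabulate(codes + 1, 256) / 9))
  expect_error(lbp_features(matrix(1, 2, 2)), "3x3")
})

test_that("patch vector is 848 with the declared block layout", {
  set.seed(6)
  patch <- list(protein = matrix(runif(1024), 32, 32),
                dna = matrix(runif(1024), 32, 32))
  v <- featurize_patch(patch)
  expect_length(v, 848)
  expect_true(all(startsWith(names(v)[1:16], "dna.")))
  expect_true(all(startsWith(names(v)[17:592], "har.")))
  expect_true(all(startsWith(names(v)[593:848], "lbp.")))
  expect_identical(v, featurize_patch(patch))   # deterministic
  expect_true(all(is.finite(v)))
})

test_that("intensity scaling leaves texture and ratio features unchanged", {
  set.seed(7)
  patch <- list(protein = matrix(runif(1024, 0.1, 1), 32, 32),
                dna = matrix(runif(1024, 0.1, 1), 32, 32))
  v1 <- featurize_patch(patch)
  v2 <- featurize_patch(list(protein = 3 * patch$protein, dna = 3 * patch$dna))
  keep <- !startsWith(names(v1), "dna.")   # texture blocks
  expect_equal(v1[keep], v2[keep], tolerance = 1e-9)
  expect_equal(v1["dna.intensity_ratio"], v2["dna.intensity_ratio"], tolerance = 1e-9)
})

test_that("image features are the mean of patch features", {
  ch <- make_channels("iii", size = 96, seed = 5)
  ps <- select_patches(ch, n = 3, size = 32, image_ref = "img")
  vi <- featurize_image(ps)
  M <- vapply(ps$windows, featurize_patch, numeric(848))
  expect_equal(vi, rowMeans(M), tolerance = 1e-12)
  ps1 <- select_patches(ch, n = 1, size = 32)
  expect_equal(featurize_image(ps1), featurize_patch(ps1$windows[[1]]),
               tolerance = 1e-12)
})

test_that("random windows never produce NaN features", {
  set.seed(8)
  for (i in 1:25) {
    p <- list(protein = matrix(runif(1024) * rbinom(1024, 1, runif(1)), 32, 32),
              dna = matrix(runif(1024) * rbinom(1024, 1, runif(1)), 32, 32))
    expect_true(all(is.finite(featurize_patch(p))))
  }
})
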