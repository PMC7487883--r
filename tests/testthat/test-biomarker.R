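test_that("image score vectors concatenate seven probability triples", {
  tm <- toy_seven_models()
  set.seed(1)
  v <- image_score_vector(tm$models, tm$feature_for("ii"))
  expect_length(v, 21)
  triples <- matrix(v, 3, 7)
  expect_equal(unname(colSums(triples)), rep(1, 7), tolerance = 1e-9)
  # block order matches the combined-feature backbone order
  expect_equal(names(v)[1:3], paste("googlenet", c("i", "ii", "iii"), sep = "."))
  expect_equal(names(v)[19:21], paste("gapnet_pl", c("i", "ii", "iii"), sep = "."))
  expect_error(image_score_vector(tm$models[1:3], tm$feature_for("i")),
               "seven")
})

test_that("t-test closed forms, bounds and degenerate variances", {
  # identical samples with spread: p = 1
  a <- matrix(c(0.1, 0.2, 0.3), 3, 1)
  expect_equal(translocation_test(a, a)[1], 1)
  # {1,2,3} vs {4,5,6}: pooled t = -3.674, p ~ 0.0214
  p <- translocation_test(matrix(1:3, 3, 1), matrix(4:6, 3, 1))
  t_hand <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(p[1], 2 * pt(-abs(t_hand), 4), tolerance = 1e-9)
  expect_equal(p[1], 0.02131, tolerance = 1e-4)
  # zero pooled variance
  z_same <- translocation_test(matrix(2, 3, 1), matrix(2, 3, 1))
  z_diff <- translocation_test(matrix(2, 3, 1), matrix(5, 3, 1))
  expect_equal(z_same[1], 1)
  expect_equal(z_diff[1], 0)
  expect_error(translocation_test(matrix(1, 1, 1), matrix(1:3, 3, 1)), "at least 2")
  # agreement with stats::t.test on random data, both variants
  set.seed(2)
  x <- matrix(rnorm(40), 8, 5); yv <- matrix(rnorm(30, 0.5), 6, 5)
  expect_equal(unname(translocation_test(x, yv, "student")),
               vapply(1:5, function(j)
                 t.test(x[, j], yv[, j], var.equal = TRUE)$p.value, 0.0),
               tolerance = 1e-12)
  expect_equal(unname(translocation_test(x, yv, "welch")),
               vapply(1:5, function(j) t.test(x[, j], yv[, j])$p.value, 0.0),
               tolerance = 1e-12)
})

test_that("t-test p agrees with a permutation oracle", {
  set.seed(3)
  x <- matrix(rnorm(5 * 2), 5, 2)
  y <- matrix(rnorm(7 * 2, 0.8), 7, 2)
  p <- translocation_test(x, y)
  pooled <- rbind(x, y)
  nperm <- 1e5
  for (j in 1:2) {
    obs <- abs(mean(x[, j]) - mean(y[, j]))
    v <- pooled[, j]
    perm <- vapply(seq_len(nperm), function(i) {
      s <- sample(12, 5)
      abs(mean(v[s]) - mean(v[-s]))
    }, 0.0)
    expect_lt(abs(p[j] - mean(perm >= obs - 1e-12)), 0.01)
  }
})

test_that("biomarker flag follows the min-p rule with optional correction", {
  expect_false(flag_biomarker(rep(0.5, 21)))
  expect_true(flag_biomarker(c(0.01, rep(0.9, 20))))
  expect_false(flag_biomarker(c(0.01, rep(0.9, 20)), correction = "bonferroni"))
  expect_error(flag_biomarker(0.5, alpha = 0), "alpha")
})

test_that("min-p over correlated dimensions is liberal under the null", {
  set.seed(4)
  nsim <- 1000
  flags <- vapply(seq_len(nsim), function(i) {
    z <- rnorm(5 + 15)                        # shared latent factor
    base <- matrix(rnorm(20 * 21), 20, 21) * 0.5 + z
    flag_biomarker(translocation_test(base[1:5, ], base[6:20, ]))
  }, TRUE)
  expect_gt(mean(flags), 0.05)               # documented liberality
})

test_that("null control splits normal images evenly and reproducibly", {
  set.seed(5)
  X <- matrix(rnorm(8 * 21), 8, 21)
  p1 <- null_control(X, seed = 3)
  p2 <- null_control(X, seed = 3)
  expect_identical(p1, p2)
  expect_length(p1, 21)
  X7 <- matrix(rnorm(7 * 21), 7, 21)
  expect_silent(null_control(X7, seed = 1))   # split 3 vs 4
  expect_error(null_control(X[1:3, ]), "at least 4")
})

test_that("same-protein null control yields mostly large p-values", {
  set.seed(6)
  n_prot <- 200
  frac <- vapply(seq_len(n_prot), function(i) {
    mu <- rnorm(21, 0.5, 0.2)                 # protein-specific mean scores
    X <- matrix(rnorm(8 * 21, mu, 0.1), 8, 21, byrow = TRUE)
    mean(null_control(X, seed = i) > 0.05)
  }, 0.0)
  expect_gte(mean(frac), 0.85)
})

test_that("gamma MLE recovers parameters and the control flags degeneracy", {
  set.seed(7)
  d <- rgamma(1e4, shape = 2, scale = 1.5)
  fit <- MASS::fitdistr(d, "gamma")
  expect_equal(unname(fit$estimate["shape"]), 2, tolerance = 0.1)
  expect_equal(unname(1 / fit$estimate["rate"]), 1.5, tolerance = 0.1)

  mkimg <- function(s) matrix(runif(64, 0, s), 8, 8)
  imgs_n <- lapply(1:4, function(p) lapply(1:3, function(i) mkimg(p)))
  imgs_c <- lapply(1:4, function(p) lapply(1:3, function(i) mkimg(p + 0.5)))
  ctl <- intensity_distance_control(imgs_n, imgs_c,
                                    detected_flags = c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.finite(c(ctl$detected, ctl$undetected))))
  expect_gt(ctl$detected["shape"], 0)
  # distances are symmetric in argument order
  h1 <- ihcloc:::intensity_histogram(imgs_n[[1]][[1]])
  h2 <- ihcloc:::intensity_histogram(imgs_c[[1]][[1]])
  expect_equal(sqrt(sum((h1 - h2)^2)), sqrt(sum((h2 - h1)^2)))
  same <- lapply(1:4, function(p) lapply(1:3, function(i) matrix(1, 8, 8)))
  expect_error(intensity_distance_control(same, same, c(TRUE, TRUE, FALSE, FALSE)),
               "degenerate")
})

test_that("detect_biomarkers separates shifted from stable proteins", {
  tm <- toy_seven_models()
  set.seed(8)
  # build a manifest + feature matrix: P1 translocates (i -> ii), P2 stable
  mk_rows <- function(pid, cls_n, cls_c) {
    paths <- paste0(pid, "_", 1:8)
    list(rec = data.frame(protein_id = pid, image_path = paths,
                          tissue_state = rep(c("normal", "cancer"), each = 4),
                          label = "unknown"),
         X = t(vapply(1:8, function(i)
           tm$feature_for(if (i <= 4) cls_n else cls_c, noise = 0.2),
           numeric(14))))
  }
  a <- mk_rows("P1", "i", "ii"); b <- mk_rows("P2", "iii", "iii")
  man <- manifest(rbind(a$rec, b$rec))
  X <- rbind(a$X, b$X)
  rownames(X) <- c(a$rec$image_path, b$rec$image_path)
  rep <- detect_biomarkers(tm$models, X, man)
  expect_true(rep$is_biomarker[rep$protein_id == "P1"])
  expect_equal(rep$normal_loc[rep$protein_id == "P1"], "i")
  expect_equal(rep$cancer_loc[rep$protein_id == "P1"], "ii")
  expect_equal(rep$normal_loc[rep$protein_id == "P2"], "iii")
  expect_equal(rep$min_p, apply(as.matrix(rep[, grep("^p\\.", names(rep))]), 1, min))
})
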