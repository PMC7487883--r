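test_that("window scores match a brute-force oracle", {
  set.seed(3)
  prot <- matrix(runif(64 * 64), 64, 64)
  size <- 16
  sc <- score_windows(prot, size = size)
  sm <- as.matrix(EBImage::gblur(prot, sigma = size / 8))
  for (k in sample(nrow(sc), 12)) {
    r <- sc$row[k]; c <- sc$col[k]
    expect_equal(sc$score[k],
                 mean(sm[(r + 1):(r + size), (c + 1):(c + size)]),
                 tolerance = 1e-10)
  }
  # uniform image: all scores equal
  scu <- score_windows(matrix(1, 40, 40), size = 8)
  expect_lt(diff(range(scu$score)), 1e-9)
  expect_error(score_windows(matrix(1, 10, 10), size = 20), "exceeds")
})

test_that("a bright on-grid square wins the top window", {
  prot <- matrix(0, 64, 64)
  prot[17:32, 33:48] <- 1          # top-left (16, 32) on the stride-8 grid
  ch <- structure(list(protein = prot, dna = prot * 0, method = "LIN"),
                  class = "StainChannels")
  ps <- select_patches(ch, n = 1, size = 16)
  expect_equal(c(ps$coords$row[1], ps$coords$col[1]), c(16, 32))
})

test_that("greedy selection respects count, overlap and order", {
  prot <- matrix(0, 96, 96)
  blobs <- list(c(8, 8), c(8, 72), c(72, 40))
  for (b in blobs) prot[b[1]:(b[1] + 15), b[2]:(b[2] + 15)] <- 1
  ch <- structure(list(protein = prot, dna = prot * 0, method = "LIN"),
                  class = "StainChannels")
  ps <- select_patches(ch, n = 3, size = 16, max_overlap = 0.25)
  expect_equal(nrow(ps$coords), 3)
  expect_true(all(diff(ps$coords$score) <= 1e-12))   # non-increasing
  # pairwise overlap constraint holds exhaustively
  s <- ps$size
  for (i in 1:2) for (j in (i + 1):3) {
    ovr <- max(0, s - abs(ps$coords$row[i] - ps$coords$row[j])) *
           max(0, s - abs(ps$coords$col[i] - ps$coords$col[j])) / s^2
    expect_lte(ovr, 0.25)
  }
  # determinism
  ps2 <- select_patches(ch, n = 3, size = 16, max_overlap = 0.25)
  expect_identical(ps$coords, ps2$coords)
  # each blob is covered by exactly one patch
  hits <- vapply(blobs, function(b) sum(abs(ps$coords$row - b[1]) < 8 &
                                          abs(ps$coords$col - b[2]) < 8), 0L)
  expect_true(all(hits == 1))
})

test_that("greedy matches a brute-force recomputation on a toy score map", {
  prot <- matrix(0, 40, 40)
  set.seed(8)
  prot[] <- runif(1600)
  ch <- structure(list(protein = prot, dna = prot * 0, method = "LIN"),
                  class = "StainChannels")
  size <- 8; max_ov <- 0.25
  ps <- select_patches(ch, n = 5, size = size, max_overlap = max_ov)
  cand <- score_windows(prot, size = size)
  cand <- cand[order(-cand$score, cand$row, cand$col), ]
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(kept) >= 5) break
    ok <- all(vapply(kept, function(k)
      max(0, size - abs(cand$row[i] - k[1])) *
        max(0, size - abs(cand$col[i] - k[2])) / size^2 <= max_ov, TRUE))
    if (ok) kept[[length(kept) + 1]] <- c(cand$row[i], cand$col[i])
  }
  expect_equal(unname(as.matrix(ps$coords[, c("row", "col")])),
               do.call(rbind, kept))
})

test_that("empty protein channel warns and falls back to position order", {
  ch <- structure(list(protein = matrix(0, 32, 32), dna = matrix(0, 32, 32),
                       method = "LIN"), class = "StainChannels")
  expect_warning(ps <- select_patches(ch, n = 2, size = 8), "empty")
  expect_equal(nrow(ps$coords), 2)
})

test_that("default grids match the published search space", {
  g <- default_patch_grid()
  expect_length(g$counts, 19)
  expect_length(g$sizes, 7)
  expect_equal(range(g$counts), c(25, 385))
  expect_equal(range(g$sizes), c(45, 225))
  expect_equal(length(g$counts) * length(g$sizes), 133)
})

test_that("one-cell grid search returns that cell as the optimum", {
  ds <- shared_dataset()
  res <- patch_grid_search(ds$manifest, counts = 2L, sizes = 32L,
                           eval = list(k = 3L, max_k = 15L))
  expect_equal(nrow(res$table), 1)
  expect_equal(res$best$count, 2)
  expect_equal(res$best$size, 32)
  expect_true(is.finite(res$best$accuracy))
})
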