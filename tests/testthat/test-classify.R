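make_blobs <- function(n_per = 20, sigma = 0.5, seed = 1, sep = 3) {
  set.seed(seed)
  centers <- list(i = c(0, 0), ii = c(sep, 0), iii = c(0, sep))
  y <- rep(c("i", "ii", "iii"), each = n_per)
  X <- t(vapply(y, function(cl) centers[[cl]] + rnorm(2, 0, sigma), numeric(2)))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = y)
}

test_that("SVM separates blobs and calibrates probabilities", {
  b <- make_blobs(sigma = 0.3)
  m <- train_svm(b$X, b$y, grid = list(c = c(1, 10), g = c(0.5, 2)), seed = 1)
  sc <- predict_scores(m, b$X)
  expect_equal(unname(rowSums(sc)), rep(1, 60), tolerance = 1e-9)
  expect_equal(mean(c("i", "ii", "iii")[max.col(sc)] == b$y), 1)
  # a deep interior point gets a confident score
  expect_gt(predict_scores(m, matrix(c(0, 3), 1, 2,
                                     dimnames = list(NULL, c("f1", "f2"))))[, "iii"],
            0.9)
  # determinism across calls
  expect_identical(sc, predict_scores(m, b$X))
  expect_error(train_svm(b$X, rep("i", 60)), "single class")
})

test_that("one-cell grids are selected verbatim and columns are checked", {
  b <- make_blobs()
  m <- train_svm(b$X, b$y, grid = list(c = 4, g = 0.25), seed = 1)
  expect_equal(m$c, 4)
  expect_equal(m$g, 0.25)
  bad <- b$X; colnames(bad) <- c("f1", "zz")
  expect_error(predict_scores(m, bad), "f2")
})

test_that("cross-validated accuracy approaches the Bayes rate on blobs", {
  # sigma chosen so the 3-class Bayes accuracy is ~95%
  sigma <- 0.9
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  set.seed(42)
  mc <- matrix(rnorm(2e5, 0, sigma), ncol = 2)
  bayes <- mean(vapply(seq_len(nrow(mc)), function(i) {
    x <- centers[1 + (i %% 3), ] + mc[i, ]
    d <- rowSums(sweep(centers, 2, x)^2)
    which.min(d) == 1 + (i %% 3)
  }, TRUE))
  b <- make_blobs(n_per = 60, sigma = sigma, seed = 2)
  df <- data.frame(protein_id = paste0("P", seq_along(b$y)),
                   image_path = paste0("img", seq_along(b$y)),
                   tissue_state = "normal", label = b$y)
  rownames(b$X) <- df$image_path
  cv <- crossval(manifest(df), b$X, mode = "per_image", k = 5, seed = 1,
                 grid = list(c = c(1, 10, 100), g = c(0.25, 1, 4)))
  expect_gt(cv$accuracy, bayes - 0.05)
})

test_that("per-protein folds never split a protein and cover every image", {
  ds <- shared_dataset()
  set.seed(1)
  feats <- matrix(rnorm(nrow(ds$manifest$records) * 4), ncol = 4,
                  dimnames = list(ds$manifest$records$image_path,
                                  paste0("f", 1:4)))
  rec <- ds$manifest$records
  fold <- ihcloc:::grouped_folds(rec$protein_id, k = 3, seed = 2)
  for (f in unique(fold))
    expect_length(intersect(rec$protein_id[fold == f],
                            rec$protein_id[fold != f]), 0)
  cv <- suppressWarnings(crossval(ds$manifest, feats, mode = "per_protein",
                                  k = 3, seed = 2,
                                  grid = list(c = 1, g = 0.5)))
  expect_equal(sum(cv$confusion), nrow(rec))       # every image tested once
  expect_error(crossval(ds$manifest, feats, mode = "per_protein", k = 50),
               "fewer groups")
})

test_that("k=2 over 4 images tests 2 images per fold", {
  df <- data.frame(protein_id = paste0("P", 1:4),
                   image_path = paste0("i", 1:4),
                   tissue_state = "normal",
                   label = c("i", "i", "ii", "ii"))
  X <- matrix(c(0, 0.1, 5, 5.1, 0, 0.1, 5, 5.1), 4, 2,
              dimnames = list(df$image_path, c("f1", "f2")))
  fold <- ihcloc:::stratified_folds(df$label, 2, seed = 1)
  expect_equal(as.integer(table(fold)), c(2L, 2L))
  cv <- suppressWarnings(crossval(manifest(df), X, mode = "per_image", k = 2,
                                  seed = 1, grid = list(c = 1, g = 1)))
  expect_equal(sum(cv$confusion), 4)
})

test_that("metrics match hand computation and permutation symmetry", {
  perfect <- diag(c(5L, 3L, 2L))
  m <- compute_metrics(perfect)
  expect_equal(unlist(m), c(accuracy = 1, macro_recall = 1,
                            macro_precision = 1, f1 = 1))
  conf <- matrix(c(5, 0, 0, 0, 0, 5, 0, 0, 5), 3, 3, byrow = TRUE)
  m2 <- suppressWarnings(compute_metrics(conf))
  expect_equal(m2$accuracy, 10 / 15)
  expect_equal(m2$macro_recall, (1 + 0 + 1) / 3)
  expect_equal(m2$f1, 2 * m2$macro_precision * m2$macro_recall /
                 (m2$macro_precision + m2$macro_recall), tolerance = 1e-9)
  perm <- c(3, 1, 2)
  expect_equal(suppressWarnings(compute_metrics(conf[perm, perm]))$accuracy,
               m2$accuracy)
  expect_error(compute_metrics(matrix(0, 3, 3)), "all zero")
})

test_that("protein vote follows majority with mean-score tie-break", {
  s3 <- matrix(1 / 3, 3, 3)
  expect_equal(protein_vote(c("i", "i", "ii"), s3), "i")
  tie <- matrix(c(0.4, 0.6, 0, 0.1, 0.9, 0), 2, 3, byrow = TRUE)
  expect_equal(protein_vote(c("i", "ii"), tie), "ii")
  # brute-force oracle over random vote sets
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(1:7, 1)
    sc <- matrix(runif(3 * n), n, 3)
    sc <- sc / rowSums(sc)
    labs <- c("i", "ii", "iii")[max.col(sc)]
    counts <- table(factor(labs, levels = c("i", "ii", "iii")))
    top <- names(counts)[counts == max(counts)]
    want <- if (length(top) == 1) top else {
      ms <- colMeans(sc); names(ms) <- c("i", "ii", "iii")
      top[which.max(ms[top])]
    }
    expect_equal(protein_vote(labs, sc), want)
  }
})
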