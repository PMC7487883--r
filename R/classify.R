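# RBF-SVM classification of localization classes, with grid-searched
# hyperparameters, per-image / per-protein cross-validation and
# protein-level voting. The SVM is libsvm (via e1071), the toolbox family
# the pipeline was designed around; multiclass handling is one-vs-one
# with pairwise-coupled probability estimates.

#' Default RBF hyperparameter grid
#'
#' The standard coarse grid: `c = 2^(-5), 2^(-3), ..., 2^15` and
#' `g = 2^(-15), 2^(-13), ..., 2^3`.
#'
#' @return list with `c` and `g` numeric vectors.
#' @export
default_svm_grid <- function() {
  list(c = 2^seq(-5, 15, by = 2), g = 2^seq(-15, 3, by = 2))
}

# Compact grid used by the cross-validation and pipeline defaults; the
# full coarse grid is available through default_svm_grid().
small_svm_grid <- function() list(c = 2^c(-1, 3, 7), g = 2^c(-9, -5, -1))

minmax_fit <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  hi[hi - lo < .Machine$double.eps] <- lo[hi - lo < .Machine$double.eps] + 1
  list(lo = lo, hi = hi)
}
minmax_apply <- function(X, s) {
  X <- sweep(X, 2, s$lo, "-")
  X <- sweep(X, 2, s$hi - s$lo, "/")
  X[X < 0] <- 0; X[X > 1] <- 1
  X
}

#' Train an RBF-kernel SVM with hyperparameter grid search
#'
#' Features are min-max scaled to `[0, 1]` with statistics from the
#' training data; `(c, g)` is chosen by inner 5-fold cross-validated
#' accuracy (ties break to the smaller `c`, then the smaller `g`), and
#' the final model is refit on all data with probability outputs.
#'
#' @param X numeric matrix (samples x features, named columns).
#' @param y class labels (factors over `"i"`, `"ii"`, `"iii"` or any
#'   >= 2-level labeling).
#' @param grid list with `c` and `g` vectors; default [small_svm_grid]
#'   behavior via `default_svm_grid()` is available for exhaustive runs.
#' @param seed integer seed (inner-fold assignment).
#' @param inner_k inner folds for the grid search (default 5).
#' @return A `TrainedModel` list: `svm`, `scaler`, `classes`, `columns`,
#'   `c`, `g`.
#' @export
train_svm <- function(X, y, grid = small_svm_grid(), seed = 1L, inner_k = 5L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  stopifnot(length(grid$c) >= 1, length(grid$g) >= 1)
  sc <- minmax_fit(X)
  Xs <- minmax_apply(X, sc)

  cells <- expand.grid(g = sort(grid$g), c = sort(grid$c))[, c("c", "g")]
  cells <- cells[order(cells$c, cells$g), ]
  best <- NULL; best_acc <- -1
  if (nrow(cells) == 1L) {
    best <- cells[1, ]
  } else {
    k <- min(inner_k, min(table(y)))
    for (i in seq_len(nrow(cells))) {
      set.seed(seed)
      acc <- tryCatch({
        m <- e1071::svm(Xs, y, kernel = "radial", cost = cells$c[i],
                        gamma = cells$g[i], cross = max(k, 2), scale = FALSE)
        m$tot.accuracy / 100
      }, error = function(e) -Inf)
      if (acc > best_acc + 1e-12) { best_acc <- acc; best <- cells[i, ] }
    }
  }
  set.seed(seed + 1L)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = best$c, gamma = best$g,
                    probability = TRUE, scale = FALSE)
  structure(list(svm = fit, scaler = sc, classes = levels(y),
                 columns = colnames(X), c = best$c, g = best$g),
            class = "TrainedModel")
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel (RBF SVM): %d features, classes {%s}, c=%g g=%g\n",
              length(x$columns), paste(x$classes, collapse = ","), x$c, x$g))
  invisible(x)
}

#' Class-probability scores for new samples
#'
#' @param model a `TrainedModel`.
#' @param X matrix whose columns match the training columns (matched by
#'   name when both are named).
#' @return rows x 3 matrix of probabilities over classes
#'   `i`, `ii`, `iii` (absent training classes get probability 0); rows
#'   sum to 1.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "TrainedModel"))
  X <- as.matrix(X)
  if (!is.null(model$columns) && !is.null(colnames(X))) {
    missing <- setdiff(model$columns, colnames(X))
    if (length(missing))
      stop("feature columns missing from input: ",
           paste(head(missing, 5), collapse = ", "))
    X <- X[, model$columns, drop = FALSE]
  } else if (ncol(X) != length(model$columns)) {
    stop("feature count mismatch: model expects ", length(model$columns),
         ", got ", ncol(X))
  }
  Xs <- minmax_apply(X, model$scaler)
  pr <- attr(predict(model$svm, Xs, probability = TRUE), "probabilities")
  out <- matrix(0, nrow(X), 3, dimnames = list(rownames(X), LABEL_LEVELS))
  out[, colnames(pr)[colnames(pr) %in% LABEL_LEVELS]] <-
    pr[, colnames(pr)[colnames(pr) %in% LABEL_LEVELS], drop = FALSE]
  out / rowSums(out)
}

# Stratified fold assignment over instances (seeded).
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Grouped fold assignment: whole groups to folds, balanced by size.
grouped_folds <- function(groups, k, seed) {
  set.seed(seed)
  gid <- unique(groups)
  if (length(gid) < k) stop("fewer groups (", length(gid), ") than folds (", k, ")")
  sizes <- table(groups)[gid]
  ord <- sample(seq_along(gid))           # shuffle, then greedy size balance
  gid <- gid[ord]; sizes <- sizes[ord]
  gid <- gid[order(-sizes)]
  load <- numeric(k); gfold <- setNames(integer(length(gid)), gid)
  for (g in gid) {
    f <- which.min(load)
    gfold[g] <- f
    load[f] <- load[f] + sum(groups == g)
  }
  unname(gfold[as.character(groups)])
}

#' Cross-validated evaluation under per-image or per-protein partitions
#'
#' `per_image` uses stratified k-folds over images; `per_protein` uses
#' grouped k-folds over proteins so that no protein contributes images
#' to both the training and test side of any fold — the partition that
#' measures generalization to new proteins. Held-out predictions are
#' aggregated into one confusion matrix.
#'
#' @param man a `DatasetManifest`; rows with label `"unknown"` are
#'   excluded.
#' @param features numeric matrix with one row per manifest record
#'   (rownames = image_path).
#' @param mode `"per_image"` or `"per_protein"`.
#' @param k folds (default 10).
#' @param seed fold-assignment and SVM seed.
#' @param grid SVM hyperparameter grid.
#' @param max_k optional SDA cap: when non-NULL, [sda_select()] runs on
#'   each training fold and the model uses only the selected columns.
#' @return An `EvalReport`: `confusion` (3x3, true x predicted),
#'   `accuracy`, `macro_recall`, `macro_precision`, `f1`, `mode`, `k`,
#'   plus `predictions` (per-image held-out labels and scores).
#' @export
crossval <- function(man, features, mode = c("per_image", "per_protein"),
                     k = 10L, seed = 1L, grid = small_svm_grid(),
                     max_k = NULL) {
  mode <- match.arg(mode)
  stopifnot(k >= 2)
  rec <- man$records
  keep <- rec$label %in% LABEL_LEVELS
  rec <- rec[keep, , drop = FALSE]
  X <- as.matrix(features)[keep, , drop = FALSE]
  y <- factor(rec$label, levels = LABEL_LEVELS)

  fold <- if (mode == "per_image") stratified_folds(as.character(y), k, seed)
          else grouped_folds(rec$protein_id, k, seed)

  conf <- matrix(0L, 3, 3, dimnames = list(true = LABEL_LEVELS,
                                           pred = LABEL_LEVELS))
  pred_lab <- character(nrow(rec))
  pred_scores <- matrix(NA_real_, nrow(rec), 3,
                        dimnames = list(rec$image_path, LABEL_LEVELS))
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    cols <- seq_len(ncol(X))
    if (!is.null(max_k)) {
      sel <- suppressWarnings(
        sda_select(X[tr, , drop = FALSE], droplevels(y[tr]), max_k = max_k))
      if (length(sel$selected)) cols <- sel$selected
    }
    m <- train_svm(X[tr, cols, drop = FALSE], droplevels(y[tr]),
                   grid = grid, seed = seed + f)
    sc <- predict_scores(m, X[te, cols, drop = FALSE])
    pl <- LABEL_LEVELS[max.col(sc, ties.method = "first")]
    pred_lab[te] <- pl
    pred_scores[te, ] <- sc
    for (i in which(te))
      conf[as.character(y[i]), pred_lab[i]] <- conf[as.character(y[i]), pred_lab[i]] + 1L
  }
  met <- compute_metrics(conf)
  structure(c(list(confusion = conf, mode = mode, k = k,
                   predictions = data.frame(image_path = rec$image_path,
                                            protein_id = rec$protein_id,
                                            tissue_state = rec$tissue_state,
                                            true = as.character(y),
                                            pred = pred_lab,
                                            stringsAsFactors = FALSE),
                   scores = pred_scores),
              met), class = "EvalReport")
}

#' Classification metrics from a 3x3 confusion matrix
#'
#' Accuracy is trace/total; recall and precision are macro (unweighted
#' class means, classes with no true/predicted samples excluded with a
#' warning); F1 is the harmonic mean of macro precision and macro
#' recall.
#'
#' @param confusion non-negative integer matrix, rows = true classes.
#' @return list: `accuracy`, `macro_recall`, `macro_precision`, `f1`.
#' @export
compute_metrics <- function(confusion) {
  conf <- as.matrix(confusion)
  total <- sum(conf)
  if (total == 0) stop("confusion matrix is all zero")
  acc <- sum(diag(conf)) / total
  rs <- rowSums(conf); cs <- colSums(conf)
  if (any(rs == 0)) warning("class(es) with no true samples excluded from macro recall")
  rec <- mean(diag(conf)[rs > 0] / rs[rs > 0])
  if (any(cs == 0)) warning("class(es) never predicted excluded from macro precision")
  prec <- mean(diag(conf)[cs > 0] / cs[cs > 0])
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = acc, macro_recall = rec, macro_precision = prec, f1 = f1)
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (%s, %d-fold): accuracy %.3f, macro recall %.3f, macro precision %.3f, F1 %.3f\n",
              x$mode, x$k, x$accuracy, x$macro_recall, x$macro_precision, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Protein-level label by majority vote
#'
#' Majority vote over per-image predicted labels; ties break to the tied
#' class with the largest mean score across the protein's images.
#'
#' @param labels character vector of per-image predicted labels.
#' @param scores rows x 3 score matrix aligned with `labels`.
#' @return The winning label.
#' @export
protein_vote <- function(labels, scores) {
  stopifnot(length(labels) >= 1)
  counts <- table(factor(labels, levels = LABEL_LEVELS))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  mean_sc <- colMeans(matrix(scores, ncol = 3,
                             dimnames = list(NULL, LABEL_LEVELS)))
  top[which.max(mean_sc[top])]
}
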