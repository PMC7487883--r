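# Stepwise discriminant analysis (SDA).
#
# Features are ranked by how much they reduce Wilks' lambda
# Lambda = det(W) / det(T), the ratio of within-class to total scatter
# determinants restricted to the candidate subset. The classic forward
# procedure enters the feature with the largest partial F if it exceeds
# f_enter, then removes any entered feature whose partial F has dropped
# below f_remove; partial F values come from the Schur-complement ratio
# Lambda_{p+1} / Lambda_p, so each step costs O(p^2) per candidate.

# Centered data matrices: Xt total-centered, Xw class-centered, so that
# T = crossprod(Xt) and W = crossprod(Xw).
center_scatter <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  Xt <- scale(X, center = TRUE, scale = FALSE)
  Xw <- X
  for (lv in levels(y)) {
    idx <- which(y == lv)
    Xw[idx, ] <- scale(X[idx, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  list(Xt = Xt, Xw = Xw, n = nrow(X), g = nlevels(y))
}

#' Wilks' lambda of a feature subset
#'
#' `Lambda = det(W) / det(T)` for the within-class scatter `W` and total
#' scatter `T` restricted to `subset`; `0 < Lambda <= 1`, smaller is more
#' discriminative. A singular total scatter is ridge-stabilized
#' (`lambda = 1e-8 * trace`) with a warning.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels (>= 2 classes, each with >= 2 samples).
#' @param subset column indices (default all columns).
#' @return Wilks' lambda scalar.
#' @export
wilks_lambda <- function(X, y, subset = seq_len(ncol(as.matrix(X)))) {
  cs <- center_scatter(X, y)
  if (!length(subset)) stop("subset must be non-empty")
  W <- crossprod(cs$Xw[, subset, drop = FALSE])
  T <- crossprod(cs$Xt[, subset, drop = FALSE])
  dT <- det(T)
  if (!is.finite(dT) || dT <= .Machine$double.eps * max(diag(T), 1)^length(subset)) {
    lam <- 1e-8 * max(sum(diag(T)), 1)
    warning("singular total scatter; ridge-stabilized with lambda = ", signif(lam, 3))
    W <- W + diag(lam, nrow(W))
    T <- T + diag(lam, nrow(T))
    dT <- det(T)
  }
  max(min(det(W) / dT, 1), .Machine$double.xmin)
}

#' Stepwise discriminant feature selection
#'
#' Forward selection with backward elimination on Wilks' lambda partial-F
#' statistics. At each step the feature with the largest partial F enters
#' if it exceeds `f_enter`; afterwards any entered feature whose partial
#' F falls below `f_remove` is removed. Stops when no feature can enter
#' or `max_k` features are selected. Deterministic; ties break to the
#' lower column index.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels.
#' @param f_enter,f_remove F thresholds, `f_enter > f_remove > 0`
#'   (defaults 3.84 / 2.71, the chi-square-1 conventions).
#' @param max_k maximum number of selected features; default
#'   `min(200, floor(n/3))` to keep the scatter well-conditioned.
#' @return An `SDAResult` list: `selected` (ordered column indices),
#'   `wilks_trace` (lambda after each accepted step, strictly
#'   decreasing), `f_enter`, `f_remove`.
#' @export
sda_select <- function(X, y, f_enter = 3.84, f_remove = 2.71,
                       max_k = min(200L, nrow(as.matrix(X)) %/% 3L)) {
  stopifnot(f_enter > f_remove, f_remove > 0)
  X <- as.matrix(X)
  max_k <- min(max_k, ncol(X))
  cs <- center_scatter(X, y)
  n <- cs$n; g <- cs$g
  wdiag <- colSums(cs$Xw^2)
  tdiag <- colSums(cs$Xt^2)
  tol <- 1e-10 * max(tdiag, 1)

  S <- integer(0)
  lambda <- 1
  trace <- numeric(0)
  WSS_inv <- TSS_inv <- matrix(0, 0, 0)

  # Schur complements of every candidate given the current subset:
  # ratio_j = Lambda_{S+j} / Lambda_S.
  schur_ratios <- function() {
    if (!length(S)) {
      num <- wdiag; den <- tdiag
    } else {
      WS <- crossprod(cs$Xw[, S, drop = FALSE], cs$Xw)   # p x k
      TS <- crossprod(cs$Xt[, S, drop = FALSE], cs$Xt)
      num <- wdiag - colSums((WSS_inv %*% WS) * WS)
      den <- tdiag - colSums((TSS_inv %*% TS) * TS)
    }
    ratio <- num / den
    ratio[!is.finite(ratio) | den <= tol] <- 1   # no independent variance
    ratio[ratio > 1] <- 1
    ratio[ratio < 0] <- 0
    ratio
  }

  refresh_inverses <- function() {
    if (length(S)) {
      WSS_inv <<- solve(crossprod(cs$Xw[, S, drop = FALSE]) +
                        diag(tol, length(S)))
      TSS_inv <<- solve(crossprod(cs$Xt[, S, drop = FALSE]) +
                        diag(tol, length(S)))
    }
  }

  repeat {
    if (length(S) >= max_k) break
    p <- length(S)
    ratio <- schur_ratios()
    ratio[S] <- 1
    Fent <- ((n - g - p) / (g - 1)) * (1 / ratio - 1)
    Fent[!is.finite(Fent)] <- 0
    best <- which.max(Fent)          # which.max takes the first (lowest index) tie
    if (Fent[best] <= f_enter) {
      if (!length(S)) warning("no feature passes f_enter; empty selection")
      break
    }
    S <- c(S, best)
    lambda <- lambda * ratio[best]
    trace <- c(trace, lambda)
    refresh_inverses()

    # backward pass: drop any feature whose partial F fell below f_remove
    repeat {
      if (length(S) < 2) break
      p <- length(S)
      Frem <- vapply(seq_along(S), function(i) {
        rest <- S[-i]
        lam_wo <- wilks_subset(cs, rest, tol)
        ((n - g - p + 1) / (g - 1)) * (lam_wo / lambda - 1)
      }, 0.0)
      worst <- which.min(Frem)
      if (Frem[worst] >= f_remove) break
      if (S[worst] == S[length(S)]) break   # never remove the feature just entered
      lambda <- wilks_subset(cs, S[-worst], tol)
      S <- S[-worst]
      trace <- c(trace, lambda)
      refresh_inverses()
    }
  }
  structure(list(selected = S, wilks_trace = trace,
                 f_enter = f_enter, f_remove = f_remove),
            class = "SDAResult")
}

# Wilks' lambda of a subset from precomputed centered data.
wilks_subset <- function(cs, subset, tol) {
  W <- crossprod(cs$Xw[, subset, drop = FALSE]) + diag(tol, length(subset))
  T <- crossprod(cs$Xt[, subset, drop = FALSE]) + diag(tol, length(subset))
  max(min(det(W) / det(T), 1), .Machine$double.xmin)
}

#' @export
print.SDAResult <- function(x, ...) {
  cat(sprintf("SDAResult: %d features selected, final Wilks' lambda %.4g\n",
              length(x$selected),
              if (length(x$wilks_trace)) x$wilks_trace[length(x$wilks_trace)] else 1))
  invisible(x)
}
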