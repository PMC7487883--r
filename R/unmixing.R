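# Stain unmixing: optical-density transform, fixed-basis linear unmixing
# (LIN) and per-image blind rank-2 NMF.
#
# In brightfield IHC the two chromogens (hematoxylin on DNA, DAB on the
# target protein) absorb light multiplicatively; taking the optical
# density OD = -log10(I / I0) makes their contributions additive
# (Beer-Lambert), so per-pixel stain concentrations are recovered by
# linear algebra on the OD vectors.

#' Optical-density transform
#'
#' `OD = -log10((pixel + eps) / 255)` per channel with `eps = 1` to avoid
#' `log(0)`; all OD values are >= 0.
#'
#' @param image an `IHCImage` or an H x W x 3 array of 8-bit values.
#' @param eps additive offset in gray levels (default 1).
#' @return H x W x 3 numeric array of optical densities.
#' @export
od_transform <- function(image, eps = 1) {
  px <- if (inherits(image, "IHCImage")) image$pixels else image
  od <- -log10((px + eps) / 255)
  od[od < 0] <- 0
  od
}

# Inverse of od_transform (used by round-trip tests and re-rendering).
od_inverse <- function(od, eps = 1) {
  px <- 255 * 10^(-od) - eps
  pmin(pmax(round(px), 0), 255)
}

# Core solver: least-squares projection of per-pixel OD vectors onto the
# two basis rows via the pseudo-inverse, negatives clipped to zero.
unmix_od <- function(od, basis) {
  B <- unclass(basis)
  g <- B %*% t(B)
  if (kappa(g, exact = TRUE) > 1e8)
    stop("stain basis is numerically singular (condition number > 1e8)")
  d <- dim(od)
  odm <- matrix(od, ncol = 3)                 # (H*W) x 3
  conc <- odm %*% t(B) %*% solve(g)           # (H*W) x 2, rows (dna, protein)
  conc[conc < 0] <- 0
  list(dna = matrix(conc[, 1], d[1], d[2]),
       protein = matrix(conc[, 2], d[1], d[2]))
}

#' Linear spectral unmixing with a fixed stain basis
#'
#' One empirical color-base matrix separates every image: per-pixel
#' least-squares projection of the OD vector onto the two stain rows,
#' negative solutions clipped at zero (concentrations are physical).
#'
#' @param image an `IHCImage`, or an H x W x 3 numeric array interpreted
#'   directly as an optical-density map (useful for exact noise-free
#'   validation without 8-bit quantization).
#' @param basis a `StainBasis`; default [default_basis()].
#' @return A `StainChannels` list: `protein`, `dna` (H x W non-negative
#'   maps), `basis_used`, `method = "LIN"`.
#' @export
unmix_linear <- function(image, basis = default_basis()) {
  od <- if (inherits(image, "IHCImage")) od_transform(image) else image
  ch <- unmix_od(od, basis)
  structure(list(protein = ch$protein, dna = ch$dna,
                 basis_used = basis, method = "LIN"),
            class = "StainChannels")
}

#' @export
print.StainChannels <- function(x, ...) {
  cat(sprintf("StainChannels (%s) %dx%d  protein OD range [%.3g, %.3g]\n",
              x$method, nrow(x$protein), ncol(x$protein),
              min(x$protein), max(x$protein)))
  invisible(x)
}

# Deterministic extreme-ray initialization for rank-2 NMF of A (n x 3):
# project OD pixels onto their top-2 singular plane and take the color
# directions at the extreme angular percentiles (the geometry of
# SVD-based stain estimation). Rank-2 NMF is only identified up to a
# cone; starting at the data cone's extreme rays makes the fitted basis
# land on the true stain vectors whenever near-pure pixels of each
# stain exist. Seeded random fallback if the projection is degenerate.
extreme_ray_init <- function(A, seed, qlo = 0.01, qhi = 0.99) {
  keep <- rowSums(A) > 0.05
  Ak <- A[keep, , drop = FALSE]
  H <- tryCatch({
    s <- svd(Ak, nu = 0, nv = 2)
    proj <- Ak %*% s$v
    ang <- stats::quantile(atan2(proj[, 2], proj[, 1]), c(qlo, qhi))
    H0 <- rbind(cos(ang[1]) * s$v[, 1] + sin(ang[1]) * s$v[, 2],
                cos(ang[2]) * s$v[, 1] + sin(ang[2]) * s$v[, 2])
    H0[H0 < 0] <- 0
    if (any(rowSums(H0^2) < 1e-8)) stop("degenerate ray")
    H0 / sqrt(rowSums(H0^2))
  }, error = function(e) {
    set.seed(seed)
    matrix(runif(6, 0.1, 1), 2, 3)
  })
  W <- A %*% t(H) %*% solve(H %*% t(H) + diag(1e-9, 2))
  list(W = pmax(W, 1e-9), H = pmax(H, 1e-9))
}

#' Blind stain unmixing by rank-2 NMF
#'
#' Fits a per-image 2 x 3 stain basis by non-negative matrix
#' factorization of the (pixels x 3) OD matrix with multiplicative
#' updates (Frobenius objective), deterministic extreme-ray (angular
#' percentile) initialization with a seeded random fallback. The fitted
#' rows are unit-normalized and matched to a reference basis with
#' [match_channels()] so the output channel order is (dna, protein).
#'
#' @param image an `IHCImage` or an H x W x 3 OD array.
#' @param seed integer seed (initialization fallback only).
#' @param max_iter iteration cap (default 500).
#' @param tol relative-change convergence tolerance (default 1e-5).
#' @param reference basis used to identify which fitted component is
#'   hematoxylin and which is DAB; default [default_basis()].
#' @return A `StainChannels` with `method = "NMF"` and `basis_used` set to
#'   the fitted (matched, row-normalized) basis.
#' @export
unmix_nmf <- function(image, seed = 1L, max_iter = 500, tol = 1e-5,
                      reference = default_basis()) {
  od <- if (inherits(image, "IHCImage")) od_transform(image) else image
  d <- dim(od)
  A <- matrix(od, ncol = 3)
  keep <- rowSums(A) > 1e-4                 # ignore blank background pixels
  if (sum(keep) < 10 || qr(A[keep, , drop = FALSE])$rank < 2)
    stop("image is degenerate for blind unmixing (needs >= 2 distinct stain colors)")

  init <- extreme_ray_init(A, seed)
  W <- init$W; H <- init$H
  err_prev <- Inf
  scale_A <- sqrt(sum(A^2))
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% A) / pmax(t(W) %*% W %*% H, 1e-12)
    W <- W * (A %*% t(H)) / pmax(W %*% H %*% t(H), 1e-12)
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((A - W %*% H)^2))
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, 1e-6 * scale_A)) break
      err_prev <- err
    }
  }
  if (it == max_iter)
    warning("NMF did not converge within ", max_iter,
            " iterations; returning best iterate")

  # absorb row norms of H into W, so H rows are unit color vectors
  nrm <- sqrt(rowSums(H^2))
  H <- H / nrm
  W <- W * rep(nrm, each = nrow(W))
  perm <- match_channels(stain_basis(pmax(H, 0)), reference)
  H <- H[perm, , drop = FALSE]
  W <- W[, perm, drop = FALSE]
  structure(list(protein = matrix(W[, 2], d[1], d[2]),
                 dna = matrix(W[, 1], d[1], d[2]),
                 basis_used = stain_basis(pmax(H, 0)), method = "NMF"),
            class = "StainChannels")
}

#' Match fitted stain components to a reference basis
#'
#' NMF component order is arbitrary; this returns the row permutation of
#' the fitted basis that maximizes the summed row-wise cosine similarity
#' to the reference. Ties break to the identity permutation.
#'
#' @param fitted_basis,reference `StainBasis` objects.
#' @return Integer permutation vector of length 2: `fitted_basis[perm, ]`
#'   aligns with `reference`.
#' @export
match_channels <- function(fitted_basis, reference) {
  F <- unclass(fitted_basis); R <- unclass(reference)
  cosim <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  s_id <- cosim(F[1, ], R[1, ]) + cosim(F[2, ], R[2, ])
  s_sw <- cosim(F[2, ], R[1, ]) + cosim(F[1, ], R[2, ])
  if (s_sw > s_id) c(2L, 1L) else c(1L, 2L)
}
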