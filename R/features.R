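# Engineered per-patch features: 16 DNA colocalization/distance features,
# 576 Haralick texture features on wavelet subbands, 256 local binary
# pattern features — 848 per patch.

#' Haralick configuration
#'
#' @param wavelet_filter Daubechies filter `"db1"` .. `"db10"`.
#' @param levels wavelet decomposition depth (default 5, giving
#'   `3*5 + 1 = 16` subbands).
#' @param gray_levels GLCM quantization bins (default 32).
#' @return A `HaralickConfig` list. Feature count is
#'   `(3*levels + 1) * 4 offsets * 9 statistics` = 576 at defaults.
#' @export
haralick_config <- function(wavelet_filter = "db4", levels = 5L,
                            gray_levels = 32L) {
  db_filters(wavelet_filter)
  stopifnot(levels >= 1, gray_levels >= 2)
  structure(list(wavelet_filter = wavelet_filter, levels = as.integer(levels),
                 gray_levels = as.integer(gray_levels)),
            class = "HaralickConfig")
}

GLCM_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

HARALICK_STAT_NAMES <- c("energy", "contrast", "correlation", "variance",
                         "homogeneity", "sum_average", "entropy",
                         "sum_entropy", "diff_entropy")

# Otsu threshold on a numeric vector (256-bin); returns the cut value.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(mean(x))     # unimodal fallback
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-257]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  thr <- mids[which.max(sigma_b)]
  # degenerate split (empty side) -> mean fallback
  if (!any(x > thr) || !any(x <= thr)) mean(x) else thr
}

# Euclidean distance from every pixel to the nearest TRUE pixel of mask.
dist_to_mask <- function(mask) {
  dm <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask)), metric = "euclidean")
  as.matrix(dm)
}

#' DNA colocalization and distance features (16 values)
#'
#' Both channels are binarized by Otsu's threshold (mean fallback for
#' unimodal windows) into a protein mask P and DNA mask D, then, in fixed
#' order: (1) area(D)/area(P); (2) |P∩D|/|P|; (3) |P∩D|/|D|; (4) total
#' DNA / total protein intensity; (5) Manders-style M1 — protein
#' intensity in P∩D over protein intensity in P; (6) M2 — DNA intensity
#' in P∩D over DNA intensity in D; (7) Pearson correlation of the two
#' intensity maps over P∪D; (8) intensity-weighted centroid distance
#' normalized by the window diagonal; (9–12) mean, median, sd, max of
#' distances from P pixels to the nearest D pixel (diagonal-normalized);
#' (13–16) the same from D to P. Degenerate denominators give 0;
#' empty-mask distance statistics are imputed at the diagonal (value 1).
#'
#' @param patch_protein,patch_dna equal-shape numeric windows.
#' @return Named numeric vector of length 16, prefix `dna.`.
#' @export
dna_features <- function(patch_protein, patch_dna) {
  stopifnot(all(dim(patch_protein) == dim(patch_dna)))
  P <- patch_protein > otsu_threshold(patch_protein)
  D <- patch_dna > otsu_threshold(patch_dna)
  diag_len <- sqrt(sum(dim(patch_protein)^2))
  sdiv <- function(a, b) if (b > 0) a / b else 0

  inter <- sum(P & D)
  f <- numeric(16)
  f[1] <- sdiv(sum(D), sum(P))
  f[2] <- sdiv(inter, sum(P))
  f[3] <- sdiv(inter, sum(D))
  f[4] <- sdiv(sum(patch_dna), sum(patch_protein))
  f[5] <- sdiv(sum(patch_protein[P & D]), sum(patch_protein[P]))
  f[6] <- sdiv(sum(patch_dna[P & D]), sum(patch_dna[D]))
  un <- P | D
  f[7] <- if (sum(un) > 1 && sd(patch_protein[un]) > 0 && sd(patch_dna[un]) > 0)
            cor(patch_protein[un], patch_dna[un]) else 0
  cen <- function(w) {
    tot <- sum(w)
    if (tot <= 0) return(c(NA, NA))
    c(sum(row(w) * w), sum(col(w) * w)) / tot
  }
  cp <- cen(patch_protein); cd <- cen(patch_dna)
  f[8] <- if (anyNA(c(cp, cd))) 0 else sqrt(sum((cp - cd)^2)) / diag_len

  dstats <- function(from, to) {
    if (!any(from) || !any(to)) return(rep(1, 4))  # maximal imputation
    d <- dist_to_mask(to)[from] / diag_len
    c(mean(d), median(d), if (length(d) > 1) sd(d) else 0, max(d))
  }
  f[9:12] <- dstats(P, D)
  f[13:16] <- dstats(D, P)
  names(f) <- paste0("dna.", c("area_ratio", "overlap_p", "overlap_d",
                               "intensity_ratio", "manders_m1", "manders_m2",
                               "pearson", "centroid_dist",
                               "pd_mean", "pd_median", "pd_sd", "pd_max",
                               "dp_mean", "dp_median", "dp_sd", "dp_max"))
  f
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence probabilities of quantized values at a fixed
#' pixel offset.
#'
#' @param quantized integer matrix with values in `[0, gray_levels)`.
#' @param offset length-2 integer `(dr, dc)`.
#' @param gray_levels number of gray levels.
#' @return `gray_levels` x `gray_levels` matrix summing to 1.
#' @export
glcm <- function(quantized, offset, gray_levels) {
  dr <- offset[1]; dc <- offset[2]
  h <- nrow(quantized); w <- ncol(quantized)
  if (h <= abs(dr) || w <= abs(dc))
    stop("window (", h, "x", w, ") is smaller than the offset span")
  if (min(quantized) < 0 || max(quantized) >= gray_levels)
    stop("quantized values must lie in [0, gray_levels)")
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  a <- quantized[r1, c1, drop = FALSE]
  b <- quantized[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate(a * gray_levels + b + 1L, nbins = gray_levels^2)
  M <- matrix(counts, gray_levels, gray_levels, byrow = TRUE)
  M <- M + t(M)                       # symmetrize
  M / sum(M)
}

#' Haralick statistics of a GLCM (9 values)
#'
#' Energy, contrast, correlation, variance, homogeneity (inverse
#' difference moment), sum average, entropy, sum entropy and difference
#' entropy, in that order. Logarithms are base 2 with `0*log(0) := 0`;
#' zero-variance correlation is 0.
#'
#' @param P normalized GLCM.
#' @return Named numeric vector of length 9.
#' @export
haralick_stats <- function(P) {
  G <- nrow(P)
  v <- seq_len(G) - 1
  px <- rowSums(P); py <- colSums(P)
  I <- row(P) - 1; J <- col(P) - 1
  xlog2 <- function(p) { s <- p > 0; -sum(p[s] * log2(p[s])) }
  mux <- sum(v * px); muy <- sum(v * py)
  sx <- sqrt(sum((v - mux)^2 * px)); sy <- sqrt(sum((v - muy)^2 * py))

  psum <- vapply(0:(2 * G - 2), function(k) sum(P[I + J == k]), 0.0)
  pdif <- vapply(0:(G - 1), function(k) sum(P[abs(I - J) == k]), 0.0)

  out <- c(
    energy       = sum(P^2),
    contrast     = sum((I - J)^2 * P),
    correlation  = if (sx > 0 && sy > 0)
                     sum((I - mux) * (J - muy) * P) / (sx * sy) else 0,
    variance     = sum((I - mux)^2 * P),
    homogeneity  = sum(P / (1 + (I - J)^2)),
    sum_average  = sum((0:(2 * G - 2)) * psum),
    entropy      = xlog2(P),
    sum_entropy  = xlog2(psum),
    diff_entropy = xlog2(pdif)
  )
  names(out) <- HARALICK_STAT_NAMES
  out
}

# Min-max quantization of a subband to [0, G) integer bins; a constant
# subband maps every pixel to bin 0.
quantize_minmax <- function(m, gray_levels) {
  rng <- range(m)
  # near-constant guard: do not let quantization amplify float noise in
  # (analytically zero) detail subbands
  if (diff(rng) <= 1e-10 * max(1, abs(rng))) return(matrix(0L, nrow(m), ncol(m)))
  q <- floor((m - rng[1]) / diff(rng) * gray_levels)
  q[q >= gray_levels] <- gray_levels - 1L
  storage.mode(q) <- "integer"
  q
}

# Degenerate-subband imputation: statistics of the delta GLCM (all mass
# at (0,0)), used when a subband is too small for the offset span.
DEGENERATE_HARALICK <- c(energy = 1, contrast = 0, correlation = 0,
                         variance = 0, homogeneity = 1, sum_average = 0,
                         entropy = 0, sum_entropy = 0, diff_entropy = 0)

#' Haralick-on-wavelet texture features (576 values)
#'
#' Decomposes the protein window into `3*levels + 1` wavelet subbands,
#' min-max quantizes each to `gray_levels` bins, and computes the 9
#' Haralick statistics of the GLCM at the four unit-distance offsets
#' (0°, 45°, 90°, 135°), concatenated in (subband, offset, statistic)
#' order: 16 x 4 x 9 = 576 values at defaults. Subbands too small for an
#' offset get the degenerate single-entry-GLCM statistics.
#'
#' @param patch_protein numeric window (side >= `2^levels`).
#' @param cfg a [haralick_config()].
#' @return Named numeric vector of length 576 (defaults), prefix
#'   `har.<filter>.`.
#' @export
haralick_features <- function(patch_protein, cfg = haralick_config()) {
  sb <- wavelet_subbands(patch_protein, cfg$wavelet_filter, cfg$levels)
  out <- numeric(0)
  for (bn in names(sb)) {
    q <- quantize_minmax(sb[[bn]], cfg$gray_levels)
    for (off in names(GLCM_OFFSETS)) {
      o <- GLCM_OFFSETS[[off]]
      st <- if (nrow(q) > abs(o[1]) && ncol(q) > abs(o[2]))
        haralick_stats(glcm(q, o, cfg$gray_levels))
      else DEGENERATE_HARALICK
      names(st) <- sprintf("har.%s.%s.o%s.%s", cfg$wavelet_filter, bn, off,
                           HARALICK_STAT_NAMES)
      out <- c(out, st)
    }
  }
  out
}

#' Local binary pattern histogram (256 values)
#'
#' Classic 8-neighbor radius-1 LBP: for every interior pixel, bit `b` is
#' set iff neighbor `b` >= the center value, neighbors ordered clockwise
#' from the top-left (top-left = least significant bit). Returns the
#' 256-bin code histogram normalized to sum 1. A constant window puts
#' all mass at code 255 (every neighbor ties the center).
#'
#' @param patch_protein numeric window, at least 3 x 3.
#' @return Named numeric vector of length 256, prefix `lbp.`.
#' @export
lbp_features <- function(patch_protein) {
  h <- nrow(patch_protein); w <- ncol(patch_protein)
  if (h < 3 || w < 3) stop("LBP needs a window of at least 3x3")
  ctr <- patch_protein[2:(h - 1), 2:(w - 1)]
  # clockwise from top-left
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, h - 2, w - 2)
  for (b in seq_along(offs)) {
    o <- offs[[b]]
    nb <- patch_protein[(2 + o[1]):(h - 1 + o[1]), (2 + o[2]):(w - 1 + o[2])]
    code <- code + as.integer(nb >= ctr) * 2L^(b - 1L)
  }
  hist <- tabulate(code + 1L, nbins = 256)
  out <- hist / sum(hist)
  names(out) <- sprintf("lbp.c%03d", 0:255)
  out
}

#' Full engineered feature vector for one patch (848 values)
#'
#' Concatenation `[dna(16) | haralick(576) | lbp(256)]` with
#' block-prefixed names.
#'
#' @param patch a `list(protein =, dna =)` window pair (one entry of a
#'   `PatchSet`'s `windows`).
#' @param cfg a [haralick_config()].
#' @return Named numeric vector of length 848; never NaN/Inf.
#' @export
featurize_patch <- function(patch, cfg = haralick_config()) {
  v <- c(dna_features(patch$protein, patch$dna),
         haralick_features(patch$protein, cfg),
         lbp_features(patch$protein))
  stopifnot(length(v) == 848L)
  v[!is.finite(v)] <- 0
  v
}

#' Image-level engineered features by patch averaging
#'
#' Element-wise mean of the per-patch 848-vectors of a `PatchSet`.
#'
#' @param patches a `PatchSet` with at least one patch.
#' @param cfg a [haralick_config()].
#' @return Named numeric vector of length 848.
#' @export
featurize_image <- function(patches, cfg = haralick_config()) {
  stopifnot(inherits(patches, "PatchSet"))
  if (length(patches$windows) == 0) stop("PatchSet is empty")
  M <- vapply(patches$windows, featurize_patch, numeric(848), cfg = cfg)
  rowMeans(M)   # vapply returns 848 x n_patches
}

#' Engineered feature matrix for a whole manifest
#'
#' Reads every image, unmixes it, selects patches and averages the
#' per-patch engineered features into one row per image.
#'
#' @param man a `DatasetManifest`.
#' @param n_patches,patch_size patch selection parameters (defaults 205
#'   and 75, the grid-search optimum for the engineered pipeline).
#' @param wavelet Daubechies filter name.
#' @param unmix `"lin"` or `"nmf"`.
#' @param basis stain basis for LIN.
#' @param max_overlap passed to [select_patches()].
#' @param loader function(path) -> `IHCImage`; override to featurize
#'   in-memory images.
#' @return Numeric matrix, rows = images (rownames = image_path),
#'   848 named columns.
#' @export
featurize_manifest <- function(man, n_patches = 205L, patch_size = 75L,
                               wavelet = "db4", unmix = c("lin", "nmf"),
                               basis = default_basis(), max_overlap = 0.25,
                               loader = read_image) {
  stopifnot(inherits(man, "DatasetManifest"))
  unmix <- match.arg(unmix)
  cfg <- haralick_config(wavelet_filter = wavelet)
  rows <- lapply(seq_len(nrow(man$records)), function(i) {
    img <- loader(man$records$image_path[i])
    ch <- if (unmix == "lin") unmix_linear(img, basis) else
      unmix_nmf(img, seed = i)
    ps <- suppressWarnings(select_patches(ch, n = n_patches, size = patch_size,
                                          max_overlap = max_overlap,
                                          image_ref = man$records$image_path[i]))
    featurize_image(ps, cfg)
  })
  M <- do.call(rbind, rows)
  rownames(M) <- man$records$image_path
  M
}
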