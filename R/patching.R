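# Interest-patch selection.
#
# An IHC image mixes stained glands, unstained stroma and background;
# only regions with high protein expression carry localization
# information. The selector smooths the protein channel with a Gaussian
# low-pass filter, scores candidate square windows on a stride grid by
# their mean smoothed intensity, and greedily keeps the top-scoring
# windows subject to a pairwise overlap cap.

#' Score candidate square windows on the protein channel
#'
#' @param protein H x W protein channel (non-negative).
#' @param size window side length in pixels.
#' @param sigma Gaussian low-pass standard deviation; default `size / 8`.
#' @param stride grid step between candidate top-left corners; default
#'   `floor(size / 2)`.
#' @return data.frame with 0-based `row`, `col` top-left corners and the
#'   `score` (mean smoothed intensity) of each candidate window.
#' @export
score_windows <- function(protein, size, sigma = size / 8,
                          stride = max(1L, size %/% 2L)) {
  h <- nrow(protein); w <- ncol(protein)
  if (size > min(h, w)) stop("patch size ", size, " exceeds image size ", min(h, w))
  stopifnot(sigma > 0, stride >= 1)
  sm <- as.matrix(EBImage::gblur(protein, sigma = sigma))
  # integral image for O(1) window sums
  S <- rbind(0, cbind(0, apply(apply(sm, 2, cumsum), 1, cumsum)))
  S <- t(S)  # apply() transposed; restore (h+1) x (w+1)
  rows <- seq(0L, h - size, by = stride)
  cols <- seq(0L, w - size, by = stride)
  g <- expand.grid(row = rows, col = cols)
  wsum <- S[cbind(g$row + size + 1L, g$col + size + 1L)] -
          S[cbind(g$row + 1L,        g$col + size + 1L)] -
          S[cbind(g$row + size + 1L, g$col + 1L)] +
          S[cbind(g$row + 1L,        g$col + 1L)]
  data.frame(row = g$row, col = g$col, score = wsum / size^2)
}

#' Select high-expression patches from unmixed channels
#'
#' Greedy non-maximum suppression over the scored candidate windows:
#' candidates are visited in order of decreasing score (ties by row then
#' column), and a window is kept unless its area-overlap fraction with an
#' already kept window exceeds `max_overlap`. Stops at `n` patches or
#' when candidates are exhausted (with a warning).
#'
#' @param channels a `StainChannels` (from [unmix_linear()] /
#'   [unmix_nmf()]).
#' @param n number of patches requested.
#' @param size patch side length in pixels.
#' @param max_overlap maximum allowed pairwise area-overlap fraction in
#'   `[0, 1)`; default 0.25.
#' @param sigma,stride passed to [score_windows()].
#' @param image_ref identifier stored on the result.
#' @return A `PatchSet`: list with `image_ref`, `size`, `coords`
#'   (data.frame `row`, `col`, `score`, 0-based, ordered by decreasing
#'   score) and `windows` (list of `list(protein =, dna =)` crops).
#' @export
select_patches <- function(channels, n, size, max_overlap = 0.25,
                           sigma = size / 8, stride = max(1L, size %/% 2L),
                           image_ref = "") {
  stopifnot(inherits(channels, "StainChannels"), n >= 1,
            max_overlap >= 0, max_overlap < 1)
  cand <- score_windows(channels$protein, size, sigma, stride)
  if (all(cand$score == 0))
    warning("protein channel is empty; patches selected by position order")
  ord <- order(-cand$score, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]

  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept) >= n) break
    ok <- TRUE
    for (j in kept) {
      ov_r <- max(0, size - abs(cand$row[i] - cand$row[j]))
      ov_c <- max(0, size - abs(cand$col[i] - cand$col[j]))
      if (ov_r * ov_c / size^2 > max_overlap) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  if (length(kept) < n)
    warning(sprintf("only %d of %d requested patches available", length(kept), n))
  coords <- cand[kept, , drop = FALSE]
  rownames(coords) <- NULL
  windows <- lapply(seq_len(nrow(coords)), function(i) {
    rr <- (coords$row[i] + 1L):(coords$row[i] + size)
    cc <- (coords$col[i] + 1L):(coords$col[i] + size)
    list(protein = channels$protein[rr, cc, drop = FALSE],
         dna = channels$dna[rr, cc, drop = FALSE])
  })
  structure(list(image_ref = image_ref, size = as.integer(size),
                 coords = coords, windows = windows),
            class = "PatchSet")
}

#' @export
print.PatchSet <- function(x, ...) {
  cat(sprintf("PatchSet '%s': %d patches of %dx%d px\n",
              x$image_ref, nrow(x$coords), x$size, x$size))
  invisible(x)
}

#' Default patch-parameter grids
#'
#' Patch count 25..385 in steps of 20 (19 values) and side length 45..225
#' in steps of 30 pixels (7 values): the search space over which the
#' optimum (205 patches of 75 px) was selected for the engineered
#' pipeline. Deep backbones use a separate default of 35 patches of
#' 224 px.
#'
#' @return list with `counts` and `sizes` integer vectors.
#' @export
default_patch_grid <- function() {
  list(counts = seq(25L, 385L, by = 20L), sizes = seq(45L, 225L, by = 30L))
}

#' Grid search over patch count and size
#'
#' For every (count, size) pair, runs the engineered-feature + RBF-SVM
#' cross-validation on the manifest's images and records accuracy. A
#' failing cell is recorded as `NA` and the search continues. The best
#' cell maximizes accuracy; ties break to the smaller size, then the
#' smaller count.
#'
#' @param man a `DatasetManifest`.
#' @param counts,sizes integer grids (defaults [default_patch_grid()]).
#' @param eval list of evaluation settings passed to the internal
#'   pipeline: `k` folds, `mode` partition, `seed`, `wavelet` filter,
#'   `max_k` SDA cap, plus any [select_patches()] arguments.
#' @return list with `table` (data.frame `count`, `size`, `accuracy`) and
#'   `best` (the argmax row).
#' @export
patch_grid_search <- function(man, counts = default_patch_grid()$counts,
                              sizes = default_patch_grid()$sizes,
                              eval = list()) {
  stopifnot(length(counts) >= 1, length(sizes) >= 1)
  ev <- modifyList(list(k = 5L, mode = "per_image", seed = 1L,
                        wavelet = "db4", max_k = 30L), eval)
  grid <- expand.grid(count = counts, size = sizes)
  acc <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    acc[i] <- tryCatch({
      fm <- featurize_manifest(man, n_patches = grid$count[i],
                               patch_size = grid$size[i],
                               wavelet = ev$wavelet)
      rep <- crossval(man, fm, mode = ev$mode, k = ev$k, seed = ev$seed,
                      max_k = ev$max_k)
      rep$accuracy
    }, error = function(e) NA_real_)
  }
  tab <- cbind(grid, accuracy = acc)
  ok <- which(!is.na(acc))
  if (!length(ok)) stop("every grid cell failed")
  best <- ok[order(-acc[ok], grid$size[ok], grid$count[ok])][1]
  list(table = tab, best = tab[best, , drop = FALSE])
}
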