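# Multilevel 2-D discrete wavelet transform with Daubechies filters.
#
# Orthonormal Daubechies lowpass (scaling) coefficients for vanishing
# moments 1..10, standard published values (db1 is the Haar filter). The
# highpass filter is the quadrature mirror g[k] = (-1)^k h[L-1-k].
# Signal extension is periodic ("periodization"): odd-length signals are
# wrap-padded by one sample before circular convolution, and each output
# band has ceil(n/2) samples.

DAUBECHIES_LO <- list(
  db1 = c(7.0710678118654757e-01, 7.0710678118654757e-01),
  db2 = c(-1.2940952255126037e-01, 2.2414386804201339e-01,
          8.3651630373780794e-01, 4.8296291314453416e-01),
  db3 = c(3.5226291885709533e-02, -8.5441273882026658e-02,
          -1.3501102001025458e-01, 4.5987750211849154e-01,
          8.0689150931109255e-01, 3.3267055295008263e-01),
  db4 = c(-1.0597401785069032e-02, 3.2883011666885197e-02,
          3.0841381835560764e-02, -1.8703481171909309e-01,
          -2.7983769416859854e-02, 6.3088076792985892e-01,
          7.1484657055291567e-01, 2.3037781330889651e-01),
  db5 = c(3.3357252854737712e-03, -1.2580751999081999e-02,
          -6.2414902127982744e-03, 7.7571493840045719e-02,
          -3.2244869584638375e-02, -2.4229488706638203e-01,
          1.3842814590132074e-01, 7.2430852843777294e-01,
          6.0382926979718965e-01, 1.6010239797419293e-01),
  db6 = c(-1.0773010853084796e-03, 4.7772575109455108e-03,
          5.5384220116149613e-04, -3.1582039317486030e-02,
          2.7522865530305727e-02, 9.7501605587323043e-02,
          -1.2976686756726194e-01, -2.2626469396543983e-01,
          3.1525035170919763e-01, 7.5113390802109536e-01,
          4.9462389039845306e-01, 1.1154074335010947e-01),
  db7 = c(3.5371379997452024e-04, -1.8016407040474908e-03,
          4.2957797292136651e-04, 1.2550998556099840e-02,
          -1.6574541630666881e-02, -3.8029936935014413e-02,
          8.0612609151083078e-02, 7.1309219266830259e-02,
          -2.2403618499387498e-01, -1.4390600392856498e-01,
          4.6978228740519312e-01, 7.2913209084623509e-01,
          3.9653931948191729e-01, 7.7852054085009184e-02),
  db8 = c(-1.1747678412476953e-04, 6.7544940645056933e-04,
          -3.9174037337694705e-04, -4.8703529934515741e-03,
          8.7460940474057766e-03, 1.3981027917398282e-02,
          -4.4088253930794755e-02, -1.7369301001807547e-02,
          1.2874742662047847e-01, 4.7248457391328279e-04,
          -2.8401554296154691e-01, -1.5829105256349306e-02,
          5.8535468365420673e-01, 6.7563073629728976e-01,
          3.1287159091429995e-01, 5.4415842243104008e-02),
  db9 = c(3.9347320316271603e-05, -2.5196318894271012e-04,
          2.3038576352319597e-04, 1.8476468830562265e-03,
          -4.2815036824634303e-03, -4.7232047577513972e-03,
          2.2361662123679096e-02, 2.5094711483145197e-04,
          -6.7632829061329974e-02, 3.0725681479333380e-02,
          1.4854074933810638e-01, -9.6840783222976456e-02,
          -2.9327378327917492e-01, 1.3319738582500756e-01,
          6.5728807805130052e-01, 6.0482312369011115e-01,
          2.4383467461259034e-01, 3.8077947363878345e-02),
  db10 = c(-1.3264202894521244e-05, 9.3588670320069592e-05,
           -1.1646685512928545e-04, -6.8585669495971162e-04,
           1.9924052951850561e-03, 1.3953517470529011e-03,
           -1.0733175483330575e-02, 3.6065535669561697e-03,
           3.3212674059341002e-02, -2.9457536821875813e-02,
           -7.1394147166397082e-02, 9.3057364603572348e-02,
           1.2736934033579325e-01, -1.9594627437737705e-01,
           -2.4984642432731538e-01, 2.8117234366057747e-01,
           6.8845903945360354e-01, 5.2720118893172563e-01,
           1.8817680007769150e-01, 2.6670057900555554e-02)
)

# Filter pair for a Daubechies family member. Coefficients are stored in
# synthesis order; decomposition uses the reversed lowpass and the QMF
# highpass, as is conventional.
db_filters <- function(filter) {
  if (!filter %in% names(DAUBECHIES_LO))
    stop("unknown wavelet filter '", filter, "'; use db1..db10")
  lo <- DAUBECHIES_LO[[filter]]
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(dec_lo = lo, dec_hi = hi)
}

# Analysis operator as a decimated circulant matrix: row k of the result
# holds filter taps at circular positions 2(k-1) + (1..L), so that
# (P %*% x)[k] is the k-th downsampled circular-convolution coefficient.
# Odd-length signals are wrap-padded by one sample (handled by caller).
dwt_op_matrix <- function(n, taps) {
  L <- length(taps)
  na <- n %/% 2
  P <- matrix(0, na, n)
  for (k in seq_len(na)) {
    cols <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (u in seq_len(L)) P[k, cols[u]] <- P[k, cols[u]] + taps[u]
  }
  P
}

.dwt_op_cache <- new.env(parent = emptyenv())

dwt_ops <- function(n, filter) {
  key <- paste0(filter, "_", n)
  if (is.null(.dwt_op_cache[[key]])) {
    f <- db_filters(filter)
    .dwt_op_cache[[key]] <- list(lo = dwt_op_matrix(n, f$dec_lo),
                                 hi = dwt_op_matrix(n, f$dec_hi))
  }
  .dwt_op_cache[[key]]
}

# One periodized analysis step along a vector (reference implementation;
# the 2-D path uses the cached operator matrices).
dwt_step_1d <- function(x, filter) {
  if (length(x) %% 2 == 1) x <- c(x, x[1])
  op <- dwt_ops(length(x), filter)
  list(a = as.numeric(op$lo %*% x), d = as.numeric(op$hi %*% x))
}

# One 2-D analysis step: columns then rows; returns LL, LH, HL, HH.
dwt_step_2d <- function(m, filter) {
  if (nrow(m) %% 2 == 1) m <- rbind(m, m[1, , drop = FALSE])
  if (ncol(m) %% 2 == 1) m <- cbind(m, m[, 1, drop = FALSE])
  opr <- dwt_ops(nrow(m), filter)
  Lc <- opr$lo %*% m               # filter along columns (row index)
  Hc <- opr$hi %*% m
  opc <- dwt_ops(ncol(m), filter)
  list(LL = Lc %*% t(opc$lo), LH = Hc %*% t(opc$lo),
       HL = Lc %*% t(opc$hi), HH = Hc %*% t(opc$hi))
}

#' Multilevel 2-D wavelet decomposition
#'
#' Periodized multilevel DWT of a single-channel window. Returns
#' `3 * levels + 1` subband maps: the approximation at the deepest level
#' first, then `(LH, HL, HH)` per level from deepest to shallowest —
#' 16 subbands at the default depth of 5.
#'
#' @param channel numeric matrix (window).
#' @param filter `"db1"` .. `"db10"`.
#' @param levels decomposition depth; window side must be >= `2^levels`.
#' @return Named list of subband matrices
#'   (`a5`, `lh5`, `hl5`, `hh5`, `lh4`, ... at `levels = 5`).
#' @export
wavelet_subbands <- function(channel, filter = "db4", levels = 5L) {
  stopifnot(is.matrix(channel), levels >= 1)
  if (min(dim(channel)) < 2^levels)
    stop("window side ", min(dim(channel)), " is too small for depth ",
         levels, "; need at least ", 2^levels)
  db_filters(filter)  # validates the filter name
  details <- list()
  a <- channel
  for (lv in seq_len(levels)) {
    s <- dwt_step_2d(a, filter)
    details[[lv]] <- list(lh = s$LH, hl = s$HL, hh = s$HH)
    a <- s$LL
  }
  out <- list(a)
  names(out) <- paste0("a", levels)
  for (lv in rev(seq_len(levels))) {
    nm <- paste0(c("lh", "hl", "hh"), lv)
    out[nm] <- details[[lv]][c("lh", "hl", "hh")]
  }
  out
}
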