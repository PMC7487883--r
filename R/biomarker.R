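# Translocation biomarker screening.
#
# Each image is represented by the concatenated 3-class probability
# outputs of the seven single classifiers (one per deep backbone, each
# trained on engineered + that backbone's features): a 21-dimensional
# score vector. For a protein with m normal-tissue and n cancer-tissue
# images, a per-dimension independent two-sample t-test compares the m
# and n score vectors; the protein is flagged as a location biomarker
# when the smallest of the 21 P values falls below alpha (0.05, no
# multiplicity correction by default). Two controls probe the decision
# rule: a null split of the normal images, and gamma fits of the
# protein-channel intensity-histogram distances of detected versus
# undetected proteins.

#' Concatenated score vector of the seven single classifiers
#'
#' @param models named list of the seven `TrainedModel`s, one per
#'   backbone, in [BACKBONE_ORDER] order (names must match).
#' @param features named numeric vector (or 1-row matrix) holding the
#'   combined feature columns of one image; each model picks its own
#'   columns by name.
#' @return Numeric vector of length 21 (7 classifiers x 3 class scores);
#'   each consecutive triple sums to 1.
#' @export
image_score_vector <- function(models, features) {
  if (!all(BACKBONE_ORDER %in% names(models)))
    stop("models must be named after all seven backbones")
  X <- if (is.matrix(features)) features else
    matrix(features, 1, dimnames = list(NULL, names(features)))
  out <- unlist(lapply(BACKBONE_ORDER, function(nm)
    predict_scores(models[[nm]], X)[1, ]))
  names(out) <- paste(rep(BACKBONE_ORDER, each = 3),
                      rep(LABEL_LEVELS, 7), sep = ".")
  out
}

#' Per-dimension independent two-sample t-test
#'
#' Two-sided t-test of equal means per score dimension between the
#' normal-state and cancer-state rows. `"student"` (default) pools the
#' variances, `"welch"` does not. Dimensions with zero pooled variance
#' give p = 1 when the means agree and p = 0 otherwise.
#'
#' @param normal m x d matrix (m >= 2).
#' @param cancer n x d matrix (n >= 2).
#' @param variant `"student"` or `"welch"`.
#' @return Numeric vector of d p-values in `[0, 1]`.
#' @export
translocation_test <- function(normal, cancer, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  normal <- as.matrix(normal); cancer <- as.matrix(cancer)
  m <- nrow(normal); n <- nrow(cancer)
  if (m < 2 || n < 2) stop("need at least 2 images per state (m=", m, ", n=", n, ")")
  stopifnot(ncol(normal) == ncol(cancer))
  mu1 <- colMeans(normal); mu2 <- colMeans(cancer)
  v1 <- apply(normal, 2, var); v2 <- apply(cancer, 2, var)
  if (variant == "student") {
    sp2 <- ((m - 1) * v1 + (n - 1) * v2) / (m + n - 2)
    se <- sqrt(sp2 * (1 / m + 1 / n))
    df <- rep(m + n - 2, length(se))
  } else {
    se <- sqrt(v1 / m + v2 / n)
    df <- (v1 / m + v2 / n)^2 /
      (v1^2 / (m^2 * (m - 1)) + v2^2 / (n^2 * (n - 1)))
  }
  t <- (mu1 - mu2) / se
  p <- 2 * pt(-abs(t), df)
  zero <- !is.finite(t)
  p[zero] <- ifelse(abs(mu1[zero] - mu2[zero]) < 1e-12, 1, 0)
  pmin(pmax(p, 0), 1)
}

#' Biomarker decision from a p-value vector
#'
#' TRUE iff the smallest p-value is below `alpha`. No multiple-testing
#' correction by default (the single-threshold rule); `"bonferroni"` or
#' `"BH"` are available.
#'
#' @param p_values numeric vector of p-values.
#' @param alpha significance level (default 0.05).
#' @param correction `"none"`, `"bonferroni"` or `"BH"`.
#' @return logical scalar.
#' @export
flag_biomarker <- function(p_values, alpha = 0.05, correction = "none") {
  stopifnot(alpha > 0, alpha < 1)
  p <- if (correction == "none") p_values else p.adjust(p_values, method = correction)
  min(p) < alpha
}

#' Null control: split the normal images against themselves
#'
#' Randomly halves a protein's normal-state score vectors and runs
#' [translocation_test()] between the halves; under the no-translocation
#' null, large p-values are expected.
#'
#' @param normal m x d score matrix, m >= 4.
#' @param seed split seed.
#' @param variant passed to [translocation_test()].
#' @return Numeric vector of d p-values.
#' @export
null_control <- function(normal, seed = 1L, variant = "student") {
  normal <- as.matrix(normal)
  m <- nrow(normal)
  if (m < 4) stop("null control needs at least 4 normal images, got ", m)
  set.seed(seed)
  half <- sample(m, m %/% 2)
  translocation_test(normal[half, , drop = FALSE],
                     normal[-half, , drop = FALSE], variant = variant)
}

# 64-bin normalized intensity histogram of a protein channel.
intensity_histogram <- function(channel, bins = 64L) {
  x <- as.numeric(channel)
  rng <- range(x)
  if (diff(rng) == 0) return(c(1, rep(0, bins - 1)))
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = bins)
  h / sum(h)
}

#' Pixel-distribution control: gamma fits of histogram distances
#'
#' Represents every image by the 64-bin normalized intensity histogram
#' of its protein channel, collects all normal-by-cancer pairwise
#' Euclidean histogram distances per protein, pools them by detection
#' flag, and fits each pool with a maximum-likelihood gamma
#' distribution. Similar fitted shapes for detected and undetected
#' proteins indicate the detection is not driven by raw pixel
#' distributions.
#'
#' @param images_normal,images_cancer lists (per protein) of lists of
#'   protein-channel matrices.
#' @param detected_flags logical vector, one per protein.
#' @param bins histogram bins (default 64).
#' @return list with elements `detected` and `undetected`, each
#'   `c(shape =, scale =)`, plus the pooled `distances` per group.
#' @export
intensity_distance_control <- function(images_normal, images_cancer,
                                       detected_flags, bins = 64L) {
  stopifnot(length(images_normal) == length(images_cancer),
            length(detected_flags) == length(images_normal))
  if (sum(detected_flags) < 2 || sum(!detected_flags) < 2)
    stop("need at least 2 proteins per flag group")
  prot_dist <- lapply(seq_along(images_normal), function(p) {
    hn <- vapply(images_normal[[p]], intensity_histogram, numeric(bins), bins = bins)
    hc <- vapply(images_cancer[[p]], intensity_histogram, numeric(bins), bins = bins)
    as.numeric(sqrt(pmax(outer(colSums(hn^2), colSums(hc^2), "+") -
                         2 * crossprod(hn, hc), 0)))
  })
  fit_group <- function(d) {
    if (all(d < 1e-12))
      stop("degenerate distances (all zero); gamma fit is undefined")
    fit <- MASS::fitdistr(d[d > 0], "gamma")
    c(shape = unname(fit$estimate["shape"]),
      scale = unname(1 / fit$estimate["rate"]))
  }
  d_det <- unlist(prot_dist[detected_flags])
  d_un <- unlist(prot_dist[!detected_flags])
  list(detected = fit_group(d_det), undetected = fit_group(d_un),
       distances = list(detected = d_det, undetected = d_un))
}

#' Screen a dataset for translocation biomarkers
#'
#' For every protein with at least 2 normal and 2 cancer images, builds
#' the per-image 21-dimensional score vectors from the seven single
#' classifiers, determines the normal- and cancer-state localization by
#' voting over per-image predictions, runs the per-dimension t-test and
#' flags significant proteins.
#'
#' @param models named list of seven `TrainedModel`s (one per backbone).
#' @param features combined per-image feature matrix (rows =
#'   image_path).
#' @param man the `DatasetManifest` of the biomarker dataset.
#' @param alpha significance level (default 0.05).
#' @param variant t-test variant.
#' @param vote_model optional `TrainedModel` (e.g. the final combined
#'   classifier) used for the location vote; by default the mean of the
#'   seven 3-score blocks votes.
#' @return A `TranslocationReport` data.frame: `protein_id`,
#'   `normal_loc`, `cancer_loc`, `min_p`, `is_biomarker`, and the 21
#'   per-dimension p-values.
#' @export
detect_biomarkers <- function(models, features, man, alpha = 0.05,
                              variant = "student", vote_model = NULL) {
  stopifnot(inherits(man, "DatasetManifest"))
  features <- as.matrix(features)
  rows <- lapply(names(man$groups), function(pid) {
    idx <- man$groups[[pid]]
    rec <- man$records[idx, , drop = FALSE]
    sv <- t(vapply(idx, function(i)
      image_score_vector(models, features[man$records$image_path[i], ]),
      numeric(21)))
    is_norm <- rec$tissue_state == "normal"
    if (sum(is_norm) < 2 || sum(!is_norm) < 2) {
      warning("protein ", pid, " lacks >= 2 images per state; skipped")
      return(NULL)
    }
    vote_for <- function(sel) {
      if (!is.null(vote_model)) {
        sc <- predict_scores(vote_model, features[man$records$image_path[idx[sel]], , drop = FALSE])
      } else {
        sc <- t(vapply(which(sel), function(j)
          colMeans(matrix(sv[j, ], 7, 3, byrow = TRUE,
                          dimnames = list(NULL, LABEL_LEVELS))), numeric(3)))
      }
      protein_vote(LABEL_LEVELS[max.col(sc, ties.method = "first")], sc)
    }
    p <- translocation_test(sv[is_norm, , drop = FALSE],
                            sv[!is_norm, , drop = FALSE], variant = variant)
    out <- data.frame(protein_id = pid,
                      normal_loc = vote_for(is_norm),
                      cancer_loc = vote_for(!is_norm),
                      min_p = min(p),
                      is_biomarker = flag_biomarker(p, alpha),
                      stringsAsFactors = FALSE)
    pv <- as.data.frame(t(p))
    names(pv) <- paste0("p.", names(p))
    cbind(out, pv)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  rep <- do.call(rbind, rows)
  attr(rep, "alpha") <- alpha
  class(rep) <- c("TranslocationReport", "data.frame")
  rep
}
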