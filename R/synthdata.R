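# Synthetic IHC image generator.
#
# Emulates the statistical structure the pipeline assumes rather than
# histological realism: elliptical hematoxylin-stained nuclei, a DAB-stained
# protein compartment drawn according to one of the three localization
# classes, and Beer-Lambert color mixing through a known stain basis, so
# that every stage (unmixing, patching, features, classification,
# translocation screening) can be validated against ground truth.

#' Standard hematoxylin/DAB stain basis
#'
#' The widely used published optical-density color vectors for the
#' hematoxylin + DAB stain pair (Ruifrok & Johnston's calibration),
#' row-normalized to unit Euclidean norm. Row 1 is hematoxylin (DNA),
#' row 2 is DAB (protein).
#'
#' @return A `StainBasis`.
#' @export
default_basis <- function() {
  stain_basis(rbind(
    c(0.650, 0.704, 0.286),   # hematoxylin
    c(0.268, 0.570, 0.776)    # DAB
  ))
}

#' Specification for one synthetic IHC image
#'
#' @param image_size side length in pixels of the square image.
#' @param n_nuclei number of elliptical nuclei to draw.
#' @param nucleus_axes length-2 range (pixels) the ellipse semi-axes are
#'   drawn from.
#' @param class_pattern localization class of the protein stain:
#'   `"i"` protein inside nuclei, `"ii"` annular cytoplasm/membrane rings
#'   around nuclei (excluded from nuclei), `"iii"` both.
#' @param dab_strength,hema_strength peak optical densities of the protein
#'   and DNA stains (dimensionless OD units).
#' @param ring_width thickness in pixels of the class-ii annulus.
#' @param noise_sd standard deviation of additive Gaussian OD noise.
#' @param seed integer seed; the image is deterministic given the spec.
#' @return A `SynthSpec` list.
#' @export
synth_spec <- function(image_size = 512, n_nuclei = 25,
                       nucleus_axes = c(8, 16), class_pattern = "i",
                       dab_strength = 0.9, hema_strength = 0.7,
                       ring_width = 8, noise_sd = 0.02, seed = 1L) {
  stopifnot(image_size >= 16, n_nuclei >= 1, noise_sd >= 0,
            length(nucleus_axes) == 2, nucleus_axes[1] <= nucleus_axes[2],
            class_pattern %in% LABEL_LEVELS)
  structure(list(image_size = as.integer(image_size),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_axes = nucleus_axes,
                 class_pattern = class_pattern,
                 dab_strength = dab_strength,
                 hema_strength = hema_strength,
                 ring_width = ring_width,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "SynthSpec")
}

# Rasterize one rotated ellipse into a logical H x W matrix.
ellipse_mask <- function(h, w, r0, c0, a, b, theta) {
  rmax <- ceiling(max(a, b))
  rr <- max(1, floor(r0 - rmax)):min(h, ceiling(r0 + rmax))
  cc <- max(1, floor(c0 - rmax)):min(w, ceiling(c0 + rmax))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  m <- matrix(FALSE, h, w)
  m[rr, cc] <- u^2 + v^2 <= 1
  m
}

# Binary dilation by a disc of radius rad (EBImage morphological kernel).
dilate_mask <- function(mask, rad) {
  if (rad <= 0) return(mask)
  k <- EBImage::makeBrush(2 * ceiling(rad) + 1, shape = "disc")
  EBImage::dilate(mask * 1, k) > 0
}

#' Generate one synthetic IHC image with ground truth
#'
#' Draws `n_nuclei` random ellipses carrying hematoxylin optical density,
#' places protein (DAB) optical density according to the localization
#' class, renders RGB by the Beer-Lambert law
#' `RGB = 255 * 10^-(C %*% basis)` (base-10 OD, matching
#' [od_transform()]), adds Gaussian OD noise, and quantizes to 8 bits.
#'
#' @param spec a [synth_spec()].
#' @param basis stain basis to mix with; default [default_basis()].
#' @param protein_id,tissue_state metadata stored on the image.
#' @return A list with elements
#'   `image` (`IHCImage`),
#'   `truth` (`SynthTruth`: `dna_mask`, `protein_mask` logical H x W,
#'   `od_dna`, `od_protein` continuous concentration maps, `basis`,
#'   `class_label`).
#' @export
synth_image <- function(spec, basis = default_basis(),
                        protein_id = "synthP", tissue_state = "normal") {
  stopifnot(inherits(spec, "SynthSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  h <- w <- spec$image_size
  dna_mask <- matrix(FALSE, h, w)
  ring_mask <- matrix(FALSE, h, w)
  centers <- matrix(NA_real_, 0, 2)
  margin <- spec$nucleus_axes[2] + spec$ring_width + 1
  if (2 * margin >= h) margin <- floor(h / 4)
  min_sep <- 1.2 * spec$nucleus_axes[2]
  for (i in seq_len(spec$n_nuclei)) {
    placed <- FALSE
    for (try in 1:100) {
      r0 <- runif(1, margin, h - margin)
      c0 <- runif(1, margin, w - margin)
      if (nrow(centers) == 0 ||
          min((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2) > min_sep^2) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (i <= 1) stop("could not place nuclei without total overlap")
      break  # image is simply less crowded than requested
    }
    centers <- rbind(centers, c(r0, c0))
    a <- runif(1, spec$nucleus_axes[1], spec$nucleus_axes[2])
    b <- runif(1, spec$nucleus_axes[1], spec$nucleus_axes[2])
    theta <- runif(1, 0, pi)
    nuc <- ellipse_mask(h, w, r0, c0, a, b, theta)
    dna_mask <- dna_mask | nuc
    ring <- ellipse_mask(h, w, r0, c0, a + spec$ring_width, b + spec$ring_width, theta)
    ring_mask <- ring_mask | ring
  }
  # class-ii compartment: annulus, kept clear of nuclei (1 px guard band)
  annulus <- ring_mask & !dilate_mask(dna_mask, 1)

  protein_mask <- switch(spec$class_pattern,
    i   = dna_mask,
    ii  = annulus,
    iii = dna_mask | annulus)

  # per-nucleus-ish smooth intensity variation so patches carry texture
  jitter_field <- function(mask, strength) {
    od <- matrix(0, h, w)
    if (!any(mask)) return(od)
    f <- matrix(rnorm(h * w, 1, 0.25), h, w)
    f <- as.matrix(EBImage::gblur(f, sigma = 3))
    od[mask] <- strength * pmax(f[mask], 0.15)
    od
  }
  od_dna <- jitter_field(dna_mask, spec$hema_strength)
  od_protein <- jitter_field(protein_mask, spec$dab_strength)

  conc <- cbind(as.vector(od_dna), as.vector(od_protein))
  od_rgb <- conc %*% unclass(basis)                    # (H*W) x 3
  if (spec$noise_sd > 0)
    od_rgb <- od_rgb + rnorm(length(od_rgb), 0, spec$noise_sd)
  od_rgb[od_rgb < 0] <- 0
  px <- array(255 * 10^(-od_rgb), dim = c(h, w, 3))
  px <- pmin(pmax(round(px), 0), 255)

  img <- ihc_image(px, protein_id = protein_id, tissue_state = tissue_state,
                   label = spec$class_pattern)
  truth <- structure(list(dna_mask = dna_mask, protein_mask = protein_mask,
                          od_dna = od_dna, od_protein = od_protein,
                          basis = basis, class_label = spec$class_pattern),
                     class = "SynthTruth")
  list(image = img, truth = truth)
}

#' Generate a synthetic multi-protein dataset on disk
#'
#' Assigns each protein a localization class in the normal state; a
#' `biomarker_fraction` of proteins translocate, i.e. get a different
#' class in the cancer state, while the rest keep their class. Images are
#' written as PNG files together with a manifest CSV and a ground-truth
#' CSV (`protein_id, normal_class, cancer_class, is_biomarker`).
#'
#' Each protein also receives a small random multiplicative offset on its
#' stain strength and nucleus size (`protein_jitter`), so images of one
#' protein share a nuisance signature — the structure that makes
#' per-protein cross-validation strictly harder than per-image.
#'
#' @param out_dir output directory (created if missing).
#' @param n_proteins number of proteins.
#' @param images_per_state length-2 integer vector: images per protein in
#'   the normal and cancer state.
#' @param biomarker_fraction proportion of proteins that translocate.
#' @param spec base [synth_spec()] shared by all images.
#' @param seed master seed; per-image seeds are derived as
#'   `seed + image index`.
#' @param protein_jitter sd of the per-protein log-normal nuisance factor.
#' @return A list: `manifest` (`DatasetManifest`), `truth` (data.frame),
#'   `manifest_path`, `truth_path`.
#' @export
synth_dataset <- function(out_dir, n_proteins = 10,
                          images_per_state = c(4L, 12L),
                          biomarker_fraction = 0.5,
                          spec = synth_spec(image_size = 128, n_nuclei = 8,
                                            nucleus_axes = c(6, 11),
                                            ring_width = 5),
                          seed = 1L, protein_jitter = 0.25) {
  stopifnot(n_proteins >= 1, all(images_per_state >= 1),
            biomarker_fraction >= 0, biomarker_fraction <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_bio <- round(biomarker_fraction * n_proteins)
  is_bio <- rep(FALSE, n_proteins)
  if (n_bio > 0) is_bio[sample(n_proteins, n_bio)] <- TRUE
  # balanced class table: every localization class appears (shuffled)
  normal_class <- sample(rep_len(LABEL_LEVELS, n_proteins))
  cancer_class <- normal_class
  for (p in which(is_bio))
    cancer_class[p] <- sample(setdiff(LABEL_LEVELS, normal_class[p]), 1)
  jit <- exp(rnorm(n_proteins, 0, protein_jitter))

  rec <- list(); img_idx <- 0L
  for (p in seq_len(n_proteins)) {
    pid <- sprintf("P%03d", p)
    for (state in c("normal", "cancer")) {
      n_img <- images_per_state[if (state == "normal") 1 else 2]
      cls <- if (state == "normal") normal_class[p] else cancer_class[p]
      for (k in seq_len(n_img)) {
        img_idx <- img_idx + 1L
        sp <- spec
        sp$class_pattern <- cls
        sp$seed <- as.integer(seed + img_idx)
        sp$dab_strength <- spec$dab_strength * jit[p]
        sp$hema_strength <- spec$hema_strength * jit[p]
        sp$nucleus_axes <- pmax(3, spec$nucleus_axes * jit[p]^0.5)
        out <- synth_image(sp, protein_id = pid, tissue_state = state)
        fname <- sprintf("%s_%s_%02d.png", pid, state, k)
        write_image(out$image, file.path(out_dir, fname))
        rec[[img_idx]] <- data.frame(protein_id = pid,
                                     image_path = file.path(out_dir, fname),
                                     tissue_state = state, label = cls,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  man <- manifest(do.call(rbind, rec))
  truth <- data.frame(protein_id = sprintf("P%03d", seq_len(n_proteins)),
                      normal_class = normal_class,
                      cancer_class = cancer_class,
                      is_biomarker = is_bio, stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_manifest(man, manifest_path)
  write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  list(manifest = man, truth = truth,
       manifest_path = manifest_path, truth_path = truth_path)
}
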