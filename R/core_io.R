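# Shared domain types and file plumbing.
#
# Conventions used throughout the package:
#   * pixel arrays are H x W (row, col), 0-based coordinates in patch
#     bookkeeping, half-open windows [r0, r0+s) x [c0, c0+s);
#   * localization labels are the strings "i", "ii", "iii" (nucleus,
#     cytoplasm/membrane, both) or "unknown"; internal integer codes are
#     0/1/2 in that order;
#   * a stain basis is a 2x3 matrix of unit-norm optical-density color
#     vectors, row 1 = hematoxylin (DNA), row 2 = DAB (protein).

LABEL_LEVELS <- c("i", "ii", "iii")

#' Construct an IHC image object
#'
#' Bundles an 8-bit RGB pixel array with the metadata the pipeline carries
#' along: protein identity, tissue state and (optional) localization label.
#'
#' @param pixels integer H x W x 3 array with values in `[0, 255]`.
#' @param protein_id character scalar, e.g. an antibody or gene id.
#' @param tissue_state `"normal"` or `"cancer"`.
#' @param label localization class `"i"`, `"ii"`, `"iii"` or `"unknown"`.
#' @param source_path file the pixels came from (informative only).
#' @return An object of class `IHCImage`.
#' @export
ihc_image <- function(pixels, protein_id = "", tissue_state = "",
                      label = "unknown", source_path = "") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  if (!label %in% c(LABEL_LEVELS, "unknown"))
    stop("label must be one of i/ii/iii/unknown, got: ", label)
  structure(list(
    pixels       = array(as.integer(round(pixels)), dim = dim(pixels)),
    protein_id   = as.character(protein_id),
    tissue_state = as.character(tissue_state),
    label        = label,
    source_path  = as.character(source_path)
  ), class = "IHCImage")
}

#' @export
print.IHCImage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("IHCImage %dx%d  protein=%s  state=%s  label=%s\n",
              d[1], d[2],
              if (nzchar(x$protein_id)) x$protein_id else "<none>",
              if (nzchar(x$tissue_state)) x$tissue_state else "<none>",
              x$label))
  invisible(x)
}

#' Construct and validate a stain basis
#'
#' @param matrix 2 x 3 non-negative matrix of stain color vectors in
#'   optical-density space; row 1 hematoxylin/DNA, row 2 DAB/protein.
#'   Rows are normalized to unit Euclidean norm.
#' @return A `StainBasis` (2 x 3 matrix with rownames `dna`, `protein`).
#' @export
stain_basis <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(2L, 3L))) stop("stain basis must be 2 x 3")
  if (any(m < 0)) stop("stain basis entries must be non-negative")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("stain basis rows must be nonzero")
  m <- m / nrm
  if (abs(det(m %*% t(m))) < 1e-12)
    stop("stain basis rows are linearly dependent")
  dimnames(m) <- list(c("dna", "protein"), c("R", "G", "B"))
  class(m) <- c("StainBasis", "matrix")
  m
}

#' Load a dataset manifest from CSV
#'
#' The manifest lists one image per row with columns
#' `protein_id,image_path,tissue_state,label`. Tissue states are
#' case-folded to lower case; labels are validated against
#' `i`/`ii`/`iii`/`unknown`.
#'
#' @param path CSV file path.
#' @return A `DatasetManifest`: list with `records` (data.frame) and
#'   `groups` (named list mapping protein_id to row indices).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("protein_id", "image_path", "tissue_state", "label")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[needed]
  df$tissue_state <- tolower(trimws(df$tissue_state))
  df$label <- tolower(trimws(df$label))
  manifest(df)
}

#' Build a manifest from a records data.frame
#'
#' @param records data.frame with columns
#'   `protein_id,image_path,tissue_state,label`.
#' @return A `DatasetManifest`.
#' @export
manifest <- function(records) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (anyDuplicated(df$image_path))
    stop("duplicate image_path in manifest: ",
         df$image_path[duplicated(df$image_path)][1])
  if (any(!nzchar(df$protein_id)) || any(is.na(df$protein_id)))
    stop("protein_id must be non-empty for every record")
  if (!all(df$tissue_state %in% c("normal", "cancer")))
    stop("tissue_state must be 'normal' or 'cancer'")
  bad <- setdiff(unique(df$label), c(LABEL_LEVELS, "unknown"))
  if (length(bad))
    stop("invalid label(s): ", paste(bad, collapse = ", "))
  groups <- split(seq_len(nrow(df)), df$protein_id)
  structure(list(records = df, groups = groups), class = "DatasetManifest")
}

#' Write a manifest back to CSV
#'
#' Inverse of [load_manifest()]: the written file reloads to an identical
#' manifest.
#'
#' @param m a `DatasetManifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "DatasetManifest"))
  write.csv(m$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.DatasetManifest <- function(x, ...) {
  cat(sprintf("DatasetManifest: %d images, %d proteins (%d normal, %d cancer)\n",
              nrow(x$records), length(x$groups),
              sum(x$records$tissue_state == "normal"),
              sum(x$records$tissue_state == "cancer")))
  invisible(x)
}

#' Read an RGB image file as an IHC image
#'
#' Reads PNG, TIFF or JPEG through EBImage. 16-bit input is rescaled to
#' 8 bits by max-value division; grayscale files are rejected because
#' stain unmixing needs three channels.
#'
#' @param path image file.
#' @param protein_id,tissue_state,label optional metadata to attach.
#' @return An `IHCImage` with 8-bit pixels.
#' @export
read_image <- function(path, protein_id = "", tissue_state = "",
                       label = "unknown") {
  if (!file.exists(path)) stop("image not found: ", path)
  img <- EBImage::readImage(path)   # values in [0, 1], dims (x, y[, c])
  d <- dim(img)
  if (length(d) < 3L || d[3] < 3L)
    stop("image is not 3-channel RGB (stain unmixing needs color): ", path)
  dat <- EBImage::imageData(img)[, , 1:3, drop = FALSE]
  # EBImage is column-major (x, y); transpose each channel to (row, col)
  px <- array(0L, dim = c(d[2], d[1], 3L))
  for (ch in 1:3) px[, , ch] <- t(dat[, , ch])
  px <- round(px * 255)
  ihc_image(px, protein_id, tissue_state, label, source_path = path)
}

#' Write an IHC image to PNG
#'
#' Lossless for 8-bit data: [read_image()] on the written file returns
#' bit-identical pixels.
#'
#' @param image an `IHCImage`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "IHCImage"))
  d <- dim(image$pixels)
  dat <- array(0, dim = c(d[2], d[1], 3L))
  for (ch in 1:3) dat[, , ch] <- t(image$pixels[, , ch]) / 255
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}

# Internal: integer class codes 0/1/2 from labels.
label_code <- function(label) match(label, LABEL_LEVELS) - 1L
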