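#' Labeled sample: multi-channel image plus co-registered label map
#'
#' The basic unit all mixers operate on: a real-valued intensity image of
#' shape `(H, W, C)` with values in `[0, 1]` (for dual-fluorescence sections,
#' `C = 2` coupled synaptic-marker channels) and an integer label map of shape
#' `(H, W)` on the same pixel grid, where 0 is background and positive values
#' are subregion labels. Coordinates are row-major, 1-based in R, origin at
#' the top-left corner.
#'
#' @param image Numeric array `(H, W, C)` or matrix `(H, W)` (promoted to
#'   `C = 1`); finite, non-negative, at most 1.
#' @param labels Integer matrix `(H, W)`; 0 = background.
#' @param sample_id Character scalar identifying the sample.
#' @param taxonomy Optional [region_taxonomy()]; when supplied, every nonzero
#'   label present must be a key of the taxonomy.
#' @return An object of class `labeled_sample` with fields `image`, `labels`,
#'   `sample_id`.
#' @export
labeled_sample <- function(image, labels, sample_id = "sample", taxonomy = NULL) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("image must be an (H, W, C) array or an (H, W) matrix", call. = FALSE)
  if (!is.matrix(labels))
    stop("labels must be an (H, W) integer matrix", call. = FALSE)
  if (!all(dim(image)[1:2] == dim(labels)))
    stop(sprintf("image (%dx%d) and labels (%dx%d) must share the same grid",
                 dim(image)[1], dim(image)[2], nrow(labels), ncol(labels)),
         call. = FALSE)
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop("image intensities must be finite and in [0, 1]", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative integers", call. = FALSE)
  s <- structure(list(image = image, labels = labels,
                      sample_id = as.character(sample_id)),
                 class = "labeled_sample")
  if (!is.null(taxonomy)) validate_sample(s, taxonomy)
  s
}

#' Validate a sample against a taxonomy
#'
#' Checks that every nonzero label value present in the sample's label map is
#' a key of `taxonomy`.
#'
#' @param sample A [labeled_sample()].
#' @param taxonomy A [region_taxonomy()].
#' @return `sample`, invisibly; errors naming the first offending label.
#' @export
validate_sample <- function(sample, taxonomy) {
  stopifnot(inherits(sample, "labeled_sample"), inherits(taxonomy, "region_taxonomy"))
  present <- setdiff(unique(as.vector(sample$labels)), 0L)
  known <- as.integer(names(taxonomy$subregion_to_primary))
  bad <- setdiff(present, known)
  if (length(bad))
    stop(sprintf("label value %d in sample '%s' is not in the taxonomy",
                 bad[1], sample$sample_id), call. = FALSE)
  invisible(sample)
}

#' @export
print.labeled_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_sample> '%s' %dx%d, %d channel(s), %d label(s), fg %.2f\n",
              x$sample_id, d[1], d[2], d[3],
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              mean(x$labels > 0L)))
  invisible(x)
}

#' Binary mask of one primary region
#'
#' Returns the union of all subregion masks belonging to primary region `p`:
#' `mask[i, j]` is `TRUE` iff the taxonomy maps `labels[i, j]` to `p`. A
#' primary region absent from the sample yields an all-`FALSE` mask (not an
#' error). Together with the background mask, the `P` primary masks partition
#' the grid.
#'
#' @param labels Integer label matrix or a [labeled_sample()].
#' @param taxonomy A [region_taxonomy()].
#' @param p Primary-region ID in `1..P`.
#' @return Logical matrix of the same shape as `labels`.
#' @export
extract_primary_mask <- function(labels, taxonomy, p) {
  if (inherits(labels, "labeled_sample")) labels <- labels$labels
  subs <- subregions_of(taxonomy, p)  # validates p
  m <- matrix(labels %in% subs, nrow(labels), ncol(labels))
  m
}

#' Primary regions present in a sample
#'
#' @inheritParams extract_primary_mask
#' @return Sorted integer vector of primary-region IDs with at least one pixel.
#' @export
primary_regions_present <- function(labels, taxonomy) {
  if (inherits(labels, "labeled_sample")) labels <- labels$labels
  present <- setdiff(unique(as.vector(labels)), 0L)
  sort(unique(as.integer(taxonomy$subregion_to_primary[as.character(present)])))
}

#' Pad two samples to a common grid
#'
#' Pairwise mixing operations require a shared grid; datasets may contain
#' images of differing sizes. The smaller grid is padded with background
#' (zero intensity, label 0), anchored at the top-left corner.
#'
#' @param a,b [labeled_sample()] objects.
#' @return List of the two samples on the common `(max H, max W)` grid.
#' @export
pad_to_common <- function(a, b) {
  H <- max(nrow(a$labels), nrow(b$labels))
  W <- max(ncol(a$labels), ncol(b$labels))
  list(pad_sample(a, H, W), pad_sample(b, H, W))
}

pad_sample <- function(s, H, W) {
  d <- dim(s$image)
  if (d[1] == H && d[2] == W) return(s)
  img <- array(0, c(H, W, d[3]))
  img[seq_len(d[1]), seq_len(d[2]), ] <- s$image
  lab <- matrix(0L, H, W)
  lab[seq_len(d[1]), seq_len(d[2])] <- s$labels
  labeled_sample(img, lab, s$sample_id)
}

# ---- file I/O ---------------------------------------------------------------

#' Load a labeled sample from image and label-map files
#'
#' Images are read from TIFF (preferred; multi-channel stored as one page per
#' channel) or PNG and rescaled to `[0, 1]` by the dtype maximum.
#' Label maps are read from single-channel integer TIFF/PNG.
#'
#' @param image_path,label_path File paths (`.tif`/`.tiff` or `.png`).
#' @param taxonomy A [region_taxonomy()] used to validate label values.
#' @param sample_id Sample ID; defaults to the image file stem.
#' @return A validated [labeled_sample()].
#' @export
load_sample <- function(image_path, label_path, taxonomy,
                        sample_id = tools::file_path_sans_ext(basename(image_path))) {
  img <- read_image_file(image_path)
  lab <- read_label_map(label_path)
  if (!all(dim(img)[1:2] == dim(lab)))
    stop(sprintf("image %s (%dx%d) and labels %s (%dx%d) have mismatched grids",
                 basename(image_path), dim(img)[1], dim(img)[2],
                 basename(label_path), nrow(lab), ncol(lab)), call. = FALSE)
  labeled_sample(img, lab, sample_id, taxonomy)
}

#' Write a labeled sample to image and label-map files
#'
#' @param sample A [labeled_sample()].
#' @param image_path,label_path Output paths; format chosen by extension.
#' @return Invisibly, the two paths.
#' @export
write_sample <- function(sample, image_path, label_path) {
  write_image_file(sample$image, image_path)
  write_label_map(sample$labels, label_path)
  invisible(c(image_path, label_path))
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    img <- simplify2array(pages)
    if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
    # a single RGB(A) page comes back (H, W, C) inside a length-1 list
    if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) img <- pages[[1]]
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  } else stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  clamp01(img)
}

write_image_file <- function(image, path) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(dim(image)[3]), function(k) image[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    x <- if (dim(image)[3] == 1L) image[, , 1] else image
    png::writePNG(x, path)
  } else stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  invisible(path)
}

# Label maps are stored as 16-bit grayscale TIFF (values <= 65535 round-trip
# bit-exactly) or 8-bit PNG (values <= 255 only).
read_label_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    lab <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    lab <- round(png::readPNG(path) * 255)
  } else stop(sprintf("unsupported label format '.%s'", ext), call. = FALSE)
  if (length(dim(lab)) != 2L)
    stop("label map must be a single-channel image", call. = FALSE)
  storage.mode(lab) <- "integer"
  lab
}

write_label_map <- function(labels, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (any(labels > 65535L))
      stop("label values above 65535 cannot be stored in 16-bit label maps",
           call. = FALSE)
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (any(labels > 255L))
      stop("PNG label maps are 8-bit; use TIFF for label values above 255",
           call. = FALSE)
    png::writePNG(labels / 255, path)
  } else stop(sprintf("unsupported label format '.%s'", ext), call. = FALSE)
  invisible(path)
}
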