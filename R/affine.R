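#' Search configuration for overlap-aware placement
#'
#' Bundles the affine sampling ranges and the greedy-search knobs used by
#' [oaa()]. Ranges left `NULL` are resolved per call from the grid size:
#' translation and shift default to +/- 5% and +/- 10% of `min(H, W)` pixels
#' and the shift stepsize to `max(1, floor(min(H, W) / 64))`, so behavior is
#' size-invariant from toy grids to full sections. The overlap tolerance
#' `tau` is an absolute pixel count; when `NULL` it is resolved per call as
#' `ceiling(tau_rel * area)` of the transformed source mask, keeping the
#' tolerated spill proportional to the region being placed.
#'
#' @param tau Overlap tolerance in pixels (`NULL` = relative via `tau_rel`).
#' @param tau_rel Relative tolerance used when `tau` is `NULL`; default 0.02.
#' @param rotation_range Degrees, `c(low, high)`; default `c(-10, 10)`.
#' @param scale_range Unitless, default `c(0.9, 1.1)`.
#' @param translation_range Pixels, `c(low, high)` applied to both axes;
#'   `NULL` = +/- 5% of `min(H, W)`.
#' @param shift_range Greedy-search shift window in pixels; `NULL` = +/- 10%
#'   of `min(H, W)`.
#' @param stepsize Shift grid step in pixels (`NULL` = resolved from grid).
#' @param early_stop Stop the whole search at the first shift whose overlap
#'   falls below `tau` (the default); `FALSE` scans the full grid.
#' @param overlap_mode `"complement"` counts query pixels outside the
#'   target's own region (background spill counts, the literal mask-complement
#'   rule); `"foreground"` counts only spill onto other foreground regions.
#' @param restarts Number of independent affine draws; the placement with the
#'   lowest overlap wins. Default 1 (single draw, per the base algorithm).
#' @return An object of class `search_config`.
#' @export
search_config <- function(tau = NULL, tau_rel = 0.02,
                          rotation_range = c(-10, 10),
                          scale_range = c(0.9, 1.1),
                          translation_range = NULL,
                          shift_range = NULL,
                          stepsize = NULL,
                          early_stop = TRUE,
                          overlap_mode = c("complement", "foreground"),
                          restarts = 1L) {
  overlap_mode <- match.arg(overlap_mode)
  chk_range <- function(r, name) {
    if (!is.null(r)) {
      if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
        stop(sprintf("`%s` must be c(low, high) with low <= high", name), call. = FALSE)
    }
    r
  }
  if (!is.null(tau)) {
    # Inf is a valid (vacuous) tolerance: every placement converges at once
    if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
      stop("`tau` must be a single non-negative number (Inf allowed)", call. = FALSE)
  }
  assert_scalar_num(tau_rel, "tau_rel", lo = 0)
  chk_range(rotation_range, "rotation_range")
  chk_range(scale_range, "scale_range")
  if (any(scale_range <= 0)) stop("scale must be positive", call. = FALSE)
  chk_range(translation_range, "translation_range")
  chk_range(shift_range, "shift_range")
  if (!is.null(stepsize)) assert_scalar_num(stepsize, "stepsize", lo = 1)
  structure(list(tau = tau, tau_rel = tau_rel,
                 rotation_range = rotation_range, scale_range = scale_range,
                 translation_range = translation_range, shift_range = shift_range,
                 stepsize = stepsize, early_stop = isTRUE(early_stop),
                 overlap_mode = overlap_mode, restarts = as.integer(restarts)),
            class = "search_config")
}

# Fill in grid-dependent defaults.
resolve_search_config <- function(config, dims) {
  m <- min(dims[1], dims[2])
  config$translation_range <- config$translation_range %||% (c(-1, 1) * 0.05 * m)
  config$shift_range <- config$shift_range %||% (c(-1, 1) * round(0.10 * m))
  config$stepsize <- as.integer(config$stepsize %||% max(1, floor(m / 64)))
  config
}

#' Affine transform parameters
#'
#' Rotation (degrees), isotropic scale, and a `(rows, cols)` pixel
#' translation; composed as rotate-then-scale about a centre point, then
#' translate.
#'
#' @param rotation Degrees; positive rotates from the +row axis toward the
#'   +col axis.
#' @param scale Positive unitless factor.
#' @param translation Numeric length-2 `(rows, cols)` offset in pixels.
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(rotation = 0, scale = 1, translation = c(0, 0)) {
  assert_scalar_num(rotation, "rotation")
  assert_scalar_num(scale, "scale")
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  stopifnot(length(translation) == 2L, all(is.finite(translation)))
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "affine_params")
}

#' Draw random affine parameters
#'
#' Samples rotation, scale, and the two translation components independently
#' and uniformly from the ranges in `config` (resolved against `dims` when
#' ranges are grid-relative).
#'
#' @param config A [search_config()].
#' @param dims Grid `c(H, W)` used to resolve relative ranges.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An [affine_params()] object.
#' @export
random_affine <- function(config, dims = c(64, 64), seed = NULL) {
  config <- resolve_search_config(config, dims)
  with_seed(seed, {
    rot <- stats::runif(1, config$rotation_range[1], config$rotation_range[2])
    sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    tr <- stats::runif(2, config$translation_range[1], config$translation_range[2])
    affine_params(rot, sc, tr)
  })
}

# 3x2 forward matrix for EBImage::affine. EBImage samples in corner-based
# continuous coordinates (pixel i is centred at i - 0.5), so a 1-based pixel
# centre `centre` becomes `centre - 0.5` before building the map
#   x' = (x - c) %*% (s R) + c + t.
ebimage_affine_matrix <- function(params, centre) {
  th <- params$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = TRUE)
  A <- params$scale * R
  cc <- as.numeric(centre) - 0.5
  rbind(A, cc - cc %*% A + params$translation)
}

# Foreground centroid (rows, cols) of a mask / nonzero grid.
mask_centroid <- function(grid) {
  idx <- which(grid > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_))
  colMeans(idx)
}

#' Apply an affine transform to a mask, label map, or image
#'
#' Rotation and scaling are performed about `centre` (by default the grid's
#' own foreground centroid; pass the companion region mask's centroid when
#' transforming image channels so geometry stays synchronized), followed by
#' translation. Binary masks and integer label maps are resampled
#' nearest-neighbor (output stays binary / keeps exact label values); numeric
#' image channels are resampled bilinearly. All channels of an `(H, W, C)`
#' array share one geometric transform. Pixels mapped from outside the grid
#' become background/zero.
#'
#' @param grid Logical/integer matrix (mask or label map) or numeric
#'   matrix/array (image).
#' @param params An [affine_params()].
#' @param centre `(row, col)` rotation/scale centre; default foreground
#'   centroid of `grid`.
#' @param filter `"auto"` (nearest for logical/integer, bilinear otherwise),
#'   `"nearest"`, or `"bilinear"`.
#' @return Transformed grid of the same shape and storage mode; carries
#'   attribute `empty = TRUE` (with a warning) if a nonempty foreground was
#'   mapped entirely out of bounds.
#' @export
apply_affine <- function(grid, params, centre = NULL,
                         filter = c("auto", "nearest", "bilinear")) {
  filter <- match.arg(filter)
  was_logical <- is.logical(grid)
  was_int <- is.integer(grid)
  if (filter == "auto") filter <- if (was_logical || was_int) "nearest" else "bilinear"
  ebfilter <- if (filter == "nearest") "none" else "bilinear"
  x <- grid
  if (was_logical || was_int) storage.mode(x) <- "double"
  dims <- dim(x)[1:2]
  if (is.null(centre)) {
    centre <- if (length(dim(x)) == 3L) mask_centroid(x[, , 1]) else mask_centroid(x)
    if (anyNA(centre)) centre <- (dims + 1) / 2
  }
  m <- ebimage_affine_matrix(params, centre)
  out <- EBImage::imageData(EBImage::affine(
    EBImage::Image(x), m, filter = ebfilter, output.dim = dims,
    bg.col = 0, antialias = FALSE))
  dim(out) <- dim(grid)
  had_fg <- any(grid > 0)
  if (was_logical) out <- out > 0.5
  if (was_int) storage.mode(out) <- "integer"
  if (had_fg && !any(out > 0)) {
    warning("affine transform mapped the entire foreground out of bounds")
    attr(out, "empty") <- TRUE
  }
  out
}

# Integer lattice shift by s = (rows, cols); pixels shifted off the grid are
# lost, vacated pixels become 0/FALSE.
shift_grid <- function(grid, s) {
  s <- as.integer(round(s))
  d <- dim(grid)
  out <- grid
  out[] <- if (is.logical(grid)) FALSE else if (is.integer(grid)) 0L else 0
  r_src <- seq_len(d[1]) - s[1]
  c_src <- seq_len(d[2]) - s[2]
  rok <- r_src >= 1L & r_src <= d[1]
  cok <- c_src >= 1L & c_src <= d[2]
  if (!any(rok) || !any(cok)) return(out)
  if (length(d) == 3L) {
    out[which(rok), which(cok), ] <- grid[r_src[rok], c_src[cok], , drop = FALSE]
  } else {
    out[which(rok), which(cok)] <- grid[r_src[rok], c_src[cok], drop = FALSE]
  }
  out
}
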