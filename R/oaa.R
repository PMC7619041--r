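#' Overlap between a placed mask and the complement of a target region
#'
#' Counts the pixels of `query` that fall outside the target's own region
#' mask, i.e. `|query & !target|` — the spill a transplanted region would
#' inflict on territory that is not its own.
#'
#' @param query,target Logical matrices on a common grid.
#' @return Non-negative integer pixel count.
#' @export
overlap <- function(query, target) {
  if (!all(dim(query) == dim(target)))
    stop("query and target masks must share the same grid", call. = FALSE)
  sum(query & !target)
}

#' Overlap-aware augmentation: place a source region into a target
#'
#' The placement engine of PRMix. A random affine transform (rotation and
#' scale about the region centroid, then translation) is applied to the
#' source's primary-region mask. If the transformed mask already spills fewer
#' than `tau` pixels onto the complement of the target's corresponding region,
#' it is pasted at that location (shift `(0, 0)`). Otherwise a greedy grid
#' search scans integer shifts `(sx, sy)` over `shift_range` at `stepsize`
#' (rows outer, cols inner, ascending), tracking the lowest overlap and — by
#' default — stopping at the first shift below `tau`. The winning shift is
#' re-applied synchronously to the source's subregion labels (nearest
#' neighbor) and to all image channels (bilinear), so the multi-channel
#' signal moves as a coupled unit.
#'
#' The unshifted placement is the first evaluated candidate, so the returned
#' overlap never exceeds it; with `early_stop = FALSE` and `stepsize = 1` the
#' returned overlap is the exact minimum over the full shift grid. Ties keep
#' the earliest-scanned shift.
#'
#' @param source,target [labeled_sample()] objects (padded to a common grid
#'   internally if sizes differ).
#' @param p Primary-region ID; must be present in `source`.
#' @param taxonomy A [region_taxonomy()].
#' @param config A [search_config()].
#' @param seed Optional integer seed for the affine draw.
#' @return An object of class `oaa_result`: `mask` (optimized placement
#'   mask), `labels` (transported source subregion labels, nonzero exactly on
#'   `mask`), `image_patch` (transformed source channels, zero outside
#'   `mask`), `overlap` (achieved pixel count), `shift`, `converged`
#'   (`overlap < tau`), `tau` (resolved pixel tolerance), `params`, `centre`,
#'   and `n_evaluated` (number of shift-grid evaluations).
#' @export
oaa <- function(source, target, p, taxonomy, config = search_config(),
                seed = NULL) {
  stopifnot(inherits(config, "search_config"))
  ps <- pad_to_common(source, target)
  source <- ps[[1]]; target <- ps[[2]]
  dims <- dim(source$labels)
  config <- resolve_search_config(config, dims)

  subs <- subregions_of(taxonomy, p)
  lab_p <- source$labels
  lab_p[!(lab_p %in% subs)] <- 0L
  if (!any(lab_p > 0L))
    stop(sprintf("primary region %d is absent from source '%s'", p, source$sample_id),
         call. = FALSE)
  Mtp <- extract_primary_mask(target$labels, taxonomy, p)
  anti <- if (config$overlap_mode == "foreground") {
    target$labels > 0L & !Mtp
  } else {
    !Mtp
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1L, config$restarts))) {
      cand <- oaa_single(lab_p, anti, dims, config)
      if (is.null(best) || cand$overlap < best$overlap) best <- cand
      if (best$converged) break
    }
    res <- best
    # Transport labels and image channels under the winning transform + shift.
    labels_t <- shift_grid(res$labels_t, res$shift)
    mask <- labels_t > 0L
    img_t <- shift_grid(
      apply_affine(source$image, res$params, centre = res$centre,
                   filter = "bilinear"),
      res$shift)
    img_t[array(!mask, dim(img_t))] <- 0
    structure(list(mask = mask, labels = labels_t, image_patch = img_t,
                   overlap = res$overlap, shift = res$shift,
                   converged = res$converged, tau = res$tau,
                   params = res$params, centre = res$centre,
                   n_evaluated = res$n_evaluated),
              class = "oaa_result")
  })
}

# One affine draw + greedy shift search on the label grid only.
oaa_single <- function(lab_p, anti, dims, config) {
  params <- affine_params(
    stats::runif(1, config$rotation_range[1], config$rotation_range[2]),
    stats::runif(1, config$scale_range[1], config$scale_range[2]),
    stats::runif(2, config$translation_range[1], config$translation_range[2]))
  centre <- mask_centroid(lab_p)
  labels_t <- apply_affine(lab_p, params, centre = centre, filter = "nearest")
  if (!any(labels_t > 0L))
    stop("affine transform produced an empty region mask (degenerate result)",
         call. = FALSE)
  q <- which(labels_t > 0L)
  qr <- ((q - 1L) %% dims[1]) + 1L
  qc <- ((q - 1L) %/% dims[1]) + 1L
  area <- length(q)
  tau <- config$tau %||% ceiling(config$tau_rel * area)
  anti_v <- as.vector(anti)
  H <- dims[1]

  ov_at <- function(sx, sy) {
    r2 <- qr + sx; c2 <- qc + sy
    ok <- r2 >= 1L & r2 <= dims[1] & c2 >= 1L & c2 <= dims[2]
    sum(anti_v[(c2[ok] - 1L) * H + r2[ok]])
  }

  best_o <- ov_at(0L, 0L)
  best_s <- c(0L, 0L)
  n_eval <- 0L
  if (best_o >= tau) {
    shifts <- seq(config$shift_range[1], config$shift_range[2], by = config$stepsize)
    shifts <- as.integer(round(shifts))
    done <- FALSE
    for (sx in shifts) {
      for (sy in shifts) {
        o <- ov_at(sx, sy)
        n_eval <- n_eval + 1L
        if (o < best_o) {
          best_o <- o
          best_s <- c(sx, sy)
        }
        if (config$early_stop && best_o < tau) { done <- TRUE; break }
      }
      if (done) break
    }
  }
  list(params = params, centre = centre, labels_t = labels_t,
       overlap = best_o, shift = best_s, converged = best_o < tau,
       tau = tau, n_evaluated = n_eval)
}

#' @export
print.oaa_result <- function(x, ...) {
  cat(sprintf(
    "<oaa_result> overlap %d px (tau %d, %s), shift (%d, %d), rot %.2f deg, scale %.3f, %d shift evals\n",
    x$overlap, x$tau, if (x$converged) "converged" else "not converged",
    x$shift[1], x$shift[2], x$params$rotation, x$params$scale, x$n_evaluated))
  invisible(x)
}
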