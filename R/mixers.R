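#' Mixing configuration
#'
#' Controls multi-source primary-region mixing: how many images take part in
#' one mix (`n_mix_images`, target included; three is the empirically best
#' setting), how many primary regions are replaced per mix (a uniform integer
#' draw from `regions_per_mix`, default 3 to 9), the hard-candidate
#' oversampling rate, the placement search knobs, and the post-mix label
#' opening radius.
#'
#' @param n_mix_images Total images per mix (target + sources); default 3.
#' @param regions_per_mix Integer range `c(min, max)`; default `c(3, 9)`.
#' @param hard_fraction Probability of drawing a hard source; default 0.8.
#' @param search A [search_config()].
#' @param opening_radius Disk radius (pixels) for the post-mix label opening;
#'   default 1.
#' @param vacated `"background"` (default) assigns label 0 and zero intensity
#'   to target-region pixels not covered by the pasted source;
#'   `"retain"` keeps the target content there instead.
#' @return An object of class `mix_config`.
#' @export
mix_config <- function(n_mix_images = 3L, regions_per_mix = c(3L, 9L),
                       hard_fraction = 0.8, search = search_config(),
                       opening_radius = 1L,
                       vacated = c("background", "retain")) {
  vacated <- match.arg(vacated)
  assert_scalar_num(n_mix_images, "n_mix_images", lo = 2)
  if (length(regions_per_mix) != 2L || regions_per_mix[1] > regions_per_mix[2] ||
      regions_per_mix[1] < 1)
    stop("`regions_per_mix` must be c(min, max) with 1 <= min <= max", call. = FALSE)
  assert_scalar_num(hard_fraction, "hard_fraction", lo = 0, hi = 1)
  assert_scalar_num(opening_radius, "opening_radius", lo = 0)
  stopifnot(inherits(search, "search_config"))
  structure(list(n_mix_images = as.integer(n_mix_images),
                 regions_per_mix = as.integer(regions_per_mix),
                 hard_fraction = hard_fraction, search = search,
                 opening_radius = as.integer(opening_radius), vacated = vacated),
            class = "mix_config")
}

#' MixUp: convex blending of a sample pair
#'
#' `X = lam * Xs + (1 - lam) * Xt` per channel. Hard labels are not
#' well-defined under convex blending for segmentation, so labels are
#' returned as a per-class soft weight map: `lam * onehot(Ys) +
#' (1 - lam) * onehot(Yt)`, summing to 1 at every pixel. Use [hard_labels()]
#' for an argmax export.
#'
#' @param source,target [labeled_sample()] objects.
#' @param lam Blending factor in `[0, 1]`; draw `runif(1)` for the canonical
#'   `U(0, 1)` law.
#' @return An object of class `mixup_sample`: `image`, `label_weights`
#'   (`(H, W, K)` array), `classes` (label value of each weight plane,
#'   background 0 first), `sample_id`.
#' @export
mixup <- function(source, target, lam) {
  assert_scalar_num(lam, "lam", lo = 0, hi = 1)
  ps <- pad_to_common(source, target)
  s <- ps[[1]]; t <- ps[[2]]
  img <- s$image * lam + t$image * (1 - lam)
  classes <- sort(union(unique(as.vector(s$labels)), unique(as.vector(t$labels))))
  K <- length(classes)
  d <- dim(s$labels)
  w <- array(0, c(d, K))
  for (k in seq_len(K)) {
    w[, , k] <- lam * (s$labels == classes[k]) + (1 - lam) * (t$labels == classes[k])
  }
  structure(list(image = img, label_weights = w, classes = as.integer(classes),
                 sample_id = sprintf("mixup(%s,%s)", s$sample_id, t$sample_id)),
            class = "mixup_sample")
}

#' Collapse soft MixUp labels to a hard label map
#'
#' @param x A `mixup_sample`.
#' @return Integer label matrix (argmax class per pixel; ties keep the
#'   lowest class value).
#' @export
hard_labels <- function(x) {
  stopifnot(inherits(x, "mixup_sample"))
  d <- dim(x$label_weights)
  flat <- matrix(x$label_weights, d[1] * d[2], d[3])
  matrix(x$classes[max.col(flat, ties.method = "first")], d[1], d[2])
}

#' Masked mixing (CutMix / CarveMix form)
#'
#' `X = Xs * M + Xt * (1 - M)` and likewise for labels: inside the binary
#' mask the source content is used, outside the target's. With an
#' axis-aligned rectangular mask this is CutMix; with a label-derived
#' semantic mask it is CarveMix-style. See [cutmix_mask()] and
#' [carvemix_mask()] for the two mask constructors.
#'
#' @param source,target [labeled_sample()] objects.
#' @param mask Logical matrix on the common grid.
#' @return A [labeled_sample()].
#' @export
masked_mix <- function(source, target, mask) {
  ps <- pad_to_common(source, target)
  s <- ps[[1]]; t <- ps[[2]]
  if (!all(dim(mask) == dim(s$labels)))
    stop("mask grid does not match the (padded) sample grid", call. = FALSE)
  img <- t$image
  img[array(mask, dim(img))] <- s$image[array(mask, dim(img))]
  lab <- t$labels
  lab[mask] <- s$labels[mask]
  labeled_sample(img, lab, sprintf("maskmix(%s,%s)", s$sample_id, t$sample_id))
}

#' Rectangular CutMix mask
#'
#' Draws an axis-aligned rectangle covering approximately `area_frac` of the
#' grid (side lengths scale with `sqrt(area_frac)`), uniformly positioned and
#' clipped to the grid.
#'
#' @param dims Grid `c(H, W)`.
#' @param area_frac Target area fraction in `(0, 1]`; default a `U(0, 1)`
#'   draw.
#' @param seed Optional integer seed.
#' @return Logical matrix.
#' @export
cutmix_mask <- function(dims, area_frac = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(area_frac)) area_frac <- stats::runif(1)
    assert_scalar_num(area_frac, "area_frac", lo = 0, hi = 1)
    h <- max(1L, round(dims[1] * sqrt(area_frac)))
    w <- max(1L, round(dims[2] * sqrt(area_frac)))
    r0 <- sample.int(max(1L, dims[1] - h + 1L), 1L)
    c0 <- sample.int(max(1L, dims[2] - w + 1L), 1L)
    m <- matrix(FALSE, dims[1], dims[2])
    m[r0:min(dims[1], r0 + h - 1L), c0:min(dims[2], c0 + w - 1L)] <- TRUE
    m
  })
}

#' Semantic CarveMix-style mask
#'
#' The mask of one primary region of the source sample (a label-derived
#' semantic region pasted at its original location).
#'
#' @param sample A [labeled_sample()].
#' @param taxonomy A [region_taxonomy()].
#' @param p Primary-region ID; default a uniform draw among regions present.
#' @param seed Optional integer seed.
#' @return Logical matrix.
#' @export
carvemix_mask <- function(sample, taxonomy, p = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(p)) {
      present <- primary_regions_present(sample$labels, taxonomy)
      if (length(present) == 0L)
        stop("sample has no foreground region to carve", call. = FALSE)
      p <- present[sample.int(length(present), 1L)]
    }
    extract_primary_mask(sample$labels, taxonomy, p)
  })
}

#' PRMix: pairwise primary-region mix
#'
#' For each requested primary region `p`, runs the overlap-aware placement
#' [oaa()] to obtain an overlap-mitigated source mask with its transported
#' subregion labels and image channels, then composes
#' `X = Xs_hat * Ms_hat + Xt * (1 - Mtp)`: the target's own region content is
#' removed, the placed source content substituted, and pixels vacated by the
#' target region but not covered by the placement become background (label 0,
#' zero intensity) under the default `vacated = "background"` policy. Both
#' fluorescence channels are pasted as one coupled unit; no label value is
#' ever invented. Regions are processed in ascending ID order.
#'
#' @param source,target [labeled_sample()] objects.
#' @param regions Integer vector of primary-region IDs; each must be present
#'   in both samples (`on_missing = "error"`) or is skipped with a warning
#'   (`on_missing = "skip"`).
#' @param taxonomy A [region_taxonomy()].
#' @param config A [mix_config()].
#' @param seed Optional integer seed.
#' @param on_missing `"error"` or `"skip"`.
#' @param keep_oaa Keep the full [oaa()] results (masks and patches) in the
#'   manifest; default `FALSE` stores diagnostics only.
#' @return A [labeled_sample()] with a `manifest` field: per-region source
#'   ID, placement diagnostics (overlap, shift, converged, affine), and any
#'   skipped regions.
#' @export
prmix_pair <- function(source, target, regions, taxonomy, config = mix_config(),
                       seed = NULL, on_missing = c("error", "skip"),
                       keep_oaa = FALSE) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(config, "mix_config"))
  ps <- pad_to_common(source, target)
  source <- ps[[1]]; target <- ps[[2]]
  regions <- sort(unique(as.integer(regions)))
  out_img <- target$image
  out_lab <- target$labels
  diag_list <- list()
  skipped <- integer(0)
  with_seed(seed, {
    for (p in regions) {
      in_s <- any(extract_primary_mask(source$labels, taxonomy, p))
      in_t <- any(extract_primary_mask(out_lab, taxonomy, p))
      if (!in_s || !in_t) {
        msg <- sprintf("region %d absent from %s", p,
                       if (!in_s) sprintf("source '%s'", source$sample_id)
                       else sprintf("target '%s'", target$sample_id))
        if (on_missing == "error") stop(msg, call. = FALSE)
        warning(paste0(msg, "; skipping"))
        skipped <- c(skipped, p)
        next
      }
      res <- tryCatch(
        oaa(source, labeled_sample(out_img, out_lab, target$sample_id),
            p, taxonomy, config$search),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("placement of region %d failed (%s); target content retained",
                        p, conditionMessage(res)))
        skipped <- c(skipped, p)
        next
      }
      Mtp <- extract_primary_mask(out_lab, taxonomy, p)
      if (config$vacated == "background") {
        vac <- Mtp & !res$mask
        out_lab[vac] <- 0L
        out_img[array(vac, dim(out_img))] <- 0
      }
      out_lab[res$mask] <- res$labels[res$mask]
      sel <- array(res$mask, dim(out_img))
      out_img[sel] <- res$image_patch[sel]
      d <- list(region = p, source_id = source$sample_id,
                overlap = res$overlap, tau = res$tau, shift = res$shift,
                converged = res$converged,
                rotation = res$params$rotation, scale = res$params$scale,
                translation = res$params$translation, centre = res$centre)
      if (keep_oaa) d$oaa <- res
      diag_list[[as.character(p)]] <- d
    }
  })
  out <- labeled_sample(out_img, out_lab,
                        sprintf("prmix(%s<-%s)", target$sample_id, source$sample_id))
  out$manifest <- list(target_id = target$sample_id, source_ids = source$sample_id,
                       regions = setdiff(regions, skipped), skipped = skipped,
                       placements = diag_list)
  out
}

#' PRMix: iterated multi-source primary-region mix
#'
#' The multi-source extension: draws the number of regions to replace
#' (uniform integer in `regions_per_mix`, capped by availability), selects
#' that many distinct primary regions uniformly among those present in the
#' target and in at least one source, assigns each region to a uniformly
#' chosen eligible source, and folds [prmix_pair()] over the sources — each
#' iteration replacing its assigned regions in the running target. The
#' output's `manifest` records every replaced region, its source, and the
#' placement diagnostics.
#'
#' @param sources List of [labeled_sample()] (length `n_mix_images - 1`).
#' @param target A [labeled_sample()].
#' @param taxonomy A [region_taxonomy()].
#' @param config A [mix_config()].
#' @param regions Optional forced region selection (skips the draw); regions
#'   not eligible are skipped with a warning.
#' @param seed Optional integer seed.
#' @param keep_oaa See [prmix_pair()].
#' @return A [labeled_sample()] with a `manifest` field.
#' @export
prmix_multi <- function(sources, target, taxonomy, config = mix_config(),
                        regions = NULL, seed = NULL, keep_oaa = FALSE) {
  stopifnot(inherits(config, "mix_config"), length(sources) >= 1L)
  with_seed(seed, {
    tgt_regions <- primary_regions_present(target$labels, taxonomy)
    src_regions <- lapply(sources, function(s)
      primary_regions_present(s$labels, taxonomy))
    eligible <- intersect(tgt_regions, sort(unique(unlist(src_regions))))
    if (is.null(regions)) {
      if (length(eligible) == 0L) {
        warning("no primary region is shared between the target and any source; returning the target unchanged")
        out <- target
        out$manifest <- list(target_id = target$sample_id,
                             source_ids = character(0), regions = integer(0),
                             skipped = integer(0), placements = list())
        return(out)
      }
      r <- sample.int(config$regions_per_mix[2] - config$regions_per_mix[1] + 1L,
                      1L) + config$regions_per_mix[1] - 1L
      r <- min(r, length(eligible))
      regions <- sort(eligible[sample.int(length(eligible), r)])
    } else {
      regions <- sort(unique(as.integer(regions)))
    }
    # assign each region to a uniformly chosen source that contains it
    assignment <- stats::setNames(integer(length(regions)), regions)
    for (k in seq_along(regions)) {
      holders <- which(vapply(src_regions, function(rs) regions[k] %in% rs,
                              logical(1)))
      assignment[k] <- if (length(holders))
        holders[sample.int(length(holders), 1L)] else NA_integer_
    }
    running <- target
    all_diag <- list()
    skipped <- regions[is.na(assignment)]
    for (si in seq_along(sources)) {
      mine_regions <- regions[!is.na(assignment) & assignment == si]
      if (length(mine_regions) == 0L) next
      running <- prmix_pair(sources[[si]], running, mine_regions, taxonomy,
                            config, on_missing = "skip", keep_oaa = keep_oaa)
      all_diag <- c(all_diag, running$manifest$placements)
      skipped <- c(skipped, running$manifest$skipped)
    }
    replaced <- as.integer(names(all_diag))
    out <- labeled_sample(running$image, running$labels,
                          sprintf("prmix(%s)", target$sample_id))
    out$manifest <- list(
      target_id = target$sample_id,
      source_ids = vapply(sources, `[[`, character(1), "sample_id"),
      regions = sort(replaced), n_regions = length(replaced),
      skipped = sort(unique(skipped)),
      assignment = stats::setNames(
        vapply(sources, `[[`, character(1), "sample_id")[assignment[!is.na(assignment)]],
        regions[!is.na(assignment)]),
      placements = all_diag)
    out
  })
}

#' Per-label morphological opening of a label map
#'
#' Erosion followed by dilation with a disk structuring element, applied to
#' each label's binary mask in ascending label order; smooths the artificial
#' boundary edges left by mixing. Opening is anti-extensive, so opened masks
#' stay inside their original labels and never collide; pixels removed from a
#' label and claimed by no other become background. Radius 0 is the identity.
#'
#' @param labels Integer label matrix.
#' @param radius Disk radius in pixels (structuring element
#'   `EBImage::makeBrush(2 * radius + 1, "disc")`).
#' @return Integer label matrix of the same shape.
#' @export
morphological_opening <- function(labels, radius = 1L) {
  assert_scalar_num(radius, "radius", lo = 0)
  if (radius == 0) return(labels)
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (lv in sort(setdiff(unique(as.vector(labels)), 0L))) {
    m <- EBImage::opening((labels == lv) * 1, kern)
    out[EBImage::imageData(m) > 0.5] <- as.integer(lv)
  }
  out
}
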