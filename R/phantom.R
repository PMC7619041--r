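#' Phantom generator configuration
#'
#' Defaults emulate the statistics of annotated dual-fluorescence parasagittal
#' sections: a near-dense elliptical "brain" foreground with a
#' foreground-to-background pixel ratio of about 0.84, eleven contiguous
#' primary regions subdivided into a two-level label hierarchy (subregion
#' totals near 118 at the default 2-12 subregions per primary), two coupled
#' intensity channels with region-specific means, and per-sample missing
#' primary regions at a 10% dropout rate (sections cut at slightly different
#' planes lack different structures). The default 256 x 512 grid keeps the
#' native portrait-through-landscape aspect while staying desk-sized; the
#' native section scale is reachable through `grid` but not needed for
#' testing.
#'
#' @param grid `c(H, W)`; default `c(256, 512)`.
#' @param n_primary Number of primary regions; default 11.
#' @param subregions_per_primary Integer range, default `c(2, 12)`.
#' @param foreground_ratio_target Foreground:background pixel ratio the
#'   elliptical foreground is sized to; default 0.84.
#' @param channel_count Intensity channels; default 2.
#' @param intensity_contrast Width of the band subregion mean intensities are
#'   drawn from; default 0.6.
#' @param dropout_prob Probability a primary region is absent from a given
#'   sample; default 0.1.
#' @param texture_noise_sd Gaussian texture noise SD; default 0.05.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(256L, 512L), n_primary = 11L,
                           subregions_per_primary = c(2L, 12L),
                           foreground_ratio_target = 0.84,
                           channel_count = 2L, intensity_contrast = 0.6,
                           dropout_prob = 0.1, texture_noise_sd = 0.05) {
  stopifnot(length(grid) == 2L, all(grid >= 1))
  assert_scalar_num(n_primary, "n_primary", lo = 1)
  assert_scalar_num(foreground_ratio_target, "foreground_ratio_target")
  if (foreground_ratio_target <= 0)
    stop("`foreground_ratio_target` must be positive", call. = FALSE)
  if (foreground_ratio_target / (1 + foreground_ratio_target) > 0.785)
    stop("`foreground_ratio_target` too large for an inscribed ellipse", call. = FALSE)
  assert_scalar_num(dropout_prob, "dropout_prob", lo = 0)
  if (dropout_prob >= 1) stop("`dropout_prob` must be below 1", call. = FALSE)
  assert_scalar_num(channel_count, "channel_count", lo = 1)
  assert_scalar_num(intensity_contrast, "intensity_contrast", lo = 0.05, hi = 0.75)
  assert_scalar_num(texture_noise_sd, "texture_noise_sd", lo = 0)
  stopifnot(length(subregions_per_primary) == 2L,
            subregions_per_primary[1] >= 1,
            subregions_per_primary[1] <= subregions_per_primary[2])
  if (prod(grid) < 4 * n_primary)
    stop("grid too small: need at least 4 pixels per primary region", call. = FALSE)
  structure(list(grid = as.integer(grid), n_primary = as.integer(n_primary),
                 subregions_per_primary = as.integer(subregions_per_primary),
                 foreground_ratio_target = foreground_ratio_target,
                 channel_count = as.integer(channel_count),
                 intensity_contrast = intensity_contrast,
                 dropout_prob = dropout_prob,
                 texture_noise_sd = texture_noise_sd),
            class = "phantom_config")
}

#' Draw a taxonomy for a phantom dataset
#'
#' Samples the number of subregions per primary region from
#' `subregions_per_primary` and assigns consecutive subregion labels to each
#' primary. One taxonomy is shared by all samples of a dataset.
#'
#' @param config A [phantom_config()].
#' @param seed Optional integer seed.
#' @return A [region_taxonomy()].
#' @export
phantom_taxonomy <- function(config, seed = NULL) {
  with_seed(seed, {
    lo <- config$subregions_per_primary[1]
    hi <- config$subregions_per_primary[2]
    k <- lo + sample.int(hi - lo + 1L, config$n_primary, replace = TRUE) - 1L
    region_taxonomy(
      stats::setNames(rep(seq_len(config$n_primary), k), seq_len(sum(k))),
      sprintf("P%02d", seq_len(config$n_primary)))
  })
}

#' Generate one synthetic labeled phantom
#'
#' Builds an elliptical foreground sized so that the foreground:background
#' pixel ratio matches `foreground_ratio_target`, partitions it into
#' contiguous primary regions by Voronoi growth from random interior seed
#' points (after applying per-region dropout: dropped regions' territory is
#' absorbed by the surviving neighbors), subdivides each primary region into
#' its taxonomy subregions by a second Voronoi pass, and paints each
#' subregion with per-channel mean intensities plus Gaussian texture noise.
#' Channel means within a subregion share a common base level, emulating the
#' coupled expression of the two synaptic markers.
#'
#' @param config A [phantom_config()].
#' @param taxonomy Optional shared [region_taxonomy()] (drawn via
#'   [phantom_taxonomy()] when `NULL`).
#' @param seed Optional integer seed.
#' @param sample_id Sample ID string.
#' @return A list with elements `sample` ([labeled_sample()]) and `taxonomy`.
#' @export
generate_phantom <- function(config = phantom_config(), taxonomy = NULL,
                             seed = NULL, sample_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    if (is.null(taxonomy)) taxonomy <- phantom_taxonomy(config)
    H <- config$grid[1]; W <- config$grid[2]
    frac <- config$foreground_ratio_target / (1 + config$foreground_ratio_target)

    # elliptical foreground, slight per-sample aspect/centre jitter that
    # preserves area (hence the foreground ratio) up to discretization
    t0 <- sqrt(frac / pi)
    u <- stats::runif(1, 0.93, 1.07)
    a <- t0 * H * u
    b <- t0 * W / u
    cy <- H / 2 + stats::runif(1, -0.015, 0.015) * H
    cx <- W / 2 + stats::runif(1, -0.015, 0.015) * W
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    fg <- ((rr - cy) / a)^2 + ((cc - cx) / b)^2 <= 1
    fg_idx <- which(fg)
    fr <- rr[fg_idx]; fc <- cc[fg_idx]

    # primary-region dropout, then Voronoi growth from surviving seeds
    keep <- stats::runif(config$n_primary) >= config$dropout_prob
    if (!any(keep)) keep[sample.int(config$n_primary, 1L)] <- TRUE
    kept <- which(keep)
    seeds <- fg_idx[sample.int(length(fg_idx), length(kept))]
    sr <- rr[seeds]; sc <- cc[seeds]
    d2 <- outer(fr, sr, `-`)^2 + outer(fc, sc, `-`)^2
    pri_of_px <- kept[max.col(-d2, ties.method = "first")]

    labels <- matrix(0L, H, W)
    for (p in kept) {
      px <- fg_idx[pri_of_px == p]
      if (length(px) == 0L) next
      subs <- subregions_of(taxonomy, p)
      k <- min(length(subs), length(px))
      sseed <- px[sample.int(length(px), k)]
      d2s <- outer(rr[px], rr[sseed], `-`)^2 + outer(cc[px], cc[sseed], `-`)^2
      labels[px] <- subs[max.col(-d2s, ties.method = "first")]
    }

    # region-specific channel intensities: correlated channels via shared base
    all_subs <- as.integer(names(taxonomy$subregion_to_primary))
    base <- stats::setNames(stats::runif(length(all_subs)), all_subs)
    img <- array(0, c(H, W, config$channel_count))
    lab_v <- as.vector(labels)
    fg_v <- lab_v > 0L
    lo_mean <- (1 - config$intensity_contrast) / 2
    for (ch in seq_len(config$channel_count)) {
      wobble <- stats::setNames(
        clamp01(base + stats::runif(length(all_subs), -0.12, 0.12)), all_subs)
      means <- lo_mean + config$intensity_contrast * wobble
      plane <- numeric(H * W)
      plane[fg_v] <- means[as.character(lab_v[fg_v])] +
        stats::rnorm(sum(fg_v), 0, config$texture_noise_sd)
      img[, , ch] <- clamp01(matrix(plane, H, W))
    }
    list(sample = labeled_sample(img, labels, sample_id, taxonomy),
         taxonomy = taxonomy)
  })
}

#' Generate a phantom dataset sharing one taxonomy
#'
#' Draws the shared taxonomy from `seed`, then generates `n` phantoms with
#' per-sample derived seeds, so the whole dataset is reproducible from
#' `(n, config, seed)`.
#'
#' @param n Number of samples.
#' @param config A [phantom_config()].
#' @param seed Integer master seed.
#' @return A list with `samples` (list of [labeled_sample()]) and `taxonomy`.
#' @export
generate_dataset <- function(n, config = phantom_config(), seed = 1L) {
  assert_scalar_num(n, "n", lo = 1)
  taxonomy <- phantom_taxonomy(config, seed = derive_seed(seed, "taxonomy"))
  samples <- lapply(seq_len(n), function(i) {
    generate_phantom(config, taxonomy, seed = derive_seed(seed, "phantom", i),
                     sample_id = sprintf("phantom%03d", i))$sample
  })
  list(samples = samples, taxonomy = taxonomy)
}

#' Write a phantom dataset to a directory
#'
#' Writes `<id>_img.tif` / `<id>_lab.tif` per sample plus `taxonomy.json`, the
#' directory layout the pipeline driver [augment_dataset()] reads.
#'
#' @param dataset A [generate_dataset()] result (or a list with `samples` and
#'   `taxonomy`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.json"))
  for (s in dataset$samples) {
    write_sample(s, file.path(dir, sprintf("%s_img.tif", s$sample_id)),
                 file.path(dir, sprintf("%s_lab.tif", s$sample_id)))
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `taxonomy.json` and paired
#'   `*_img.tif` / `*_lab.tif` files.
#' @return A list with `samples` and `taxonomy`.
#' @export
read_dataset <- function(dir) {
  tax_path <- file.path(dir, "taxonomy.json")
  if (!file.exists(tax_path))
    stop(sprintf("no taxonomy.json in '%s'", dir), call. = FALSE)
  taxonomy <- read_taxonomy(tax_path)
  imgs <- sort(list.files(dir, pattern = "_img\\.(tif|tiff|png)$", full.names = TRUE))
  if (length(imgs) == 0L)
    stop(sprintf("no '*_img.*' files found in '%s'", dir), call. = FALSE)
  samples <- lapply(imgs, function(ip) {
    id <- sub("_img\\.[^.]+$", "", basename(ip))
    lp <- list.files(dir, pattern = paste0("^", id, "_lab\\.(tif|tiff|png)$"),
                     full.names = TRUE)
    if (length(lp) != 1L)
      stop(sprintf("missing label map for sample '%s'", id), call. = FALSE)
    load_sample(ip, lp, taxonomy, sample_id = id)
  })
  list(samples = samples, taxonomy = taxonomy)
}
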