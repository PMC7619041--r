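#' Run configuration for offline dataset augmentation
#'
#' @param input_dir Directory with samples + `taxonomy.json`
#'   (see [write_dataset()]); may be `NULL` when driving [augment_samples()]
#'   in memory.
#' @param output_dir Output directory for augmented samples + manifest.
#' @param fold_multiplier Augmented samples per original target (5/10/20 are
#'   the usual presets); default 5.
#' @param mix A [mix_config()].
#' @param method One of `"prmix"`, `"mixup"`, `"cutmix"`, `"carvemix"`.
#' @param easy_fraction Easy fraction for mining; default 0.2.
#' @param pre_transforms Named logical toggles `normalize` (per-channel
#'   rescale to `[0, 1]`), `jitter` (per-channel gain/offset), `affine`
#'   (global small affine); all off by default.
#' @param retry_skips Retry a skipped mix with a fresh region draw instead of
#'   counting it; default `FALSE` so output counts stay predictable.
#' @param seed Integer master seed; every per-mix stream is derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = NULL,
                       fold_multiplier = 5L, mix = mix_config(),
                       method = c("prmix", "mixup", "cutmix", "carvemix"),
                       easy_fraction = 0.2,
                       pre_transforms = list(normalize = FALSE, jitter = FALSE,
                                             affine = FALSE),
                       retry_skips = FALSE, seed = 1L) {
  method <- match.arg(method)
  assert_scalar_num(fold_multiplier, "fold_multiplier", lo = 1)
  stopifnot(inherits(mix, "mix_config"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 fold_multiplier = as.integer(fold_multiplier), mix = mix,
                 method = method, easy_fraction = easy_fraction,
                 pre_transforms = pre_transforms,
                 retry_skips = isTRUE(retry_skips), seed = as.integer(seed)),
            class = "run_config")
}

#' Offline augmentation over an in-memory dataset
#'
#' The core pipeline: mines the similarity table once, then for each of
#' `fold_multiplier` passes over every target draws sources (oversampling
#' hard candidates), draws the primary regions to replace, applies the
#' selected mixing method, and applies the post-mix label opening. For PRMix,
#' regions are drawn from the full taxonomy `1..P`; a mix whose drawn regions
#' include one absent from the target or from every source is skipped and
#' counted (the exclusion rule), so
#' `length(outputs) + skips == n_targets * fold_multiplier`. Every per-mix
#' random stream is derived from `(seed, target_id, pass)`, making reruns
#' bit-identical.
#'
#' @param samples List of [labeled_sample()] (`>= 2`).
#' @param taxonomy A [region_taxonomy()].
#' @param config A [run_config()].
#' @param table Optional pre-computed [mine()] table.
#' @return List with `outputs` (labeled samples; `mixup_sample`s for MixUp),
#'   `manifest` (per-mix provenance, skip log, seed, config hash), and
#'   `table`.
#' @export
augment_samples <- function(samples, taxonomy, config = run_config(),
                            table = NULL) {
  stopifnot(inherits(config, "run_config"), length(samples) >= 2L)
  for (s in samples) validate_sample(s, taxonomy)
  if (is.null(table)) table <- mine(samples, taxonomy, config$easy_fraction)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  by_id <- stats::setNames(samples, ids)
  n_sources <- config$mix$n_mix_images - 1L
  outputs <- list()
  entries <- list()
  skips <- 0L
  for (pass in seq_len(config$fold_multiplier)) {
    for (tid in ids) {
      mix_seed <- derive_seed(config$seed, tid, pass)
      entry <- with_seed(mix_seed, run_one_mix(
        by_id, tid, table, taxonomy, config, pass))
      entry$seed <- mix_seed
      if (entry$skipped) {
        skips <- skips + 1L
      } else {
        out <- entry$output
        out$sample_id <- sprintf("%s_p%02d_%s", tid, pass, config$method)
        entry$output_id <- out$sample_id
        outputs[[out$sample_id]] <- out
      }
      entry$output <- NULL
      entries[[length(entries) + 1L]] <- entry
    }
  }
  manifest <- list(method = config$method, seed = config$seed,
                   fold_multiplier = config$fold_multiplier,
                   n_targets = length(ids), n_outputs = length(outputs),
                   skips = skips,
                   config_hash = config_hash(serialize_run_config(config)),
                   mixes = entries)
  list(outputs = outputs, manifest = manifest, table = table)
}

# One mix attempt for (target, pass); runs inside a derived-seed stream.
run_one_mix <- function(by_id, tid, table, taxonomy, config, pass) {
  target <- by_id[[tid]]
  n_sources <- config$mix$n_mix_images - 1L
  entry <- list(target_id = tid, pass = pass, method = config$method,
                skipped = FALSE)
  repeat {
    if (config$method == "mixup") {
      src_id <- sample_sources(table, tid, 1L, config$mix$hard_fraction)
      lam <- stats::runif(1)
      out <- mixup(by_id[[src_id]], target, lam)
      out <- apply_pre_transforms(out, config$pre_transforms)
      entry$source_ids <- src_id; entry$lambda <- lam
      entry$output <- out
      return(entry)
    }
    if (config$method %in% c("cutmix", "carvemix")) {
      src_id <- sample_sources(table, tid, 1L, config$mix$hard_fraction)
      src <- by_id[[src_id]]
      mask <- if (config$method == "cutmix") {
        cutmix_mask(dim(target$labels))
      } else {
        carvemix_mask(src, taxonomy)
      }
      out <- masked_mix(src, target, mask)
      out$labels <- morphological_opening(out$labels, config$mix$opening_radius)
      out <- apply_pre_transforms(out, config$pre_transforms)
      entry$source_ids <- src_id
      entry$output <- out
      return(entry)
    }
    # prmix: draw regions from the full taxonomy, apply the exclusion rule
    src_ids <- sample_sources(table, tid, n_sources, config$mix$hard_fraction)
    sources <- by_id[src_ids]
    rpm <- config$mix$regions_per_mix
    r <- sample.int(rpm[2] - rpm[1] + 1L, 1L) + rpm[1] - 1L
    r <- min(r, taxonomy$P)
    drawn <- sort(sample.int(taxonomy$P, r))
    tgt_regions <- primary_regions_present(target$labels, taxonomy)
    src_regions <- sort(unique(unlist(lapply(sources, function(s)
      primary_regions_present(s$labels, taxonomy)))))
    missing <- drawn[!(drawn %in% tgt_regions) | !(drawn %in% src_regions)]
    if (length(missing)) {
      if (config$retry_skips) next
      entry$skipped <- TRUE
      entry$source_ids <- src_ids
      entry$regions_drawn <- drawn
      entry$missing_regions <- missing
      return(entry)
    }
    out <- prmix_multi(sources, target, taxonomy, config$mix, regions = drawn)
    out$labels <- morphological_opening(out$labels, config$mix$opening_radius)
    out <- apply_pre_transforms(out, config$pre_transforms)
    entry$source_ids <- src_ids
    entry$regions_drawn <- drawn
    entry$mix_manifest <- out$manifest[c("regions", "n_regions", "skipped",
                                         "assignment", "placements")]
    entry$output <- out
    return(entry)
  }
}

# Minimal standard pre-transforms, off by default.
apply_pre_transforms <- function(out, toggles) {
  if (!any(unlist(toggles))) return(out)
  img <- out$image
  C <- dim(img)[3]
  if (isTRUE(toggles$normalize)) {
    for (k in seq_len(C)) {
      v <- img[, , k]
      rng <- range(v)
      if (rng[2] > rng[1]) img[, , k] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (isTRUE(toggles$jitter)) {
    for (k in seq_len(C)) {
      gain <- stats::runif(1, 0.9, 1.1)
      off <- stats::runif(1, -0.05, 0.05)
      img[, , k] <- clamp01(img[, , k] * gain + off)
    }
  }
  if (isTRUE(toggles$affine)) {
    params <- affine_params(stats::runif(1, -5, 5), stats::runif(1, 0.95, 1.05),
                            stats::runif(2, -2, 2))
    centre <- (dim(img)[1:2] + 1) / 2
    img <- apply_affine(img, params, centre = centre, filter = "bilinear")
    if (!inherits(out, "mixup_sample")) {
      out$labels <- apply_affine(out$labels, params, centre = centre,
                                 filter = "nearest")
    } else {
      out$label_weights <- apply_affine(out$label_weights, params,
                                        centre = centre, filter = "bilinear")
    }
  }
  out$image <- img
  out
}

serialize_run_config <- function(config) {
  list(fold_multiplier = config$fold_multiplier, method = config$method,
       easy_fraction = config$easy_fraction, seed = config$seed,
       pre_transforms = config$pre_transforms,
       mix = unclass(config$mix)[c("n_mix_images", "regions_per_mix",
                                   "hard_fraction", "opening_radius", "vacated")],
       search = unclass(config$mix$search))
}

#' Offline augmentation of a dataset directory
#'
#' Disk-level driver: reads `config$input_dir` (layout of [write_dataset()]),
#' runs [augment_samples()], writes every output as image + label TIFF plus a
#' JSON run manifest (`manifest.json`) recording provenance, the skip log,
#' the seed and a config hash. MixUp outputs store the argmax label export.
#'
#' @param config A [run_config()] with `input_dir` and `output_dir` set.
#' @return Invisibly, the run manifest.
#' @export
augment_dataset <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_dir) || is.null(config$output_dir))
    stop("`input_dir` and `output_dir` must be set", call. = FALSE)
  ds <- read_dataset(config$input_dir)
  res <- augment_samples(ds$samples, ds$taxonomy, config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (out in res$outputs) {
    if (inherits(out, "mixup_sample")) {
      out <- labeled_sample(out$image, hard_labels(out), out$sample_id)
    }
    write_sample(out,
                 file.path(config$output_dir, sprintf("%s_img.tif", out$sample_id)),
                 file.path(config$output_dir, sprintf("%s_lab.tif", out$sample_id)))
  }
  write_taxonomy(ds$taxonomy, file.path(config$output_dir, "taxonomy.json"))
  jsonlite::write_json(res$manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(res$manifest)
}
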