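#' Region taxonomy: subregion labels grouped into primary regions
#'
#' A `region_taxonomy` maps every positive integer subregion label found in a
#' label map to exactly one of `P` coarse anatomical "primary regions"
#' (numbered contiguously `1..P`). Primary regions are the unit that PRMix
#' swaps between images; subregion labels travel through mixing unchanged so
#' the provenance of every pixel's annotation is preserved. Background
#' (label 0) never appears in the map.
#'
#' @param map Named integer vector (or coercible list): names are subregion
#'   labels (positive integers as strings), values are primary-region IDs.
#' @param primary_names Character vector naming primary regions `1..P`.
#' @return An object of class `region_taxonomy` with fields
#'   `subregion_to_primary` (named integer vector), `primary_names`, and `P`.
#' @examples
#' tax <- region_taxonomy(c(`1` = 1, `2` = 1, `3` = 2), c("CB", "TH"))
#' subregions_of(tax, 1)
#' @export
region_taxonomy <- function(map, primary_names) {
  map <- unlist(map)
  sub <- suppressWarnings(as.integer(names(map)))
  pri <- as.integer(map)
  if (anyNA(sub) || any(sub <= 0))
    stop("subregion labels must be positive integers; background 0 is never a key",
         call. = FALSE)
  if (anyDuplicated(sub))
    stop("every subregion label must map to exactly one primary region", call. = FALSE)
  primary_names <- as.character(primary_names)
  P <- length(primary_names)
  if (P < 1 || !setequal(unique(pri), seq_len(P)) && !all(pri %in% seq_len(P)))
    stop("primary-region IDs must lie in the contiguous range 1..P", call. = FALSE)
  if (any(pri < 1L | pri > P))
    stop("primary-region IDs must lie in the contiguous range 1..P", call. = FALSE)
  names(pri) <- as.character(sub)
  structure(
    list(subregion_to_primary = pri, primary_names = primary_names, P = P),
    class = "region_taxonomy"
  )
}

#' @export
print.region_taxonomy <- function(x, ...) {
  cat(sprintf("<region_taxonomy> %d primary regions, %d subregions\n",
              x$P, length(x$subregion_to_primary)))
  counts <- tabulate(x$subregion_to_primary, nbins = x$P)
  cat(paste(sprintf("  %d %s (%d subregions)", seq_len(x$P), x$primary_names, counts),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Subregion labels belonging to one primary region
#'
#' @param taxonomy A [region_taxonomy()].
#' @param p Primary-region ID in `1..P`.
#' @return Integer vector of subregion labels (possibly empty).
#' @export
subregions_of <- function(taxonomy, p) {
  stopifnot(inherits(taxonomy, "region_taxonomy"))
  if (!(length(p) == 1L && p %in% seq_len(taxonomy$P)))
    stop(sprintf("unknown primary region %s (taxonomy has 1..%d)", p, taxonomy$P),
         call. = FALSE)
  m <- taxonomy$subregion_to_primary
  as.integer(names(m)[m == p])
}

#' The default 11-primary-region taxonomy
#'
#' Loads the taxonomy bundled with the package: the 11 primary regions of the
#' parasagittal mouse brain (CB, TH, MB, HB, Isocortex, HY, OLF, CTXsp, STR,
#' PAL, HPF) with a synthetic assignment of 118 subregion labels to them. The
#' subregion-to-primary table is a placeholder with realistic per-group
#' counts; users working with a real atlas annotation should supply their own
#' mapping via [read_taxonomy()].
#'
#' @return A [region_taxonomy()] with `P = 11` and 118 subregions.
#' @export
default_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "primary_regions_synthetic.json",
                            package = "prmixr", mustWork = TRUE))
}

#' Read / write a taxonomy JSON file
#'
#' The on-disk format is a JSON object
#' `{"primary": {"1": "CB", ...}, "map": {"101": 1, ...}}` where `primary`
#' names the primary regions `1..P` and `map` assigns each subregion label to
#' a primary-region ID.
#'
#' @param path File path.
#' @return `read_taxonomy()` returns a [region_taxonomy()];
#'   `write_taxonomy()` returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$primary) || is.null(obj$map))
    stop("taxonomy JSON must contain 'primary' and 'map' objects", call. = FALSE)
  ids <- as.integer(names(obj$primary))
  nm <- character(max(ids))
  nm[ids] <- unlist(obj$primary)
  region_taxonomy(obj$map, nm)
}

#' @rdname read_taxonomy
#' @param taxonomy A [region_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "region_taxonomy"))
  obj <- list(
    primary = stats::setNames(as.list(taxonomy$primary_names),
                              as.character(seq_len(taxonomy$P))),
    map = as.list(taxonomy$subregion_to_primary)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
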