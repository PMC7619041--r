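#' Mask-overlap similarity between two labeled samples
#'
#' Structural similarity used by hard-sample mining: the mean, over primary
#' regions present in at least one of the two samples, of the
#' intersection-over-union of the corresponding primary-region masks. A
#' region present in only one sample contributes IoU 0 (maximally
#' dissimilar), so missing-region patterns count toward hardness. The score
#' is symmetric, lies in `[0, 1]`, and equals 1 exactly when all primary
#' masks coincide. Intensity and texture play no role: structural variation
#' is what region mixing must cope with, while ordinary augmentations cover
#' photometric variation.
#'
#' @param a,b [labeled_sample()] objects (grids padded to a common size).
#' @param taxonomy A [region_taxonomy()].
#' @param score_fn Optional replacement for the per-pair score; a function
#'   `(labels_a, labels_b, taxonomy) -> [0, 1]`.
#' @return Similarity in `[0, 1]`.
#' @export
mask_overlap_score <- function(a, b, taxonomy, score_fn = NULL) {
  ps <- pad_to_common(a, b)
  if (!is.null(score_fn)) return(score_fn(ps[[1]]$labels, ps[[2]]$labels, taxonomy))
  la <- ps[[1]]$labels; lb <- ps[[2]]$labels
  if (!any(la > 0L) && !any(lb > 0L))
    stop("similarity is undefined when both samples are entirely background",
         call. = FALSE)
  pa <- primary_map(la, taxonomy)
  pb <- primary_map(lb, taxonomy)
  regions <- sort(union(setdiff(unique(as.vector(pa)), 0L),
                        setdiff(unique(as.vector(pb)), 0L)))
  ious <- vapply(regions, function(p) {
    ma <- pa == p; mb <- pb == p
    u <- sum(ma | mb)
    if (u == 0L) return(NA_real_)
    sum(ma & mb) / u
  }, numeric(1))
  mean(ious)
}

# Map a subregion label matrix to its primary-region IDs (0 stays 0).
primary_map <- function(labels, taxonomy) {
  lut <- integer(max(as.integer(names(taxonomy$subregion_to_primary))) + 1L)
  lut[as.integer(names(taxonomy$subregion_to_primary)) + 1L] <-
    taxonomy$subregion_to_primary
  out <- matrix(lut[labels + 1L], nrow(labels), ncol(labels))
  out
}

#' Offline hard-sample mining over a dataset
#'
#' Computes the full pairwise mask-overlap similarity matrix and, for every
#' target, partitions the remaining samples into an "easy" set (the
#' `ceiling(easy_fraction * (N - 1))` most similar candidates) and a "hard"
#' set (the complement). Ties at the cut are broken by ascending sample ID so
#' the partition is reproducible. Mining is deterministic and intended to run
#' once per dataset; the matrix can be cached with
#' [write_similarity_csv()] / [read_similarity_csv()].
#'
#' @param dataset List of [labeled_sample()] with unique `sample_id`s,
#'   `N >= 2`.
#' @param taxonomy A [region_taxonomy()].
#' @param easy_fraction Fraction of candidates labeled easy; default 0.2.
#' @param score_fn Optional pluggable score (see [mask_overlap_score()]).
#' @return An object of class `similarity_table`: `ids`, symmetric `score`
#'   matrix (unit diagonal for identical maps), per-target `easy` and `hard`
#'   ID lists, and `easy_fraction`.
#' @export
mine <- function(dataset, taxonomy, easy_fraction = 0.2, score_fn = NULL) {
  N <- length(dataset)
  if (N < 2L) stop("hard-sample mining requires at least 2 samples", call. = FALSE)
  assert_scalar_num(easy_fraction, "easy_fraction")
  if (easy_fraction <= 0 || easy_fraction >= 1)
    stop("`easy_fraction` must lie strictly between 0 and 1", call. = FALSE)
  ids <- vapply(dataset, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("sample IDs must be unique", call. = FALSE)
  score <- matrix(NA_real_, N, N, dimnames = list(ids, ids))
  for (i in seq_len(N)) {
    score[i, i] <- mask_overlap_score(dataset[[i]], dataset[[i]], taxonomy, score_fn)
    for (j in seq_len(N)) {
      if (j <= i) next
      s <- mask_overlap_score(dataset[[i]], dataset[[j]], taxonomy, score_fn)
      score[i, j] <- s
      score[j, i] <- s
    }
  }
  partition_table(ids, score, easy_fraction)
}

partition_table <- function(ids, score, easy_fraction) {
  N <- length(ids)
  ne <- as.integer(ceiling(easy_fraction * (N - 1L)))
  easy <- hard <- stats::setNames(vector("list", N), ids)
  for (i in seq_len(N)) {
    others <- setdiff(seq_len(N), i)
    # descending score; ties broken by ascending ID
    ord <- others[order(-score[i, others], ids[others], method = "radix")]
    easy[[i]] <- ids[ord[seq_len(ne)]]
    hard[[i]] <- ids[ord[-seq_len(ne)]]
  }
  structure(list(ids = ids, score = score, easy = easy, hard = hard,
                 easy_fraction = easy_fraction),
            class = "similarity_table")
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("<similarity_table> %d samples, easy fraction %.2f (|easy| = %d per target)\n",
              length(x$ids), x$easy_fraction, length(x$easy[[1]])))
  off <- x$score[upper.tri(x$score)]
  cat(sprintf("  off-diagonal scores: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Sample mixing sources for a target, oversampling hard candidates
#'
#' Draws `n_sources` IDs independently: each draw comes uniformly from the
#' target's hard set with probability `hard_fraction` and uniformly from its
#' easy set otherwise (the empirically best setting oversamples 80% hard).
#' Sources are always distinct from the target; independent draws may repeat
#' an ID. If the selected set is empty the draw falls back to the other set
#' with a warning.
#'
#' @param table A [mine()] result.
#' @param target_id Sample ID present in the table.
#' @param n_sources Number of sources to draw.
#' @param hard_fraction Probability of drawing from the hard set; default 0.8.
#' @param seed Optional integer seed.
#' @return Character vector of `n_sources` source IDs.
#' @export
sample_sources <- function(table, target_id, n_sources, hard_fraction = 0.8,
                           seed = NULL) {
  stopifnot(inherits(table, "similarity_table"))
  if (!target_id %in% table$ids)
    stop(sprintf("unknown target '%s'", target_id), call. = FALSE)
  assert_scalar_num(n_sources, "n_sources", lo = 1)
  assert_scalar_num(hard_fraction, "hard_fraction", lo = 0, hi = 1)
  easy <- table$easy[[target_id]]
  hard <- table$hard[[target_id]]
  with_seed(seed, {
    vapply(seq_len(n_sources), function(k) {
      use_hard <- stats::runif(1) < hard_fraction
      pool <- if (use_hard) hard else easy
      if (length(pool) == 0L) {
        warning(sprintf("%s set empty for target '%s'; falling back to the other set",
                        if (use_hard) "hard" else "easy", target_id))
        pool <- if (use_hard) easy else hard
      }
      pool[sample.int(length(pool), 1L)]
    }, character(1))
  })
}

#' Cache a similarity matrix to CSV (and back)
#'
#' The matrix is written as CSV with sample IDs as header row and first
#' column. `read_similarity_csv()` rebuilds the full `similarity_table`,
#' recomputing the easy/hard partition for the requested `easy_fraction`.
#'
#' @param table A `similarity_table`.
#' @param path CSV path.
#' @return `write_similarity_csv()` returns `path` invisibly.
#' @export
write_similarity_csv <- function(table, path) {
  stopifnot(inherits(table, "similarity_table"))
  df <- data.frame(id = table$ids, table$score, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @param easy_fraction Easy fraction for the rebuilt partition.
#' @export
read_similarity_csv <- function(path, easy_fraction = 0.2) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  score <- as.matrix(df[, -1, drop = FALSE])
  dimnames(score) <- list(ids, ids)
  partition_table(ids, score, easy_fraction)
}
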