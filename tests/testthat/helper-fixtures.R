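# Shared fixtures: tiny deterministic samples and small phantom configs.

# Taxonomy with two primary regions: subregions {1, 2} -> 1, {3} -> 2.
toy_taxonomy <- function() {
  region_taxonomy(c(`1` = 1, `2` = 1, `3` = 2), c("A", "B"))
}

# Deterministic sample from a label matrix: channel intensities are simple
# functions of the label value, so image content is reproducible.
toy_sample <- function(labels, id = "toy", channels = 2L) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  img <- array(0, c(dim(labels), channels))
  for (ch in seq_len(channels)) {
    img[, , ch] <- (labels > 0) * clamp_unit(0.2 + 0.15 * labels + 0.1 * ch)
  }
  labeled_sample(img, labels, id)
}

clamp_unit <- function(x) pmin(1, pmax(0, x))

# Small, fast phantom config for unit tests.
small_phantom_config <- function(grid = c(48, 80), n_primary = 4L,
                                 dropout_prob = 0, ...) {
  phantom_config(grid = grid, n_primary = n_primary,
                 subregions_per_primary = c(2L, 3L),
                 dropout_prob = dropout_prob, ...)
}

# Brute-force placement oracle: evaluate |shifted query & anti| at every
# shift of the grid, returning the minimum (independent of the greedy path).
exhaustive_min_overlap <- function(query, anti, shifts) {
  best <- Inf
  for (sx in shifts) for (sy in shifts) {
    best <- min(best, sum(shift_mask_oracle(query, sx, sy) & anti))
  }
  best
}

shift_mask_oracle <- function(m, sx, sy) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (m[r, c]) {
      r2 <- r + sx; c2 <- c + sy
      if (r2 >= 1 && r2 <= d[1] && c2 >= 1 && c2 <= d[2]) out[r2, c2] <- TRUE
    }
  }
  out
}
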