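# Internal helpers: seeding, hashing, small assertions.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Portable deterministic string hash onto [0, 2^31 - 2] (polynomial rolling
# hash mod the Mersenne prime 2^31 - 1; no platform-dependent serialization).
stable_hash <- function(x) {
  s <- paste(as.character(x), collapse = "\x1f")
  bytes <- utf8ToInt(s)
  h <- 0
  p <- 2147483647
  for (b in bytes) h <- (h * 131 + b) %% p
  h
}

#' Derive a reproducible sub-seed
#'
#' Hashes a master seed together with arbitrary context strings (for example a
#' target sample ID and a pass index) onto a valid 32-bit seed. Used by the
#' offline pipeline so every individual mix has its own reproducible stream
#' while the whole run is controlled by one top-level seed.
#'
#' @param seed Integer master seed.
#' @param ... Context values (coerced to character) that identify the sub-task.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  as.integer(stable_hash(c(as.character(seed), ...)) %% 2147483645 + 1)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# Hash of an R object via its canonical JSON form (configs, manifests).
config_hash <- function(x) {
  sprintf("%08x", stable_hash(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)))
}
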