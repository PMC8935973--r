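# Internal helpers shared across modules.

# Mean radius of the WGS84 sphere used for all great-circle work (meters).
EARTH_RADIUS_M <- 6371008.8

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific seed from a base seed. Offsets keep independent
# stages decorrelated while staying reproducible from one user-facing integer;
# result is kept inside 32-bit integer range.
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(stream)) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable hash of an R object (used to stamp pipeline outputs with their
# effective configuration). md5 over a canonical serialization.
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  x
}
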