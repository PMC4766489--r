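#' Unit conversions between mass-concentration bases
#'
#' All food and soil concentrations in the package are carried in pg per g
#' fresh (or dry) weight; intake bookkeeping occasionally needs pg per kg.
#' The two helpers keep that factor (1000) in exactly one place.
#'
#' @param x numeric concentration(s).
#' @return converted numeric vector.
#' @export
pg_per_g_to_pg_per_kg <- function(x) x * 1000

#' @rdname pg_per_g_to_pg_per_kg
#' @export
pg_per_kg_to_pg_per_g <- function(x) x / 1000

# internal: consistent validation failure
check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and nonnegative", what), call. = FALSE)
  }
  invisible(x)
}

# internal: derive a reproducible sub-seed (< 2^31) from a base seed and a
# stage label, so every stage of a run draws from its own stream.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 1000L)) %% 2147483647L
}
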