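#' Singular spectrum analysis decomposition
#'
#' Embeds the series in a lagged trajectory matrix of window length `L`,
#' takes its singular value decomposition, and reconstructs one additive
#' component per eigentriple by diagonal (anti-diagonal) averaging. The
#' reconstructed components sum back to the original series exactly (to
#' numerical tolerance) — the SSA completeness identity.
#'
#' @param series numeric series (length >= 4), sampled annually.
#' @param window_length embedding window `L`, `2 <= L <= length(series)/2`;
#'   default `floor(length/2)`.
#' @return object of class `ssa_result`: `window_length`,
#'   `singular_values` (nonincreasing), `u`, `v` (left/right singular
#'   vectors), `components` (matrix, one reconstructed series per column),
#'   `dominant_frequency` per component (cycles/yr).
#' @export
ssa_decompose <- function(series, window_length = floor(length(series) / 2)) {
  n <- length(series)
  if (n < 4) stop("series must have at least 4 points")
  if (any(is.na(series))) stop("series contains missing values")
  l <- as.integer(window_length)
  if (l < 2 || l > n / 2) stop("window_length must be in [2, length/2]")
  k <- n - l + 1
  x <- matrix(0, l, k)
  for (j in seq_len(k)) x[, j] <- series[j:(j + l - 1)]
  sv <- svd(x)
  d <- sum(sv$d > max(sv$d) * 1e-12)
  d <- max(d, 1L)
  comps <- matrix(0, n, d)
  counts <- tabulate(rep(seq_len(l), k) + rep(seq_len(k), each = l) - 1, n)
  for (r in seq_len(d)) {
    xr <- sv$d[r] * tcrossprod(sv$u[, r], sv$v[, r])
    s <- numeric(n)
    for (j in seq_len(k)) {
      idx <- j:(j + l - 1)
      s[idx] <- s[idx] + xr[, j]
    }
    comps[, r] <- s / counts
  }
  structure(list(window_length = l,
                 singular_values = sv$d,
                 u = sv$u, v = sv$v,
                 components = comps,
                 dominant_frequency = apply(comps, 2, dominant_frequency,
                                            detrend = FALSE)),
            class = "ssa_result")
}

#' Dominant frequency of an annual series
#'
#' Frequency (cycles per year) of the periodogram maximum. The series is
#' linearly detrended first (unless `detrend = FALSE`) so that long-run
#' growth does not masquerade as spectral content; the periodogram is
#' evaluated on a 5x zero-padded frequency grid (resolution `1/(5N)` cycles
#' per year), which for a 30-year record includes the 0.04 cycles/yr
#' critical value. Constant or purely linear series return 0.
#'
#' @param series numeric series, annual sampling, length >= 4.
#' @param detrend remove the best-fit line first?
#' @param oversample zero-padding factor for the frequency grid.
#' @return dominant frequency, cycles per year.
#' @export
dominant_frequency <- function(series, detrend = TRUE, oversample = 5) {
  if (all(is.na(series))) stop("series is all missing")
  n <- length(series)
  if (n < 4) stop("series must have at least 4 points")
  x <- series
  if (detrend) {
    t_idx <- seq_len(n)
    x <- stats::lm.fit(cbind(1, t_idx), series)$residuals
  } else {
    x <- x - mean(x)
  }
  if (max(abs(x)) < 1e-12 * max(1, max(abs(series)))) return(0)
  m <- oversample * n
  freqs <- (0:floor(m / 2)) / m
  t_idx <- seq_len(n)
  power <- vapply(freqs, function(f) {
    Mod(sum(x * exp(-2i * pi * f * t_idx)))^2
  }, numeric(1))
  freqs[which.max(power)]
}

#' Classify food-consumption series against the critical risk frequency
#'
#' Each food series is labelled `above` or `below` according to whether its
#' dominant (detrended) frequency exceeds the critical frequency of the
#' cancer-risk series. The critical frequency is, in order of precedence:
#' the `critical` override, the dominant frequency of `cr_series`, or the
#' published constant 0.04 cycles/yr.
#'
#' @param food_series named list of numeric series on a common year axis.
#' @param cr_series optional cancer-risk series defining the critical
#'   frequency.
#' @param critical optional explicit critical frequency (cycles/yr).
#' @return object of class `frequency_classification`: data frame with
#'   `food`, `frequency`, `label`, and the `critical_frequency` used
#'   (attribute and column).
#' @export
classify_foods <- function(food_series, cr_series = NULL, critical = NULL) {
  crit <- if (!is.null(critical)) {
    critical
  } else if (!is.null(cr_series)) {
    dominant_frequency(cr_series)
  } else 0.04
  freqs <- vapply(food_series, dominant_frequency, numeric(1))
  out <- data.frame(food = names(food_series),
                    frequency = unname(freqs),
                    critical_frequency = crit,
                    label = ifelse(freqs > crit, "above", "below"))
  attr(out, "critical_frequency") <- crit
  class(out) <- c("frequency_classification", "data.frame")
  out
}
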