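#' Relative sensitivity of a model output to one input parameter
#'
#' The parameter is perturbed by +10 % and -10 % of its baseline value;
#' the sensitivity is the mean of the two relative-response ratios
#' `S = (dO/O) / (dI/I)`.
#'
#' @param model_fn function taking a named list of parameter values and
#'   returning a scalar output; must be deterministic.
#' @param baseline named list of baseline parameter values.
#' @param parameter name of the parameter to perturb.
#' @param delta relative perturbation (default 0.1 = +/-10 %).
#' @return object of class `sensitivity_record`: `parameter`, `s`,
#'   `delta_input`, `delta_output_up`, `delta_output_down`, `baseline_output`.
#' @export
sensitivity <- function(model_fn, baseline, parameter, delta = 0.1) {
  if (is.null(baseline[[parameter]])) stop("unknown parameter: ", parameter)
  o0 <- model_fn(baseline)
  if (!is.finite(o0) || o0 == 0) stop("baseline model output is zero; sensitivity undefined")
  perturb <- function(sign) {
    b <- baseline
    b[[parameter]] <- b[[parameter]] * (1 + sign * delta)
    model_fn(b)
  }
  o_up <- perturb(+1)
  o_dn <- perturb(-1)
  s_up <- ((o_up - o0) / o0) / delta
  s_dn <- ((o_dn - o0) / o0) / (-delta)
  structure(list(parameter = parameter, s = mean(c(s_up, s_dn)),
                 delta_input = delta,
                 delta_output_up = (o_up - o0) / o0,
                 delta_output_down = (o_dn - o0) / o0,
                 baseline_output = o0),
            class = "sensitivity_record")
}

#' Confidence factor from a coefficient of variation
#'
#' For a lognormal input, the dispersion factor spanning the 95 %
#' confidence interval around the median:
#' `Cf = exp(1.96 * sqrt(ln(1 + CV^2)))`.
#'
#' @param cv coefficient of variation (sd/mean), >= 0.
#' @return confidence factor, >= 1.
#' @export
cf_from_cv <- function(cv) {
  if (any(cv < 0)) stop("CV must be nonnegative")
  exp(1.96 * sqrt(log(1 + cv^2)))
}

#' First-order lognormal error propagation
#'
#' Combines per-parameter confidence factors through their sensitivities:
#' `ln(Cf_out) = sqrt( sum_i (S_i * ln Cf_i)^2 )`, the standard first-order
#' propagation for independent lognormal inputs.
#'
#' @param s numeric vector of relative sensitivities.
#' @param cf numeric vector of input confidence factors (all >= 1).
#' @param names optional parameter names for the contribution report.
#' @return object of class `propagation_result`: `cf_out` and
#'   per-parameter `contributions` `(S_i ln Cf_i)^2`.
#' @export
propagate_cf <- function(s, cf, names = NULL) {
  if (length(s) != length(cf)) stop("s and cf must have equal length")
  if (any(cf < 1)) stop("confidence factors must be >= 1")
  contrib <- (s * log(cf))^2
  if (!is.null(names)) names(contrib) <- names
  structure(list(cf_out = exp(sqrt(sum(contrib))),
                 contributions = contrib),
            class = "propagation_result")
}

#' Monte Carlo check of the propagated confidence factor
#'
#' Draws each uncertain input from a lognormal with median equal to its
#' baseline and spread given by its CV, evaluates the model on every draw,
#' and returns the empirical dispersion factor
#' `sqrt(q_97.5 / q_2.5)` of the output. For a model that is linear in its
#' inputs this agrees with [propagate_cf()] up to sampling error.
#'
#' @param model_fn function of a named list of parameter values -> scalar.
#' @param baseline named list of baseline (median) values.
#' @param cv named numeric vector of coefficients of variation for the
#'   uncertain parameters.
#' @param n number of draws (>= 1000 recommended; smaller n warns).
#' @param seed integer seed.
#' @return empirical confidence factor (numeric).
#' @export
monte_carlo_check <- function(model_fn, baseline, cv, n = 50000, seed = 1) {
  if (n < 1000) warning("n < 1000 draws: empirical Cf will be noisy")
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  draws <- matrix(0, n, length(cv), dimnames = list(NULL, names(cv)))
  for (p in names(cv)) {
    draws[, p] <- stats::rlnorm(n, meanlog = log(baseline[[p]]),
                                sdlog = sdlog[[p]])
  }
  out <- vapply(seq_len(n), function(i) {
    b <- baseline
    for (p in names(cv)) b[[p]] <- draws[i, p]
    model_fn(b)
  }, numeric(1))
  q <- stats::quantile(out, c(0.025, 0.975), names = FALSE)
  if (q[1] <= 0) stop("non-positive output quantile: Cf undefined")
  sqrt(q[2] / q[1])
}

#' Default input-uncertainty table
#'
#' Reads the configured parameter uncertainties (CV from data where
#' available, literature-default Cf otherwise) and fills in the missing
#' column via [cf_from_cv()].
#'
#' @param params full parameter list from [load_params()].
#' @return data frame `name, cv, cf, source`.
#' @export
uncertainty_table <- function(params) {
  rows <- lapply(params$uncertainty$params, function(p) {
    cf <- if (!is.null(p$cf)) p$cf else cf_from_cv(p$cv)
    data.frame(name = p$name, cv = if (is.null(p$cv)) NA_real_ else p$cv,
               cf = cf, source = p$source)
  })
  do.call(rbind, rows)
}
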