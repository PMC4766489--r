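#' Load the versioned model parameter set
#'
#' Chemical properties, fate-model numerics, food-web parameters, exposure
#' factors, and default input-uncertainty assignments all live in one
#' versioned YAML file shipped with the package; nothing numeric is
#' hard-coded in the model functions. `overrides` is a nested list merged
#' over the file contents (deep merge, scalars replaced).
#'
#' @param path path to a parameter YAML file; default is the shipped set.
#' @param overrides nested list of values to override.
#' @return a nested list with components `chemical`, `fate`, `food_web`,
#'   `exposure`, `uncertainty`.
#' @export
load_params <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_params.yaml", package = "tcddrisk")
  }
  if (!file.exists(path)) stop("parameter file not found: ", path)
  p <- yaml::read_yaml(path)
  if (!is.null(overrides)) p <- deep_merge(p, overrides)
  validate_params(p)
  p
}

deep_merge <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]])) {
      base[[k]] <- deep_merge(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

validate_params <- function(p) {
  ch <- p$chemical
  for (f in c("molar_mass_g_mol", "vapor_pressure_pa", "henry_pa_m3_mol",
              "washout_ratio", "dry_deposition_velocity_m_s",
              "aerosol_om_fraction")) {
    check_nonneg(ch[[f]], paste0("chemical$", f))
  }
  if (any(unlist(ch$half_life_h) <= 0)) stop("half-lives must be positive")
  fw <- p$food_web
  lf <- fw$fish$lipid_fraction
  if (lf <= 0 || lf >= 1) stop("fish lipid_fraction must be in (0,1)")
  if (any(unlist(fw$livestock$btf_d_kg) < 0)) stop("BTFs must be nonnegative")
  ex <- p$exposure
  if (ex$body_weight_kg <= 0) stop("body_weight_kg must be positive")
  if (!ex$slope_factor_unit_mode %in% c("per_pg", "per_mg")) {
    stop("slope_factor_unit_mode must be 'per_pg' or 'per_mg'")
  }
  invisible(p)
}
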