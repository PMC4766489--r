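#' Default configuration of the full desk-scale experiment
#'
#' The default grid (20 x 24 cells of 1e4 km2, 4 air levels, 1980-2009),
#' monsoon-gyre meteorology, a four-hotspot emission inventory accelerating
#' after 2000, and the default synthetic dietary pattern and population
#' grid. All fields can be overridden via [load_run_config()].
#'
#' @return named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    n_lat = 20, n_lon = 24, cell_area_km2 = 1e4, n_levels = 4,
    start_year = 1980, end_year = 2009,
    seed = 1,
    met_regime = "idealized_monsoon", wind_speed_m_s = 2,
    total_emission_1980_g = 4,
    baseline_growth = 0.03, post2000_acceleration = 3,
    total_population = 1.3e9, concentration_index = 1.5,
    scenario_ids = 1:5,
    out_dir = "results/run",
    params_path = NULL,
    compute_uncertainty = TRUE,
    ssa_critical = 0.04
  )
}

#' Load (and validate) a run configuration
#'
#' Starts from [default_run_config()], merges an optional YAML file and an
#' optional override list, and rejects unknown keys by name.
#'
#' @param path optional YAML file of configuration values.
#' @param overrides optional named list of overrides (applied last).
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  apply_over <- function(cfg, over, origin) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown configuration key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  if (!is.null(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  if (cfg$end_year < cfg$start_year) stop("end_year before start_year")
  structure(cfg, class = c("run_config", "list"))
}

#' Save a run configuration to YAML
#' @param config a `run_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Order-independent short hash of a configuration
#' @param config a `run_config` (or any list).
#' @return 8-character hexadecimal string, stable under key reordering.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) x <- lapply(x[order(names(x))], canon)
    x
  }
  s <- yaml::as.yaml(canon(unclass(config)))
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 131 + v[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Assemble the synthetic inputs described by a run configuration
#' @param config a `run_config`.
#' @return list with `grid`, `met`, `params`, `emissions`, `diet`,
#'   `population` — the input bundle consumed by [run_scenario()].
#' @export
build_experiment_inputs <- function(config) {
  grid <- grid_spec(n_lat = config$n_lat, n_lon = config$n_lon,
                    cell_area_km2 = config$cell_area_km2,
                    n_levels = config$n_levels,
                    years = config$start_year:config$end_year)
  params <- load_params(config$params_path)
  met <- generate_meteorology(grid, config$met_regime,
                              config$wind_speed_m_s,
                              seed = substream_seed(config$seed, "met"))
  emissions <- generate_emission_inventory(
    grid, default_hotspots(grid, config$total_emission_1980_g),
    baseline_growth = config$baseline_growth,
    post2000_acceleration = config$post2000_acceleration,
    seed = substream_seed(config$seed, "emission"))
  diet <- generate_dietary_pattern(grid$years)
  population <- generate_population_grid(
    grid, config$total_population, config$concentration_index,
    seed = substream_seed(config$seed, "population"))
  list(grid = grid, met = met, params = params, emissions = emissions,
       diet = diet, population = population)
}

# single-year media bundle shaped like a fate_result, scaled by `scale`
media_slice <- function(fate, y, scale = 1) {
  nl <- dim(fate$air_gas)[1]; nc <- dim(fate$air_gas)[2]
  list(air_gas = array(fate$air_gas[, , y] * scale, c(nl, nc, 1)),
       air_particle = array(fate$air_particle[, , y] * scale, c(nl, nc, 1)),
       dep_flux = array(fate$dep_flux[, , y] * scale, c(nl, nc, 1)),
       soil = array(fate$soil[, , , y] * scale, c(nl, nc, 3, 1)),
       water = array(fate$water[, , y] * scale, c(nl, nc, 1)))
}

#' Spatial-mean CR of one scenario year as a function of uncertain inputs
#'
#' Returns a closure suitable for [sensitivity()] over the default
#' uncertainty parameter set. Emission-scale perturbations exploit the
#' strict linearity of the fate model in its emission forcing (media fields
#' are scaled directly), so no transport rerun is needed; food-web and
#' exposure parameters re-evaluate only those stages.
#'
#' @param fate a `fate_result` for the scenario's emission mode.
#' @param inputs experiment input bundle.
#' @param config a `scenario_config`.
#' @param year_index index of the evaluation year (default: final year).
#' @return function(named list of parameter values) -> mean CR.
#' @export
scenario_cr_model <- function(fate, inputs, config,
                              year_index = inputs$grid$n_years) {
  grid <- inputs$grid
  diet_year <- if (config$diet_mode == "fixed_1980") grid$years[1] else
    grid$years[year_index]
  dk0 <- diet_slice(inputs$diet, config$stratum, diet_year)
  function(par) {
    p <- inputs$params
    p$exposure$body_weight_kg <- par$body_weight_kg
    p$exposure$slope_factor <- par$slope_factor
    p$food_web$livestock$btf_d_kg <- lapply(p$food_web$livestock$btf_d_kg,
                                            function(b) b * par$btf_scale)
    pl <- p$food_web$plant
    pl$gas_conductance_m_d <- pl$gas_conductance_m_d * par$plant_uptake_scale
    pl$particle_interception <- pl$particle_interception * par$plant_uptake_scale
    pl$root_concentration_factor <- pl$root_concentration_factor *
      par$plant_uptake_scale
    p$food_web$plant <- pl
    med <- media_slice(fate, year_index, scale = par$emission_scale)
    foods <- build_food_concentrations(med, p, grid)
    dk <- lapply(dk0, function(v) v * par$consumption_scale)
    food_y <- stats::setNames(
      lapply(food_items, function(it) foods$conc[, , it, 1]), food_items)
    media_y <- list(air_gas = med$air_gas[, , 1],
                    air_particle = med$air_particle[, , 1],
                    soil_surface = med$soil[, , 1, 1],
                    water = med$water[, , 1])
    res <- compute_ted(food_y, media_y, dk, p$exposure)
    mean(compute_cr(res$ted, p$exposure$slope_factor,
                    p$exposure$slope_factor_unit_mode))
  }
}

#' Confidence factor of a scenario's final-year mean CR
#'
#' Computes +/-10 % sensitivities of the scenario's final-year spatial-mean
#' CR to each configured uncertain input and propagates the configured
#' confidence factors through [propagate_cf()].
#'
#' @param fate a `fate_result` for the scenario's emission mode.
#' @param inputs experiment input bundle.
#' @param config a `scenario_config`.
#' @return list with `cf_out`, `records` (one [sensitivity()] record per
#'   parameter), and the uncertainty `table` used.
#' @export
scenario_confidence_factor <- function(fate, inputs, config) {
  tab <- uncertainty_table(inputs$params)
  model <- scenario_cr_model(fate, inputs, config)
  base <- list(emission_scale = 1, slope_factor = inputs$params$exposure$slope_factor,
               body_weight_kg = inputs$params$exposure$body_weight_kg,
               consumption_scale = 1, btf_scale = 1, plant_uptake_scale = 1)
  recs <- lapply(tab$name, function(nm) sensitivity(model, base, nm))
  s <- vapply(recs, function(r) r$s, numeric(1))
  prop <- propagate_cf(s, tab$cf, names = tab$name)
  list(cf_out = prop$cf_out, records = recs, table = tab,
       contributions = prop$contributions)
}

#' Run the full five-scenario experiment
#'
#' Generates all synthetic inputs from the configuration seed, runs the
#' requested scenarios (fate runs shared per emission mode), and derives
#' the headline products: a per-scenario summary table (CR and exceedance
#' endpoints with annual average increasing rates and confidence factors),
#' the dietary-contribution series `Con_diet`, the spectral classification
#' of food-consumption series, and the fate mass ledger. All tables are
#' written as CSV under `config$out_dir` together with a YAML run manifest.
#'
#' @param config a `run_config` (default configuration if omitted).
#' @return (invisibly) list with `summary`, `scenarios`, `con_diet`,
#'   `classification`, `inputs`, `manifest`.
#' @export
run_full_experiment <- function(config = load_run_config()) {
  inputs <- build_experiment_inputs(config)
  grid <- inputs$grid
  cache <- new.env(parent = emptyenv())
  scen <- stats::setNames(
    lapply(config$scenario_ids,
           function(i) run_scenario(build_scenario(i), inputs, cache)),
    paste0("scenario_", config$scenario_ids))

  ny <- grid$n_years
  n_int <- ny - 1
  rows <- lapply(scen, function(s) {
    cr0 <- s$mean_cr[1]; cr1 <- s$mean_cr[ny]
    ex0 <- s$exceedance[1]; ex1 <- s$exceedance[ny]
    data.frame(
      scenario = s$id,
      cr_start = cr0, cr_end = cr1,
      cr_rate_percent = if (cr0 > 0) annual_avg_increase_rate(cr0, cr1, n_int)
        else NA_real_,
      exceed_start_millions = ex0 / 1e6, exceed_end_millions = ex1 / 1e6,
      exceed_rate_percent = if (ex0 > 0)
        annual_avg_increase_rate(ex0, ex1, n_int) else NA_real_
    )
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  if (isTRUE(config$compute_uncertainty)) {
    summary$cf <- vapply(scen, function(s) {
      fate <- cache[[s$config$emission_mode]]
      scenario_confidence_factor(fate, inputs, s$config)$cf_out
    }, numeric(1))
  }

  con_diet_df <- NULL
  if (all(c("scenario_1", "scenario_3") %in% names(scen))) {
    con_diet_df <- data.frame(
      year = grid$years,
      con_diet_percent = con_diet(scen$scenario_3$mean_cr,
                                  scen$scenario_1$mean_cr))
  }

  nat <- function(items) Reduce(`+`, lapply(items, function(it)
    diet_series(inputs$diet, "national", it)))
  food_groups <- list(
    grain = nat("grain"), vegetables = nat("vegetables"),
    fruits = nat("fruits"),
    meat = nat(c("pork", "beef_mutton", "poultry", "fish")),
    cooking_oil = nat("cooking_oil"), milk = nat("milk"), eggs = nat("eggs"))
  classification <- classify_foods(food_groups, critical = config$ssa_critical)
  cr_critical <- if ("scenario_1" %in% names(scen)) {
    dominant_frequency(scen$scenario_1$mean_cr)
  } else NA_real_

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(summary, "scenario_summary.csv")
  series <- do.call(rbind, lapply(scen, function(s) {
    data.frame(scenario = s$id, year = s$years, mean_cr = s$mean_cr,
               exceedance_persons = s$exceedance)
  }))
  rownames(series) <- NULL
  wr(series, "cr_timeseries.csv")
  if (!is.null(con_diet_df)) wr(con_diet_df, "con_diet.csv")
  wr(as.data.frame(classification), "food_frequencies.csv")
  modes <- ls(cache)
  ledgers <- stats::setNames(lapply(modes, function(m) cache[[m]]$ledger),
                             modes)
  wr(do.call(rbind, lapply(modes, function(m)
    cbind(emission_mode = m, ledgers[[m]]))), "mass_ledger.csv")

  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("tcddrisk")),
                   seed = config$seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   outputs = unname(unlist(paths)),
                   cr_critical_frequency = cr_critical)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(summary = summary, scenarios = scen,
                 con_diet = con_diet_df, classification = classification,
                 cr_critical_frequency = cr_critical, ledgers = ledgers,
                 inputs = inputs, manifest = manifest))
}
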