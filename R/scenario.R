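#' Build one of the five modelling scenarios
#'
#' Scenario 1 drives the chain with annually varying emissions and national
#' diet; scenario 2 fixes both at their 1980 state; scenarios 3-5 fix the
#' 1980 emission field and let the diet vary annually for the national,
#' urban, and rural strata respectively. `fixed_1980` repeats the first
#' year's slice for every simulated year.
#'
#' @param id scenario id in 1..5.
#' @return object of class `scenario_config` with `id`, `emission_mode`,
#'   `diet_mode`, `stratum`.
#' @export
build_scenario <- function(id) {
  defs <- list(
    list(id = 1L, emission_mode = "annual", diet_mode = "annual",
         stratum = "national"),
    list(id = 2L, emission_mode = "fixed_1980", diet_mode = "fixed_1980",
         stratum = "national"),
    list(id = 3L, emission_mode = "fixed_1980", diet_mode = "annual",
         stratum = "national"),
    list(id = 4L, emission_mode = "fixed_1980", diet_mode = "annual",
         stratum = "urban"),
    list(id = 5L, emission_mode = "fixed_1980", diet_mode = "annual",
         stratum = "rural")
  )
  if (!(length(id) == 1 && id %in% 1:5)) stop("unknown scenario id: ", id)
  structure(defs[[id]], class = "scenario_config")
}

fix_emissions_1980 <- function(emissions) {
  v <- emissions$values
  for (y in seq_len(dim(v)[3])) v[, , y] <- emissions$values[, , 1]
  emissions$values <- v
  emissions
}

diet_slice <- function(diet, stratum, year) {
  d <- diet[diet$stratum == stratum & diet$year == year, ]
  if (nrow(d) == 0) stop("dietary pattern has no rows for stratum '",
                         stratum, "', year ", year)
  stats::setNames(as.list(d$kg), d$item)
}

#' Run the fate model for an emission mode, with caching
#'
#' Scenarios sharing an emission mode share environmental fields bitwise;
#' the cache holds one `fate_result` per mode.
#'
#' @param emission_mode `"annual"` or `"fixed_1980"`.
#' @param inputs scenario input list (see [run_scenario()]).
#' @param cache environment used as the fate cache (optional).
#' @return a `fate_result`.
#' @export
fate_for_mode <- function(emission_mode, inputs, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[emission_mode]])) {
    return(cache[[emission_mode]])
  }
  em <- if (emission_mode == "fixed_1980") {
    fix_emissions_1980(inputs$emissions)
  } else inputs$emissions
  res <- run_fate(em, inputs$met, inputs$params, inputs$grid)
  if (!is.null(cache)) cache[[emission_mode]] <- res
  res
}

#' Run one scenario end to end
#'
#' Chains fate -> food web -> exposure/risk per the scenario configuration
#' and summarises each simulated year.
#'
#' @param config a `scenario_config` from [build_scenario()].
#' @param inputs list with `grid`, `met`, `params`, `emissions` (an
#'   `emission_inventory`), `diet` (a `dietary_pattern`), `population`
#'   (a `population_grid`).
#' @param fate_cache optional environment for sharing fate runs across
#'   scenarios (see [fate_for_mode()]).
#' @return object of class `cr_timeseries`: `years`, `mean_cr` (spatial
#'   mean per year), `cr` (array of CR fields), `pw_cr` (population-weighted
#'   CR fields), `exceedance` (persons with CR >= threshold per year),
#'   `ingestion_share_2009`-style diagnostics in `shares`.
#' @export
run_scenario <- function(config, inputs, fate_cache = NULL) {
  grid <- inputs$grid
  fate <- tryCatch(
    fate_for_mode(config$emission_mode, inputs, fate_cache),
    error = function(e) stop("fate stage failed: ", conditionMessage(e))
  )
  foods <- tryCatch(
    build_food_concentrations(fate, inputs$params, grid),
    error = function(e) stop("food-web stage failed: ", conditionMessage(e))
  )
  ep <- inputs$params$exposure
  ny <- grid$n_years
  cr <- array(0, c(grid$n_lat, grid$n_lon, ny),
              dimnames = list(NULL, NULL, grid$years))
  pw <- cr
  mean_cr <- exceed <- numeric(ny)
  shares <- vector("list", ny)
  for (y in seq_len(ny)) {
    diet_year <- if (config$diet_mode == "fixed_1980") grid$years[1] else grid$years[y]
    dk <- diet_slice(inputs$diet, config$stratum, diet_year)
    food_y <- stats::setNames(
      lapply(food_items, function(it) foods$conc[, , it, y]), food_items)
    media_y <- list(air_gas = fate$air_gas[, , y],
                    air_particle = fate$air_particle[, , y],
                    soil_surface = fate$soil[, , 1, y],
                    water = fate$water[, , y])
    res <- tryCatch(
      compute_ted(food_y, media_y, dk, ep),
      error = function(e) stop("exposure stage failed in year ",
                               grid$years[y], ": ", conditionMessage(e))
    )
    cr_y <- compute_cr(res$ted, ep$slope_factor, ep$slope_factor_unit_mode)
    cr[, , y] <- cr_y
    mean_cr[y] <- mean(cr_y)
    pw[, , y] <- population_weighted_cr(cr_y, inputs$population$density)
    exceed[y] <- exceedance_population(cr_y, inputs$population,
                                       ep$acceptable_risk)
    shares[[y]] <- if (sum(res$ted) > 0) ingestion_share(res) else NULL
  }
  structure(list(id = config$id, config = config, years = grid$years,
                 mean_cr = mean_cr, cr = cr, pw_cr = pw,
                 exceedance = exceed, shares = shares),
            class = "cr_timeseries")
}

#' Run several scenarios with a shared fate cache
#' @param ids scenario ids.
#' @param inputs input list as for [run_scenario()].
#' @return named list of `cr_timeseries` (`scenario_1`, ...).
#' @export
run_scenarios <- function(ids, inputs) {
  cache <- new.env(parent = emptyenv())
  out <- lapply(ids, function(i) run_scenario(build_scenario(i), inputs,
                                              fate_cache = cache))
  stats::setNames(out, paste0("scenario_", ids))
}

#' Dietary-change contribution to cancer risk
#'
#' `Con_diet = 100 * CR_scenario3 / CR_scenario1`: the share of the
#' scenario-1 risk that the fixed-1980-emission, varying-diet scenario alone
#' accounts for.
#'
#' @param cr_scenario3,cr_scenario1 CR values (scalars or equal-length
#'   vectors).
#' @return percent value(s).
#' @export
con_diet <- function(cr_scenario3, cr_scenario1) {
  if (any(cr_scenario1 <= 0)) stop("scenario-1 CR must be positive")
  100 * cr_scenario3 / cr_scenario1
}

#' Annual average increasing rate
#'
#' `100 * ((end - start) / start) / n_years`, with `n_years` the interval
#' count (29 for 1980 to 2009). This is the summary statistic reported for
#' both CR and exceedance-population trends.
#'
#' @param start_value,end_value endpoint values (start must be positive).
#' @param n_years number of year intervals (>= 1).
#' @return percent per year.
#' @export
annual_avg_increase_rate <- function(start_value, end_value, n_years) {
  if (any(start_value <= 0)) stop("start value must be positive")
  if (any(n_years < 1)) stop("n_years must be >= 1")
  100 * ((end_value - start_value) / start_value) / n_years
}

#' Cellwise cancer-risk difference between two years
#' @param cr_field_end,cr_field_start congruent CR matrices.
#' @return matrix `end - start`.
#' @export
delta_cr <- function(cr_field_end, cr_field_start) {
  if (!all(dim(cr_field_end) == dim(cr_field_start))) {
    stop("CR fields not congruent")
  }
  cr_field_end - cr_field_start
}

#' Summarise the change of a consumption series or item group
#'
#' Total percent change between the first and last year plus the annualized
#' rate. Item groups (e.g. meat = pork + beef/mutton + poultry + fish) are
#' summed before differencing.
#'
#' @param diet a `dietary_pattern`.
#' @param stratum stratum name.
#' @param items one item name or a character vector forming a group.
#' @return list with `start_kg`, `end_kg`, `total_percent_change`,
#'   `annual_rate_percent`, `n_years`.
#' @export
dietary_change_summary <- function(diet, stratum, items) {
  series <- Reduce(`+`, lapply(items, function(it) diet_series(diet, stratum, it)))
  n <- length(series)
  if (series[1] <= 0) stop("starting consumption is zero")
  list(start_kg = series[1], end_kg = series[n],
       total_percent_change = 100 * (series[n] - series[1]) / series[1],
       annual_rate_percent = annual_avg_increase_rate(series[1], series[n],
                                                      n - 1),
       n_years = n - 1)
}
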