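#' Steady-state fish concentration (level-III fugacity balance)
#'
#' Gill uptake balances gill elimination, growth dilution and metabolism:
#' `C_fish = k1 * C_water / (k2 + kG + kM)` with the elimination constant
#' tied to the equilibrium bioconcentration factor, `k2 = k1 / (lipid * Kow)`.
#' In the no-growth, no-metabolism limit this reduces exactly to
#' `C_fish = lipid * Kow * C_water` (wet-weight fish vs. water on a per-gram
#' basis).
#'
#' @param water_conc_pg_l dissolved water concentration (pg/L).
#' @param fish fish parameter list (`lipid_fraction`, `gill_uptake_l_kg_d`,
#'   `growth_dilution_d`, `metabolism_d`).
#' @param chem chemical property list (uses `log_kow`).
#' @return fish concentration, pg/g fresh weight.
#' @export
fish_concentration <- function(water_conc_pg_l, fish, chem) {
  check_nonneg(water_conc_pg_l, "water_conc_pg_l")
  bcf <- fish$lipid_fraction * 10^chem$log_kow       # L/kg
  k1 <- fish$gill_uptake_l_kg_d
  k2 <- k1 / bcf
  denom <- k2 + fish$growth_dilution_d + fish$metabolism_d
  if (denom <= 0) stop("degenerate fish balance: no elimination, growth or metabolism")
  # k1 * C_w / denom is pg/kg; report pg/g
  (k1 * water_conc_pg_l / denom) / 1000
}

#' Plant (above-ground crop) concentration
#'
#' Additive three-term accumulation over a growing period: dry gaseous
#' deposition to foliage, interception of particle-bound deposition, and
#' root uptake with in-plant translocation. A crop-class scale factor
#' captures how much of the accumulating tissue the harvested item exposes
#' (protected grain kernels accumulate far less than leafy forage).
#'
#' @param air_gas_pg_m3 gaseous air concentration (pg/m3).
#' @param dep_flux_pg_m2_d particle-bound deposition flux (pg m-2 d-1).
#' @param soil_conc_pg_g root-zone soil concentration (pg/g dry weight).
#' @param plant plant parameter list (see [load_params()], `$food_web$plant`).
#' @param item_scale crop-class scale factor (dimensionless).
#' @return concentration, pg/g fresh weight.
#' @export
plant_concentration <- function(air_gas_pg_m3, dep_flux_pg_m2_d,
                                soil_conc_pg_g, plant, item_scale = 1) {
  check_nonneg(air_gas_pg_m3, "air_gas_pg_m3")
  check_nonneg(dep_flux_pg_m2_d, "dep_flux_pg_m2_d")
  check_nonneg(soil_conc_pg_g, "soil_conc_pg_g")
  gas_term <- plant$gas_conductance_m_d * air_gas_pg_m3 *
    plant$growing_period_d / plant$foliage_yield_g_m2
  part_term <- plant$particle_interception * dep_flux_pg_m2_d *
    plant$growing_period_d / plant$foliage_yield_g_m2
  root_term <- plant$root_concentration_factor * plant$translocation_factor *
    soil_conc_pg_g
  item_scale * (gas_term + part_term + root_term)
}

#' Animal-product concentration by biotransfer
#'
#' `C_product = BTF * sum_i(intake_i * C_i)`, the feed basket including a
#' soil-ingestion line. Concentrations are carried in pg/g and intakes in
#' kg/d, with the pg/g-pg/kg factor handled internally so the product is
#' returned in pg/g fresh weight.
#'
#' @param feed_concs_pg_g named list/vector of feed concentrations (pg/g):
#'   entries matching the species' feed composition plus `soil`.
#' @param product product name (`beef_mutton`, `pork`, `poultry`, `milk`,
#'   `eggs`).
#' @param livestock livestock parameter list (`feed_intake_kg_d`,
#'   `feed_composition`, `soil_intake_fraction`, `btf_d_kg`).
#' @return product concentration, pg/g fresh weight.
#' @export
animal_product_concentration <- function(feed_concs_pg_g, product, livestock) {
  btf <- livestock$btf_d_kg[[product]]
  if (is.null(btf)) stop("no biotransfer factor configured for product '",
                         product, "'")
  intake <- livestock$feed_intake_kg_d[[product]]
  comp <- livestock$feed_composition[[product]]
  daily_pg <- 0
  for (feed in names(comp)) {
    c_feed <- feed_concs_pg_g[[feed]]
    if (is.null(c_feed)) stop("feed item '", feed, "' missing from basket")
    daily_pg <- daily_pg + intake * comp[[feed]] *
      pg_per_g_to_pg_per_kg(c_feed)
  }
  soil_c <- feed_concs_pg_g[["soil"]]
  if (!is.null(soil_c)) {
    daily_pg <- daily_pg + intake * livestock$soil_intake_fraction[[product]] *
      pg_per_g_to_pg_per_kg(soil_c)
  }
  pg_per_kg_to_pg_per_g(btf * daily_pg)
}

food_items <- c("grain", "vegetables", "fruits", "pork", "beef_mutton",
                "poultry", "fish", "cooking_oil", "milk", "eggs")

#' Map environmental media to food-item concentrations
#'
#' Applies the fish, plant, and biotransfer sub-models cell-by-cell and
#' year-by-year to a fate-model output, producing concentrations for every
#' food item of the dietary pattern. The solution is steady-state within
#' each year (annual forcing changes slowly relative to organism turnover).
#' Root uptake uses the depth-weighted mean of the three soil layers;
#' livestock soil ingestion uses the surface layer.
#'
#' @param media a `fate_result` (or any list with `air_gas`, `air_particle`,
#'   `dep_flux`, `soil`, `water` arrays of matching shape).
#' @param params full parameter list from [load_params()].
#' @param grid the [grid_spec()].
#' @return object of class `food_concentrations`: array
#'   `n_lat x n_lon x item x year` (pg/g fresh weight) plus the item set.
#' @export
build_food_concentrations <- function(media, params, grid) {
  for (need in c("air_gas", "air_particle", "dep_flux", "soil", "water")) {
    if (is.null(media[[need]])) stop("missing medium in fate output: '",
                                     need, "'")
  }
  fw <- params$food_web
  depths <- params$fate$soil_layer_depth_m
  ny <- dim(media$air_gas)[3]
  out <- array(0, dim = c(grid$n_lat, grid$n_lon, length(food_items), ny),
               dimnames = list(NULL, NULL, food_items, grid$years[seq_len(ny)]))
  wts <- depths / sum(depths)
  for (y in seq_len(ny)) {
    gas <- media$air_gas[, , y]
    dep <- media$dep_flux[, , y]
    soil_root <- media$soil[, , 1, y] * wts[1] + media$soil[, , 2, y] * wts[2] +
      media$soil[, , 3, y] * wts[3]
    soil_surf <- media$soil[, , 1, y]
    water <- media$water[, , y]
    plant_c <- function(scale) plant_concentration(gas, dep, soil_root,
                                                   fw$plant, scale)
    feed <- list(grain = plant_c(fw$plant$item_scale$grain),
                 forage = plant_c(fw$plant$item_scale$forage),
                 soil = soil_surf)
    out[, , "grain", y] <- feed$grain
    out[, , "vegetables", y] <- plant_c(fw$plant$item_scale$vegetables)
    out[, , "fruits", y] <- plant_c(fw$plant$item_scale$fruits)
    out[, , "cooking_oil", y] <- feed$grain * fw$plant$oil_enrichment
    out[, , "fish", y] <- fish_concentration(water, fw$fish, params$chemical)
    for (prod in c("pork", "beef_mutton", "poultry", "milk", "eggs")) {
      out[, , prod, y] <- animal_product_concentration(feed, prod,
                                                       fw$livestock)
    }
  }
  structure(list(conc = out, items = food_items,
                 years = grid$years[seq_len(ny)]),
            class = "food_concentrations")
}
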