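params <- load_params()

test_that("fish model reduces to the equilibrium BCF closed form", {
  fish <- params$food_web$fish
  chem <- params$chemical
  expect_equal(fish_concentration(0, fish, chem), 0)
  # no growth, no metabolism: C_fish/C_water = lipid * Kow (per-gram basis)
  f0 <- fish; f0$growth_dilution_d <- 0; f0$metabolism_d <- 0
  f0$lipid_fraction <- 0.05
  ch <- chem; ch$log_kow <- 6.8
  cf <- fish_concentration(10, f0, ch)          # water: 10 pg/L
  bcf_expect <- 0.05 * 10^6.8
  expect_lt(abs(cf / (10 / 1000) - bcf_expect) / bcf_expect, 1e-3)
  # growth dilution strictly decreases the steady-state level
  expect_lt(fish_concentration(10, fish, chem), cf)
  # degenerate balance rejected
  f_bad <- f0; f_bad$gill_uptake_l_kg_d <- 0
  expect_error(fish_concentration(10, f_bad, chem), "degenerate")
})

test_that("plant model is additive in its three source terms", {
  pl <- params$food_web$plant
  expect_equal(plant_concentration(0, 0, 0, pl), 0)
  c1 <- plant_concentration(2, 5, 0.1, pl)
  expect_equal(plant_concentration(4, 10, 0.2, pl), 2 * c1)
  # gas term alone, hand-recomputed: g * C_air * t / m
  pl0 <- pl
  pl0$particle_interception <- 0; pl0$root_concentration_factor <- 0
  expect_equal(plant_concentration(3, 99, 99, pl0),
               pl$gas_conductance_m_d * 3 * pl$growing_period_d /
                 pl$foliage_yield_g_m2)
  # additivity: total = sum of single-term contributions
  pl_gas <- pl; pl_gas$particle_interception <- 0
  pl_gas$root_concentration_factor <- 0
  pl_par <- pl; pl_par$gas_conductance_m_d <- 0
  pl_par$root_concentration_factor <- 0
  pl_root <- pl; pl_root$gas_conductance_m_d <- 0
  pl_root$particle_interception <- 0
  expect_equal(c1, plant_concentration(2, 5, 0.1, pl_gas) +
                 plant_concentration(2, 5, 0.1, pl_par) +
                 plant_concentration(2, 5, 0.1, pl_root))
})

test_that("biotransfer products follow BTF x intake x concentration", {
  lv <- params$food_web$livestock
  clean <- list(grain = 0, forage = 0, soil = 0)
  for (prod in names(lv$btf_d_kg)) {
    expect_equal(animal_product_concentration(clean, prod, lv), 0)
  }
  # single feed line oracle: intake 10 kg/d at 2 pg/g, BTF 0.05 d/kg
  lv1 <- lv
  lv1$feed_intake_kg_d$milk <- 10
  lv1$btf_d_kg$milk <- 0.05
  lv1$soil_intake_fraction$milk <- 0
  lv1$feed_composition$milk <- list(forage = 1)
  got <- animal_product_concentration(list(forage = 2, soil = 0), "milk", lv1)
  expect_equal(got, 0.05 * 10 * 2000 / 1000)     # = 1 pg/g
  # zero BTF nulls the product regardless of feed
  lv0 <- lv; lv0$btf_d_kg$pork <- 0
  expect_equal(animal_product_concentration(list(grain = 50, forage = 50,
                                                 soil = 50), "pork", lv0), 0)
  expect_error(animal_product_concentration(clean, "venison", lv),
               "biotransfer factor")
})

test_that("products rank by BTF when fed identical baskets", {
  lv <- params$food_web$livestock
  for (p in names(lv$btf_d_kg)) {
    lv$feed_intake_kg_d[[p]] <- 5
    lv$soil_intake_fraction[[p]] <- 0
    lv$feed_composition[[p]] <- list(forage = 1)
  }
  basket <- list(forage = 1, soil = 0)
  conc <- vapply(names(lv$btf_d_kg),
                 function(p) animal_product_concentration(basket, p, lv),
                 numeric(1))
  expect_identical(order(conc), order(unlist(lv$btf_d_kg)))
})

test_that("food-concentration builder is linear and complete", {
  sf <- small_fate()
  foods <- build_food_concentrations(sf$fate, sf$params, sf$grid)
  expect_identical(dim(foods$conc)[3], 10L)      # every item populated
  expect_true(all(foods$conc >= 0))
  # zero media -> all foods zero
  zero_media <- lapply(sf$fate[c("air_gas", "air_particle", "dep_flux")],
                       function(a) a * 0)
  zero_media$soil <- sf$fate$soil * 0
  zero_media$water <- sf$fate$water * 0
  f0 <- build_food_concentrations(zero_media, sf$params, sf$grid)
  expect_true(all(f0$conc == 0))
  # homogeneity: scaling all media by alpha scales all foods by alpha
  alpha <- 3.7
  sc <- lapply(sf$fate[c("air_gas", "air_particle", "dep_flux")],
               function(a) a * alpha)
  sc$soil <- sf$fate$soil * alpha
  sc$water <- sf$fate$water * alpha
  fs <- build_food_concentrations(sc, sf$params, sf$grid)
  expect_equal(fs$conc, alpha * foods$conc, tolerance = 1e-12)
  # missing medium is reported by name
  broken <- sf$fate; broken$water <- NULL
  expect_error(build_food_concentrations(broken, sf$params, sf$grid),
               "water")
})

test_that("one-cell media pushed through the builder equals the scalar chain", {
  p <- load_params()
  g1 <- grid_spec(n_lat = 1, n_lon = 1, years = 1980)
  media <- list(air_gas = array(2, c(1, 1, 1)),
                air_particle = array(0.5, c(1, 1, 1)),
                dep_flux = array(40, c(1, 1, 1)),
                soil = array(rep(c(0.3, 0.2, 0.1), each = 1), c(1, 1, 3, 1)),
                water = array(0.05, c(1, 1, 1)))
  foods <- build_food_concentrations(media, p, g1)
  depths <- p$fate$soil_layer_depth_m
  wts <- depths / sum(depths)
  soil_root <- sum(c(0.3, 0.2, 0.1) * wts)
  pl <- p$food_web$plant
  veg_expect <- plant_concentration(2, 40, soil_root, pl,
                                    pl$item_scale$vegetables)
  expect_equal(foods$conc[1, 1, "vegetables", 1], veg_expect)
  fish_expect <- fish_concentration(0.05, p$food_web$fish, p$chemical)
  expect_equal(foods$conc[1, 1, "fish", 1], fish_expect)
  feed <- list(grain = plant_concentration(2, 40, soil_root, pl,
                                           pl$item_scale$grain),
               forage = plant_concentration(2, 40, soil_root, pl,
                                            pl$item_scale$forage),
               soil = 0.3)
  beef_expect <- animal_product_concentration(feed, "beef_mutton",
                                              p$food_web$livestock)
  expect_equal(foods$conc[1, 1, "beef_mutton", 1], beef_expect)
  expect_equal(foods$conc[1, 1, "cooking_oil", 1],
               feed$grain * pl$oil_enrichment)
})
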