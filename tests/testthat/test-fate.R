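chem_default <- load_params()$chemical

test_that("gas-particle partitioning follows the Koa absorption model", {
  # no particles: all gaseous
  p <- partition_gas_particle(1, 298.15, 0, chem_default)
  expect_equal(p$gas_fraction, 1)
  expect_equal(p$particle_fraction, 0)
  # normalisation for arbitrary inputs
  p <- partition_gas_particle(5, c(270, 298), c(30, 120), chem_default)
  expect_equal(p$gas_fraction + p$particle_fraction, c(1, 1))
  # scalar formula oracle: Kp = 10^(logKoa + log f_om - 11.91), phi = KpT/(1+KpT)
  ch <- chem_default
  ch$log_koa <- 10; ch$aerosol_om_fraction <- 0.2; ch$koa_kp_offset <- 11.91
  kp <- 10^(10 + log10(0.2) - 11.91)
  phi_expect <- kp * 50 / (1 + kp * 50)
  p <- partition_gas_particle(1, 298.15, 50, ch)
  expect_equal(p$particle_fraction, phi_expect, tolerance = 1e-12)
  # monotone in TSP and in Koa
  phis <- vapply(c(10, 50, 200), function(tsp)
    partition_gas_particle(1, 298.15, tsp, ch)$particle_fraction, numeric(1))
  expect_true(all(diff(phis) > 0))
  ch2 <- ch; ch2$log_koa <- 11
  expect_gt(partition_gas_particle(1, 298.15, 50, ch2)$particle_fraction,
            p$particle_fraction)
  expect_error(partition_gas_particle(1, 298.15, -1, ch), "nonnegative")
})

test_that("advection step is conservative, positive, and has exact identities", {
  g <- small_grid()
  f0 <- matrix(runif(n_cells(g)), g$n_lat, g$n_lon)
  calm <- generate_meteorology(g, "calm")
  # zero wind, zero diffusivity: identity
  expect_identical(advect_diffuse_step(f0, calm, g, 3600, 0)$field, f0)
  # uniform field + non-divergent closed-gyre wind: steady state
  mon <- generate_meteorology(g, "idealized_monsoon")
  uni <- matrix(7, g$n_lat, g$n_lon)
  expect_equal(advect_diffuse_step(uni, mon, g, 21600, 0)$field, uni)
  # point mass, closed domain, 100 steps: total mass conserved
  f <- matrix(0, g$n_lat, g$n_lon); f[2, 3] <- 123.4
  for (i in 1:100) f <- advect_diffuse_step(f, mon, g, 21600, 1000)$field
  expect_lt(abs(sum(f) - 123.4) / 123.4, 1e-9)
  expect_true(all(f >= 0))
  # Courant violation error names the offending cell
  fast <- generate_meteorology(g, "uniform_westerly", wind_speed_m_s = 50)
  expect_error(advect_diffuse_step(f0, fast, g, 86400, 0),
               "Courant.*lat.*lon")
})

test_that("deposition fluxes are linear and vanish without drivers", {
  g <- small_grid()
  met <- generate_meteorology(g)
  fp <- load_params()$fate
  cg <- matrix(2, g$n_lat, g$n_lon); cp <- matrix(10, g$n_lat, g$n_lon)
  # no precipitation -> no wet flux
  dry_met <- met; dry_met$precip_mm_yr[] <- 0
  fx <- deposition_fluxes(cg, cp, dry_met, chem_default, fp)
  expect_true(all(fx$wet == 0))
  # zero concentrations -> all fluxes zero
  z <- matrix(0, g$n_lat, g$n_lon)
  fx0 <- deposition_fluxes(z, z, met, chem_default, fp)
  expect_true(all(unlist(fx0) == 0))
  # dry particle flux = v_d * C_p, hand-recomputed for v_d = 0.2 cm/s
  ch <- chem_default; ch$dry_deposition_velocity_m_s <- 0.002
  fx <- deposition_fluxes(z, cp, met, ch, fp)
  expect_equal(fx$dry_particle, 0.002 * cp)
})

test_that("two-film exchange follows the series-resistance closed form", {
  expect_equal(air_water_exchange(2, 2, 1, 1), 0)
  # volatilization when water fugacity exceeds air fugacity
  expect_lt(air_water_exchange(1, 3, 1, 1), 0)
  # D = 1/(1/2 + 1/3) = 1.2, flux = D * delta_f
  expect_equal(air_water_exchange(1.5, 0.5, 2, 3), 1.2)
  expect_error(air_water_exchange(1, 1, 0, 1), "positive")
})

test_that("soil column conserves mass through deposition and layer exchange", {
  zs <- c(40000, 20000, 10000)
  depths <- c(0.01, 0.09, 0.2)
  soil0 <- matrix(0, 3, 3)
  # quiescent: everything zero stays zero
  up <- soil_column_update(soil0, 0, 0, 3600, zs, 1e-7, c(1e-9, 1e-9),
                           9e9, depths, 322)
  expect_identical(up$soil, soil0)
  # pure accumulation: constant flux, no exchange -> column gain = F * n
  soil <- soil0
  for (i in 1:5) {
    soil <- soil_column_update(soil, 2.5, 0, 3600, zs, 0, c(0, 0),
                               9e9, depths, 322)$soil
  }
  expect_equal(sum(soil), 2.5 * 5 * 3)   # 3 cells
  # inter-layer exchange only: column mass constant to 1e-12 relative
  soil <- matrix(c(9, 1, 0.1), 3, 3, byrow = FALSE)
  soil <- matrix(rep(c(9, 1, 0.1), each = 3), 3, 3)
  tot0 <- sum(soil)
  for (i in 1:50) {
    up <- soil_column_update(soil, 0, 0, 3600, zs, 0, c(1e-4, 1e-4),
                             9e9, depths, 322)
    soil <- up$soil
    expect_true(all(up$to_air_g == 0))
  }
  expect_lt(abs(sum(soil) - tot0) / tot0, 1e-12)
})

test_that("degradation is exact exponential decay", {
  st <- list(air = matrix(8, 2, 2), soil = matrix(8, 2, 3), water = rep(8, 2))
  ch <- chem_default
  ch$half_life_h <- list(air = 10, soil = 10, water = 10)
  # dt = half-life: exactly halved
  d <- degrade(st, ch, 10 * 3600)
  expect_equal(d$state$air, st$air / 2)
  # three half-lives: 8 -> 1
  d <- degrade(st, ch, 30 * 3600)
  expect_equal(d$state$water, rep(1, 2))
  # effectively infinite half-life: unchanged
  ch$half_life_h <- list(air = 1e15, soil = 1e15, water = 1e15)
  d <- degrade(st, ch, 3600)
  expect_equal(d$state$air, st$air, tolerance = 1e-12)
})

test_that("fate run with zero emissions stays identically zero", {
  g <- grid_spec(n_lat = 3, n_lon = 3, years = 1980:1981)
  met <- generate_meteorology(g)
  em <- generate_emission_inventory(g, data.frame(lat = integer(),
                                                  lon = integer(),
                                                  strength = numeric()))
  f <- run_fate(em, met, load_params(), g, substeps_per_year = 1460)
  expect_true(all(f$air_gas == 0) && all(f$soil == 0) && all(f$water == 0))
  expect_true(all(f$ledger$closure_error == 0))
})

test_that("single-cell run matches the analytic box model within 1 %", {
  # one cell, one level, calm air, all removal disabled except air
  # degradation: steady state M* = E / k
  g <- grid_spec(n_lat = 1, n_lon = 1, n_levels = 1, years = 1980,
                 level_thickness_m = 1000)
  met <- generate_meteorology(g, "calm")
  p <- load_params(overrides = list(
    chemical = list(washout_ratio = 0, dry_deposition_velocity_m_s = 0),
    fate = list(air_side_mtc_soil_m_s = 0, air_side_mtc_water_m_s = 0,
                horizontal_diffusivity_m2_s = 0)))
  em <- generate_emission_inventory(g, data.frame(lat = 1, lon = 1,
                                                  strength = 1000),
                                    baseline_growth = 0)
  f <- run_fate(em, met, p, g, substeps_per_year = 8760)
  k <- log(2) / (p$chemical$half_life_h$air * 3600)       # 1/s
  m_star <- 1000 / (k * 365.25 * 86400)                   # g at steady state
  expect_lt(abs(sum(f$final_state$air) - m_star) / m_star, 0.01)
  # annual-mean gas concentration approaches (1 - phi) * C*; the only bias
  # is the ~10-day spin-up at the start of the averaging year
  v <- g$cell_area_m2 * 1000
  c_gas_star <- (1 - f$phi[1, 1]) * m_star / v * 1e12
  expect_lt(abs(f$air_gas[1, 1, 1] - c_gas_star) / c_gas_star, 0.05)
})

test_that("fate model is strictly linear in the emission field", {
  sf <- small_fate()
  g <- grid_spec(n_lat = 4, n_lon = 5, years = 1980:1981)
  met <- sf$met
  em1 <- generate_emission_inventory(g, default_hotspots(g, 4))
  em2 <- em1; em2$values <- em1$values * 2
  f1 <- run_fate(em1, met, sf$params, g)
  f2 <- run_fate(em2, met, sf$params, g)
  for (fld in c("air_gas", "air_particle", "water", "dep_flux")) {
    expect_equal(f2[[fld]], 2 * f1[[fld]], tolerance = 1e-12)
  }
  expect_equal(f2$soil, 2 * f1$soil, tolerance = 1e-12)
})

test_that("mass ledger closes each year and state stays nonnegative", {
  sf <- small_fate()
  expect_true(all(sf$fate$ledger$closure_error < 1e-6))
  expect_true(all(sf$fate$air_gas >= 0) && all(sf$fate$soil >= 0) &&
                all(sf$fate$water >= 0))
})

test_that("soil and water spin up monotonically under constant forcing", {
  g <- grid_spec(n_lat = 3, n_lon = 4, years = 1980:1987)
  met <- generate_meteorology(g)
  em <- generate_emission_inventory(g, data.frame(lat = 2, lon = 2,
                                                  strength = 10),
                                    baseline_growth = 0)
  f <- run_fate(em, met, load_params(), g)
  soil_mean <- apply(f$soil, 4, mean)
  water_mean <- apply(f$water, 3, mean)
  expect_true(all(diff(soil_mean) > 0))
  expect_true(all(diff(water_mean) > 0))
})

test_that("open-outflow boundary exports mass and still closes the ledger", {
  g <- grid_spec(n_lat = 3, n_lon = 4, years = 1980:1981)
  met <- generate_meteorology(g, "uniform_westerly", wind_speed_m_s = 2)
  em <- generate_emission_inventory(g, data.frame(lat = 2, lon = 2,
                                                  strength = 10),
                                    baseline_growth = 0)
  p <- load_params(overrides = list(fate = list(boundary = "open_outflow")))
  f <- run_fate(em, met, p, g)
  expect_gt(f$ledger$advected_out[2], 0)
  expect_true(all(f$ledger$closure_error < 1e-6))
})
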