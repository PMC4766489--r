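test_that("emission inventory conserves configured totals and growth schedule", {
  g <- small_grid()
  # no sources -> identically zero field
  empty <- generate_emission_inventory(g, data.frame(lat = integer(),
                                                     lon = integer(),
                                                     strength = numeric()))
  expect_true(all(empty$values == 0))

  # one hotspot, zero growth: national total equals the configured strength
  hs <- data.frame(lat = 2, lon = 3, strength = 100)
  em <- generate_emission_inventory(g, hs, baseline_growth = 0,
                                    post2000_acceleration = 1)
  expect_equal(unname(emission_national_totals(em)),
               rep(100, g$n_years), tolerance = 1e-12)

  # growth 3 %/yr tripled after 2000: year-over-year ratios are exact
  g30 <- grid_spec(n_lat = 4, n_lon = 5, years = 1995:2005)
  em <- generate_emission_inventory(g30, data.frame(lat = 2, lon = 3,
                                                    strength = 50),
                                    baseline_growth = 0.03,
                                    post2000_acceleration = 3)
  tot <- unname(emission_national_totals(em))
  ratios <- tot[-1] / tot[-length(tot)]
  pre <- g30$years[-length(g30$years)] < 2000
  expect_equal(ratios[pre], rep(1.03, sum(pre)), tolerance = 1e-10)
  expect_equal(ratios[!pre], rep(1.09, sum(!pre)), tolerance = 1e-10)
})

test_that("emission generator validates inputs and is deterministic", {
  g <- small_grid()
  expect_error(generate_emission_inventory(
    g, data.frame(lat = 99, lon = 1, strength = 1)), "outside")
  expect_error(generate_emission_inventory(
    g, data.frame(lat = 1, lon = 1, strength = -1)), "nonnegative")
  expect_error(generate_emission_inventory(
    g, default_hotspots(g), post2000_acceleration = 0.5), ">= 1")
  a <- generate_emission_inventory(g, default_hotspots(g), seed = 5,
                                   interannual_cv = 0.05)
  b <- generate_emission_inventory(g, default_hotspots(g), seed = 5,
                                   interannual_cv = 0.05)
  expect_identical(a$values, b$values)
})

test_that("dietary series interpolation is exact, monotone and validated", {
  yrs <- 1980:2009
  for (shape in c("linear", "logistic")) {
    s <- generate_dietary_series(202, 135, yrs, shape)
    expect_equal(s[1], 202)
    expect_equal(s[30], 135)
    expect_true(all(diff(s) <= 1e-12))            # monotone decreasing
    expect_equal(100 * (s[1] - s[30]) / s[1], 33.17, tolerance = 0.01)
  }
  expect_equal(generate_dietary_series(50, 50, yrs), rep(50, 30))
  lin <- generate_dietary_series(100, 160, 2000:2010, "linear")
  expect_equal(lin[6], 130)                       # midpoint = mean of endpoints
  expect_error(generate_dietary_series(-1, 5, yrs), ">= 0")
})

test_that("dietary pattern keeps endpoints exact and is never negative", {
  d <- generate_dietary_pattern(1980:2009)
  expect_true(all(d$kg >= 0))
  ep <- default_diet_endpoints()
  for (r in sample(nrow(ep), 8)) {
    s <- diet_series(d, ep$stratum[r], ep$item[r])
    expect_equal(s[1], ep$start_kg[r], tolerance = 1e-9)
    expect_equal(s[30], ep$end_kg[r], tolerance = 1e-9)
  }
})

test_that("national aggregation is the share-weighted urban/rural mix", {
  d <- generate_dietary_pattern(1980:2009)
  sh <- urban_share_series(1980:2009)
  nat <- aggregate_national_diet(d, sh)
  u <- diet_series(d, "urban", "milk")
  r <- diet_series(d, "rural", "milk")
  expect_equal(nat$kg[nat$item == "milk"], sh * u + (1 - sh) * r)
  expect_equal(urban_share_series(c(1980, 2010)), c(0.19, 0.50))
})

test_that("population grid conserves totals and honours explicit shares", {
  g <- small_grid()
  # homogeneous limit
  p0 <- generate_population_grid(g, 1e6, concentration_index = 0)
  expect_equal(max(p0$density) - min(p0$density), 0, tolerance = 1e-9)
  # conservation under any seed
  for (seed in c(1, 42)) {
    p <- generate_population_grid(g, 12345678, seed = seed)
    expect_identical(sum(p$counts), 12345678L)
  }
  # explicit 2x2 shares allocate by direct multiplication
  g2 <- grid_spec(n_lat = 2, n_lon = 2, years = 1980)
  p2 <- generate_population_grid(g2, 1000,
                                 shares = matrix(c(0.4, 0.2, 0.3, 0.1), 2))
  expect_identical(as.vector(p2$counts), c(400L, 200L, 300L, 100L))
  expect_equal(p2$counts, p2$density * g2$cell_area_km2)
  expect_error(generate_population_grid(g, 0), "positive")
})

test_that("largest-remainder allocation is exact", {
  w <- runif(50)
  expect_identical(sum(largest_remainder(w, 99999)), 99999L)
})

test_that("meteorology regimes honour their contracts", {
  g <- small_grid()
  calm <- generate_meteorology(g, "calm")
  expect_true(all(calm$u == 0) && all(calm$v == 0))
  west <- generate_meteorology(g, "uniform_westerly", wind_speed_m_s = 3)
  expect_true(all(west$u == 3) && all(west$v == 0))
  expect_equal(max(abs(met_divergence(west, g))), 0)
  mon <- generate_meteorology(g, "idealized_monsoon", seed = 9)
  expect_lt(max(abs(met_divergence(mon, g))), 1e-18)
  expect_identical(mon, generate_meteorology(g, "idealized_monsoon", seed = 9))
  # closed-gyre: no flow through the domain edge
  expect_equal(max(abs(mon$u[, c(1, g$n_lon + 1)])), 0)
  expect_error(generate_meteorology(g, "tornado"), "arg")
})

test_that("grid specification validates its invariants", {
  expect_error(grid_spec(years = c(1980, 1982)), "contiguous")
  expect_error(grid_spec(n_levels = 2, level_thickness_m = c(100, -5)),
               "positive")
  expect_equal(n_cells(grid_spec(n_lat = 3, n_lon = 7, years = 1980)), 21)
})
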