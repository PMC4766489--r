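# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_grid <- function(years = 1980:1984) {
  grid_spec(n_lat = 4, n_lon = 5, years = years)
}

# one small fate run shared across fate / food-web tests
small_fate <- function() {
  cached("small_fate", function() {
    g <- small_grid()
    met <- generate_meteorology(g)
    em <- generate_emission_inventory(g, default_hotspots(g, 4))
    list(grid = g, met = met, emissions = em, params = load_params(),
         fate = run_fate(em, met, load_params(), g))
  })
}

# a small but complete scenario-input bundle (10 simulated years)
small_inputs <- function() {
  cached("small_inputs", function() {
    g <- grid_spec(n_lat = 4, n_lon = 5, years = 1980:1989)
    list(grid = g,
         met = generate_meteorology(g),
         params = load_params(),
         emissions = generate_emission_inventory(g, default_hotspots(g, 4)),
         diet = generate_dietary_pattern(g$years),
         population = generate_population_grid(g, 1e8, seed = 7))
  })
}

ingestion_pathways_for_test <- function() {
  c("ing_cereal", "ing_vegetable", "ing_oil", "ing_fruit", "ing_fish",
    "ing_meat", "ing_milk", "ing_egg", "ing_water")
}

# the full default desk-scale experiment (used by the acceptance suite)
default_experiment <- function() {
  cached("default_experiment", function() {
    cfg <- load_run_config(overrides = list(
      out_dir = file.path(tempdir(), "tcddrisk-default-run")))
    run_full_experiment(cfg)
  })
}
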