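# Versioned default parameter set for the TCDD fate / food-web / exposure
# chain. Values are literature-style defaults for 2,3,7,8-TCDD and a
# temperate agricultural system; every entry can be overridden at load time.
version: 1
chemical:
  name: "2,3,7,8-TCDD"
  molar_mass_g_mol: 321.97
  vapor_pressure_pa: 2.0e-7
  henry_pa_m3_mol: 3.3
  log_kow: 6.8
  log_koa: 10.1
  half_life_h:
    air: 170
    soil: 96000        # ~11 y, surface-soil scale
    water: 1700
  washout_ratio: 20000         # dimensionless volumetric scavenging ratio
  dry_deposition_velocity_m_s: 2.0e-3
  aerosol_om_fraction: 0.2     # organic-matter fraction of TSP
  koa_kp_offset: 11.91         # log Kp = log Koa + log f_om - offset
fate:
  substeps_per_year: 1460      # ~0.25 d explicit substep
  horizontal_diffusivity_m2_s: 1000
  vertical_diffusivity_m2_s: 10
  air_side_mtc_soil_m_s: 5.0e-4
  soil_side_mtc_m_s: 1.0e-6
  air_side_mtc_water_m_s: 3.0e-3
  water_side_mtc_m_s: 3.0e-6
  soil_layer_depth_m: [0.01, 0.09, 0.2]
  soil_foc: [0.04, 0.02, 0.01]
  soil_bulk_density_kg_m3: 1300
  soil_diffusivity_m2_s: 1.0e-10   # effective diffusion + bioturbation
  boundary: closed             # closed | open_outflow
food_web:
  fish:
    lipid_fraction: 0.05
    gill_uptake_l_kg_d: 500
    growth_dilution_d: 0.002
    metabolism_d: 0.0
  plant:
    gas_conductance_m_d: 100   # canopy-scale gas deposition velocity
    particle_interception: 0.3
    growing_period_d: 60
    foliage_yield_g_m2: 1000   # fresh standing crop per ground area
    root_concentration_factor: 5
    translocation_factor: 0.01
    item_scale:                # relative accumulation by crop class
      grain: 0.05              # protected kernels accumulate little
      vegetables: 0.15
      fruits: 0.05
      forage: 1.2              # exposed foliage, full interception
    oil_enrichment: 4          # lipophilic enrichment, oilseed -> oil
  livestock:
    feed_intake_kg_d: {beef_mutton: 12, pork: 3, poultry: 0.12,
                       milk: 16, eggs: 0.12}
    soil_intake_fraction: {beef_mutton: 0.04, pork: 0.02, poultry: 0.1,
                           milk: 0.04, eggs: 0.1}
    feed_composition:          # share of intake by feed type
      beef_mutton: {forage: 1.0}
      milk: {forage: 1.0}
      pork: {grain: 0.5, forage: 0.5}
      poultry: {grain: 1.0}
      eggs: {grain: 1.0}
    btf_d_kg: {beef_mutton: 0.16, pork: 0.12, poultry: 2.0,
               milk: 0.05, eggs: 2.0}
exposure:
  body_weight_kg: 60
  inhalation_rate_m3_d: 15
  drinking_water_l_d: 2
  skin_area_cm2: 16000
  skin_exposed_fraction: 0.2
  soil_adherence_mg_cm2_d: 0.2
  dermal_absorption_fraction: 0.03
  dermal_water_kp_cm_h: 0.001
  water_contact_h_d: 0.3
  particle_skin_deposition_m_d: 5
  soil_ingestion_mg_d: 50
  slope_factor: 1.0e-3
  slope_factor_unit_mode: per_pg   # per_pg | per_mg
  acceptable_risk: 1.0e-4
uncertainty:
  # parameter, Cf or CV, and provenance class; Cf spans the 95% interval of
  # a lognormal input. "default" marks literature-style confidence factors.
  params:
    - {name: emission_scale,  cf: 1.5, source: default}
    - {name: slope_factor,    cf: 1.5, source: default}
    - {name: body_weight_kg,  cv: 0.2, source: data}
    - {name: consumption_scale, cv: 0.1, source: data}
    - {name: btf_scale,       cf: 1.5, source: default}
    - {name: plant_uptake_scale, cf: 1.5, source: default}
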