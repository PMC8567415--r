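# Shared fixtures, built in code.

# The published worked example: maize-stover biochar pyrolyzed at 500 degC,
# 15,000 Mg applied to 1000 ha of cropland at 10 degC mean annual soil
# temperature, 100-year timeframe, 150 kg mineral N / ha / yr.
worked_example_event <- function() {
  application_event(
    event_id = "worked-example",
    biochar = biochar_spec("maize stover", pyrolysis_temp = 500),
    mass = 15000, area_ha = 1000, soil_temp = 10, timeframe = 100,
    n_rate = 0.15
  )
}

worked_example_config <- function(...) {
  bc_config(gwp_n2o = bc_constants()$gwp_n2o_ar4, ...)
}

# A well-separated two-pool truth for recovery tests.
truth_pools_2 <- function() {
  pool_set(c(0.15, 0.85), c(0.8, 0.004), reference_temp = 20)
}

# Three pools with well-separated rates for model selection.
truth_pools_3 <- function() {
  pool_set(c(0.2, 0.35, 0.45), c(2.0, 0.12, 0.002), reference_temp = 20)
}

dense_times <- function(n = 25, tmax = 5) seq(0, tmax, length.out = n)
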