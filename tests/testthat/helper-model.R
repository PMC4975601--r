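# Shared fixtures. Calibration is deterministic and cheap; cache it so the
# suite pays for it once.

calibrated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrated_model(seed = 1)
    cache
  }
})

# Minimal two-stage flowsheet with simple round numbers for unit tests.
tiny_flowsheet <- function(volume = 1000, trains = 1L, duration = 100) {
  flowsheet(list(
    unit_operation("ferment", duration = duration, volume_in = volume,
                   volume_out = volume, step_yield = 1,
                   materials = c(medium = volume)),
    unit_operation("recover", duration = 20, volume_in = volume,
                   volume_out = volume / 10, step_yield = 0.9,
                   consumables = c(filter = 2))),
    fermenter_working_volume = volume, plant_available_days = 330,
    parallel_trains = trains)
}

tiny_prices <- function(overhead = 0, qc = 1000) {
  price_table(consumable_prices = c(filter = 500),
              material_prices = c(medium = 2),
              equipment_costs = c(ferment = 1e6, recover = 5e5),
              amortization_years = 10, facility_multiplier = 4,
              qc_cost_per_batch = qc, other_overhead_rate = overhead,
              dominant_materials = c("medium", "filter"))
}

tiny_staffing <- function(n_op = 5) {
  staffing_plan(c(production_operator = n_op), wage_schedule("UK"))
}

mc_spans <- function(cfg) {
  vapply(cfg$distributions, function(d) d$max - d$min, numeric(1))
}
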