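# Synthetic configuration fixtures: the base flowsheet, price table and
# scenario/Monte-Carlo configs the analyses run on. Flowsheet volumes,
# durations and all prices are synthetic stand-ins chosen to be
# realistic for a pilot/production Pichia facility of this scale; the
# process statistics (titer 0.242 +/- 0.134 g/L, DSP yield 95.8 +/- 1.1%,
# target 25.6 kg/yr), the scenario table and the wage schedules are the
# published study conditions.

#' Base process parameters
#'
#' Titer 0.242 g/L, DSP yield 95.8%, target output 25.6 kg/yr, no material
#' cost deviation, UK wages.
#'
#' @return A [process_parameters()] object.
#' @export
base_parameters <- function() {
  process_parameters(titer = 0.242, dsp_yield = 0.958, target_output = 25.6,
                     material_cost_deviation = 0,
                     wage_schedule = wage_schedule("UK"))
}

#' Base flowsheet
#'
#' Seed and production fermentation, cell removal, aqueous two-phase (ATPS)
#' extraction, UF/DF concentration/diafiltration, bulk fill. The ATPS step
#' yield is back-solved so the product of all step yields equals
#' `dsp_yield` exactly; fermentation steps carry yield 1 because the titer
#' is measured at end of fermentation. Durations and volumes are synthetic
#' defaults; the 2000 L working volume gives 56 base-case batches/yr, and
#' four staggered trains size the plant so the whole published scenario
#' envelope (down to worst-case titer at best-case demand) stays
#' schedulable.
#'
#' @param dsp_yield Overall downstream recovery (fraction).
#' @param fermenter_working_volume Production fermenter working volume (L).
#' @param parallel_trains Number of staggered trains.
#' @return A [flowsheet()] whose [overall_yield()] equals `dsp_yield` to
#'   within 1e-12.
#' @export
base_flowsheet <- function(dsp_yield = 0.958,
                           fermenter_working_volume = 2000,
                           parallel_trains = 4L) {
  fixed <- 0.99 * 0.99             # cell removal x UF/DF retention
  atps_yield <- dsp_yield / fixed
  if (atps_yield <= 0 || atps_yield > 1)
    stop("dsp_yield ", dsp_yield, " not reachable with the default step ",
         "yields", call. = FALSE)
  v <- fermenter_working_volume
  ops <- list(
    unit_operation("seed_fermentation", duration = 24,
                   volume_in = v / 20, volume_out = v / 20, step_yield = 1,
                   materials = c(seed_medium = v / 20)),
    unit_operation("production_fermentation", duration = 120,
                   volume_in = v, volume_out = v, step_yield = 1,
                   consumables = c(ferm_vent_filter = 4),
                   materials = c(bmgy_medium = v)),
    unit_operation("cell_removal", duration = 8,
                   volume_in = v, volume_out = 0.95 * v, step_yield = 0.99,
                   consumables = c(depth_filter = 10)),
    unit_operation("atps_extraction", duration = 12,
                   volume_in = 0.95 * v, volume_out = 0.3 * v,
                   step_yield = atps_yield,
                   materials = c(peg = 0.2 * v, phosphate_salt = 0.15 * v)),
    unit_operation("uf_df", duration = 24,
                   volume_in = 0.3 * v, volume_out = 0.025 * v,
                   step_yield = 0.99,
                   consumables = c(ufdf_membrane = 24),
                   materials = c(diafiltration_buffer = 0.25 * v)),
    unit_operation("bulk_fill", duration = 8,
                   volume_in = 0.025 * v, volume_out = 0.025 * v,
                   step_yield = 1,
                   consumables = c(fill_assembly = 1)))
  flowsheet(ops, fermenter_working_volume = v,
            plant_available_days = 330, parallel_trains = parallel_trains)
}

#' Base price table
#'
#' Synthetic open stand-in for a commercial supplier database: unit prices
#' for the demanded consumables and materials, installed equipment capital
#' per operation, and the capital/QC/overhead constants. The dominant
#' material set (fermentation medium and UF/DF membranes) carries the
#' material-cost deviation. Values are the uncalibrated starting point;
#' [calibrate()] adjusts the free constants to the published anchors.
#'
#' @return A [price_table()].
#' @export
base_price_table <- function() {
  price_table(
    consumable_prices = c(ferm_vent_filter = 800, depth_filter = 1500,
                          ufdf_membrane = 4000, fill_assembly = 2000),
    material_prices = c(seed_medium = 20, bmgy_medium = 18, peg = 12,
                        phosphate_salt = 8, diafiltration_buffer = 6),
    equipment_costs = c(seed_fermentation = 0.8e6,
                        production_fermentation = 8.0e6,
                        cell_removal = 1.8e6,
                        atps_extraction = 2.4e6,
                        uf_df = 3.2e6,
                        bulk_fill = 1.4e6),
    amortization_years = 10,
    facility_multiplier = 4,
    qc_cost_per_batch = 31000,
    other_overhead_rate = 0.089,
    dominant_materials = c("bmgy_medium", "ufdf_membrane"))
}

#' Monte Carlo configuration before titer optimization
#'
#' Triangular distributions with the scenario-table bounds as min/max and
#' the base values as mode: titer (0.108, 0.242, 0.376) g/L, target output
#' (12.8, 25.6, 51.2) kg/yr, material cost (-25, 0, +25) %.
#'
#' @param seed Integer seed.
#' @return An [mc_config()].
#' @export
mc_config_before <- function(seed = 1L) {
  mc_config(list(titer = triangular_dist(0.108, 0.242, 0.376),
                 target_output = triangular_dist(12.8, 25.6, 51.2),
                 material_cost = triangular_dist(-25, 0, 25)),
            max_runs = 300, ma_window = 50, ma_tolerance = 0.01,
            seed = seed)
}

#' Monte Carlo configuration after titer optimization
#'
#' The titer distribution becomes triangular with mode 5.44 g/L and
#' min/max one reported standard deviation (2.44 g/L) either side,
#' mirroring the mean +/- 1 SD convention used for the base scenario
#' bounds; target output and material cost are unchanged.
#'
#' @param seed Integer seed.
#' @return An [mc_config()].
#' @export
mc_config_after <- function(seed = 1L) {
  t <- titer_after_optimization()
  mc_config(list(titer = triangular_dist(t[["mean"]] - t[["sd"]],
                                         t[["mean"]],
                                         t[["mean"]] + t[["sd"]]),
                 target_output = triangular_dist(12.8, 25.6, 51.2),
                 material_cost = triangular_dist(-25, 0, 25)),
            max_runs = 300, ma_window = 50, ma_tolerance = 0.01,
            seed = seed)
}

#' Write the full fixture file set
#'
#' Writes the declarative YAML configuration for the whole analysis:
#' `parameters.yaml`, `flowsheet.yaml`, `prices.yaml`, `scenarios.yaml`,
#' `mc_before.yaml`, `mc_after.yaml`. Every file carries the schema key
#' `biocogs/1`, explicit units, and a provenance note distinguishing
#' published study conditions from synthetic stand-in values. Deterministic
#' given `seed` (which also seeds the Monte Carlo configs).
#'
#' @param dir Destination directory (created if needed).
#' @param seed Integer seed recorded in the Monte Carlo configs.
#' @return Invisibly, the character vector of files written.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("Cannot create fixture directory: ", dir, call. = FALSE)
  seed <- as.integer(seed)
  fs <- base_flowsheet()
  prices <- base_price_table()

  files <- character()
  emit <- function(name, obj) {
    path <- file.path(dir, name)
    yaml::write_yaml(obj, path, precision = 15)
    files <<- c(files, path)
  }

  emit("parameters.yaml", list(
    schema = "biocogs/1", kind = "parameters",
    provenance = "published base-case process statistics",
    units = list(titer = "g/L", dsp_yield = "fraction",
                 target_output = "kg/yr", material_cost_deviation = "%"),
    titer = 0.242, dsp_yield = 0.958, target_output = 25.6,
    material_cost_deviation = 0, wage_location = "UK"))

  emit("flowsheet.yaml", list(
    schema = "biocogs/1", kind = "flowsheet",
    provenance = paste("synthetic stand-in: stage durations, volumes and",
                       "per-batch demands are plausible defaults, not",
                       "published values"),
    units = list(duration = "h", volume = "L",
                 fermenter_working_volume = "L"),
    fermenter_working_volume = fs$fermenter_working_volume,
    plant_available_days = fs$plant_available_days,
    parallel_trains = fs$parallel_trains,
    operations = lapply(unname(fs$operations), function(op) list(
      name = op$name, duration = op$duration,
      volume_in = op$volume_in, volume_out = op$volume_out,
      step_yield = op$step_yield,
      consumables = as.list(op$consumables),
      materials = as.list(op$materials)))))

  emit("prices.yaml", list(
    schema = "biocogs/1", kind = "prices",
    provenance = paste("synthetic stand-in for a commercial supplier",
                       "database; free constants are calibrated to the",
                       "published cost anchors"),
    units = list(prices = "USD per demanded unit",
                 equipment_costs = "USD installed",
                 amortization_years = "yr", qc_cost_per_batch = "USD",
                 other_overhead_rate = "fraction of direct cost"),
    consumable_prices = as.list(prices$consumable_prices),
    material_prices = as.list(prices$material_prices),
    equipment_costs = as.list(prices$equipment_costs),
    amortization_years = prices$amortization_years,
    facility_multiplier = prices$facility_multiplier,
    qc_cost_per_batch = prices$qc_cost_per_batch,
    other_overhead_rate = prices$other_overhead_rate,
    dominant_materials = as.list(prices$dominant_materials)))

  emit("scenarios.yaml", list(
    schema = "biocogs/1", kind = "scenarios",
    provenance = "published sensitivity scenario table",
    units = list(fermentation_titer = "g/L", dsp_yield = "%",
                 material_cost = "%", target_output = "kg/yr",
                 wages = "USD/yr"),
    fermentation_titer = list(worst = 0.108, base = 0.242, best = 0.376),
    dsp_yield = list(worst = 94.7, base = 95.8, best = 96.9),
    material_cost = list(worst = 25, base = 0, best = -25),
    target_output = list(worst = 12.8, base = 25.6, best = 51.2),
    operator_wage = list(worst = "US", base = "UK", best = "Mexico"),
    wages = list(US = as.list(wage_schedule("US")),
                 UK = as.list(wage_schedule("UK")),
                 Mexico = as.list(wage_schedule("Mexico")))))

  mc_yaml <- function(cfg) list(
    schema = "biocogs/1", kind = "monte_carlo",
    units = list(titer = "g/L", target_output = "kg/yr",
                 material_cost = "%"),
    distributions = lapply(cfg$distributions, function(d)
      list(min = d$min, mode = d$mode, max = d$max)),
    max_runs = cfg$max_runs, ma_window = cfg$ma_window,
    ma_tolerance = cfg$ma_tolerance, seed = cfg$seed)
  emit("mc_before.yaml", mc_yaml(mc_config_before(seed)))
  emit("mc_after.yaml", mc_yaml(mc_config_after(seed)))

  invisible(files)
}
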