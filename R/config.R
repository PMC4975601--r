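# Declarative YAML configuration: reading, validation and constructors.
# All files carry the versioned schema key `biocogs/1` and explicit units.

SCHEMA_VERSION <- "biocogs/1"

#' Read a biocogs YAML configuration file
#'
#' @param file Path to a YAML file with `schema: biocogs/1`.
#' @return The parsed configuration list.
#' @export
read_config <- function(file) {
  if (!file.exists(file)) stop("Config file not found: ", file,
                               call. = FALSE)
  cfg <- yaml::read_yaml(file)
  if (!identical(cfg$schema, SCHEMA_VERSION))
    stop("Unsupported or missing schema in ", file, " (expected '",
         SCHEMA_VERSION, "')", call. = FALSE)
  cfg
}

#' Validate a configuration file
#'
#' Schema- and invariant-checks the file, collecting every problem rather
#' than failing on the first.
#'
#' @param file Path to a YAML configuration file.
#' @return Character vector of error messages, each prefixed with the file
#'   name; empty when the file is valid.
#' @export
validate_config <- function(file) {
  errors <- character()
  note <- function(msg) errors <<- c(errors, paste0(file, ": ", msg))
  cfg <- tryCatch(yaml::read_yaml(file), error = function(e) {
    note(conditionMessage(e)); NULL
  })
  if (is.null(cfg)) return(errors)
  if (!identical(cfg$schema, SCHEMA_VERSION))
    note(paste0("schema must be '", SCHEMA_VERSION, "'"))
  if (is.null(cfg$kind)) {
    note("missing 'kind'")
    return(errors)
  }
  if (is.null(cfg$units)) note("missing 'units' block")
  num <- function(field, lower = -Inf, upper = Inf, open_lower = FALSE,
                  what = cfg$kind) {
    v <- cfg[[field]]
    if (is.null(v) || !is.numeric(v)) {
      note(paste0(what, ".", field, " missing or non-numeric"))
      return(invisible())
    }
    bad <- v < lower | v > upper | (open_lower & v == lower)
    if (any(bad))
      note(sprintf("%s.%s = %s violates bound %s%g, %g]", what, field,
                   paste(v[bad], collapse = ", "),
                   if (open_lower) "(" else "[", lower, upper))
  }
  switch(cfg$kind,
    parameters = {
      num("titer", 0, Inf, open_lower = TRUE, what = "ProcessParameters")
      num("dsp_yield", 0, 1, open_lower = TRUE, what = "ProcessParameters")
      num("target_output", 0, Inf, open_lower = TRUE,
          what = "ProcessParameters")
      num("material_cost_deviation", -100, Inf, what = "ProcessParameters")
      if (!is.null(cfg$wage_location) &&
          !cfg$wage_location %in% c("US", "UK", "Mexico"))
        note("unknown wage_location")
    },
    flowsheet = {
      num("fermenter_working_volume", 0, Inf, open_lower = TRUE)
      num("plant_available_days", 0, 366, open_lower = TRUE)
      num("parallel_trains", 1, Inf)
      if (!length(cfg$operations)) note("flowsheet has no operations")
      for (op in cfg$operations) {
        nm <- if (is.null(op$name)) "<unnamed>" else op$name
        for (f in c("duration", "volume_in", "volume_out"))
          if (is.null(op[[f]]) || !is.numeric(op[[f]]) || op[[f]] <= 0)
            note(paste0("operation '", nm, "': ", f, " must be > 0"))
        if (is.null(op$step_yield) || op$step_yield <= 0 ||
            op$step_yield > 1)
          note(paste0("operation '", nm, "': step_yield must lie in (0, 1]"))
      }
    },
    prices = {
      for (f in c("consumable_prices", "material_prices", "equipment_costs"))
        if (any(unlist(cfg[[f]]) < 0))
          note(paste0(f, " contains negative entries"))
      num("amortization_years", 1, Inf)
      num("facility_multiplier", 0, Inf, open_lower = TRUE)
      num("qc_cost_per_batch", 0, Inf)
      num("other_overhead_rate", 0, Inf)
    },
    monte_carlo = {
      for (p in c("titer", "target_output", "material_cost")) {
        d <- cfg$distributions[[p]]
        if (is.null(d)) { note(paste0("missing distribution: ", p)); next }
        if (!(d$min <= d$mode && d$mode <= d$max))
          note(paste0("distribution ", p, ": need min <= mode <= max"))
      }
      num("max_runs", 2, Inf)
      num("ma_window", 2, Inf)
      num("ma_tolerance", 0, Inf, open_lower = TRUE)
    },
    scenarios = {
      for (p in c("fermentation_titer", "dsp_yield", "material_cost",
                  "target_output", "operator_wage"))
        if (is.null(cfg[[p]])) note(paste0("missing scenario row: ", p))
      for (loc in names(cfg$wages))
        if (length(setdiff(c("production_operator", "production_supervisor",
                             "quality_assurance", "quality_control"),
                           names(cfg$wages[[loc]]))))
          note(paste0("wage schedule for ", loc, " is incomplete"))
    },
    note(paste0("unknown kind '", cfg$kind, "'")))
  errors
}

#' Build process parameters from a parameters config
#'
#' @param cfg Parsed `kind: parameters` configuration (see
#'   [read_config()]).
#' @return A [process_parameters()] object.
#' @export
parameters_from_config <- function(cfg) {
  process_parameters(titer = cfg$titer, dsp_yield = cfg$dsp_yield,
                     target_output = cfg$target_output,
                     material_cost_deviation =
                       cfg$material_cost_deviation %||% 0,
                     wage_schedule = wage_schedule(cfg$wage_location %||%
                                                     "UK"))
}

#' Build a flowsheet from a flowsheet config
#'
#' @param cfg Parsed `kind: flowsheet` configuration.
#' @return A [flowsheet()] object.
#' @export
flowsheet_from_config <- function(cfg) {
  ops <- lapply(cfg$operations, function(op)
    unit_operation(op$name, op$duration, op$volume_in, op$volume_out,
                   op$step_yield,
                   consumables = unlist(op$consumables) %||% numeric(),
                   materials = unlist(op$materials) %||% numeric()))
  flowsheet(ops, fermenter_working_volume = cfg$fermenter_working_volume,
            plant_available_days = cfg$plant_available_days %||% 330,
            parallel_trains = cfg$parallel_trains %||% 1L)
}

#' Build a price table from a prices config
#'
#' @param cfg Parsed `kind: prices` configuration.
#' @return A [price_table()] object.
#' @export
prices_from_config <- function(cfg) {
  price_table(consumable_prices = unlist(cfg$consumable_prices),
              material_prices = unlist(cfg$material_prices),
              equipment_costs = unlist(cfg$equipment_costs),
              amortization_years = cfg$amortization_years %||% 10,
              facility_multiplier = cfg$facility_multiplier %||% 4,
              qc_cost_per_batch = cfg$qc_cost_per_batch %||% 0,
              other_overhead_rate = cfg$other_overhead_rate %||% 0,
              dominant_materials = unlist(cfg$dominant_materials) %||%
                character())
}

#' Build a Monte Carlo config from a monte_carlo config file
#'
#' @param cfg Parsed `kind: monte_carlo` configuration.
#' @return An [mc_config()] object.
#' @export
mc_config_from_config <- function(cfg) {
  dists <- lapply(cfg$distributions, function(d)
    triangular_dist(d$min, d$mode, d$max))
  mc_config(dists, max_runs = cfg$max_runs %||% 300,
            ma_window = cfg$ma_window %||% 50,
            ma_tolerance = cfg$ma_tolerance %||% 0.01,
            seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
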