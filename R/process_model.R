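# Flowsheet representation and mass-balance / scheduling arithmetic.

#' Process parameters for the cost model
#'
#' Bundles the uncertain inputs the analysis varies: end-of-fermentation
#' titer, overall downstream (DSP) recovery, annual target output, a signed
#' percentage deviation applied to the dominant material costs, and the wage
#' schedule in force.
#'
#' @param titer Product concentration at end of fermentation (g/L); > 0.
#' @param dsp_yield Overall downstream recovery as a fraction in (0, 1].
#' @param target_output Required annual product mass (kg/yr); > 0.
#' @param material_cost_deviation Signed percentage applied to the dominant
#'   materials (e.g. +25 means a 25% price increase); must be >= -100.
#' @param wage_schedule Named numeric vector of annual salaries (currency/yr)
#'   per labor role, e.g. [wage_schedule()]; defaults to the UK schedule.
#' @return An object of class `biocogs_parameters`.
#' @examples
#' p <- process_parameters(titer = 0.242, dsp_yield = 0.958,
#'                         target_output = 25.6)
#' @export
process_parameters <- function(titer, dsp_yield, target_output,
                               material_cost_deviation = 0,
                               wage_schedule = NULL) {
  if (is.null(wage_schedule))
    wage_schedule <- get("wage_schedule", mode = "function")("UK")
  stopifnot(is.numeric(titer), length(titer) == 1L,
            is.numeric(dsp_yield), length(dsp_yield) == 1L,
            is.numeric(target_output), length(target_output) == 1L,
            is.numeric(material_cost_deviation),
            length(material_cost_deviation) == 1L)
  if (!is.finite(titer) || titer <= 0)
    stop("ProcessParameters.titer must be > 0, got ", titer, call. = FALSE)
  if (!is.finite(dsp_yield) || dsp_yield <= 0 || dsp_yield > 1)
    stop("ProcessParameters.dsp_yield must lie in (0, 1], got ", dsp_yield,
         call. = FALSE)
  if (!is.finite(target_output) || target_output <= 0)
    stop("ProcessParameters.target_output must be > 0, got ", target_output,
         call. = FALSE)
  if (material_cost_deviation < -100)
    stop("ProcessParameters.material_cost_deviation must be >= -100",
         call. = FALSE)
  structure(list(titer = titer, dsp_yield = dsp_yield,
                 target_output = target_output,
                 material_cost_deviation = material_cost_deviation,
                 wage_schedule = wage_schedule),
            class = "biocogs_parameters")
}

#' Single unit operation of a flowsheet
#'
#' @param name Identifier, unique within a flowsheet.
#' @param duration Batch occupancy time (h); > 0.
#' @param volume_in,volume_out Process volumes (L); > 0.
#' @param step_yield Fraction of product retained across the step, in (0, 1].
#' @param consumables Named numeric vector: consumable item id -> quantity
#'   demanded per batch (units as priced).
#' @param materials Named numeric vector: material item id -> quantity per
#'   batch.
#' @return An object of class `biocogs_unit_operation`.
#' @export
unit_operation <- function(name, duration, volume_in, volume_out, step_yield,
                           consumables = numeric(), materials = numeric()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (duration <= 0) stop("UnitOperation '", name, "': duration must be > 0",
                          call. = FALSE)
  if (volume_in <= 0 || volume_out <= 0)
    stop("UnitOperation '", name, "': volumes must be > 0", call. = FALSE)
  if (step_yield <= 0 || step_yield > 1)
    stop("UnitOperation '", name, "': step_yield must lie in (0, 1]",
         call. = FALSE)
  check_demand <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
      stop("UnitOperation '", name, "': ", what, " must be a named vector",
           call. = FALSE)
    if (any(x < 0))
      stop("UnitOperation '", name, "': negative ", what, " demand",
           call. = FALSE)
  }
  check_demand(consumables, "consumable")
  check_demand(materials, "material")
  structure(list(name = name, duration = duration,
                 volume_in = volume_in, volume_out = volume_out,
                 step_yield = step_yield,
                 consumables = consumables, materials = materials),
            class = "biocogs_unit_operation")
}

#' Ordered process flowsheet
#'
#' @param operations List of [unit_operation()] objects, in process order.
#' @param fermenter_working_volume Working volume of the production
#'   fermenter (L); the broth volume the titer applies to.
#' @param plant_available_days Scheduling capacity (days/yr). Default 330,
#'   leaving an annual maintenance shutdown.
#' @param parallel_trains Number of staggered identical trains (integer
#'   >= 1). Batch occupancy per train is the longest single stage, so
#'   capacity is `floor(plant_available_days * 24 / max duration) *
#'   parallel_trains` batches/yr.
#' @return An object of class `biocogs_flowsheet`.
#' @export
flowsheet <- function(operations, fermenter_working_volume,
                      plant_available_days = 330, parallel_trains = 1L) {
  if (!length(operations))
    stop("Flowsheet must contain at least one unit operation", call. = FALSE)
  ok <- vapply(operations, inherits, logical(1), "biocogs_unit_operation")
  if (!all(ok))
    stop("All flowsheet operations must be unit_operation objects",
         call. = FALSE)
  nms <- vapply(operations, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("Duplicate unit operation names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  if (fermenter_working_volume <= 0)
    stop("fermenter_working_volume must be > 0", call. = FALSE)
  if (plant_available_days <= 0)
    stop("plant_available_days must be > 0", call. = FALSE)
  parallel_trains <- as.integer(parallel_trains)
  if (is.na(parallel_trains) || parallel_trains < 1L)
    stop("parallel_trains must be an integer >= 1", call. = FALSE)
  names(operations) <- nms
  structure(list(operations = operations,
                 fermenter_working_volume = fermenter_working_volume,
                 plant_available_days = plant_available_days,
                 parallel_trains = parallel_trains),
            class = "biocogs_flowsheet")
}

#' Overall downstream yield of a flowsheet
#'
#' Product of the step yields of every operation.
#'
#' @param fs A [flowsheet()].
#' @return Overall fractional recovery in (0, 1].
#' @examples
#' fs <- flowsheet(list(unit_operation("a", 1, 1, 1, 0.98),
#'                      unit_operation("b", 1, 1, 1, 0.97755)),
#'                 fermenter_working_volume = 2000)
#' overall_yield(fs) # ~0.958
#' @export
overall_yield <- function(fs) {
  stopifnot(inherits(fs, "biocogs_flowsheet"))
  prod(vapply(fs$operations, `[[`, numeric(1), "step_yield"))
}

#' Product mass recovered per batch
#'
#' Titer times fermenter working volume times overall flowsheet yield.
#'
#' @param params A [process_parameters()] object.
#' @param fs A [flowsheet()].
#' @return Mass of product per batch (g).
#' @export
per_batch_output <- function(params, fs) {
  stopifnot(inherits(params, "biocogs_parameters"))
  params$titer * fs$fermenter_working_volume * overall_yield(fs)
}

#' Annual batch capacity of the plant
#'
#' With staggered trains the bottleneck stage sets the batch cadence per
#' train.
#'
#' @inheritParams per_batch_output
#' @return Maximum whole batches per year across all trains.
#' @export
batch_capacity <- function(fs) {
  stopifnot(inherits(fs, "biocogs_flowsheet"))
  occupancy <- max(vapply(fs$operations, `[[`, numeric(1), "duration"))
  floor(fs$plant_available_days * 24 / occupancy) * fs$parallel_trains
}

#' Batches required per year to meet the target output
#'
#' The smallest integer B with `B * per_batch_output >= target_output`.
#' Errors when B exceeds the scheduling capacity unless `expand_capacity` is
#' set, in which case the plant is notionally extended with additional
#' parallel trains (the cost engine then scales capital accordingly and
#' flags the result).
#'
#' @inheritParams per_batch_output
#' @param expand_capacity If `TRUE`, never fail on capacity: report the
#'   batch count and let callers query [capacity_expansion()].
#' @return Integer batch count.
#' @examples
#' \dontrun{
#' batches_per_year(process_parameters(0.242, 0.958, 25.6), fs) # 56
#' }
#' @export
batches_per_year <- function(params, fs, expand_capacity = FALSE) {
  m <- per_batch_output(params, fs)
  if (m <= 0) stop("per-batch output must be > 0", call. = FALSE)
  b <- as.integer(ceiling(params$target_output * 1000 / m))
  b <- max(b, 1L)
  cap <- batch_capacity(fs)
  if (b > cap && !expand_capacity) {
    stop(infeasible_schedule_error(required = b, available = cap))
  }
  b
}

#' Capacity-expansion factor for a batch demand
#'
#' Ratio of trains needed to trains configured (>= 1); 1 when the schedule
#' is feasible as configured.
#'
#' @param batches Required batch count.
#' @param fs A [flowsheet()].
#' @return Numeric factor >= 1 by which train count (and train capital) must
#'   grow to fit `batches` into the schedule.
#' @export
capacity_expansion <- function(batches, fs) {
  per_train <- batch_capacity(fs) / fs$parallel_trains
  trains_needed <- ceiling(batches / per_train)
  max(1, trains_needed / fs$parallel_trains)
}

infeasible_schedule_error <- function(required, available) {
  structure(class = c("biocogs_infeasible_schedule", "error", "condition"),
            list(message = sprintf(
              paste0("Infeasible schedule: %d batches required but only %d ",
                     "fit in the available plant time"), required, available),
              call = NULL, required = required, available = available))
}

#' @export
print.biocogs_flowsheet <- function(x, ...) {
  cat(sprintf("Flowsheet: %d operations, %g L working volume, %d train(s)\n",
              length(x$operations), x$fermenter_working_volume,
              x$parallel_trains))
  for (op in x$operations)
    cat(sprintf("  %-24s %5g h  %7g -> %7g L  yield %.4f\n", op$name,
                op$duration, op$volume_in, op$volume_out, op$step_yield))
  cat(sprintf("Overall DSP yield: %.4f; capacity %d batches/yr\n",
              overall_yield(x), batch_capacity(x)))
  invisible(x)
}

#' @export
print.biocogs_parameters <- function(x, ...) {
  cat(sprintf(paste0("Process parameters: titer %.3f g/L, DSP yield %.3f, ",
                     "target %.1f kg/yr, material deviation %+.1f%%\n"),
              x$titer, x$dsp_yield, x$target_output,
              x$material_cost_deviation))
  invisible(x)
}
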