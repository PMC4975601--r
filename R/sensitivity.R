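# One-at-a-time scenario (tornado) sensitivity analysis.

#' Build the worst/base/best scenario table
#'
#' Titer and DSP yield bounds are mean -/+ one standard deviation; material
#' cost swings by a symmetric percentage applied to the dominant items;
#' target output is halved (worst) and doubled (best, or more generally
#' divided/multiplied by `output_factor`); wages switch between complete
#' location schedules. "Worst" always means the direction that raises
#' CoG/g, so the worst material deviation is +swing and the worst target is
#' the low one (fixed costs spread over fewer grams).
#'
#' @param base A [process_parameters()] object holding the base values.
#' @param titer_sd Titer standard deviation (g/L).
#' @param yield_sd DSP-yield standard deviation (fraction).
#' @param material_swing Material-cost swing (percent, applied as +/-).
#' @param output_factor Fold applied to target output (> 1).
#' @param wage_locations Named character vector with entries `worst`,
#'   `base`, `best` naming wage-schedule locations.
#' @return An object of class `biocogs_scenarios`: per parameter a named
#'   list with `worst`, `base`, `best` values.
#' @examples
#' p <- process_parameters(0.242, 0.958, 25.6)
#' s <- build_scenarios(p, titer_sd = 0.134, yield_sd = 0.011)
#' s$fermentation_titer # worst 0.108, best 0.376
#' @export
build_scenarios <- function(base, titer_sd = 0.134, yield_sd = 0.011,
                            material_swing = 25, output_factor = 2,
                            wage_locations = c(worst = "US", base = "UK",
                                               best = "Mexico")) {
  stopifnot(inherits(base, "biocogs_parameters"))
  if (titer_sd < 0 || yield_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (output_factor <= 1) stop("output_factor must be > 1", call. = FALSE)
  structure(list(
    fermentation_titer = list(worst = base$titer - titer_sd,
                              base = base$titer,
                              best = base$titer + titer_sd),
    dsp_yield = list(worst = base$dsp_yield - yield_sd,
                     base = base$dsp_yield,
                     best = min(1, base$dsp_yield + yield_sd)),
    material_cost = list(worst = +material_swing, base = 0,
                         best = -material_swing),
    target_output = list(worst = base$target_output / output_factor,
                         base = base$target_output,
                         best = base$target_output * output_factor),
    operator_wage = as.list(wage_locations[c("worst", "base", "best")])),
    class = "biocogs_scenarios")
}

# Apply one scenario value to a copy of the base parameters.
apply_scenario <- function(params, parameter, value) {
  switch(parameter,
         fermentation_titer = { params$titer <- value },
         dsp_yield = { params$dsp_yield <- value },
         material_cost = { params$material_cost_deviation <- value },
         target_output = { params$target_output <- value },
         operator_wage = { params$wage_schedule <- wage_schedule(value) },
         stop("Unknown scenario parameter: ", parameter, call. = FALSE))
  params
}

# DSP yield scenarios rescale the flowsheet's recovery steps so that the
# flowsheet product matches the requested overall yield.
rescale_flowsheet_yield <- function(fs, new_yield) {
  cur <- overall_yield(fs)
  factor <- (new_yield / cur)^(1 / length(fs$operations))
  fs$operations <- lapply(fs$operations, function(op) {
    op$step_yield <- min(1, op$step_yield * factor)
    op
  })
  # distribute any residual (from clipping at 1) onto the last lossy step
  resid <- new_yield / overall_yield(fs)
  for (i in rev(seq_along(fs$operations))) {
    y <- fs$operations[[i]]$step_yield * resid
    if (y <= 1) { fs$operations[[i]]$step_yield <- y; break }
  }
  fs
}

# Evaluate CoG/g for one parameter setting; staffing held at the base plan
# (headcount is fixed plant staff) but wage scenarios reprice it.
scenario_cog <- function(params, fs, prices, staffing, cog_basis) {
  if (abs(overall_yield(fs) - params$dsp_yield) > 1e-12)
    fs <- rescale_flowsheet_yield(fs, params$dsp_yield)
  staffing$wages <- params$wage_schedule
  cb <- annual_costs(params, fs, prices, staffing, cog_basis = cog_basis,
                     expand_capacity = TRUE)
  list(cog = cb$cog_per_gram, feasible = !cb$capacity_expanded)
}

#' Tornado analysis: rank parameters by one-at-a-time CoG/g impact
#'
#' Each parameter is perturbed individually to its worst and best scenario
#' while all others stay at base; parameters are ranked by impact. An
#' over-capacity scenario (e.g. worst titer demanding more batches than the
#' schedule holds) is costed under notional capacity expansion and flagged
#' infeasible rather than aborting the analysis.
#'
#' @param params Base [process_parameters()].
#' @param scenarios A [build_scenarios()] table.
#' @param fs,prices,staffing Model context (see [annual_costs()]).
#' @param metric Ranking metric: `"one_sided_max"` (default) ranks by the
#'   larger absolute one-sided delta; `"range"` ranks by
#'   `|CoG(worst) - CoG(best)|`.
#' @param cog_basis Passed to [annual_costs()].
#' @return A `data.frame` (class `biocogs_tornado`), one row per parameter,
#'   sorted by decreasing impact, with columns `parameter`, `cog_worst`,
#'   `cog_base`, `cog_best`, `delta_worst`, `delta_best`, `impact`,
#'   `feasible_worst`, `feasible_best`.
#' @export
tornado <- function(params, scenarios, fs, prices, staffing,
                    metric = c("one_sided_max", "range"),
                    cog_basis = "actual") {
  metric <- match.arg(metric)
  stopifnot(inherits(scenarios, "biocogs_scenarios"))
  base_eval <- scenario_cog(params, fs, prices, staffing, cog_basis)
  rows <- lapply(names(scenarios), function(pname) {
    sc <- scenarios[[pname]]
    worst <- scenario_cog(apply_scenario(params, pname, sc$worst),
                          fs, prices, staffing, cog_basis)
    best <- scenario_cog(apply_scenario(params, pname, sc$best),
                         fs, prices, staffing, cog_basis)
    data.frame(parameter = pname,
               cog_worst = worst$cog, cog_base = base_eval$cog,
               cog_best = best$cog,
               delta_worst = worst$cog - base_eval$cog,
               delta_best = best$cog - base_eval$cog,
               feasible_worst = worst$feasible,
               feasible_best = best$feasible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$impact <- switch(metric,
                       one_sided_max = pmax(abs(out$delta_worst),
                                            abs(out$delta_best)),
                       range = abs(out$cog_worst - out$cog_best))
  out <- out[order(-out$impact), ]
  rownames(out) <- NULL
  class(out) <- c("biocogs_tornado", "data.frame")
  out
}

#' @export
print.biocogs_tornado <- function(x, ...) {
  cat(sprintf("Tornado analysis (base CoG/g = %.2f)\n", x$cog_base[1]))
  df <- data.frame(parameter = x$parameter,
                   worst = round(x$cog_worst, 2),
                   best = round(x$cog_best, 2),
                   impact = round(x$impact, 2),
                   feasible = ifelse(x$feasible_worst & x$feasible_best,
                                     "", "expanded"))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
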