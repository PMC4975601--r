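# Annual cost engine: category and per-operation breakdowns, CoG/g.

#' Wage schedules by location
#'
#' Annual salaries (US$/yr) for the four plant roles in the three locations
#' used by the wage sensitivity scenarios. The UK schedule is the base case.
#'
#' @param location One of `"US"`, `"UK"`, `"Mexico"`.
#' @return Named numeric vector of annual wages.
#' @examples
#' wage_schedule("UK")["production_operator"] # 32935
#' @export
wage_schedule <- function(location = c("UK", "US", "Mexico")) {
  location <- match.arg(location)
  tables <- list(
    US = c(production_operator = 41872, production_supervisor = 52337,
           quality_assurance = 70149, quality_control = 39101),
    UK = c(production_operator = 32935, production_supervisor = 38490,
           quality_assurance = 56176, quality_control = 31400),
    Mexico = c(production_operator = 37689, production_supervisor = 37689,
               quality_assurance = 35995, quality_control = 35995))
  tables[[location]]
}

#' Price table and cost-model constants
#'
#' Unit prices for every consumable and material the flowsheet demands,
#' installed equipment capital per operation, and the capital / QC /
#' overhead constants of the cost model.
#'
#' @param consumable_prices Named numeric vector: item id -> unit price.
#' @param material_prices Named numeric vector: item id -> unit price.
#' @param equipment_costs Named numeric vector: operation name -> installed
#'   capital cost (currency) at the configured train count.
#' @param amortization_years Straight-line amortization period (yr), >= 1.
#' @param facility_multiplier Lang-type multiplier converting installed
#'   equipment cost to total facility capital.
#' @param qc_cost_per_batch Flat quality-control cost per batch (currency).
#' @param other_overhead_rate Overhead charged as a fraction of direct cost
#'   (consumables + materials + labor).
#' @param dominant_materials Item ids (across both price lists) that the
#'   material-cost deviation applies to.
#' @return An object of class `biocogs_price_table`.
#' @export
price_table <- function(consumable_prices = numeric(),
                        material_prices = numeric(),
                        equipment_costs = numeric(),
                        amortization_years = 10,
                        facility_multiplier = 4,
                        qc_cost_per_batch = 0,
                        other_overhead_rate = 0,
                        dominant_materials = character()) {
  for (v in list(consumable_prices, material_prices, equipment_costs))
    if (any(v < 0)) stop("Prices and equipment costs must be >= 0",
                         call. = FALSE)
  if (amortization_years < 1)
    stop("amortization_years must be >= 1", call. = FALSE)
  if (facility_multiplier <= 0 || qc_cost_per_batch < 0 ||
      other_overhead_rate < 0)
    stop("Invalid capital/QC/overhead constants", call. = FALSE)
  structure(list(consumable_prices = consumable_prices,
                 material_prices = material_prices,
                 equipment_costs = equipment_costs,
                 amortization_years = amortization_years,
                 facility_multiplier = facility_multiplier,
                 qc_cost_per_batch = qc_cost_per_batch,
                 other_overhead_rate = other_overhead_rate,
                 dominant_materials = dominant_materials),
            class = "biocogs_price_table")
}

#' Staffing plan
#'
#' @param headcount Named integer vector: role -> number employed.
#' @param wages Named numeric vector: role -> annual wage; must cover every
#'   role in `headcount`.
#' @return An object of class `biocogs_staffing`. Its annual cost is
#'   `sum(headcount * wages[names(headcount)])`.
#' @export
staffing_plan <- function(headcount, wages) {
  if (length(headcount) && any(headcount < 0))
    stop("Headcounts must be >= 0", call. = FALSE)
  missing <- setdiff(names(headcount), names(wages))
  if (length(missing))
    stop("No wage given for role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(headcount = headcount, wages = wages),
            class = "biocogs_staffing")
}

labor_cost <- function(staffing) {
  if (!length(staffing$headcount)) return(0)
  sum(staffing$headcount * staffing$wages[names(staffing$headcount)])
}

#' Price multiplier from a material-cost deviation
#'
#' The deviation is applied only to the designated dominant items (for the
#' base flowsheet: the buffered glycerol-complex fermentation medium and the
#' UF/DF membranes); every other item keeps its listed price.
#'
#' @param deviation Signed percentage, >= -100.
#' @param item Item id.
#' @param dominant_set Character vector of dominant item ids.
#' @return Multiplicative factor: `1 + deviation/100` for dominant items,
#'   otherwise 1.
#' @examples
#' material_cost_multiplier(25, "ufdf_membrane", "ufdf_membrane") # 1.25
#' @export
material_cost_multiplier <- function(deviation, item, dominant_set) {
  if (deviation < -100) stop("deviation must be >= -100", call. = FALSE)
  ifelse(item %in% dominant_set, 1 + deviation / 100, 1)
}

# Per-batch cost of one demand vector under the active deviation.
demand_cost <- function(demand, prices, deviation, dominant_set) {
  if (!length(demand)) return(0)
  missing <- setdiff(names(demand), names(prices))
  if (length(missing))
    stop("Missing price for item(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- prices[names(demand)] *
    material_cost_multiplier(deviation, names(demand), dominant_set)
  sum(demand * p)
}

#' Annual cost breakdown and cost of goods per gram
#'
#' Runs the scheduling and mass balance, then assembles the annual cost by
#' category: straight-line amortized facility capital, per-batch consumables
#' and materials (with the dominant-item deviation applied), labor from the
#' staffing plan, and "other" (flat QC per batch plus an overhead rate on
#' direct cost). Consumable and material spend is also attributed to the
#' unit operation that demands it; capital and labor are reported at plant
#' level only.
#'
#' @param params A [process_parameters()] object.
#' @param fs A [flowsheet()].
#' @param prices A [price_table()].
#' @param staffing A [staffing_plan()].
#' @param cog_basis Denominator for CoG/g: `"actual"` (default) divides by
#'   the mass actually made, `B * per_batch_output`; `"target"` divides by
#'   the nominal annual target.
#' @param expand_capacity If `TRUE`, an over-capacity schedule is costed by
#'   notionally adding parallel trains (capital scales with the expansion
#'   factor) instead of failing; the result is flagged via
#'   `$capacity_expanded`.
#' @return An object of class `biocogs_costs` with elements `by_category`
#'   (named numeric: capital, consumables, materials, labor, other),
#'   `by_unit_operation`, `total`, `batches`, `annual_mass` (g/yr),
#'   `cog_per_gram`, `capacity_expanded`, and `expansion_factor`.
#' @export
annual_costs <- function(params, fs, prices, staffing,
                         cog_basis = c("actual", "target"),
                         expand_capacity = FALSE) {
  cog_basis <- match.arg(cog_basis)
  stopifnot(inherits(prices, "biocogs_price_table"),
            inherits(staffing, "biocogs_staffing"))
  m <- per_batch_output(params, fs)
  batches <- batches_per_year(params, fs, expand_capacity = expand_capacity)
  expansion <- capacity_expansion(batches, fs)
  dev <- params$material_cost_deviation
  dom <- prices$dominant_materials

  cons_pb <- vapply(fs$operations, function(op)
    demand_cost(op$consumables, prices$consumable_prices, dev, dom),
    numeric(1))
  mat_pb <- vapply(fs$operations, function(op)
    demand_cost(op$materials, prices$material_prices, dev, dom), numeric(1))

  capital <- sum(prices$equipment_costs) * expansion *
    prices$facility_multiplier / prices$amortization_years
  consumables <- sum(cons_pb) * batches
  materials <- sum(mat_pb) * batches
  labor <- labor_cost(staffing)
  direct <- consumables + materials + labor
  other <- prices$qc_cost_per_batch * batches +
    prices$other_overhead_rate * direct

  by_category <- c(capital = capital, consumables = consumables,
                   materials = materials, labor = labor, other = other)
  total <- sum(by_category)
  annual_mass <- batches * m
  denom <- if (cog_basis == "actual") annual_mass else
    params$target_output * 1000

  structure(list(by_category = by_category,
                 by_unit_operation = (cons_pb + mat_pb) * batches,
                 total = total,
                 batches = batches,
                 per_batch_output = m,
                 annual_mass = annual_mass,
                 cog_basis = cog_basis,
                 cog_per_gram = total / denom,
                 capacity_expanded = expansion > 1,
                 expansion_factor = expansion,
                 staffing = staffing),
            class = "biocogs_costs")
}

#' Size the staffing plan from a target labor share
#'
#' Labor budgets in biomanufacturing are commonly set as a fraction of total
#' production cost (10-15%). Because total cost itself contains labor (and
#' overhead charged on labor), the budget solves the fixed point
#' `labor = share * total`. With overhead rate r on direct cost and
#' non-labor cost N (which already includes overhead on consumables and
#' materials), the closed form is
#' `labor = share * N / (1 - share * (1 + r))`.
#' The budget is then spent across the four roles in a fixed ratio
#' (operator : supervisor : QA : QC = 6 : 1 : 2 : 2) with headcounts rounded
#' to whole employees.
#'
#' @param target_share Desired labor fraction of total cost, in (0, 1).
#' @inheritParams annual_costs
#' @param role_ratio Relative headcount mix across roles.
#' @return A [staffing_plan()] whose realized labor share is within 0.5
#'   percentage points of `target_share` (headcount rounding permitting).
#' @export
staffing_from_labor_share <- function(target_share, params, fs, prices,
                                      role_ratio = c(production_operator = 6,
                                                     production_supervisor = 1,
                                                     quality_assurance = 2,
                                                     quality_control = 2),
                                      cog_basis = "actual",
                                      expand_capacity = FALSE) {
  wages <- params$wage_schedule
  if (target_share == 0)
    return(staffing_plan(stats::setNames(integer(0), character(0)), wages))
  if (target_share <= 0 || target_share >= 1)
    stop("target_share must lie in (0, 1)", call. = FALSE)
  r <- prices$other_overhead_rate
  if (target_share * (1 + r) >= 1)
    stop("Labor share unattainable: overhead coupling ", 1 + r,
         " times share ", target_share, " reaches 1", call. = FALSE)
  empty <- staffing_plan(stats::setNames(integer(0), character(0)), wages)
  nonlabor <- annual_costs(params, fs, prices, empty, cog_basis = cog_basis,
                           expand_capacity = expand_capacity)$total
  budget <- target_share * nonlabor / (1 - target_share * (1 + r))
  missing <- setdiff(names(role_ratio), names(wages))
  if (length(missing))
    stop("No wage for role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unit_cost <- sum(role_ratio * wages[names(role_ratio)])
  k <- budget / unit_cost
  headcount <- round(role_ratio * k)
  staffing_plan(headcount, wages)
}

#' Labor share of a cost breakdown
#'
#' @param costs A `biocogs_costs` object.
#' @return Labor cost as a fraction of total annual cost.
#' @export
labor_share <- function(costs) {
  unname(costs$by_category["labor"] / costs$total)
}

#' @export
print.biocogs_costs <- function(x, ...) {
  cat(sprintf("Annual cost breakdown (%d batches, %.1f g/batch):\n",
              x$batches, x$per_batch_output))
  pct <- 100 * x$by_category / x$total
  for (i in seq_along(x$by_category))
    cat(sprintf("  %-12s %14s  (%4.1f%%)\n", names(x$by_category)[i],
                format(round(x$by_category[i]), big.mark = ","), pct[i]))
  cat(sprintf("  %-12s %14s\n", "total",
              format(round(x$total), big.mark = ",")))
  cat(sprintf("CoG/g: %.2f (basis: %s mass %.0f g/yr)%s\n", x$cog_per_gram,
              x$cog_basis, x$annual_mass,
              if (x$capacity_expanded)
                sprintf("  [capacity expanded x%.2f]", x$expansion_factor)
              else ""))
  invisible(x)
}
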