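test_that("material-cost multiplier hits only the dominant set", {
  dom <- c("bmgy_medium", "ufdf_membrane")
  expect_identical(material_cost_multiplier(0, "anything", dom), 1)
  expect_identical(material_cost_multiplier(25, "ufdf_membrane", dom), 1.25)
  expect_identical(material_cost_multiplier(-25, "depth_filter", dom), 1)
  expect_error(material_cost_multiplier(-150, "x", dom), ">= -100")
})

test_that("cost categories are conserved for randomized valid inputs", {
  set.seed(13)
  for (i in 1:20) {
    fs <- tiny_flowsheet(volume = stats::runif(1, 500, 3000), trains = 5L)
    prices <- tiny_prices(overhead = stats::runif(1, 0, 0.3),
                          qc = stats::runif(1, 0, 5000))
    p <- process_parameters(stats::runif(1, 0.1, 2),
                            stats::runif(1, 0.5, 1),
                            stats::runif(1, 1, 30),
                            stats::runif(1, -25, 25))
    cb <- annual_costs(p, fs, prices, tiny_staffing(sample(0:10, 1)))
    expect_equal(sum(cb$by_category), cb$total, tolerance = 1e-9)
    expect_equal(sum(cb$by_unit_operation),
                 sum(cb$by_category[c("consumables", "materials")]),
                 tolerance = 1e-9)
    expect_equal(cb$cog_per_gram, cb$total / cb$annual_mass)
  }
})

test_that("doubling consumable prices doubles only the consumables", {
  fs <- tiny_flowsheet()
  p <- process_parameters(0.5, 0.9, 10)
  pr1 <- tiny_prices()
  pr2 <- pr1
  pr2$consumable_prices <- pr1$consumable_prices * 2
  cb1 <- annual_costs(p, fs, pr1, tiny_staffing())
  cb2 <- annual_costs(p, fs, pr2, tiny_staffing())
  expect_equal(cb2$by_category["consumables"],
               2 * cb1$by_category["consumables"])
  for (cat in c("capital", "materials", "labor"))
    expect_equal(cb2$by_category[cat], cb1$by_category[cat])
})

test_that("a demanded item without a price is an explicit error", {
  fs <- tiny_flowsheet()
  pr <- tiny_prices()
  pr$material_prices <- pr$material_prices[0]
  expect_error(
    annual_costs(process_parameters(0.5, 0.9, 10), fs, pr, tiny_staffing()),
    "Missing price for item\\(s\\): medium")
})

test_that("a minimal target still costs one full batch of consumables", {
  fs <- tiny_flowsheet()
  p <- process_parameters(0.5, 0.9, 1e-6)
  cb <- annual_costs(p, fs, tiny_prices(), tiny_staffing())
  expect_identical(cb$batches, 1L)
  expect_equal(unname(cb$by_category["consumables"]), 2 * 500)
})

test_that("labor-share solver reproduces its closed form", {
  # fixed costs 870k/yr, no overhead coupling: budget = 0.13/0.87 * 870k
  fs <- flowsheet(list(unit_operation("only", 10, 1, 1, 1)),
                  fermenter_working_volume = 1000)
  prices <- price_table(equipment_costs = c(only = 870e3 * 10 / 4),
                        qc_cost_per_batch = 0, other_overhead_rate = 0)
  p <- process_parameters(1, 1, 0.9,
                          wage_schedule = c(production_operator = 1000))
  st <- staffing_from_labor_share(0.13, p, fs, prices,
                                  role_ratio = c(production_operator = 1))
  budget <- 0.13 / 0.87 * 870e3
  expect_equal(unname(sum(st$headcount * st$wages[names(st$headcount)])),
               round(budget / 1000) * 1000)
  expect_equal(unname(st$headcount), 130)
  # zero share: empty staffing
  st0 <- staffing_from_labor_share(0, p, fs, prices)
  expect_length(st0$headcount, 0)
  # overhead coupling that reaches 1 is a configuration error
  prices$other_overhead_rate <- 9
  expect_error(staffing_from_labor_share(0.13, p, fs, prices),
               "overhead coupling")
})

test_that("calibrated base case holds labor at 13% within half a point", {
  cal <- calibrated_fixture()
  expect_lt(abs(labor_share(cal$costs) - 0.13), 0.005)
})

test_that("CoG/g falls with titer and yield at fixed nominal target", {
  # on the nominal-target basis the batch count is the only moving part,
  # so CoG/g must be nonincreasing in titer and DSP yield
  cal <- calibrated_fixture()
  cogs <- vapply(seq(0.108, 0.376, length.out = 12), function(t) {
    p <- cal$params; p$titer <- t
    annual_costs(p, cal$flowsheet, cal$prices, cal$staffing,
                 cog_basis = "target")$cog_per_gram
  }, numeric(1))
  expect_true(all(diff(cogs) <= 1e-9))
  cogy <- vapply(c(0.90, 0.93, 0.958, 0.969), function(y) {
    p <- cal$params; p$dsp_yield <- y
    fs <- base_flowsheet(y, cal$flowsheet$fermenter_working_volume)
    annual_costs(p, fs, cal$prices, cal$staffing,
                 cog_basis = "target")$cog_per_gram
  }, numeric(1))
  expect_true(all(diff(cogy) <= 1e-9))
})

test_that("CoG/g per actual gram falls as the target output grows", {
  cal <- calibrated_fixture()
  cogs <- vapply(seq(12.8, 51.2, length.out = 15), function(g) {
    p <- cal$params; p$target_output <- g
    annual_costs(p, cal$flowsheet, cal$prices, cal$staffing)$cog_per_gram
  }, numeric(1))
  expect_true(all(diff(cogs) <= 1e-9))
})

test_that("titer impact on CoG/g is asymmetric around the base case", {
  cal <- calibrated_fixture()
  at_titer <- function(t) {
    p <- cal$params; p$titer <- t
    annual_costs(p, cal$flowsheet, cal$prices, cal$staffing,
                 expand_capacity = TRUE)$cog_per_gram
  }
  base <- at_titer(0.242)
  expect_gt(at_titer(0.108) - base, base - at_titer(0.376))
})

test_that("marginal material-cost sensitivity shrinks as titer rises", {
  cal <- calibrated_fixture()
  slope <- function(t) {
    p <- cal$params; p$titer <- t
    at <- function(dev) {
      p$material_cost_deviation <- dev
      annual_costs(p, cal$flowsheet, cal$prices, cal$staffing)$cog_per_gram
    }
    (at(1) - at(0)) / 1
  }
  expect_gt(abs(slope(0.242)), abs(slope(5.44)))
})
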