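test_that("overall yield is the product of step yields", {
  mk <- function(yields) flowsheet(
    lapply(seq_along(yields), function(i)
      unit_operation(paste0("op", i), 1, 1, 1, yields[i])),
    fermenter_working_volume = 2000)
  expect_identical(overall_yield(mk(c(1, 1, 1))), 1)
  expect_equal(overall_yield(mk(c(0.98, 0.97755))), 0.958, tolerance = 1e-4)
  expect_equal(overall_yield(mk(0.958)), 0.958)

  # oracle equivalence: brute-force fold over randomized step yields
  set.seed(42)
  for (i in 1:20) {
    y <- stats::runif(sample(1:6, 1), 0.8, 1)
    expect_equal(overall_yield(mk(y)), Reduce(`*`, y, accumulate = FALSE))
  }
  expect_error(flowsheet(list(), fermenter_working_volume = 10),
               "at least one")
})

test_that("flowsheet built from a given DSP yield reproduces it exactly", {
  for (y in c(0.9, 0.958, 0.97)) {
    fs <- base_flowsheet(dsp_yield = y)
    expect_equal(overall_yield(fs), y, tolerance = 1e-9)
  }
})

test_that("per-batch output follows titer x volume x yield", {
  fs <- base_flowsheet(dsp_yield = 0.958, fermenter_working_volume = 2000)
  p <- function(t) process_parameters(t, 0.958, 25.6)
  expect_equal(per_batch_output(p(0.242), fs), 463.7, tolerance = 1e-3)
  expect_equal(per_batch_output(p(5.44), fs), 10423.0, tolerance = 1e-4)
  one <- flowsheet(list(unit_operation("x", 1, 1, 1, 1)),
                   fermenter_working_volume = 1)
  expect_identical(per_batch_output(process_parameters(1, 1, 1), one), 1)
})

test_that("batch count is the ceiling of target over per-batch output", {
  fs <- base_flowsheet()
  p <- function(t, target) process_parameters(t, 0.958, target)
  expect_identical(batches_per_year(p(0.242, 25.6), fs), 56L)
  expect_identical(batches_per_year(p(5.44, 25.6), fs), 3L)
  # exact divisibility: target exactly 10 batches
  m <- per_batch_output(p(0.242, 1), fs)
  expect_identical(batches_per_year(p(0.242, 10 * m / 1000), fs), 10L)
})

test_that("ceiling-batch contract holds over randomized parameters", {
  set.seed(7)
  fs <- base_flowsheet(parallel_trains = 50L)
  for (i in 1:50) {
    p <- process_parameters(stats::runif(1, 0.05, 6), stats::runif(1, 0.5, 1),
                            stats::runif(1, 1, 60))
    b <- batches_per_year(p, fs)
    m <- per_batch_output(p, fs)
    expect_gte(b * m, p$target_output * 1000)
    if (b > 1) expect_lt((b - 1) * m, p$target_output * 1000)
  }
})

test_that("batch demand is monotone in titer, yield, volume and target", {
  set.seed(11)
  for (i in 1:25) {
    titer <- stats::runif(1, 0.1, 2); yield <- stats::runif(1, 0.6, 0.93)
    target <- stats::runif(1, 5, 40); vol <- stats::runif(1, 1000, 3000)
    b0 <- batches_per_year(
      process_parameters(titer, yield, target),
      base_flowsheet(yield, vol, parallel_trains = 50L))
    up <- function(t = titer, y = yield, g = target, v = vol)
      batches_per_year(process_parameters(t, y, g),
                       base_flowsheet(y, v, parallel_trains = 50L))
    expect_lte(up(t = titer * 1.3), b0)
    expect_lte(up(y = min(1, yield * 1.05)), b0)
    expect_lte(up(v = vol * 1.2), b0)
    expect_gte(up(g = target * 1.5), b0)
  }
})

test_that("over-capacity schedules error with required vs available counts", {
  fs <- tiny_flowsheet(volume = 1000, trains = 1L, duration = 1000)
  p <- process_parameters(0.1, 0.9, 50)   # needs far more than capacity
  err <- expect_error(batches_per_year(p, fs),
                      class = "biocogs_infeasible_schedule")
  expect_match(conditionMessage(err), "\\d+ batches required")
  expect_gt(err$required, err$available)
  # expansion path reports the batch count and the train scale-up needed
  b <- batches_per_year(p, fs, expand_capacity = TRUE)
  expect_gt(capacity_expansion(b, fs), 1)
})

test_that("parameter invariants are enforced", {
  expect_error(process_parameters(-1, 0.9, 10), "titer")
  expect_error(process_parameters(1, 1.2, 10), "dsp_yield")
  expect_error(process_parameters(1, 0.9, 0), "target_output")
  expect_error(process_parameters(1, 0.9, 10, -150), "material_cost")
  expect_error(unit_operation("x", 1, 1, 1, 1.5), "step_yield")
  expect_error(unit_operation("x", 0, 1, 1, 1), "duration")
})
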