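test_that("triangular quantile transform spans the support correctly", {
  d <- triangular_dist(12.8, 25.6, 51.2)
  expect_equal(qtriangular(0, d), 12.8)
  expect_equal(qtriangular(1, d), 51.2)
  # CDF at the mode maps back to the mode
  fc <- (25.6 - 12.8) / (51.2 - 12.8)
  expect_equal(qtriangular(fc, d), 25.6)
  # continuous and nondecreasing
  u <- seq(0, 1, length.out = 1001)
  q <- qtriangular(u, d)
  expect_true(all(diff(q) >= 0))
  expect_lt(max(abs(diff(q))), 1)
  expect_error(qtriangular(1.01, d), "\\[0, 1\\]")
  expect_error(triangular_dist(2, 1, 3), "min <= mode <= max")
  # degenerate distribution collapses to the mode
  d0 <- triangular_dist(5, 5, 5)
  expect_equal(qtriangular(c(0, 0.5, 1), d0), c(5, 5, 5))
})

test_that("empirical triangular moments match the closed forms", {
  set.seed(99)
  n <- 1e5
  for (d in list(triangular_dist(12.8, 25.6, 51.2),
                 triangular_dist(0.108, 0.242, 0.376),
                 triangular_dist(-25, 0, 25))) {
    x <- rtriangular(n, d)
    expect_true(all(x >= d$min & x <= d$max))
    m <- triangular_moments(d)
    expect_lt(abs(mean(x) - m["mean"]), 3 * sqrt(m["var"] / n))
    # SE of the sample variance ~ var * sqrt(2/n) (conservative here:
    # triangular excess kurtosis is negative)
    expect_lt(abs(stats::var(x) - m["var"]), 3 * m["var"] * sqrt(2 / n))
  }
})

test_that("moving-average stopping rule handles the canonical series", {
  expect_identical(moving_average_convergence(rep(5, 100), 50, 0.01), 50L)
  # an odd window cannot balance a +/- alternating series, so its moving
  # average keeps oscillating and never stabilizes
  alternating <- rep(c(100, -100), 100)
  expect_identical(moving_average_convergence(alternating, 9, 1e-6),
                   NA_integer_)
  expect_error(moving_average_convergence(1:5, 10, 0.01), "shorter")
  # a series that settles after a noisy burn-in converges after it
  settled <- c(stats::rnorm(60, 100, 40), rep(100, 140))
  conv <- moving_average_convergence(settled, 50, 0.001)
  expect_false(is.na(conv))
  expect_gt(conv, 60)
})

test_that("Monte Carlo runs are deterministic and summary-consistent", {
  cal <- calibrated_fixture()
  cfg <- mc_config_before(seed = 7)
  mc1 <- run_monte_carlo(cfg, cal$params, cal$flowsheet, cal$prices,
                         cal$staffing)
  mc2 <- run_monte_carlo(cfg, cal$params, cal$flowsheet, cal$prices,
                         cal$staffing)
  expect_identical(mc1$samples, mc2$samples)
  expect_identical(mc1$summary, mc2$summary)
  # summary recomputable exactly from the stored samples
  expect_identical(mc1$summary[["mean"]], mean(mc1$samples$cog))
  expect_identical(mc1$summary[["median"]], stats::median(mc1$samples$cog))
  expect_identical(mc1$summary[["range"]], diff(range(mc1$samples$cog)))
  expect_identical(mc1$summary[["sd"]], stats::sd(mc1$samples$cog))
  # all sampled parameters stay inside their supports
  for (p in c("titer", "target_output", "material_cost")) {
    d <- cfg$distributions[[p]]
    col <- mc1$samples[[p]]
    expect_true(all(col >= d$min & col <= d$max))
  }
  # the global RNG stream is left untouched
  set.seed(123); before <- stats::runif(3)
  set.seed(123); invisible(run_monte_carlo(cfg, cal$params, cal$flowsheet,
                                           cal$prices, cal$staffing))
  expect_identical(stats::runif(3), before)
})

test_that("degenerate distributions reproduce the deterministic base case", {
  cal <- calibrated_fixture()
  p <- cal$params
  cfg <- mc_config(list(titer = triangular_dist(p$titer, p$titer, p$titer),
                        target_output = triangular_dist(
                          p$target_output, p$target_output, p$target_output),
                        material_cost = triangular_dist(0, 0, 0)),
                   max_runs = 20, ma_window = 5, seed = 1)
  mc <- run_monte_carlo(cfg, p, cal$flowsheet, cal$prices, cal$staffing)
  base <- annual_costs(p, cal$flowsheet, cal$prices,
                       cal$staffing)$cog_per_gram
  expect_equal(mc$samples$cog, rep(base, 20))
  expect_identical(mc$runs_to_convergence, 5L)
})

test_that("CoG/g samples respect the corner bounds of the monotone model", {
  cal <- calibrated_fixture()
  corner <- function(cfg, which) {
    p <- cal$params
    pick <- function(d) if (which == "best") d$max else d$min
    p$titer <- pick(cfg$distributions$titer)
    p$target_output <- pick(cfg$distributions$target_output)
    p$material_cost_deviation <- if (which == "best")
      cfg$distributions$material_cost$min else
        cfg$distributions$material_cost$max
    annual_costs(p, cal$flowsheet, cal$prices, cal$staffing,
                 expand_capacity = TRUE)$cog_per_gram
  }
  for (cfg in list(mc_config_before(5), mc_config_after(5))) {
    mc <- run_monte_carlo(cfg, cal$params, cal$flowsheet, cal$prices,
                          cal$staffing)
    lo <- corner(cfg, "best"); hi <- corner(cfg, "worst")
    # slack covers the sawtooth from whole-batch granularity
    expect_true(all(mc$samples$cog >= lo * (1 - 1e-3)))
    expect_true(all(mc$samples$cog <= hi * (1 + 1e-3)))
  }
})

test_that("the base configuration stabilizes within the standard 300 runs", {
  cal <- calibrated_fixture()
  mc <- run_monte_carlo(mc_config_before(seed = 1), cal$params,
                        cal$flowsheet, cal$prices, cal$staffing)
  expect_false(is.na(mc$runs_to_convergence))
  expect_lte(mc$runs_to_convergence, 300L)
})
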