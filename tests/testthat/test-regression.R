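sim_samples <- function(n, beta = c(10, -2, 0, 0), sd = 0,
                        titer = stats::runif(n, 0.1, 0.4),
                        target = stats::runif(n, 12, 52),
                        material = stats::runif(n, -25, 25)) {
  data.frame(titer = titer, target_output = target, material_cost = material,
             cog = beta[1] + beta[2] * titer + beta[3] * target +
               beta[4] * material + stats::rnorm(n, 0, sd))
}

test_that("noiseless linear data is recovered to machine precision", {
  set.seed(21)
  s <- sim_samples(60, beta = c(10, -2, 0, 0), sd = 0)
  fit <- suppressWarnings(fit_ols(s))  # summary.lm flags the perfect fit
  expect_equal(fit$coefficients$estimate, c(10, -2, 0, 0),
               tolerance = 1e-10)
})

test_that("the fit equals a brute-force normal-equations solve", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(8:50, 1)
    s <- sim_samples(n, beta = stats::rnorm(4, 0, 5), sd = stats::runif(1, 0.1, 3))
    fit <- fit_ols(s)
    X <- cbind(1, s$titer, s$target_output, s$material_cost)
    beta <- solve(t(X) %*% X, t(X) %*% s$cog)
    expect_equal(fit$coefficients$estimate, as.numeric(beta),
                 tolerance = 1e-8)
    resid <- s$cog - X %*% beta
    sigma2 <- sum(resid^2) / (n - 4)
    expect_equal(fit$sigma2, sigma2, tolerance = 1e-8)
    se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
    expect_equal(fit$coefficients$std_error, unname(se), tolerance = 1e-8)
    tv <- as.numeric(beta) / se
    expect_equal(fit$coefficients$t_value, unname(tv), tolerance = 1e-8)
    expect_equal(fit$coefficients$p_value,
                 unname(2 * stats::pt(abs(tv), n - 4, lower.tail = FALSE)),
                 tolerance = 1e-8)
  }
})

test_that("degenerate predictors raise an error naming the column", {
  set.seed(23)
  s <- sim_samples(30)
  s$material_cost <- 5
  expect_error(fit_ols(s), "constant column\\(s\\): material_cost")
  expect_error(fit_ols(sim_samples(4)), "at least 5")
})

test_that("the significance screen applies the alpha threshold", {
  set.seed(24)
  # strong titer signal, pure-noise material term
  s <- sim_samples(200, beta = c(100, -50, 0, 0), sd = 1)
  screen <- significance_screen(fit_ols(s), alpha = 0.01)
  expect_true(screen[["titer"]])
  expect_false(screen[["material_cost"]])
  expect_error(significance_screen(fit_ols(s), alpha = 0), "alpha")
})

test_that("simulated coefficients are recovered within three SEs", {
  set.seed(25)
  beta <- c(1700, -1900, -14, 2.6)
  s <- sim_samples(300, beta = beta, sd = 60)
  fit <- fit_ols(s)
  expect_true(all(abs(fit$coefficients$estimate - beta) <
                    3 * fit$coefficients$std_error))
})

test_that("type-I error of the material-coefficient test is near alpha", {
  set.seed(26)
  alpha <- 0.05
  reps <- 500
  rejections <- 0L
  for (r in seq_len(reps)) {
    s <- sim_samples(300, beta = c(1000, -500, -10, 0), sd = 50)
    p <- fit_ols(s)$coefficients$p_value[4]
    if (p < alpha) rejections <- rejections + 1L
  }
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(rejections / reps - alpha), 3.5 * se)
})

test_that("driver ranking reports influence, shifts and lost significance", {
  set.seed(27)
  spans <- c(titer = 0.268, target_output = 38.4, material_cost = 50)
  dominant <- fit_ols(sim_samples(200, beta = c(0, -1000, 0.1, 1), sd = 1))
  rep0 <- strategy_shift_report(dominant, dominant, spans)
  expect_false(rep0$rank_changed)
  expect_length(rep0$significance_lost, 0)
  expect_identical(rep0$top_before, "titer")  # dominant coefficient first
  # a target-dominated fit flips the ranking and drowns the material term
  flipped <- fit_ols(sim_samples(200, beta = c(0, -50, -400, 0.0001),
                                 sd = 1))
  rep1 <- strategy_shift_report(dominant, flipped, spans)
  expect_true(rep1$rank_changed)
  expect_identical(rep1$top_after, "target_output")
  expect_identical(rep1$significance_lost, "material_cost")
})
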