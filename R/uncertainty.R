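# Joint Monte Carlo over titer, target output and material cost with
# triangular input distributions and a moving-average stopping rule.

#' Triangular distribution
#'
#' Three-point (min, mode, max) distribution, the standard choice for
#' bioprocess parameters known only by their bounds and most likely value.
#'
#' @param min,mode,max Support and mode; `min <= mode <= max`, `min < max`.
#'   A degenerate distribution (`min == mode == max`) is allowed and always
#'   returns `mode`.
#' @return An object of class `biocogs_triangular`.
#' @export
triangular_dist <- function(min, mode, max) {
  if (!(min <= mode && mode <= max))
    stop("Triangular distribution requires min <= mode <= max", call. = FALSE)
  structure(list(min = min, mode = mode, max = max),
            class = "biocogs_triangular")
}

#' Triangular quantile function (inverse CDF)
#'
#' @param u Probabilities in \[0, 1\].
#' @param dist A [triangular_dist()].
#' @return Quantiles; `u = 0` maps to `min`, `u = 1` to `max`, and the
#'   transform is continuous and nondecreasing in `u`.
#' @examples
#' d <- triangular_dist(12.8, 25.6, 51.2)
#' qtriangular(c(0, 1), d) # 12.8 51.2
#' @export
qtriangular <- function(u, dist) {
  stopifnot(inherits(dist, "biocogs_triangular"))
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]", call. = FALSE)
  a <- dist$min; b <- dist$max; c <- dist$mode
  if (a == b) return(rep(c, length(u)))
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Random draws from a triangular distribution
#'
#' Inverse-CDF transform of `runif(n)`; uses (and advances) R's global RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param n Number of draws.
#' @param dist A [triangular_dist()].
#' @return Numeric vector of length `n` within `[min, max]`.
#' @export
rtriangular <- function(n, dist) qtriangular(stats::runif(n), dist)

#' Closed-form moments of a triangular distribution
#'
#' @param dist A [triangular_dist()].
#' @return Named numeric `c(mean, var)`: mean `(a + b + c) / 3` and
#'   variance `(a^2 + b^2 + c^2 - ab - ac - bc) / 18`.
#' @export
triangular_moments <- function(dist) {
  a <- dist$min; b <- dist$max; c <- dist$mode
  c(mean = (a + b + c) / 3,
    var = (a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18)
}

#' Monte Carlo configuration
#'
#' @param distributions Named list of [triangular_dist()] objects for
#'   `titer` (g/L), `target_output` (kg/yr) and `material_cost` (%).
#' @param max_runs Number of simulation runs (default 300, at which the
#'   moving average of CoG/g is stable for the base configurations).
#' @param ma_window Moving-average window (runs).
#' @param ma_tolerance Relative moving-average change below which the
#'   simulation counts as stable.
#' @param seed Integer seed controlling all sampling.
#' @return An object of class `biocogs_mc_config`.
#' @export
mc_config <- function(distributions, max_runs = 300, ma_window = 50,
                      ma_tolerance = 0.01, seed = 1L) {
  required <- c("titer", "target_output", "material_cost")
  missing <- setdiff(required, names(distributions))
  if (length(missing))
    stop("Missing distribution(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ok <- vapply(distributions, inherits, logical(1), "biocogs_triangular")
  if (!all(ok)) stop("All distributions must be triangular_dist objects",
                     call. = FALSE)
  if (ma_window < 2 || max_runs < ma_window)
    stop("Need max_runs >= ma_window >= 2", call. = FALSE)
  if (ma_tolerance <= 0) stop("ma_tolerance must be > 0", call. = FALSE)
  structure(list(distributions = distributions,
                 max_runs = as.integer(max_runs),
                 ma_window = as.integer(ma_window),
                 ma_tolerance = ma_tolerance, seed = as.integer(seed)),
            class = "biocogs_mc_config")
}

#' First run at which a moving average has stabilized
#'
#' Tracks the trailing moving average `ma[t] = mean(x[max(1, t-w+1) .. t])`
#' (partial windows during warm-up, so the statistic exists from run 1) and
#' its relative step `rel[t] = |ma[t] - ma[t-1]| / |ma[t-1]|`. The series
#' counts as converged at the first index `t >= w` whose trailing window of
#' relative steps (`rel[t-w+2] .. rel[t]`, clipped to `t >= 2`) lies
#' entirely below `tolerance`: a constant series converges exactly at the
#' window length, a persistently oscillating one never does.
#'
#' @param x Numeric series (e.g. CoG/g per run).
#' @param window Window length `w >= 2`.
#' @param tolerance Relative change threshold (> 0).
#' @return The converging run index, or `NA_integer_` if the series never
#'   stabilizes.
#' @examples
#' moving_average_convergence(rep(5, 100), 50, 0.01) # 50
#' @export
moving_average_convergence <- function(x, window, tolerance) {
  n <- length(x)
  if (n < window) stop("series shorter than window", call. = FALSE)
  cs <- cumsum(x)
  t <- seq_len(n)
  lo <- pmax(1L, t - as.integer(window) + 1L)
  ma <- (cs - c(0, cs)[lo]) / (t - lo + 1)
  rel <- c(NA_real_, abs(diff(ma)) / abs(ma[-n]))
  rel[is.nan(rel)] <- 0            # 0 -> 0 steps count as no change
  for (t in window:n) {
    span <- max(2L, t - window + 2L):t
    if (all(rel[span] < tolerance)) return(as.integer(t))
  }
  NA_integer_
}

#' Joint Monte Carlo uncertainty analysis of CoG/g
#'
#' Draws titer, target output and material-cost deviation independently
#' from their triangular distributions each run, evaluates the full cost
#' model, and tracks the moving average of CoG/g. Draws whose batch demand
#' exceeds the configured schedule are costed under notional capacity
#' expansion and flagged, never dropped. Deterministic given the config
#' seed.
#'
#' @param cfg An [mc_config()].
#' @param params Base [process_parameters()] (supplies DSP yield and the
#'   wage schedule; the three sampled fields are overwritten each run).
#' @param fs,prices,staffing Model context (see [annual_costs()]).
#' @param cog_basis Passed to [annual_costs()].
#' @return An object of class `biocogs_mc`: `samples` (data.frame with
#'   columns `run`, `titer`, `target_output`, `material_cost`, `cog`,
#'   `capacity_expanded`), `summary` (mean, median, range, sd of CoG/g),
#'   `runs_to_convergence` (or `NA`), and the echoed `seed`.
#' @export
run_monte_carlo <- function(cfg, params, fs, prices, staffing,
                            cog_basis = "actual") {
  stopifnot(inherits(cfg, "biocogs_mc_config"))
  n <- cfg$max_runs
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  titer <- rtriangular(n, cfg$distributions$titer)
  target <- rtriangular(n, cfg$distributions$target_output)
  matdev <- rtriangular(n, cfg$distributions$material_cost)
  cog <- numeric(n)
  expanded <- logical(n)
  for (i in seq_len(n)) {
    p <- params
    p$titer <- titer[i]
    p$target_output <- target[i]
    p$material_cost_deviation <- matdev[i]
    cb <- annual_costs(p, fs, prices, staffing, cog_basis = cog_basis,
                       expand_capacity = TRUE)
    cog[i] <- cb$cog_per_gram
    expanded[i] <- cb$capacity_expanded
  }
  samples <- data.frame(run = seq_len(n), titer = titer,
                        target_output = target, material_cost = matdev,
                        cog = cog, capacity_expanded = expanded)
  structure(list(
    samples = samples,
    summary = c(mean = mean(cog), median = stats::median(cog),
                range = diff(range(cog)), sd = stats::sd(cog)),
    runs_to_convergence = moving_average_convergence(
      cog, cfg$ma_window, cfg$ma_tolerance),
    seed = cfg$seed,
    config = cfg),
    class = "biocogs_mc")
}

#' @export
print.biocogs_mc <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Monte Carlo: %d runs (seed %d)\n",
                     "CoG/g: mean = %.2f, median = %.2f, range = %.2f, ",
                     "sd = %.2f\n"),
              nrow(x$samples), x$seed, s["mean"], s["median"], s["range"],
              s["sd"]))
  conv <- x$runs_to_convergence
  cat(if (is.na(conv)) "Moving average did not stabilize\n" else
    sprintf("Moving average stable from run %d\n", conv))
  if (any(x$samples$capacity_expanded))
    cat(sprintf("%d run(s) required notional capacity expansion\n",
                sum(x$samples$capacity_expanded)))
  invisible(x)
}
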