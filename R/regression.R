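# Linear sensitivity meta-model: CoG/g ~ titer + target output + material
# cost, with t-tests and an alpha-level significance screen.

#' Fit the linear CoG/g sensitivity model
#'
#' Ordinary least squares of CoG/g on the three jointly varied parameters,
#' via `stats::lm()`. Standard errors use the unbiased residual variance;
#' two-sided p-values come from the t distribution with `n - 4` degrees of
#' freedom.
#'
#' @param samples A `biocogs_mc` result or a data.frame with columns `cog`,
#'   `titer`, `target_output`, `material_cost`.
#' @return An object of class `biocogs_fit` with a coefficient table
#'   (`estimate`, `std_error`, `t_value`, `p_value` for intercept, titer,
#'   target_output, material_cost), `sigma2` (residual variance), `n`, and
#'   `df_residual`.
#' @export
fit_ols <- function(samples) {
  if (inherits(samples, "biocogs_mc")) samples <- samples$samples
  needed <- c("cog", "titer", "target_output", "material_cost")
  missing <- setdiff(needed, names(samples))
  if (length(missing))
    stop("samples lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(samples)
  if (n < 5) stop("Need at least 5 samples to fit 4 coefficients",
                  call. = FALSE)
  preds <- c("titer", "target_output", "material_cost")
  degenerate <- preds[vapply(samples[preds], function(v)
    isTRUE(all.equal(stats::var(v), 0)) || stats::var(v) == 0, logical(1))]
  if (length(degenerate))
    stop("Design matrix rank-deficient; constant column(s): ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  fit <- stats::lm(cog ~ titer + target_output + material_cost,
                   data = samples)
  if (fit$rank < 4L)
    stop("Design matrix rank-deficient (collinear predictors)",
         call. = FALSE)
  sm <- summary(fit)
  tab <- sm$coefficients
  coefficients <- data.frame(
    term = c("intercept", preds),
    estimate = unname(tab[, "Estimate"]),
    std_error = unname(tab[, "Std. Error"]),
    t_value = unname(tab[, "t value"]),
    p_value = unname(tab[, "Pr(>|t|)"]),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefficients,
                 sigma2 = sm$sigma^2, n = n,
                 df_residual = fit$df.residual,
                 lm = fit),
            class = "biocogs_fit")
}

#' Significance screen at a fixed alpha level
#'
#' @param fit A [fit_ols()] result.
#' @param alpha Significance level (default 0.01).
#' @return Named logical vector over the model terms: `TRUE` where
#'   `p < alpha`.
#' @export
significance_screen <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "biocogs_fit"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  stats::setNames(fit$coefficients$p_value < alpha, fit$coefficients$term)
}

#' Rank cost drivers and report the strategy shift
#'
#' Each parameter's influence is summarized as |coefficient| x the span of
#' its sampled range, i.e. the CoG/g swing it can cause across its
#' uncertainty. Comparing the ranking before and after titer optimization
#' shows whether the manufacturing strategy is process-oriented (titer
#' dominates) or product-oriented (target output dominates).
#'
#' @param before,after [fit_ols()] results for the two configurations.
#' @param spans_before,spans_after Named numeric vectors (`titer`,
#'   `target_output`, `material_cost`) giving each parameter's sampled span
#'   (max - min) in the respective configuration.
#' @param alpha Significance level for the screen (default 0.01).
#' @return A list of class `biocogs_shift`: `ranking_before` /
#'   `ranking_after` (data.frames sorted by decreasing influence with the
#'   significance flag), `top_before`, `top_after`, `rank_changed`
#'   (logical), and `significance_lost` (terms significant before but not
#'   after).
#' @export
strategy_shift_report <- function(before, after, spans_before,
                                  spans_after = spans_before,
                                  alpha = 0.01) {
  stopifnot(inherits(before, "biocogs_fit"), inherits(after, "biocogs_fit"))
  rank_one <- function(fit, spans) {
    tab <- fit$coefficients[fit$coefficients$term != "intercept", ]
    missing <- setdiff(tab$term, names(spans))
    if (length(missing))
      stop("No span for term(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    tab$span <- unname(spans[tab$term])
    tab$influence <- abs(tab$estimate) * tab$span
    tab$significant <- tab$p_value < alpha
    tab <- tab[order(-tab$influence), ]
    rownames(tab) <- NULL
    tab
  }
  rb <- rank_one(before, spans_before)
  ra <- rank_one(after, spans_after)
  lost <- intersect(rb$term[rb$significant], ra$term[!ra$significant])
  structure(list(ranking_before = rb, ranking_after = ra,
                 top_before = rb$term[1], top_after = ra$term[1],
                 rank_changed = !identical(rb$term, ra$term),
                 significance_lost = lost, alpha = alpha),
            class = "biocogs_shift")
}

#' @export
print.biocogs_fit <- function(x, ...) {
  cat(sprintf("Linear CoG/g sensitivity model (n = %d, df = %d)\n",
              x$n, x$df_residual))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 6)
  tab$std_error <- signif(tab$std_error, 4)
  tab$t_value <- round(tab$t_value, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.biocogs_shift <- function(x, ...) {
  cat(sprintf("Driver ranking (influence = |coefficient| x span):\n"))
  cat(sprintf("  before: %s\n",
              paste(x$ranking_before$term, collapse = " > ")))
  cat(sprintf("  after:  %s\n",
              paste(x$ranking_after$term, collapse = " > ")))
  if (length(x$significance_lost))
    cat(sprintf("Lost significance at alpha = %g: %s\n", x$alpha,
                paste(x$significance_lost, collapse = ", ")))
  cat(sprintf("Strategy: %s-driven before, %s-driven after\n",
              x$top_before, x$top_after))
  invisible(x)
}
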