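#' Chi-square goodness of fit of predicted vs observed category counts
#'
#' Expected counts are rescaled to the observed total (so expected may be
#' given as proportions or as counts on any scale); the statistic is
#' `sum((O - E)^2 / E)` on `df = k - 1` where `k` is the number of
#' categories compared. Typical use: the predicted living-state split of
#' survivors against a later observed wave (4 categories, df 3); a
#' five-category comparison including deaths is equally valid.
#'
#' @param observed Non-negative counts per category.
#' @param expected Positive expected counts or proportions, same categories.
#' @return A `fit_test_result`: `statistic`, `df`, `p_value`, and the
#'   observed and (rescaled) expected counts.
#' @export
chi_square_fit <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must cover the same categories", call. = FALSE)
  }
  if (any(observed < 0)) stop("observed counts must be >= 0", call. = FALSE)
  if (sum(observed) <= 0) stop("observed total must be > 0", call. = FALSE)
  if (any(expected <= 0)) {
    stop("expected counts must all be > 0; pool sparse categories before ",
         "testing", call. = FALSE)
  }
  e <- expected / sum(expected) * sum(observed)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = observed, expected = e),
            class = "fit_test_result")
}

#' @export
print.fit_test_result <- function(x, ...) {
  cat("Chi-square goodness of fit: X2 =", format(x$statistic, digits = 4),
      ", df =", x$df, ", p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

# internal: severity-directed perturbation of one matrix set.
# direction "down": deterioration entries (toward worse states / death) at
# their upper limits, others at lower limits -> pessimistic survival
# scenario; "up" is the reverse. Rows are renormalized proportionally.
perturb_matrices <- function(limits, direction) {
  states <- health_states()
  mats <- list()
  for (a in names(limits$point$matrices)) {
    lo <- limits$lower$matrices[[a]]
    hi <- limits$upper$matrices[[a]]
    m <- matrix(0, 5, 5, dimnames = list(states, states))
    for (i in seq_len(4)) {
      worse <- seq_len(5) > i
      row <- if (direction == "down") {
        ifelse(worse, hi[i, ], lo[i, ])
      } else {
        ifelse(worse, lo[i, ], hi[i, ])
      }
      if (sum(row) <= 0) {
        stop("cannot renormalize all-zero perturbed row (",
             a, ", ", states[i], ")", call. = FALSE)
      }
      m[i, ] <- row / sum(row)
    }
    m["DEATH", ] <- c(0, 0, 0, 0, 1)
    mats[[a]] <- m
  }
  transition_matrix_set(mats, step_years = limits$point$step_years)
}

#' Scenario bounds on a projection by confidence-limit perturbation
#'
#' Pushes every transition probability to a 95% (or other level) confidence
#' limit, simultaneously and directionally: for the lower population bound,
#' deterioration entries (any move to a worse state, death included) take
#' their upper limits and the remaining entries their lower limits; the
#' upper bound reverses the directions. Each perturbed row is renormalized
#' proportionally to restore row-stochasticity, and the perturbed sets are
#' projected like the point estimate. The result is a scenario bound, not a
#' calibrated confidence interval.
#'
#' @param baseline A `population_table`.
#' @param limits An `interval_matrix_set` from [probability_limits()].
#' @param n_steps Projection steps.
#' @param schedule Optional `staffing_schedule`; when supplied the interval
#'   is propagated to total staff demand (millions) instead of population.
#' @param age_threshold Passed to [project()].
#' @return A `prediction_interval` with `point`, `lower`, `upper`, the
#'   quantity name, `method = "bound-perturbation"` and the level.
#' @export
perturbation_interval <- function(baseline, limits, n_steps, schedule = NULL,
                                  age_threshold = 80) {
  stopifnot(inherits(limits, "interval_matrix_set"))
  sets <- list(point = limits$point,
               lower = perturb_matrices(limits, "down"),
               upper = perturb_matrices(limits, "up"))
  vals <- vapply(sets, function(m) {
    tot <- totals_by_state(project(baseline, m, n_steps,
                                   age_threshold = age_threshold))
    if (is.null(schedule)) attr(tot, "total") else
      sum(tot * schedule$ratios) / 1e6
  }, numeric(1))
  structure(list(point = vals[["point"]],
                 lower = min(vals[["lower"]], vals[["point"]]),
                 upper = max(vals[["upper"]], vals[["point"]]),
                 quantity = if (is.null(schedule)) "population_total" else
                   paste0("demand_total_millions_", schedule$name),
                 method = "bound-perturbation", level = limits$level),
            class = "prediction_interval")
}

#' Monte Carlo prediction interval by Dirichlet resampling
#'
#' Draws `B` transition-matrix sets with each living row sampled from
#' `Dirichlet(counts + 1)` (the conjugate posterior of a multinomial row
#' under a uniform prior), projects the baseline under each draw, and takes
#' percentile limits of the projected quantity. The point estimate is the
#' projection under the empirical (count-proportion) matrices.
#'
#' @param counts A `transition_counts`.
#' @param baseline A `population_table`.
#' @param n_steps Projection steps.
#' @param B Number of replicates, >= 100.
#' @param seed Seed for the Dirichlet draws.
#' @param level Interval level in (0, 1).
#' @param schedule Optional `staffing_schedule`, as in
#'   [perturbation_interval()].
#' @param age_threshold Passed to [project()].
#' @return A `prediction_interval` with `method = "monte-carlo"`.
#' @export
monte_carlo_interval <- function(counts, baseline, n_steps, B = 500, seed = 1,
                                 level = 0.95, schedule = NULL,
                                 age_threshold = 80) {
  stopifnot(inherits(counts, "transition_counts"), B >= 100,
            level > 0, level < 1)
  states <- health_states()
  quantity_of <- function(m) {
    tot <- totals_by_state(project(baseline, m, n_steps,
                                   age_threshold = age_threshold))
    if (is.null(schedule)) attr(tot, "total") else
      sum(tot * schedule$ratios) / 1e6
  }
  point <- quantity_of(empirical_matrix(counts, alpha = 0))
  draws <- with_seed(seed, vapply(seq_len(B), function(b) {
    mats <- list()
    for (a in dimnames(counts)[[1]]) {
      m <- matrix(0, 5, 5, dimnames = list(states, states))
      for (i in seq_len(4)) {
        g <- stats::rgamma(5, shape = counts[a, i, ] + 1)
        m[i, ] <- g / sum(g)
      }
      m["DEATH", ] <- c(0, 0, 0, 0, 1)
      mats[[a]] <- m
    }
    quantity_of(transition_matrix_set(mats))
  }, numeric(1)))
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(point = point, lower = qs[1], upper = qs[2],
                 quantity = if (is.null(schedule)) "population_total" else
                   paste0("demand_total_millions_", schedule$name),
                 method = "monte-carlo", level = level, B = B, seed = seed),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(x$quantity, " (", x$method, ", ", 100 * x$level, "%): ",
      format(x$point, digits = 6), " [", format(x$lower, digits = 6), ", ",
      format(x$upper, digits = 6), "]\n", sep = "")
  invisible(x)
}
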