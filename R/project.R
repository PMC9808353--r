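#' One Markov step for a population mass vector
#'
#' Multiplies a five-state mass vector by the transition matrix of the age
#' band containing `current_age` (ages of 85 or more use the open band).
#' Mass is conserved exactly: the result sums to the input sum.
#'
#' @param state_vector Non-negative numeric vector of persons in each of the
#'   five states (HEALTHY, MILD, MODERATE, SEVERE, DEATH).
#' @param matrices A `transition_matrix_set`.
#' @param current_age Age in years of the cohort at the start of the step.
#' @return Numeric vector of persons per state after one step.
#' @export
advance_step <- function(state_vector, matrices, current_age) {
  stopifnot(length(state_vector) == 5)
  if (any(state_vector < 0)) stop("state vector must be >= 0", call. = FALSE)
  m <- matrix_for_age(matrices, current_age)
  out <- as.vector(state_vector %*% m)
  names(out) <- health_states()
  out
}

#' Project a baseline population forward in Markov steps with cohort aging
#'
#' Every (age band, living state) baseline cell becomes a cohort carrying a
#' midpoint age (67, 72, 77, 82 and the open-band midpoint at baseline).
#' Each step multiplies the cohort's five-state mass vector by the matrix of
#' the band containing its *current* midpoint age, then advances the
#' midpoint by `step_years`. The chain is time-homogeneous: the same
#' matrices apply at every step (a stationarity assumption -- age-specific
#' morbidity and mortality are held at their estimation-period values).
#' Masses are real-valued throughout; rounding is left to reporting.
#'
#' @param baseline A `population_table`.
#' @param matrices A `transition_matrix_set`.
#' @param n_steps Number of steps, >= 1.
#' @param step_years Years per step (default the matrix set's step).
#' @param age_threshold Cohorts whose final midpoint age is below this are
#'   excluded from the target-year table (default 80: the oldest-old).
#' @return A `projection_result`: per-cohort trajectories, the target-year
#'   `population_table` of living states (indexed by attained age band),
#'   the total dead mass, and a long-format endpoint table
#'   (`origin_age_group, origin_state, target_state, persons`).
#' @export
project <- function(baseline, matrices, n_steps,
                    step_years = matrices$step_years, age_threshold = 80) {
  stopifnot(inherits(baseline, "population_table"))
  validate_matrix_set(matrices)
  if (!is.numeric(n_steps) || n_steps < 1 || n_steps != round(n_steps)) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  groups <- matrices$groups
  states <- health_states()
  trajectories <- list()
  for (r in seq_len(nrow(baseline))) {
    a <- baseline$age_group[r]
    s <- baseline$state[r]
    mass <- baseline$count[r]
    v <- stats::setNames(numeric(5), states)
    v[s] <- mass
    age <- groups$midpoint[groups$label == a]
    path <- matrix(NA_real_, n_steps + 1, 5, dimnames = list(NULL, states))
    ages <- numeric(n_steps + 1)
    path[1, ] <- v
    ages[1] <- age
    for (k in seq_len(n_steps)) {
      v <- advance_step(v, matrices, age)
      age <- age + step_years
      path[k + 1, ] <- v
      ages[k + 1] <- age
    }
    trajectories[[paste(a, s)]] <- list(origin_age_group = a,
                                        origin_state = s, origin_count = mass,
                                        states = path, ages = ages)
  }
  endpoints <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(origin_age_group = tr$origin_age_group,
               origin_state = tr$origin_state,
               target_state = states,
               persons = unname(tr$states[n_steps + 1, ]),
               final_age = tr$ages[n_steps + 1],
               stringsAsFactors = FALSE)
  }))
  rownames(endpoints) <- NULL
  kept <- endpoints[endpoints$final_age >= age_threshold &
                      endpoints$target_state != "DEATH", ]
  kept$attained_band <- age_band_for(kept$final_age, groups)
  agg <- stats::aggregate(persons ~ attained_band + target_state, data = kept,
                          FUN = sum)
  target <- population_table(
    data.frame(age_group = agg$attained_band, state = agg$target_state,
               count = agg$persons, stringsAsFactors = FALSE),
    year = baseline$year[1] + n_steps * step_years)
  structure(list(trajectories = trajectories, target_table = target,
                 endpoints = endpoints,
                 death_total = sum(endpoints$persons[endpoints$target_state ==
                                                       "DEATH"]),
                 baseline_total = sum(baseline$count),
                 n_steps = n_steps, step_years = step_years,
                 age_threshold = age_threshold,
                 target_year = baseline$year[1] + n_steps * step_years),
            class = "projection_result")
}

#' Per-state living totals of a projection
#'
#' Sums the target-year living-state masses over all retained cohorts.
#'
#' @param result A `projection_result`.
#' @return Named numeric vector over the four living states, with attribute
#'   `total` (their sum, the projected oldest-old population).
#' @export
totals_by_state <- function(result) {
  stopifnot(inherits(result, "projection_result"))
  state_totals(result$target_table)
}

#' @export
print.projection_result <- function(x, ...) {
  tot <- totals_by_state(x)
  cat("Projection to", x$target_year, "(", x$n_steps, "steps of",
      x$step_years, "years )\n")
  cat("Living population aged >=", x$age_threshold, "by state (millions):\n")
  print(round(tot / 1e6, 2))
  cat("Total:", round(attr(tot, "total") / 1e6, 2), "million;",
      "deaths:", round(x$death_total / 1e6, 2), "million\n")
  invisible(x)
}

#' Write a projection's endpoint table as long-format CSV
#'
#' Columns: `origin_age_group, origin_state, target_state, persons`.
#'
#' @param result A `projection_result`.
#' @param path File path.
#' @param header Optional provenance comment lines.
#' @export
write_projection_csv <- function(result, path, header = NULL) {
  stopifnot(inherits(result, "projection_result"))
  cols <- c("origin_age_group", "origin_state", "target_state", "persons")
  write_csv_with_header(result$endpoints[, cols], path, header)
  invisible(path)
}
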