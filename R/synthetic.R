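#' Synthetic data generation
#'
#' Generators that emulate the statistical structure the downstream analysis
#' assumes: a two-wave ageing-panel (baseline living state, follow-up state
#' drawn from an age- and state-specific multinomial row), and a census-style
#' baseline population split over age bands and living states. All
#' randomness is controlled by an explicit `seed`; the caller's RNG state is
#' left untouched.
#'
#' @name synthetic
NULL

# internal: run code under a fixed seed without disturbing the global RNG
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default synthetic cohort sizes
#'
#' Integer counts per (age band, baseline living state) reproducing the
#' descriptive marginals of the emulated survey: 13,269 individuals with age
#' distribution (1111, 1223, 1118, 1593, 8224) across the five bands and a
#' baseline state split of 78.42 / 11.01 / 5.15 / 5.42 percent, allocated
#' within each band by largest-remainder rounding.
#'
#' @return Matrix of counts, age bands in rows, living states in columns.
#' @export
default_cohort_sizes <- function() {
  age_n <- c("65-69" = 1111, "70-74" = 1223, "75-79" = 1118,
             "80-84" = 1593, "85+" = 8224)
  split <- c(HEALTHY = 0.7842, MILD = 0.1101, MODERATE = 0.0515,
             SEVERE = 0.0542)
  out <- t(vapply(age_n, function(n) largest_remainder(n * split / sum(split)),
                  numeric(4)))
  dimnames(out) <- list(names(age_n), living_states())
  out
}

#' Simulate a two-wave panel from a transition matrix set
#'
#' Each individual's follow-up state is an independent multinomial draw from
#' the matrix row matching their (age band, baseline state).
#'
#' @param matrices A `transition_matrix_set`.
#' @param cohort_sizes Non-negative integer matrix of individuals per
#'   (age band, living state), bands in rows; defaults to
#'   [default_cohort_sizes()].
#' @param seed Integer seed controlling the draws.
#' @return A `panel_dataset` with `sum(cohort_sizes)` records.
#' @export
simulate_panel <- function(matrices, cohort_sizes = default_cohort_sizes(),
                           seed) {
  validate_matrix_set(matrices)
  cohort_sizes <- as.matrix(cohort_sizes)
  if (any(cohort_sizes < 0)) stop("cohort sizes must be >= 0", call. = FALSE)
  if (is.null(rownames(cohort_sizes))) {
    rownames(cohort_sizes) <- age_groups()$label[seq_len(nrow(cohort_sizes))]
  }
  if (is.null(colnames(cohort_sizes))) {
    colnames(cohort_sizes) <- living_states()[seq_len(ncol(cohort_sizes))]
  }
  states <- health_states()
  with_seed(seed, {
    parts <- list()
    for (a in rownames(cohort_sizes)) {
      for (s in colnames(cohort_sizes)) {
        n <- cohort_sizes[a, s]
        if (n == 0) next
        p <- matrices$matrices[[a]][s, ]
        parts[[paste(a, s)]] <- data.frame(
          age_group = a, state_baseline = s,
          state_followup = states[sample.int(5, n, replace = TRUE, prob = p)],
          stringsAsFactors = FALSE)
      }
    }
    df <- if (length(parts) > 0) do.call(rbind, parts) else {
      data.frame(age_group = character(), state_baseline = character(),
                 state_followup = character(), stringsAsFactors = FALSE)
    }
    df <- cbind(id = seq_len(nrow(df)), df)
    rownames(df) <- NULL
    panel_dataset(df, wave_gap = matrices$step_years)
  })
}

#' Largest-remainder integer rounding
#'
#' Rounds a non-negative numeric vector to integers that sum exactly to
#' `round(sum(x))`, flooring first and distributing the remaining units to
#' the largest fractional parts (ties broken by position).
#'
#' @param x Non-negative numeric vector.
#' @return Integer-valued numeric vector, same length, same order.
#' @export
largest_remainder <- function(x) {
  stopifnot(all(x >= 0))
  target <- round(sum(x))
  fl <- floor(x)
  short <- target - sum(fl)
  if (short > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(short)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Simulate a census-style baseline population
#'
#' Splits per-state totals over age bands by fixed weights, with
#' largest-remainder rounding so each state total is conserved exactly. The
#' default state totals emulate the 2010 Chinese 65+ census distribution
#' (about 107.3 / 6.4 / 2.2 / 2.9 million healthy / mild / moderate /
#' severe); the default age weights follow the shape of the 65+ census age
#' pyramid, since the survey's own age-by-state baseline is not published.
#'
#' @param state_totals Named vector of persons per living state.
#' @param age_weights Proportions per age band, summing to 1 within 1e-9.
#' @param year Reference year of the table.
#' @return A `population_table`.
#' @export
simulate_census <- function(state_totals = c(HEALTHY = 107.3e6, MILD = 6.4e6,
                                             MODERATE = 2.2e6, SEVERE = 2.9e6),
                            age_weights = c(0.35, 0.28, 0.20, 0.11, 0.06),
                            year = 2010) {
  if (abs(sum(age_weights) - 1) > 1e-9) {
    stop("age weights must sum to 1 (got ", sum(age_weights), ")",
         call. = FALSE)
  }
  if (any(state_totals < 0)) stop("state totals must be >= 0", call. = FALSE)
  if (is.null(names(state_totals))) names(state_totals) <- living_states()
  check_states(names(state_totals), living_states(), "state")
  labels <- age_groups()$label
  stopifnot(length(age_weights) == length(labels))
  cells <- do.call(rbind, lapply(names(state_totals), function(s) {
    counts <- largest_remainder(state_totals[[s]] * age_weights)
    data.frame(age_group = labels, state = s, count = counts,
               stringsAsFactors = FALSE)
  }))
  population_table(cells, year = year)
}

#' Deterministic fixture panel with published descriptive marginals
#'
#' Builds a panel whose *marginal* distributions match the emulated survey's
#' descriptive tables exactly: 13,269 individuals; 5,655 male / 7,614 female;
#' ages (1111, 1223, 1118, 1593, 8224) over the five bands; baseline states
#' (10406, 1461, 683, 719); follow-up states (5767, 1086, 383, 612) among
#' the 7,848 survivors plus 5,421 deaths. Columns are assigned
#' independently, so joint distributions are arbitrary -- the object is meant
#' for descriptive-summary tests, not for transition estimation.
#'
#' @return A `panel_dataset` with an extra `sex` column.
#' @export
fixture_panel <- function() {
  n <- 13269
  ages <- rep(age_groups()$label, times = c(1111, 1223, 1118, 1593, 8224))
  base <- rep(living_states(), times = c(10406, 1461, 683, 719))
  fup <- rep(health_states(), times = c(5767, 1086, 383, 612, 5421))
  sex <- rep(c("male", "female"), times = c(5655, 7614))
  panel_dataset(data.frame(id = seq_len(n), age_group = ages,
                           state_baseline = base, state_followup = fup,
                           sex = sex, stringsAsFactors = FALSE),
                wave_gap = 3)
}
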