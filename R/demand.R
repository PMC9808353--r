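#' Staffing schedules for the human-population-ratio method
#'
#' A schedule assigns each living state a staff-per-elder ratio. Ratios must
#' be strictly positive, at most 1, and non-decreasing with disability
#' severity (a sicker elder never needs fewer staff per head).
#'
#' The default low and high schedules follow commonly legislated
#' nursing-home allocation standards: low = 1:10 healthy, 1:8 mild, 1:6
#' moderate, 1:4 severe; high = 1:5, 1:4, 1:2.5, 1:1.5. They are config
#' defaults, not constants: any JSON schedule file can replace them.
#'
#' @param ratios Named numeric vector of staff-per-elder ratios over the
#'   four living states.
#' @param name Schedule name.
#' @return A `staffing_schedule`.
#' @export
staffing_schedule <- function(ratios, name = "custom") {
  if (is.null(names(ratios))) names(ratios) <- living_states()
  missing <- setdiff(living_states(), names(ratios))
  if (length(missing) > 0) {
    stop("schedule lacks ratio(s) for state(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ratios <- ratios[living_states()]
  if (any(ratios <= 0) || any(ratios > 1)) {
    stop("staffing ratios must lie in (0, 1]", call. = FALSE)
  }
  if (any(diff(ratios) < 0)) {
    stop("staffing ratios must be non-decreasing with disability severity",
         call. = FALSE)
  }
  structure(list(name = name, ratios = ratios), class = "staffing_schedule")
}

#' @rdname staffing_schedule
#' @export
default_schedules <- function() {
  list(low = staffing_schedule(c(HEALTHY = 1 / 10, MILD = 1 / 8,
                                 MODERATE = 1 / 6, SEVERE = 1 / 4), "low"),
       high = staffing_schedule(c(HEALTHY = 1 / 5, MILD = 1 / 4,
                                  MODERATE = 1 / 2.5, SEVERE = 1 / 1.5),
                                "high"))
}

#' Read staffing schedules from a JSON config
#'
#' Expected shape:
#' `{"low": {"HEALTHY": 0.1, "MILD": 0.125, "MODERATE": 0.1667, "SEVERE": 0.25}, ...}`.
#'
#' @param path JSON file.
#' @return Named list of `staffing_schedule` objects.
#' @export
read_schedule_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    staffing_schedule(unlist(raw[[nm]]), name = nm)
  })
  stats::setNames(out, names(raw))
}

#' @rdname read_schedule_json
#' @param schedules Named list of `staffing_schedule` objects to write.
#' @export
write_schedule_json <- function(schedules, path) {
  payload <- lapply(schedules, function(s) as.list(s$ratios))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Nursing-staff demand by the human-population-ratio method
#'
#' Demand per state is `population_s x ratio_s` (the WHO workforce-planning
#' identity: future demand = staffing ratio x target-year population).
#' Demands are reported in millions at 2 decimal places; the total follows
#' the rounding policy of [total_demand()].
#'
#' @param populations Named vector of persons per living state (e.g. from
#'   [totals_by_state()]), or a `projection_result`.
#' @param schedule A `staffing_schedule`.
#' @param policy Rounding policy for the total; see [total_demand()].
#' @return A `demand_forecast`: per-state demand in persons and in rounded
#'   millions, the total, the schedule and policy used.
#' @export
demand_by_state <- function(populations, schedule,
                            policy = c("round-then-sum", "sum-then-round")) {
  policy <- match.arg(policy)
  stopifnot(inherits(schedule, "staffing_schedule"))
  if (inherits(populations, "projection_result")) {
    populations <- totals_by_state(populations)
  }
  if (is.null(names(populations))) names(populations) <- living_states()
  missing <- setdiff(living_states(), names(populations))
  if (length(missing) > 0) {
    stop("populations lack state(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  populations <- populations[living_states()]
  if (any(populations < 0)) stop("populations must be >= 0", call. = FALSE)
  persons <- populations * schedule$ratios
  out <- structure(list(schedule = schedule$name,
                        demand_persons = persons,
                        demand_millions = round(persons / 1e6, 2),
                        policy = policy),
                   class = "demand_forecast")
  out$total_millions <- total_demand(out, policy)
  out
}

#' Total demand under a rounding policy
#'
#' `round-then-sum` rounds each state's demand to 2 decimal places in
#' millions and then sums (the convention used in published workforce
#' tables); `sum-then-round` keeps full precision until the final rounding.
#' The two differ by at most 0.02 million over four states.
#'
#' @param forecast A `demand_forecast`.
#' @param policy `"round-then-sum"` or `"sum-then-round"`.
#' @return Total demand in millions (scalar).
#' @export
total_demand <- function(forecast,
                         policy = c("round-then-sum", "sum-then-round")) {
  policy <- match.arg(policy)
  stopifnot(inherits(forecast, "demand_forecast"))
  if (policy == "round-then-sum") {
    sum(round(forecast$demand_persons / 1e6, 2))
  } else {
    round(sum(forecast$demand_persons) / 1e6, 2)
  }
}

#' @export
print.demand_forecast <- function(x, ...) {
  cat("Nursing-staff demand (", x$schedule, " schedule, ", x$policy,
      "), millions:\n", sep = "")
  print(x$demand_millions)
  cat("Total:", format(x$total_millions, nsmall = 2), "million\n")
  invisible(x)
}
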