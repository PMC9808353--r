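#' Population table: counts by age group and living state
#'
#' A `population_table` is a data.frame with columns `age_group`, `state`
#' (a living state), `count` (persons, non-negative) and `year`, covering the
#' full age-band x living-state grid.
#'
#' @param counts data.frame with columns `age_group`, `state`, `count`
#'   (missing grid cells are filled with 0).
#' @param year Reference year.
#' @return A `population_table`.
#' @export
population_table <- function(counts, year) {
  stopifnot(is.data.frame(counts), is.numeric(year), length(year) == 1)
  needed <- c("age_group", "state", "count")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    stop("population counts lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_age_labels(counts$age_group)
  check_states(counts$state, living_states(), "state")
  if (any(counts$count < 0)) stop("population counts must be >= 0",
                                  call. = FALSE)
  grid <- expand.grid(age_group = age_groups()$label, state = living_states(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(counts$age_group, counts$state)
  if (anyDuplicated(key)) stop("duplicate (age_group, state) cells",
                               call. = FALSE)
  grid$count <- counts$count[match(paste(grid$age_group, grid$state), key)]
  grid$count[is.na(grid$count)] <- 0
  grid$year <- year
  structure(grid, class = c("population_table", "data.frame"))
}

#' Marginal totals of a population table
#'
#' @param x A `population_table`.
#' @return Named numeric vector of per-living-state totals (in persons), with
#'   attribute `total` equal to their sum.
#' @export
state_totals <- function(x) {
  stopifnot(inherits(x, "population_table"))
  out <- vapply(living_states(),
                function(s) sum(x$count[x$state == s]), numeric(1))
  attr(out, "total") <- sum(out)
  out
}

#' @export
print.population_table <- function(x, ...) {
  cat("Population table, year", x$year[1], "\n")
  tab <- stats::xtabs(count ~ age_group + state, data = x)
  print(tab[age_groups()$label, living_states()])
  cat("Total:", format(sum(x$count), big.mark = ","), "persons\n")
  invisible(x)
}

#' Read / write a census-style population CSV
#'
#' Schema: `age_group, state, count, year`; `#` lines are provenance
#' comments. Round-trips losslessly for valid tables.
#'
#' @param path File path.
#' @return A `population_table`.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("age_group", "state", "count", "year")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("census CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  report_bad_labels(df$age_group, age_groups()$label, path, "age_group")
  report_bad_labels(df$state, living_states(), path, "state")
  population_table(df[, c("age_group", "state", "count")], year = df$year[1])
}

#' @rdname read_population_csv
#' @param pop A `population_table` to write.
#' @param header Optional provenance comment lines.
#' @export
write_population_csv <- function(pop, path, header = NULL) {
  stopifnot(inherits(pop, "population_table"))
  write_csv_with_header(as.data.frame(pop), path, header)
  invisible(path)
}
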