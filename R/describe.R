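#' Descriptive summary of a two-wave panel
#'
#' Counts and percentages by sex (when a `sex` column is present), age band,
#' baseline health state, and follow-up health state. Percentage
#' denominators follow survey-reporting convention: baseline dimensions use
#' the full panel, but follow-up *living* state percentages use survivors
#' only (deaths are reported separately against the full panel). This
#' denominator choice is easy to get wrong and is therefore recorded on the
#' returned object.
#'
#' @param panel A `panel_dataset`.
#' @param digits Decimal places for the percentages.
#' @return A `panel_summary`: a named list of data.frames
#'   (`sex` if available, `age`, `baseline_state`, `followup_state`,
#'   `deaths`), each with `level`, `n` and `percent`.
#' @export
describe_panel <- function(panel, digits = 2) {
  stopifnot(inherits(panel, "panel_dataset"))
  n <- nrow(panel)
  tab <- function(x, levels, denom) {
    cnt <- as.integer(table(factor(x, levels = levels)))
    data.frame(level = levels, n = cnt,
               percent = round(100 * cnt / denom, digits),
               stringsAsFactors = FALSE)
  }
  out <- list()
  if ("sex" %in% names(panel)) {
    out$sex <- tab(panel$sex, sort(unique(panel$sex)), n)
  }
  out$age <- tab(panel$age_group, age_groups()$label, n)
  out$baseline_state <- tab(panel$state_baseline, living_states(), n)
  survivors <- panel$state_followup[panel$state_followup != "DEATH"]
  out$followup_state <- tab(survivors, living_states(),
                            max(length(survivors), 1))
  n_dead <- sum(panel$state_followup == "DEATH")
  out$deaths <- data.frame(level = "DEATH", n = n_dead,
                           percent = round(100 * n_dead / max(n, 1), digits),
                           stringsAsFactors = FALSE)
  structure(out, n = n, n_survivors = length(survivors),
            followup_denominator = "survivors", class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("Panel summary: n =", attr(x, "n"), "(",
      attr(x, "n_survivors"), "survivors at follow-up )\n")
  for (nm in names(x)) {
    cat("\n", nm, ":\n", sep = "")
    print(x[[nm]], row.names = FALSE)
  }
  cat("\nFollow-up living-state percentages are of survivors only.\n")
  invisible(x)
}
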