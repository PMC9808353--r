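#' Two-wave panel dataset
#'
#' A `panel_dataset` is a data.frame of individual records with columns
#' `id`, `age_group` (band at baseline), `state_baseline` (a living state)
#' and `state_followup` (any of the five states, DEATH included), plus a
#' `wave_gap` attribute giving the years between waves. Extra columns (e.g.
#' `sex`) are carried through untouched.
#'
#' @param records data.frame with at least the four required columns.
#' @param wave_gap Years between the two waves; must be positive.
#' @return A `panel_dataset` (also a data.frame).
#' @export
panel_dataset <- function(records, wave_gap = 3) {
  stopifnot(is.data.frame(records), wave_gap > 0)
  needed <- c("id", "age_group", "state_baseline", "state_followup")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("panel records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) > 0) {
    if (anyDuplicated(records$id)) {
      stop("panel ids are not unique", call. = FALSE)
    }
    check_age_labels(records$age_group)
    check_states(records$state_baseline, living_states(), "baseline state")
    check_states(records$state_followup, health_states(), "follow-up state")
  }
  structure(records, wave_gap = wave_gap,
            class = c("panel_dataset", "data.frame"))
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Panel dataset:", nrow(x), "individuals, wave gap",
      attr(x, "wave_gap"), "years\n")
  if (nrow(x) > 0) {
    print(utils::head(as.data.frame(x)))
    if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  }
  invisible(x)
}

#' Read / write a panel CSV
#'
#' Schema: `id, age_group, state_baseline, state_followup` (extra columns
#' preserved). Lines starting with `#` are treated as provenance comments.
#' Malformed state or age labels are reported with their line numbers.
#'
#' @param path File path.
#' @param wave_gap Years between waves recorded on the read object.
#' @return A `panel_dataset`.
#' @export
read_panel_csv <- function(path, wave_gap = 3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("id", "age_group", "state_baseline", "state_followup")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("panel CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  report_bad_labels(df$age_group, age_groups()$label, path, "age_group")
  report_bad_labels(df$state_baseline, living_states(), path, "state_baseline")
  report_bad_labels(df$state_followup, health_states(), path, "state_followup")
  panel_dataset(df, wave_gap = wave_gap)
}

#' @rdname read_panel_csv
#' @param panel A `panel_dataset` to write.
#' @param header Optional character vector of provenance comment lines
#'   (written prefixed with `#`).
#' @export
write_panel_csv <- function(panel, path, header = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  write_csv_with_header(as.data.frame(panel), path, header)
  invisible(path)
}

# internal: name offending values with data line numbers (1-based, excluding
# the header line)
report_bad_labels <- function(x, allowed, path, column) {
  bad <- !(as.character(x) %in% allowed)
  if (any(bad)) {
    lines <- which(bad)
    stop("parse error in ", path, ", column ", column, ": unknown label(s) ",
         paste(unique(x[bad]), collapse = ", "),
         " at data line(s) ", paste(utils::head(lines, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# internal: write a data.frame with optional '#' provenance header lines
write_csv_with_header <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
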