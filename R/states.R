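#' Health-state and age-group taxonomies
#'
#' The model grades elderly health into four living states on an activities-of
#' daily-living (ADL) scale -- healthy, mild, moderate and severe disability --
#' plus an absorbing death state. Age is banded into five groups with an open
#' top band; each band carries a representative midpoint age used for cohort
#' aging during projection.
#'
#' @name taxonomies
NULL

#' All five health states, in ordinal order (death last)
#'
#' @return Character vector `c("HEALTHY","MILD","MODERATE","SEVERE","DEATH")`.
#' @export
health_states <- function() c("HEALTHY", "MILD", "MODERATE", "SEVERE", "DEATH")

#' The four living (transient) health states
#'
#' @return Character vector of the four non-absorbing states.
#' @export
living_states <- function() c("HEALTHY", "MILD", "MODERATE", "SEVERE")

#' Age-group definitions
#'
#' Five bands: 65-69, 70-74, 75-79, 80-84 and the open band 85+. The open
#' band needs a single representative age for band lookup during projection;
#' it defaults to 87 because longitudinal ageing surveys oversample the
#' oldest-old and the band is bottom-heavy.
#'
#' @param open_midpoint Representative age (years) for the 85+ band.
#' @return A data.frame with columns `label`, `lower`, `upper` (Inf for the
#'   open band) and `midpoint`.
#' @export
age_groups <- function(open_midpoint = 87) {
  stopifnot(is.numeric(open_midpoint), length(open_midpoint) == 1,
            open_midpoint >= 85)
  data.frame(
    label = c("65-69", "70-74", "75-79", "80-84", "85+"),
    lower = c(65, 70, 75, 80, 85),
    upper = c(69, 74, 79, 84, Inf),
    midpoint = c(67, 72, 77, 82, open_midpoint),
    stringsAsFactors = FALSE
  )
}

#' Map an exact age to its age-band label
#'
#' Ages of 85 years or more all map to the open 85+ band.
#'
#' @param age Numeric vector of ages in years.
#' @param groups Age-group table, as from [age_groups()].
#' @return Character vector of band labels.
#' @export
age_band_for <- function(age, groups = age_groups()) {
  if (any(age < min(groups$lower))) {
    stop("age below the youngest band (", min(groups$lower), "): ",
         paste(age[age < min(groups$lower)], collapse = ", "), call. = FALSE)
  }
  idx <- findInterval(age, groups$lower)
  groups$label[idx]
}

# internal: validate a vector of state labels against an allowed set
check_states <- function(x, allowed, what = "state") {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

# internal: validate age-group labels
check_age_labels <- function(x, groups = age_groups()) {
  check_states(x, groups$label, what = "age_group")
}
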