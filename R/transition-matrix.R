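#' Age-stratified transition probability matrices
#'
#' A `transition_matrix_set` holds one 5x5 row-stochastic matrix per age
#' band. Rows index the state at the start of a step, columns the state one
#' step (default 3 years) later; the DEATH row is absorbing, i.e. equal to
#' (0, 0, 0, 0, 1).
#'
#' @param matrices Named list of 5x5 numeric matrices, one per age-band label
#'   in [age_groups()] order, with dimnames equal to [health_states()].
#' @param step_years Length of one transition step in years.
#' @param groups Age-group table the set is stratified over.
#' @return An object of class `transition_matrix_set`.
#' @export
transition_matrix_set <- function(matrices, step_years = 3,
                                  groups = age_groups()) {
  stopifnot(is.list(matrices), step_years > 0)
  missing <- setdiff(groups$label, names(matrices))
  if (length(missing) > 0) {
    stop("matrices missing for age band(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  matrices <- matrices[groups$label]
  states <- health_states()
  for (a in names(matrices)) {
    m <- as.matrix(matrices[[a]])
    if (!all(dim(m) == c(5, 5))) {
      stop("matrix for band ", a, " is not 5x5", call. = FALSE)
    }
    if (is.null(dimnames(m))) dimnames(m) <- list(states, states)
    matrices[[a]] <- m[states, states]
  }
  obj <- structure(list(matrices = matrices, step_years = step_years,
                        groups = groups),
                   class = "transition_matrix_set")
  validate_matrix_set(obj)
  obj
}

#' Validate a transition matrix set
#'
#' Checks entries lie in `[0, 1]`, rows sum to 1 within `tol`, and the DEATH
#' row is exactly absorbing.
#'
#' @param x A `transition_matrix_set`.
#' @param tol Row-sum tolerance.
#' @return `x` invisibly; errors name the offending (band, row).
#' @export
validate_matrix_set <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "transition_matrix_set"))
  for (a in names(x$matrices)) {
    m <- x$matrices[[a]]
    if (any(m < -tol) || any(m > 1 + tol)) {
      stop("band ", a, ": probabilities outside [0, 1]", call. = FALSE)
    }
    rs <- rowSums(m)
    bad <- which(abs(rs - 1) > tol)
    if (length(bad) > 0) {
      stop("band ", a, ", row ", rownames(m)[bad[1]],
           ": sum ", format(rs[bad[1]], digits = 12),
           " deviates from 1 by more than ", tol, call. = FALSE)
    }
    if (!isTRUE(all.equal(unname(m["DEATH", ]), c(0, 0, 0, 0, 1),
                          tolerance = tol))) {
      stop("band ", a, ": DEATH row is not absorbing", call. = FALSE)
    }
  }
  invisible(x)
}

#' Look up the matrix for the band containing an exact age
#'
#' @param x A `transition_matrix_set`.
#' @param age Age in years; ages >= 85 use the open 85+ band.
#' @return A 5x5 matrix.
#' @export
matrix_for_age <- function(x, age) {
  stopifnot(inherits(x, "transition_matrix_set"))
  x$matrices[[age_band_for(age, x$groups)]]
}

#' Published 2008-to-2011 transition matrices
#'
#' Loads the bundled fixture of age-stratified 3-year transition
#' probabilities among Chinese elderly (CLHLS 2008 to 2011 waves), with the
#' absorbing DEATH row appended. The printed probabilities carry 4 decimal
#' places, so raw row sums can deviate from 1 by up to about 2e-4; the
#' transcription is validated at print precision and each row is then
#' renormalized proportionally so the returned set is row-stochastic to
#' machine precision.
#'
#' @param path Fixture file; defaults to the copy shipped with the package.
#' @param transcription_tol Maximum allowed raw row-sum deviation before the
#'   fixture is declared corrupt (print-precision integrity check).
#' @return A `transition_matrix_set` with `step_years = 3`.
#' @export
paper_matrices <- function(path = system.file("extdata",
                                              "transition_matrices_2008_2011.csv",
                                              package = "carecast"),
                           transcription_tol = 5e-4) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  states <- health_states()
  check_age_labels(raw$age_group)
  check_states(raw$from_state, living_states(), "from_state")
  groups <- age_groups()
  mats <- list()
  for (a in groups$label) {
    m <- matrix(0, 5, 5, dimnames = list(states, states))
    for (s in living_states()) {
      row <- raw[raw$age_group == a & raw$from_state == s, states]
      if (nrow(row) != 1) {
        stop("fixture integrity: band ", a, ", row ", s,
             " appears ", nrow(row), " times", call. = FALSE)
      }
      p <- as.numeric(row)
      if (abs(sum(p) - 1) > transcription_tol) {
        stop("fixture integrity: band ", a, ", row ", s, " sums to ",
             format(sum(p), digits = 8), call. = FALSE)
      }
      m[s, ] <- p / sum(p)
    }
    m["DEATH", "DEATH"] <- 1
    mats[[a]] <- m
  }
  transition_matrix_set(mats, step_years = 3, groups = groups)
}

#' @export
print.transition_matrix_set <- function(x, digits = 4, ...) {
  cat("Transition matrix set:", length(x$matrices), "age bands,",
      x$step_years, "year step\n")
  for (a in names(x$matrices)) {
    cat("\n", a, ":\n", sep = "")
    print(round(x$matrices[[a]], digits))
  }
  invisible(x)
}

#' Write / read a matrix set as long-format CSV
#'
#' Columns: `age_group, from_state, to_state, p` and, when an interval set is
#' written, `lower, upper`.
#'
#' @param x A `transition_matrix_set` (or `interval_matrix_set` for writing).
#' @param path File path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns a `transition_matrix_set`.
#' @export
write_matrix_csv <- function(x, path) {
  if (inherits(x, "interval_matrix_set")) {
    long <- matrix_set_to_long(x$point)
    long$lower <- matrix_set_to_long(x$lower)$p
    long$upper <- matrix_set_to_long(x$upper)$p
  } else {
    long <- matrix_set_to_long(x)
  }
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @param step_years Step length recorded on the read object.
#' @export
read_matrix_csv <- function(path, step_years = 3) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("age_group", "from_state", "to_state", "p")
  if (!all(needed %in% names(long))) {
    stop("matrix CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  check_age_labels(long$age_group)
  check_states(long$from_state, health_states(), "from_state")
  check_states(long$to_state, health_states(), "to_state")
  states <- health_states()
  mats <- lapply(age_groups()$label, function(a) {
    m <- matrix(0, 5, 5, dimnames = list(states, states))
    sub <- long[long$age_group == a, ]
    m[cbind(sub$from_state, sub$to_state)] <- sub$p
    m
  })
  names(mats) <- age_groups()$label
  transition_matrix_set(mats, step_years = step_years)
}

# internal: flatten a set to long format
matrix_set_to_long <- function(x) {
  states <- health_states()
  do.call(rbind, lapply(names(x$matrices), function(a) {
    m <- x$matrices[[a]]
    data.frame(age_group = a,
               from_state = rep(states, each = 5),
               to_state = rep(states, times = 5),
               p = as.vector(t(m)),
               stringsAsFactors = FALSE)
  }))
}
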