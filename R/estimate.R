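#' Transition counts from a two-wave panel
#'
#' Cross-tabulates individuals by (age band, baseline living state,
#' follow-up state).
#'
#' @param panel A `panel_dataset`.
#' @return A `transition_counts` object: a 5 x 4 x 5 integer array
#'   (age band x from-state x to-state) with a `row_totals` attribute.
#' @export
count_transitions <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  labels <- age_groups()$label
  counts <- array(0L, dim = c(5, 4, 5),
                  dimnames = list(labels, living_states(), health_states()))
  if (nrow(panel) > 0) {
    tab <- table(factor(panel$age_group, levels = labels),
                 factor(panel$state_baseline, levels = living_states()),
                 factor(panel$state_followup, levels = health_states()))
    counts[] <- as.integer(tab)
  }
  structure(counts, row_totals = apply(counts, c(1, 2), sum),
            wave_gap = attr(panel, "wave_gap"),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition counts:", sum(x), "individuals\n")
  print(attr(x, "row_totals"))
  invisible(x)
}

#' Empirical (count-based) transition matrix
#'
#' Per-cell maximum-likelihood proportions with optional add-alpha
#' smoothing: `P(a,i,j) = (n(a,i,j) + alpha) / (n(a,i) + 5 alpha)`. The
#' DEATH row is set absorbing. Cells from rows with fewer than
#' `flag_threshold` individuals whose estimate is exactly 0 or 1 are
#' recorded in a `flags` attribute (small-sample extreme values).
#'
#' @param counts A `transition_counts`.
#' @param alpha Smoothing constant, >= 0. With `alpha = 0` every observed
#'   (age, state) row must be non-empty.
#' @param flag_threshold Row total below which extreme cells are flagged.
#' @return A `transition_matrix_set` with attribute `flags` (data.frame).
#' @export
empirical_matrix <- function(counts, alpha = 0, flag_threshold = 20) {
  stopifnot(inherits(counts, "transition_counts"), alpha >= 0)
  states <- health_states()
  totals <- attr(counts, "row_totals")
  flags <- list()
  mats <- list()
  for (a in dimnames(counts)[[1]]) {
    m <- matrix(0, 5, 5, dimnames = list(states, states))
    for (s in living_states()) {
      n_row <- totals[a, s]
      if (n_row == 0 && alpha == 0) {
        stop("no observations for cell (", a, ", ", s,
             "); use alpha > 0 or supply data", call. = FALSE)
      }
      p <- (counts[a, s, ] + alpha) / (n_row + 5 * alpha)
      m[s, ] <- p
      # flags reflect the raw proportions, whatever the smoothing
      if (n_row > 0 && n_row < flag_threshold &&
          any(counts[a, s, ] %in% c(0, n_row))) {
        flags[[paste(a, s)]] <- data.frame(
          age_group = a, from_state = s, row_total = n_row,
          stringsAsFactors = FALSE)
      }
    }
    m["DEATH", ] <- c(0, 0, 0, 0, 1)
    mats[[a]] <- m
  }
  out <- transition_matrix_set(mats, step_years = attr_or(counts, "wave_gap", 3))
  attr(out, "flags") <- if (length(flags) > 0) do.call(rbind, flags) else
    data.frame(age_group = character(), from_state = character(),
               row_total = numeric(), stringsAsFactors = FALSE)
  out
}

attr_or <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else v
}

# ---- multinomial logit -----------------------------------------------------

# internal: design matrix over the 20 (age band, living state) cells
logit_design_matrix <- function(design) {
  grid <- expand.grid(age_group = age_groups()$label, state = living_states(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (design == "saturated") {
    X <- diag(nrow(grid))
    colnames(X) <- paste(grid$age_group, grid$state, sep = ":")
  } else if (design == "additive") {
    X <- stats::model.matrix(~ factor(age_group, levels = age_groups()$label) +
                               factor(state, levels = living_states()),
                             data = grid)
    colnames(X) <- c("(Intercept)", paste0("age", age_groups()$label[-1]),
                     paste0("state", living_states()[-1]))
  } else {
    stop("unknown design: ", design, call. = FALSE)
  }
  list(X = X, grid = grid)
}

# internal: cell probabilities from a K x 4 coefficient matrix
# (reference outcome HEALTHY has implicit zero coefficients)
logit_cell_probs <- function(X, beta) {
  eta <- X %*% beta                       # cells x 4 non-reference outcomes
  # guard the softmax against overflow at the |beta| <= 30 box
  em <- exp(pmin(eta, 700))
  denom <- 1 + rowSums(em)
  p <- cbind(1, em) / denom               # HEALTHY first, then MILD..DEATH
  colnames(p) <- health_states()
  p
}

#' Fit a multinomial logit model of the follow-up state
#'
#' Maximizes the multinomial log-likelihood
#' `P(y = j | x) = exp(x b_j) / (1 + sum_k exp(x b_k))` with HEALTHY as the
#' reference outcome, over covariates built from the baseline age band and
#' living state. Fitting is box-constrained (|coefficient| <= 30) maximum
#' likelihood via L-BFGS-B with an analytic gradient on the grouped counts;
#' the box tames complete separation in sparse cells, which is reported as
#' a warning rather than an error.
#'
#' Two designs are supported: `"saturated"` (one parameter per
#' age-by-state cell and outcome, whose fitted probabilities equal the
#' empirical cell proportions) and `"additive"` (age and state main
#' effects, a smoothed matrix).
#'
#' @param panel A `panel_dataset` (or a `transition_counts` object).
#' @param design `"saturated"` (default) or `"additive"`.
#' @param maxit Iteration cap for the optimizer.
#' @return A `logit_coefficients` object: coefficient matrix (design columns
#'   x 4 non-reference outcomes), design description, final log-likelihood
#'   and convergence flag.
#' @export
fit_multinomial_logit <- function(panel, design = c("saturated", "additive"),
                                  maxit = 2000) {
  design <- match.arg(design)
  counts <- if (inherits(panel, "transition_counts")) panel else
    count_transitions(panel)
  if (sum(counts) == 0) stop("cannot fit on an empty panel", call. = FALSE)
  if (sum(apply(counts, 3, sum) > 0) < 2) {
    stop("follow-up outcome has fewer than 2 observed levels", call. = FALSE)
  }
  d <- logit_design_matrix(design)
  X <- d$X
  # grouped outcome counts aligned with the design grid
  N <- t(vapply(seq_len(nrow(d$grid)), function(r) {
    counts[d$grid$age_group[r], d$grid$state[r], ]
  }, numeric(5)))
  colnames(N) <- health_states()
  ntot <- rowSums(N)
  K <- ncol(X)
  cap <- 30

  nll <- function(par) {
    p <- logit_cell_probs(X, matrix(par, K, 4))
    -sum(N[N > 0] * log(p[N > 0]))
  }
  grad <- function(par) {
    p <- logit_cell_probs(X, matrix(par, K, 4))
    -as.vector(crossprod(X, N[, -1, drop = FALSE] -
                              ntot * p[, -1, drop = FALSE]))
  }

  start <- matrix(0, K, 4)
  if (design == "saturated") {
    # warm start at the (log-ratio) closed form; zero counts pushed to the box
    lr <- log(pmax(N[, -1, drop = FALSE], 1e-13)) - log(pmax(N[, 1], 1e-13))
    lr <- lr - pmax(apply(lr, 1, max) - cap, 0)  # shift rows into the box,
    start <- pmax(lr, -cap)                      # preserving log-ratios
    start[ntot == 0, ] <- 0
  }

  fit <- stats::optim(as.vector(start), nll, grad, method = "L-BFGS-B",
                      lower = -cap, upper = cap,
                      control = list(maxit = maxit, factr = 10, pgtol = 1e-10))
  beta <- matrix(fit$par, K, 4,
                 dimnames = list(colnames(X), health_states()[-1]))
  if (fit$convergence != 0 && fit$convergence != 52) {
    stop("multinomial logit did not converge (code ", fit$convergence, "): ",
         fit$message, call. = FALSE)
  }
  if (any(abs(beta) >= cap - 1e-6)) {
    warning("separation detected: ", sum(abs(beta) >= cap - 1e-6),
            " coefficient(s) capped at |beta| = ", cap, call. = FALSE)
  }
  structure(list(coefficients = beta, design = design,
                 loglik = -nll(fit$par), converged = TRUE,
                 n = sum(N), cap = cap),
            class = "logit_coefficients")
}

#' @export
print.logit_coefficients <- function(x, ...) {
  cat("Multinomial logit fit (", x$design, " design), n = ", x$n,
      ", logLik = ", format(x$loglik, digits = 8), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Transition matrix predicted by a fitted multinomial logit
#'
#' Evaluates the fitted outcome probabilities at every (age band, baseline
#' living state) cell; rows sum to 1 by construction and the DEATH row is
#' absorbing.
#'
#' @param coefficients A `logit_coefficients` object from
#'   [fit_multinomial_logit()].
#' @param step_years Step length recorded on the returned set.
#' @return A `transition_matrix_set`.
#' @export
predict_matrix <- function(coefficients, step_years = 3) {
  if (!inherits(coefficients, "logit_coefficients")) {
    stop("coefficients must come from fit_multinomial_logit()", call. = FALSE)
  }
  d <- logit_design_matrix(coefficients$design)
  if (!identical(dim(d$X)[2], nrow(coefficients$coefficients))) {
    stop("design mismatch: stored coefficients do not match the ",
         coefficients$design, " design", call. = FALSE)
  }
  p <- logit_cell_probs(d$X, coefficients$coefficients)
  states <- health_states()
  mats <- lapply(age_groups()$label, function(a) {
    m <- matrix(0, 5, 5, dimnames = list(states, states))
    for (s in living_states()) {
      m[s, ] <- p[d$grid$age_group == a & d$grid$state == s, ]
    }
    m["DEATH", ] <- c(0, 0, 0, 0, 1)
    m
  })
  names(mats) <- age_groups()$label
  transition_matrix_set(mats, step_years = step_years)
}

# ---- confidence limits -----------------------------------------------------

#' Pointwise confidence limits for every transition probability
#'
#' Wald limits use the per-cell binomial normal approximation
#' `p +/- z sqrt(p (1 - p) / n)`, clipped to `[0, 1]`; observed 0 or 1
#' proportions give degenerate (zero-width) Wald limits. Bootstrap limits
#' are percentile limits over `B` multinomial resamples of each row.
#' Rows with no observations get limits (0, 1) and a uniform point, with a
#' warning.
#'
#' @param counts A `transition_counts`.
#' @param level Confidence level in (0, 1).
#' @param method `"wald"` or `"bootstrap"`.
#' @param B Bootstrap replicates (>= 100) when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap resamples.
#' @return An `interval_matrix_set`: `point` (a `transition_matrix_set`),
#'   `lower` and `upper` matrix lists, `level` and `method`.
#' @export
probability_limits <- function(counts, level = 0.95,
                               method = c("wald", "bootstrap"),
                               B = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "transition_counts"), level > 0, level < 1)
  if (method == "bootstrap" && B < 100) {
    stop("bootstrap requires B >= 100", call. = FALSE)
  }
  totals <- attr(counts, "row_totals")
  states <- health_states()
  z <- stats::qnorm(1 - (1 - level) / 2)
  point <- lower <- upper <- list()
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  boot_rows <- if (method == "bootstrap") {
    with_seed(seed, {
      out <- list()
      for (a in dimnames(counts)[[1]]) for (s in living_states()) {
        n <- totals[a, s]
        if (n == 0) next
        p <- counts[a, s, ] / n
        res <- stats::rmultinom(B, n, p) / n     # 5 x B
        out[[paste(a, s)]] <- apply(res, 1, stats::quantile, probs = qs)
      }
      out
    })
  }
  for (a in dimnames(counts)[[1]]) {
    mp <- ml <- mu <- matrix(0, 5, 5, dimnames = list(states, states))
    for (s in living_states()) {
      n <- totals[a, s]
      if (n == 0) {
        warning("cell (", a, ", ", s, ") has no observations; limits (0, 1)",
                call. = FALSE)
        mp[s, ] <- 0.2
        ml[s, ] <- 0
        mu[s, ] <- 1
        next
      }
      p <- counts[a, s, ] / n
      mp[s, ] <- p
      if (method == "wald") {
        se <- sqrt(p * (1 - p) / n)
        ml[s, ] <- pmax(p - z * se, 0)
        mu[s, ] <- pmin(p + z * se, 1)
      } else {
        q <- boot_rows[[paste(a, s)]]
        ml[s, ] <- pmin(q[1, ], p)
        mu[s, ] <- pmax(q[2, ], p)
      }
    }
    mp["DEATH", ] <- ml["DEATH", ] <- mu["DEATH", ] <- c(0, 0, 0, 0, 1)
    point[[a]] <- mp
    lower[[a]] <- ml
    upper[[a]] <- mu
  }
  structure(list(point = transition_matrix_set(point,
                                               step_years = attr_or(counts, "wave_gap", 3)),
                 lower = list(matrices = lower),
                 upper = list(matrices = upper),
                 level = level, method = method),
            class = "interval_matrix_set")
}

#' @export
print.interval_matrix_set <- function(x, ...) {
  cat("Interval matrix set (", x$method, ", ", 100 * x$level, "% level)\n",
      sep = "")
  print(x$point)
  invisible(x)
}
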