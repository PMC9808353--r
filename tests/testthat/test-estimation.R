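test_that("count_transitions matches a brute-force recount", {
  # hand cross-tabulation oracle: nested loops over the raw records
  pm <- paper_matrices()
  panel <- simulate_panel(pm, cohorts(250), seed = 11)
  counts <- count_transitions(panel)
  expect_equal(sum(counts), nrow(panel))
  oracle <- array(0L, dim = c(5, 4, 5), dimnames = dimnames(counts))
  for (r in seq_len(nrow(panel))) {
    a <- panel$age_group[r]; i <- panel$state_baseline[r]
    j <- panel$state_followup[r]
    oracle[a, i, j] <- oracle[a, i, j] + 1L
  }
  expect_equal(unclass(counts), oracle, ignore_attr = TRUE)
  rt <- attr(counts, "row_totals")
  expect_equal(rt, apply(oracle, c(1, 2), sum), ignore_attr = TRUE)
})

test_that("count_transitions trivial cases", {
  empty <- panel_dataset(data.frame(id = integer(), age_group = character(),
                                    state_baseline = character(),
                                    state_followup = character()))
  expect_equal(sum(count_transitions(empty)), 0)
  one <- panel_dataset(data.frame(id = 1, age_group = "65-69",
                                  state_baseline = "HEALTHY",
                                  state_followup = "DEATH"))
  cnt <- count_transitions(one)
  expect_equal(cnt["65-69", "HEALTHY", "DEATH"], 1)
  expect_equal(sum(cnt), 1)
})

test_that("empirical_matrix computes add-alpha proportions", {
  # the published mild 65-69 row is the proportion of counts (4,5,0,0,1)
  df <- data.frame(id = 1:10, age_group = "65-69", state_baseline = "MILD",
                   state_followup = rep(health_states(), c(4, 5, 0, 0, 1)))
  cnt <- count_transitions(panel_dataset(df))
  est <- empirical_matrix(cnt, alpha = 1)  # alpha>0: other rows are empty
  expect_equal(unname(est$matrices[["65-69"]]["MILD", ]),
               (c(4, 5, 0, 0, 1) + 1) / 15)
  # symmetry: equal counts with alpha give uniform rows
  expect_equal(unname(est$matrices[["70-74"]]["HEALTHY", ]), rep(0.2, 5))
  expect_error(empirical_matrix(cnt, alpha = 0), "65-69.*HEALTHY")
})

test_that("alpha = 0 on a fully observed cell reproduces raw proportions", {
  pm <- paper_matrices()
  panel <- simulate_panel(pm, cohorts(400), seed = 3)
  cnt <- count_transitions(panel)
  est <- empirical_matrix(cnt, alpha = 0)
  expect_equal(unname(est$matrices[["85+"]]["SEVERE", ]),
               unname(cnt["85+", "SEVERE", ] / sum(cnt["85+", "SEVERE", ])))
  # smoothing never leaves exact 0/1 probabilities
  sm <- empirical_matrix(cnt, alpha = 0.5)
  living <- unlist(lapply(sm$matrices, function(m) m[living_states(), ]))
  expect_true(all(living > 0 & living < 1))
})

test_that("small-sample extreme cells are flagged", {
  df <- data.frame(id = 1:104,
                   age_group = rep(c("65-69", "70-74"), c(4, 100)),
                   state_baseline = rep(c("SEVERE", "HEALTHY"), c(4, 100)),
                   state_followup = c(rep("DEATH", 4),
                                      rep(c("HEALTHY", "DEATH"), 50)))
  est <- empirical_matrix(count_transitions(panel_dataset(df)), alpha = 1e-9)
  flags <- attr(est, "flags")
  expect_true(any(flags$age_group == "65-69" & flags$from_state == "SEVERE"))
  expect_false(any(flags$from_state == "HEALTHY" & flags$age_group == "70-74"))
})

test_that("saturated logit fit reproduces the empirical matrix (oracle)", {
  pm <- paper_matrices()
  for (s in c(21, 22)) {
    panel <- simulate_panel(pm, cohorts(300), seed = s)
    cnt <- count_transitions(panel)
    emp <- empirical_matrix(cnt, alpha = 0)
    fit <- suppressWarnings(fit_multinomial_logit(panel, "saturated"))
    pred <- predict_matrix(fit)
    dev <- mapply(function(a, b) max(abs(a - b)), pred$matrices, emp$matrices)
    expect_lt(max(dev), 1e-6)
    expect_true(fit$converged)
    expect_lt(fit$loglik, 0)
  }
})

test_that("null panels give near-zero additive coefficients", {
  # follow-up independent of covariates: same row everywhere
  panel <- simulate_panel(flat_tms(), cohorts(500), seed = 5)
  fit <- fit_multinomial_logit(panel, "additive")
  beta <- fit$coefficients
  expect_lt(max(abs(beta[-1, ])), 0.5)   # non-intercept effects ~ 0
  # intercepts recover the generating log odds
  expect_equal(unname(beta[1, ]), log(c(0.2, 0.1, 0.05, 0.05) / 0.6),
               tolerance = 0.15)
})

test_that("additive fit recovers the generating matrix approximately", {
  pm <- paper_matrices()
  panel <- simulate_panel(pm, cohorts(1000), seed = 9)
  fit <- fit_multinomial_logit(panel, "additive")
  pred <- predict_matrix(fit)
  dev <- mapply(function(a, b) max(abs(a[living_states(), ] -
                                         b[living_states(), ])),
                pred$matrices, pm$matrices)
  # additive is a smoother, not an exact reproduction; generous band
  expect_lt(max(dev), 0.3)
})

test_that("predict_matrix closed forms and design mismatch", {
  fit <- suppressWarnings(
    fit_multinomial_logit(simulate_panel(flat_tms(), cohorts(50), seed = 2),
                          "saturated"))
  # all-zero coefficients -> uniform rows at 1/5
  fit0 <- fit
  fit0$coefficients[] <- 0
  pred <- predict_matrix(fit0)
  expect_equal(unname(pred$matrices[["75-79"]]["MODERATE", ]), rep(0.2, 5))
  # a huge capped intercept concentrates the row mass on that outcome
  fitc <- fit0
  fitc$coefficients[, "DEATH"] <- 30
  expect_gt(predict_matrix(fitc)$matrices[["65-69"]]["HEALTHY", "DEATH"],
            1 - 1e-6)
  fit$coefficients <- fit$coefficients[1:3, , drop = FALSE]
  expect_error(predict_matrix(fit), "design mismatch")
  expect_error(predict_matrix(list()), "fit_multinomial_logit")
})

test_that("fit preconditions are enforced", {
  one_level <- panel_dataset(data.frame(id = 1:8, age_group = "65-69",
                                        state_baseline = "HEALTHY",
                                        state_followup = "HEALTHY"))
  expect_error(fit_multinomial_logit(one_level), "2 observed levels")
})

test_that("wald limits match the closed form and bracket the point", {
  # one row with exactly p = 0.5, n = 100
  df <- data.frame(id = 1:100, age_group = "80-84", state_baseline = "MILD",
                   state_followup = rep(c("HEALTHY", "DEATH"), each = 50))
  cnt <- count_transitions(panel_dataset(df))
  lim <- suppressWarnings(probability_limits(cnt, level = 0.95,
                                             method = "wald"))
  expect_equal(lim$lower$matrices[["80-84"]]["MILD", "HEALTHY"],
               0.5 - 0.09799820, tolerance = 1e-6)
  expect_equal(lim$upper$matrices[["80-84"]]["MILD", "HEALTHY"],
               0.5 + 0.09799820, tolerance = 1e-6)
  # degenerate cells: observed 0 -> zero-width limits
  expect_equal(lim$lower$matrices[["80-84"]]["MILD", "MODERATE"], 0)
  expect_equal(lim$upper$matrices[["80-84"]]["MILD", "MODERATE"], 0)
  # empty rows get (0, 1) with a warning (one per empty cell)
  w <- capture_warnings(probability_limits(cnt, method = "wald"))
  expect_match(w, "no observations", all = TRUE)
  expect_equal(lim$lower$matrices[["65-69"]]["HEALTHY", "DEATH"], 0)
  expect_equal(lim$upper$matrices[["65-69"]]["HEALTHY", "DEATH"], 1)
})

test_that("limits always satisfy lower <= point <= upper", {
  pm <- paper_matrices()
  panel <- simulate_panel(pm, cohorts(150), seed = 31)
  cnt <- count_transitions(panel)
  for (method in c("wald", "bootstrap")) {
    lim <- probability_limits(cnt, method = method, B = 200, seed = 4)
    for (a in names(lim$point$matrices)) {
      expect_true(all(lim$lower$matrices[[a]] <= lim$point$matrices[[a]] + 1e-12))
      expect_true(all(lim$point$matrices[[a]] <= lim$upper$matrices[[a]] + 1e-12))
      expect_true(all(lim$lower$matrices[[a]] >= 0))
      expect_true(all(lim$upper$matrices[[a]] <= 1))
    }
  }
  expect_error(probability_limits(cnt, method = "bootstrap", B = 50),
               "B >= 100")
})

test_that("bootstrap limits cover the generating probability", {
  # reduced-scale coverage check on one binomial-ish cell
  p_true <- 0.3
  sizes <- matrix(0, 5, 4, dimnames = dimnames(cohorts(0)))
  sizes["70-74", "HEALTHY"] <- 200
  gen <- flat_tms(c(p_true, 0.7, 0, 0, 0))
  hits <- vapply(1:60, function(s) {
    panel <- simulate_panel(gen, sizes, seed = 500 + s)
    # all cells but one are empty by construction; silence their warnings
    lim <- suppressWarnings(
      probability_limits(count_transitions(panel), method = "bootstrap",
                         B = 200, seed = s))
    lim$lower$matrices[["70-74"]]["HEALTHY", "HEALTHY"] <= p_true &&
      lim$upper$matrices[["70-74"]]["HEALTHY", "HEALTHY"] >= p_true
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("estimation pipeline preserves the fixture's death-age ordering", {
  pm <- paper_matrices()
  panel <- simulate_panel(pm, cohorts(20000), seed = 77)
  est <- empirical_matrix(count_transitions(panel))
  deaths <- vapply(est$matrices, function(m) m["HEALTHY", "DEATH"],
                   numeric(1))
  expect_true(all(diff(deaths) > 0))
})
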