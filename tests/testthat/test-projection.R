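pm <- paper_matrices()

test_that("advance_step applies the band matrix and conserves mass", {
  v <- advance_step(c(100, 0, 0, 0, 0), pm, 67)
  expect_equal(unname(v), unname(100 * pm$matrices[["65-69"]]["HEALTHY", ]),
               tolerance = 0)
  expect_equal(sum(v), 100)
  # identity dynamics leave any vector unchanged
  x <- c(3, 1, 4, 1, 5)
  expect_equal(unname(advance_step(x, identity_tms(), 80)), x)
  # death is absorbing
  expect_equal(unname(advance_step(c(0, 0, 0, 0, 100), pm, 90)),
               c(0, 0, 0, 0, 100))
  expect_error(advance_step(c(1, 1, 1, 1, 1), pm, 60), "youngest band")
  expect_error(advance_step(c(-1, 0, 0, 0, 2), pm, 70), ">= 0")
})

test_that("projection equals the brute-force matrix-chain oracle", {
  # independent oracle: explicit age-indexed product of band matrices
  baseline <- population_table(data.frame(age_group = "65-69",
                                          state = "HEALTHY",
                                          count = 1e6), year = 2010)
  res <- project(baseline, pm, n_steps = 5)
  bands <- c("65-69", "70-74", "70-74", "75-79", "75-79")  # ages 67,70,73,76,79
  chain <- diag(5)
  for (b in bands) chain <- chain %*% pm$matrices[[b]]
  oracle <- as.vector(c(1e6, 0, 0, 0, 0) %*% chain)
  got <- res$trajectories[["65-69 HEALTHY"]]$states[6, ]
  expect_equal(unname(got), oracle, tolerance = 1e-9)
  expect_equal(res$target_year, 2025)
  # final midpoint age 82 -> attained band 80-84, all included at threshold 80
  expect_equal(attr(totals_by_state(res), "total"), sum(oracle[1:4]),
               tolerance = 1e-9)
})

test_that("single step equals one advance_step call", {
  baseline <- population_table(data.frame(age_group = "75-79", state = "MILD",
                                          count = 500), year = 2010)
  res <- project(baseline, pm, n_steps = 1, age_threshold = 0)
  v <- advance_step(c(0, 500, 0, 0, 0), pm, 77)
  expect_equal(unname(res$trajectories[["75-79 MILD"]]$states[2, ]),
               unname(v))
  expect_error(project(baseline, pm, n_steps = 0), "positive integer")
})

test_that("absorbing-only dynamics empty the living population", {
  res <- project(simulate_census(), absorbing_tms(), n_steps = 2)
  expect_equal(attr(totals_by_state(res), "total"), 0)
  expect_equal(res$death_total, res$baseline_total)
})

test_that("mass conservation and death monotonicity hold at every step", {
  cen <- simulate_census()
  res <- project(cen, pm, n_steps = 5)
  for (tr in res$trajectories) {
    sums <- rowSums(tr$states)
    expect_equal(sums, rep(tr$origin_count, length(sums)),
                 tolerance = 1e-6)
    expect_true(all(diff(tr$states[, "DEATH"]) >= -1e-9))
  }
  # grand total: living at target + dead = baseline
  tot <- totals_by_state(res)
  expect_equal(attr(tot, "total") + res$death_total, sum(cen$count),
               tolerance = 1e-6 * sum(cen$count))
})

test_that("two steps inside one band equal one step with M squared", {
  baseline <- population_table(data.frame(age_group = "85+", state = "SEVERE",
                                          count = 1000), year = 2010)
  res <- project(baseline, pm, n_steps = 2)
  m2 <- pm$matrices[["85+"]] %*% pm$matrices[["85+"]]
  expect_equal(unname(res$trajectories[["85+ SEVERE"]]$states[3, ]),
               as.vector(c(0, 0, 0, 1000, 0) %*% m2), tolerance = 1e-12)
})

test_that("all 65+ baseline cohorts attain age >= 80 after five steps", {
  res <- project(simulate_census(), pm, n_steps = 5)
  expect_true(all(res$endpoints$final_age >= 80))
  # hence the default threshold keeps every cohort: recount oracle
  recount <- vapply(living_states(), function(s) {
    sum(res$endpoints$persons[res$endpoints$target_state == s])
  }, numeric(1))
  expect_equal(unname(totals_by_state(res)), unname(recount),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("age threshold filters young cohorts from the target table", {
  baseline <- population_table(data.frame(
    age_group = c("65-69", "85+"), state = c("HEALTHY", "HEALTHY"),
    count = c(100, 100)), year = 2010)
  res <- project(baseline, pm, n_steps = 1, age_threshold = 80)
  # 65-69 cohort ends at midpoint 70 < 80 and is excluded
  expect_equal(sum(res$target_table$count),
               sum(res$trajectories[["85+ HEALTHY"]]$states[2, 1:4]))
})

test_that("projection CSV mirrors the endpoint table", {
  path <- withr::local_tempfile(fileext = ".csv")
  res <- project(simulate_census(), pm, n_steps = 5)
  write_projection_csv(res, path, header = "test artifact")
  back <- read.csv(path, comment.char = "#")
  expect_equal(nrow(back), nrow(res$endpoints))
  expect_equal(sum(back$persons), sum(res$endpoints$persons))
})
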