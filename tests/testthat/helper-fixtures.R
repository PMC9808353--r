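# Shared fixtures built in code: tiny deterministic matrix sets and panels.

# identity dynamics: every living state keeps itself, death absorbing
identity_tms <- function() {
  states <- health_states()
  m <- diag(5)
  dimnames(m) <- list(states, states)
  mats <- stats::setNames(rep(list(m), 5), age_groups()$label)
  transition_matrix_set(mats)
}

# everyone dies in one step
absorbing_tms <- function() {
  states <- health_states()
  m <- matrix(0, 5, 5, dimnames = list(states, states))
  m[, "DEATH"] <- 1
  mats <- stats::setNames(rep(list(m), 5), age_groups()$label)
  transition_matrix_set(mats)
}

# same arbitrary (but valid) row everywhere; handy for known-truth draws
flat_tms <- function(row = c(0.6, 0.2, 0.1, 0.05, 0.05)) {
  states <- health_states()
  m <- matrix(rep(row, each = 4), 4, 5, byrow = FALSE)
  m <- rbind(m, c(0, 0, 0, 0, 1))
  dimnames(m) <- list(states, states)
  mats <- stats::setNames(rep(list(m), 5), age_groups()$label)
  transition_matrix_set(mats)
}

# a small panel written out longhand, for recount oracles
tiny_panel <- function() {
  panel_dataset(data.frame(
    id = 1:6,
    age_group = c("65-69", "65-69", "70-74", "85+", "85+", "85+"),
    state_baseline = c("HEALTHY", "HEALTHY", "MILD", "SEVERE", "SEVERE",
                       "HEALTHY"),
    state_followup = c("HEALTHY", "DEATH", "MILD", "DEATH", "SEVERE",
                       "MODERATE"),
    stringsAsFactors = FALSE))
}

# uniform cohort-size matrix
cohorts <- function(n) {
  matrix(n, 5, 4, dimnames = list(age_groups()$label, living_states()))
}
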