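#' Pipeline configuration
#'
#' Bundles paths and settings for [run_pipeline()]. Any path left `NULL`
#' falls back to a synthetic default: the panel is simulated from the
#' bundled published matrices, the census from the published 65+ state
#' totals, and the schedules are the package defaults. The target year must
#' be reachable from the baseline year in whole steps.
#'
#' @param out_dir Output directory (created if needed).
#' @param panel_csv,census_csv,schedule_json Optional input paths.
#' @param baseline_year,target_year,step_years,age_threshold Projection
#'   settings; `target_year - baseline_year` must be a positive multiple of
#'   `step_years`.
#' @param matrices `"estimate"` (fit from the panel) or `"paper"` (use the
#'   bundled published matrices directly).
#' @param design,alpha Estimation settings; see [fit_multinomial_logit()]
#'   and [empirical_matrix()].
#' @param ci_method,ci_level Confidence-limit settings; see
#'   [probability_limits()].
#' @param rounding_policy See [total_demand()].
#' @param seed Seed for all stochastic stages (always logged, never
#'   silently defaulted: the chosen value is echoed in every artifact).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            panel_csv = NULL, census_csv = NULL,
                            schedule_json = NULL,
                            baseline_year = 2010, target_year = 2025,
                            step_years = 3, age_threshold = 80,
                            matrices = c("estimate", "paper"),
                            design = c("saturated", "additive"), alpha = 0,
                            ci_method = c("wald", "bootstrap"),
                            ci_level = 0.95,
                            rounding_policy = c("round-then-sum",
                                                "sum-then-round"),
                            seed = 1) {
  span <- target_year - baseline_year
  if (span <= 0 || span %% step_years != 0) {
    stop("target_year - baseline_year must be a positive multiple of ",
         "step_years", call. = FALSE)
  }
  for (p in c(panel_csv, census_csv, schedule_json)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, panel_csv = panel_csv,
                 census_csv = census_csv, schedule_json = schedule_json,
                 baseline_year = baseline_year, target_year = target_year,
                 step_years = step_years, age_threshold = age_threshold,
                 matrices = match.arg(matrices), design = match.arg(design),
                 alpha = alpha, ci_method = match.arg(ci_method),
                 ci_level = ci_level,
                 rounding_policy = match.arg(rounding_policy),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# internal: FNV-1a hash of the serialized config, for provenance headers
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      null = "null"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 2^32
  sprintf("%08x", h)
}

# internal: provenance comment lines for text artifacts
provenance_header <- function(config) {
  c(paste0("carecast ", as.character(utils::packageVersion("carecast"))),
    paste0("config_hash=", config_hash(config)),
    paste0("seed=", config$seed))
}

#' Run the full forecasting pipeline
#'
#' Executes estimate -> project -> demand -> validate -> report and writes
#' every artifact to `config$out_dir` with a provenance header (package
#' version, config hash, seed). Deterministic under identical config and
#' seed. Stages:
#' \enumerate{
#'   \item load or simulate the panel; cross-tabulate transitions; estimate
#'     the matrix set (empirical + multinomial logit) with confidence
#'     limits, or load the bundled published matrices;
#'   \item load or simulate the baseline census and project it to the
#'     target year;
#'   \item convert projected populations to staff demand under every
#'     schedule;
#'   \item validate the one-step predicted follow-up state distribution
#'     against the panel's observed follow-up (chi-square, survivors'
#'     living states), and attach perturbation scenario bounds;
#'   \item write matrices, projection, demand, validation and summary
#'     artifacts.
#' }
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every intermediate object and the paths
#'   of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  message("carecast pipeline: seed = ", config$seed,
          ", config hash = ", config_hash(config))

  # -- estimate ---------------------------------------------------------------
  panel <- if (is.null(config$panel_csv)) {
    simulate_panel(paper_matrices(), seed = config$seed)
  } else {
    read_panel_csv(config$panel_csv, wave_gap = config$step_years)
  }
  counts <- count_transitions(panel)
  limits <- probability_limits(counts, level = config$ci_level,
                               method = config$ci_method,
                               seed = config$seed)
  fit <- fit_multinomial_logit(counts, design = config$design)
  matrices <- if (config$matrices == "paper") paper_matrices() else
    predict_matrix(fit, step_years = config$step_years)

  # -- project ----------------------------------------------------------------
  census <- if (is.null(config$census_csv)) {
    simulate_census(year = config$baseline_year)
  } else {
    read_population_csv(config$census_csv)
  }
  n_steps <- (config$target_year - config$baseline_year) %/% config$step_years
  result <- project(census, matrices, n_steps,
                    step_years = config$step_years,
                    age_threshold = config$age_threshold)
  totals <- totals_by_state(result)

  # -- demand -----------------------------------------------------------------
  schedules <- if (is.null(config$schedule_json)) default_schedules() else
    read_schedule_json(config$schedule_json)
  demands <- lapply(schedules, function(s) {
    demand_by_state(totals, s, policy = config$rounding_policy)
  })

  # -- validate ---------------------------------------------------------------
  base_counts <- apply(unclass(counts), c(1, 2), sum)
  expected <- stats::setNames(numeric(4), living_states())
  for (a in rownames(base_counts)) {
    v <- stats::setNames(numeric(5), health_states())
    v[living_states()] <- base_counts[a, ]
    mid <- matrices$groups$midpoint[matrices$groups$label == a]
    expected <- expected + advance_step(v, matrices, mid)[living_states()]
  }
  observed <- apply(unclass(counts), 3, sum)[living_states()]
  validation <- chi_square_fit(observed, expected)
  interval <- perturbation_interval(census, limits, n_steps,
                                    age_threshold = config$age_threshold)

  # -- report -----------------------------------------------------------------
  paths <- list(
    matrices = file.path(config$out_dir, "matrices.csv"),
    projection = file.path(config$out_dir, "projection.csv"),
    demand = file.path(config$out_dir, "demand.json"),
    validation = file.path(config$out_dir, "validation.json"),
    summary = file.path(config$out_dir, "summary.json"))
  write_matrix_csv(matrices, paths$matrices)
  write_projection_csv(result, paths$projection, header = hdr)
  report <- list(
    provenance = list(version = as.character(utils::packageVersion("carecast")),
                      config_hash = config_hash(config), seed = config$seed),
    summary = describe_panel(panel)[c("age", "baseline_state",
                                      "followup_state")],
    loglik = fit$loglik,
    totals_persons = as.list(totals),
    total_population_millions = round(attr(totals, "total") / 1e6, 2),
    demand_millions = lapply(demands, function(d) {
      c(as.list(d$demand_millions), list(total = d$total_millions))
    }),
    interval = interval[c("point", "lower", "upper", "method", "level")])
  write_report(list(statistic = validation$statistic, df = validation$df,
                    p_value = validation$p_value,
                    observed = as.list(validation$observed),
                    expected = as.list(validation$expected)),
               paths$validation)
  write_report(lapply(demands, function(d) {
    c(as.list(d$demand_millions),
      list(total = d$total_millions, policy = d$policy))
  }), paths$demand)
  write_report(report, paths$summary)
  invisible(list(config = config, panel = panel, counts = counts,
                 matrices = matrices, limits = limits, fit = fit,
                 census = census, projection = result, totals = totals,
                 demands = demands, validation = validation,
                 interval = interval, paths = paths))
}

#' Write a results object as pretty-printed JSON
#'
#' @param results A list (nested lists/vectors of numbers and strings).
#' @param path Output path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
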