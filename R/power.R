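# Monte-Carlo power engine.
#
# Each replicate draws one balanced dataset and feeds the SAME dataset to
# every analysis pipeline (paired across pipelines, so pipeline contrasts
# carry minimal Monte-Carlo noise). Replicate streams are spawned with
# derive_seed(master, scenario index, grid keys, replicate, arm) and are
# therefore independent across grid points and reconstructible one by one.

# stable column keys for the replicate-level p-value matrix
PIPELINE_TERMS <- c(
  "factorial:treatment", "factorial:sex", "factorial:interaction",
  "factorial:posthoc_male", "factorial:posthoc_female",
  "pooled:test",
  "disaggregated:male", "disaggregated:female",
  "single_sex_male:test", "single_sex_female:test"
)

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes (0 <= successes <= trials). Vectorised.
#' @param trials Number of trials (>= 1).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A list with numeric vectors `low` and `high`.
#' @examples
#' wilson_interval(50, 1000)
#' @export
wilson_interval <- function(successes, trials, level = 0.95) {
  if (any(trials < 1) || any(successes < 0) || any(successes > trials))
    stop_sabv("sabv_error_config",
              "need 0 <= successes <= trials and trials >= 1")
  if (level <= 0 || level >= 1)
    stop_sabv("sabv_error_config", "level must lie strictly between 0 and 1")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Closed-form power of the two-sample Student's t test
#'
#' Exact power of a two-sided equal-variance two-sample t test via the
#' noncentral t distribution: ncp = effect / (sd * sqrt(2 / n_per_group)),
#' df = 2 * n_per_group - 2. Serves as the analytic oracle for the
#' Monte-Carlo engine (a sex-free treatment comparison reduces to this
#' two-group problem).
#'
#' @param effect True difference in means (unitless). Vectorised.
#' @param n_per_group Observations per group (>= 2).
#' @param sd Common within-group standard deviation (> 0).
#' @param alpha Two-sided significance threshold.
#' @return Power in (0, 1); exactly `alpha` when `effect = 0`.
#' @examples
#' analytic_power_oracle(1, 10, sqrt(0.5))
#' @export
analytic_power_oracle <- function(effect, n_per_group, sd, alpha = 0.05) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L)
    stop_sabv("sabv_error_config", "n_per_group must be an integer >= 2")
  if (!is.finite(sd) || sd <= 0)
    stop_sabv("sabv_error_config", "sd must be > 0")
  if (alpha <= 0 || alpha >= 1)
    stop_sabv("sabv_error_config", "alpha must lie strictly between 0 and 1")
  df <- 2L * n_per_group - 2L
  ncp <- effect / (sd * sqrt(2 / n_per_group))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Monte-Carlo power estimates at one grid point
#'
#' Simulates `config$n_sim` balanced datasets from the scenario's true cell
#' means, analyses every replicate with the requested pipelines (the same
#' dataset is shared by all pipelines within a replicate), counts strict
#' rejections p < alpha per term and returns one power estimate per
#' pipeline/term with a Wilson confidence interval. Deterministic given
#' `config$seed`.
#'
#' Terms reported: factorial `treatment`/`sex`/`interaction` plus the
#' within-sex post-hoc contrasts `posthoc_male`/`posthoc_female`; pooled
#' `test`; disaggregated `male`/`female`; and, when `single_sex = TRUE`, the
#' single-sex comparator arms `single_sex_male`/`single_sex_female` (term
#' `test`), each drawn with `2 * n_per_cell` animals per group so the total N
#' matches the inclusive design.
#'
#' @param spec A [scenario_spec()] (one grid point).
#' @param config A [simulation_config()].
#' @param pipelines Subset of `c("factorial", "pooled", "disaggregated")`.
#' @param single_sex Also run the single-sex design comparator arms.
#' @param keep_replicates Attach the replicate-level p-value matrix as
#'   attribute `"replicates"` (rows = replicates, columns = pipeline:term).
#' @param ci_level Confidence level of the Wilson intervals.
#' @return A data frame (one row per pipeline/term) with columns
#'   `scenario_id`, `sex_effect`, `treatment_effect`, `interaction_effect`,
#'   `pipeline`, `term`, `power`, `n_sig`, `n_sim`, `ci_low`, `ci_high`.
#' @examples
#' estimate_power(scenario_spec("opposite_effects", interaction_effect = 1),
#'                simulation_config(n_sim = 50, seed = 1))
#' @export
estimate_power <- function(spec, config = simulation_config(),
                           pipelines = c("factorial", "pooled", "disaggregated"),
                           single_sex = FALSE, keep_replicates = FALSE,
                           ci_level = 0.95) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(config, "simulation_config"))
  pipelines <- match.arg(pipelines, several.ok = TRUE)
  means <- make_cell_means(spec, config)
  n_sim <- config$n_sim

  cols <- character(0)
  if ("factorial" %in% pipelines)
    cols <- c(cols, PIPELINE_TERMS[1:5])
  if ("pooled" %in% pipelines)
    cols <- c(cols, "pooled:test")
  if ("disaggregated" %in% pipelines)
    cols <- c(cols, "disaggregated:male", "disaggregated:female")
  if (single_sex)
    cols <- c(cols, "single_sex_male:test", "single_sex_female:test")
  if (!length(cols))
    stop_sabv("sabv_error_config", "no pipeline selected")

  keys <- c(match(spec$scenario_id, SCENARIO_IDS),
            round(1000 * spec$sex_effect),
            round(1000 * spec$treatment_effect),
            round(1000 * spec$interaction_effect))
  P <- matrix(NA_real_, nrow = n_sim, ncol = length(cols),
              dimnames = list(NULL, cols))

  for (r in seq_len(n_sim)) {
    res <- tryCatch({
      d <- sample_dataset(means, config, seed = derive_seed(config$seed, keys, r, 0L))
      p <- numeric(0)
      if ("factorial" %in% pipelines) {
        fit <- fit_factorial(d)
        ph <- posthoc_within_sex(d, fit)
        p <- c(p, fit$p_treatment, fit$p_sex, fit$p_interaction,
               ph$p_male, ph$p_female)
      }
      if ("pooled" %in% pipelines)
        p <- c(p, pooled_t_test(d)$p_value)
      if ("disaggregated" %in% pipelines) {
        dis <- disaggregated_t_tests(d)
        p <- c(p, dis$male$p_value, dis$female$p_value)
      }
      if (single_sex) {
        p <- c(p,
          single_sex_design_test(means, config, "male",
            seed = derive_seed(config$seed, keys, r, 1L))$p_value,
          single_sex_design_test(means, config, "female",
            seed = derive_seed(config$seed, keys, r, 2L))$p_value)
      }
      p
    }, sabv_error = function(e) {
      stop_sabv("sabv_error_replicate", "replicate %d failed: %s", r, conditionMessage(e))
    })
    P[r, ] <- res
  }

  n_sig <- as.integer(colSums(P < config$alpha))
  names(n_sig) <- cols
  ci <- wilson_interval(n_sig, n_sim, ci_level)
  pt_split <- strsplit(cols, ":", fixed = TRUE)
  out <- data.frame(
    scenario_id = spec$scenario_id,
    sex_effect = spec$sex_effect,
    treatment_effect = spec$treatment_effect,
    interaction_effect = spec$interaction_effect,
    pipeline = vapply(pt_split, `[`, "", 1L),
    term = vapply(pt_split, `[`, "", 2L),
    power = unname(n_sig) / n_sim,
    n_sig = unname(n_sig),
    n_sim = n_sim,
    ci_low = ci$low,
    ci_high = ci$high,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (keep_replicates) attr(out, "replicates") <- P
  out
}

#' Sweep a full scenario grid
#'
#' Maps [estimate_power()] over [scenario_grid()] and returns the stacked
#' power table. For the `one_sex_only` scenario the single-sex design
#' comparator arms are included automatically (the design comparison of
#' 10 males per group versus 5 + 5 split across sexes).
#'
#' @param scenario_id Scenario identifier.
#' @param config A [simulation_config()].
#' @param pipelines Pipelines to run (see [estimate_power()]).
#' @param single_sex Include the single-sex arms; default `TRUE` exactly for
#'   `one_sex_only`.
#' @param verbose Log per-grid-point progress to stderr.
#' @return A `power_table`: a data frame of power estimates covering the full
#'   grid, with attributes `config`, `scenario_id` and `created`.
#' @examples
#' run_scenario_sweep("opposite_effects",
#'                    simulation_config(n_sim = 20, seed = 1))
#' @export
run_scenario_sweep <- function(scenario_id, config = simulation_config(),
                               pipelines = c("factorial", "pooled", "disaggregated"),
                               single_sex = identical(scenario_id, "one_sex_only"),
                               verbose = FALSE) {
  grid <- scenario_grid(scenario_id, config)
  t0 <- Sys.time()
  parts <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    parts[[i]] <- estimate_power(grid[[i]], config, pipelines = pipelines,
                                 single_sex = single_sex)
    if (verbose)
      message(sprintf("[%s] grid point %d/%d done (%.1f s elapsed)",
                      scenario_id, i, length(grid),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out,
            class = c("power_table", "data.frame"),
            config = config,
            scenario_id = scenario_id,
            created = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' @export
print.power_table <- function(x, ...) {
  cat(sprintf("Power table: scenario '%s', %d estimates (%d grid points), n_sim = %d\n",
              paste(unique(x$scenario_id), collapse = ","),
              nrow(x),
              nrow(unique(x[, c("sex_effect", "treatment_effect", "interaction_effect")])),
              x$n_sim[1]))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
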