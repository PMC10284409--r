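#' @keywords internal
"_PACKAGE"

# canonical scenario identifiers, in sweep order
SCENARIO_IDS <- c("baseline_sex", "same_direction_interaction",
                  "one_sex_only", "opposite_effects")

# which signal fields are allowed to be non-zero in each scenario
SCENARIO_ACTIVE <- list(
  baseline_sex               = c("sex_effect", "treatment_effect"),
  same_direction_interaction = c("treatment_effect", "interaction_effect"),
  one_sex_only               = "interaction_effect",
  opposite_effects           = "interaction_effect"
)

#' Scenario specification
#'
#' A symbolic description of one simulated biology: which scenario is being
#' emulated and the sizes of the signals added to the four true cell means.
#' The four scenarios are:
#'
#' * `baseline_sex` — a baseline sex difference (`sex_effect` added to both
#'   male means) plus a common treatment effect (`treatment_effect` added to
#'   both treated means);
#' * `same_direction_interaction` — a common treatment effect plus an
#'   interaction in the same direction (`interaction_effect` added to the
#'   treated-male mean only);
#' * `one_sex_only` — a treatment effect in males only
#'   (`interaction_effect` added to the treated-male mean);
#' * `opposite_effects` — opposite treatment effects by sex
#'   (`interaction_effect` added to the treated-male mean and subtracted
#'   from the treated-female mean).
#'
#' Signal fields that are inactive for the chosen scenario must be zero;
#' setting them is rejected with a classed error.
#'
#' @param scenario_id One of `"baseline_sex"`, `"same_direction_interaction"`,
#'   `"one_sex_only"`, `"opposite_effects"`.
#' @param sex_effect Signal added to both male cell means (unitless).
#' @param treatment_effect Signal added to both treated cell means (unitless).
#' @param interaction_effect Scenario-specific interaction signal (unitless).
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("baseline_sex", sex_effect = 1, treatment_effect = 0.5)
#' @export
scenario_spec <- function(scenario_id, sex_effect = 0, treatment_effect = 0,
                          interaction_effect = 0) {
  if (length(scenario_id) != 1L || !scenario_id %in% SCENARIO_IDS)
    stop_sabv("sabv_error_scenario",
              "unknown scenario_id '%s'; must be one of: %s",
              as.character(scenario_id)[1], paste(SCENARIO_IDS, collapse = ", "))
  sig <- c(sex_effect = sex_effect, treatment_effect = treatment_effect,
           interaction_effect = interaction_effect)
  if (any(!is.finite(sig)))
    stop_sabv("sabv_error_scenario", "signal fields must be finite numbers")
  inactive <- setdiff(names(sig), SCENARIO_ACTIVE[[scenario_id]])
  bad <- inactive[sig[inactive] != 0]
  if (length(bad))
    stop_sabv("sabv_error_scenario",
              "signal field(s) %s are inactive for scenario '%s' and must be 0",
              paste(bad, collapse = ", "), scenario_id)
  structure(
    list(scenario_id = scenario_id,
         sex_effect = unname(sex_effect),
         treatment_effect = unname(treatment_effect),
         interaction_effect = unname(interaction_effect)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': sex_effect = %g, treatment_effect = %g, interaction_effect = %g\n",
              x$scenario_id, x$sex_effect, x$treatment_effect, x$interaction_effect))
  invisible(x)
}

#' True cell means for a scenario
#'
#' Derives the four true group means of the balanced 2x2 (sex x treatment)
#' design deterministically from a scenario specification and a simulation
#' configuration. All four means start at `baseline_mean`; the scenario then
#' adds its signals:
#'
#' * `baseline_sex`: `sex_effect` to both male means, `treatment_effect` to
#'   both treated means;
#' * `same_direction_interaction`: `treatment_effect` to both treated means,
#'   `interaction_effect` to the treated-male mean only;
#' * `one_sex_only`: `interaction_effect` to the treated-male mean only;
#' * `opposite_effects`: `interaction_effect` added to the treated-male mean
#'   and subtracted from the treated-female mean.
#'
#' @param spec A [scenario_spec()].
#' @param config A [simulation_config()].
#' @return An object of class `cell_means`: the four true means plus the
#'   common `noise_variance`.
#' @examples
#' make_cell_means(scenario_spec("opposite_effects", interaction_effect = 1),
#'                 simulation_config())
#' @export
make_cell_means <- function(spec, config = simulation_config()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(config, "simulation_config"))
  b <- config$baseline_mean
  fc <- ft <- mc <- mt <- b
  switch(spec$scenario_id,
    baseline_sex = {
      mc <- mc + spec$sex_effect
      mt <- mt + spec$sex_effect + spec$treatment_effect
      ft <- ft + spec$treatment_effect
    },
    same_direction_interaction = {
      ft <- ft + spec$treatment_effect
      mt <- mt + spec$treatment_effect + spec$interaction_effect
    },
    one_sex_only = {
      mt <- mt + spec$interaction_effect
    },
    opposite_effects = {
      mt <- mt + spec$interaction_effect
      ft <- ft - spec$interaction_effect
    }
  )
  structure(
    list(mean_female_control = fc, mean_female_treated = ft,
         mean_male_control = mc, mean_male_treated = mt,
         noise_variance = config$noise_variance),
    class = "cell_means"
  )
}

#' @export
print.cell_means <- function(x, ...) {
  cat("True cell means (sd =", format(sqrt(x$noise_variance)), ")\n")
  m <- matrix(c(x$mean_female_control, x$mean_female_treated,
                x$mean_male_control, x$mean_male_treated),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("female", "male"), c("control", "treated")))
  print(m)
  invisible(x)
}

#' Effect-size grid for a scenario
#'
#' Returns the full list of [scenario_spec()]s swept for a scenario, with
#' both endpoints included:
#'
#' * `baseline_sex`: sex_effect in \{0, 0.5, 1\} crossed with
#'   treatment_effect 0 to 1 in steps of 0.1 (33 specs);
#' * `same_direction_interaction`: treatment_effect 0 to 1 in steps of 0.1
#'   crossed with interaction_effect in \{0, 0.5, 1\} (33 specs);
#' * `one_sex_only`: interaction_effect 0 to 2 in steps of 0.2 (11 specs);
#' * `opposite_effects`: interaction_effect 0 to 1 in steps of 0.1 (11 specs).
#'
#' @param scenario_id Scenario identifier.
#' @param config A [simulation_config()] (carried for interface symmetry;
#'   the grids do not depend on it).
#' @return A list of `scenario_spec` objects.
#' @examples
#' length(scenario_grid("baseline_sex"))   # 33
#' @export
scenario_grid <- function(scenario_id, config = simulation_config()) {
  if (length(scenario_id) != 1L || !scenario_id %in% SCENARIO_IDS)
    stop_sabv("sabv_error_scenario",
              "unknown scenario_id '%s'; must be one of: %s",
              as.character(scenario_id)[1], paste(SCENARIO_IDS, collapse = ", "))
  fine <- seq(0, 1, by = 0.1)
  coarse <- c(0, 0.5, 1)
  switch(scenario_id,
    baseline_sex = {
      g <- expand.grid(sex = coarse, trt = fine, KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(g)), function(i)
        scenario_spec(scenario_id, sex_effect = g$sex[i], treatment_effect = g$trt[i]))
    },
    same_direction_interaction = {
      g <- expand.grid(int = coarse, trt = fine, KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(g)), function(i)
        scenario_spec(scenario_id, treatment_effect = g$trt[i], interaction_effect = g$int[i]))
    },
    one_sex_only = lapply(seq(0, 2, by = 0.2), function(d)
      scenario_spec(scenario_id, interaction_effect = d)),
    opposite_effects = lapply(fine, function(d)
      scenario_spec(scenario_id, interaction_effect = d))
  )
}

#' Sample one balanced dataset from true cell means
#'
#' Draws `n_per_cell` i.i.d. Normal(cell mean, sd = sqrt(noise_variance))
#' outcomes for each of the four sex-by-treatment cells and returns them as a
#' long-format data frame. Row order is fixed (female-control,
#' female-treated, male-control, male-treated blocks); animal ids are
#' generated labels `f1..f2n`, `m1..m2n`.
#'
#' @param means A [make_cell_means()] result.
#' @param config A [simulation_config()].
#' @param seed Optional integer; when supplied the RNG is seeded with it so
#'   the draw is reproducible in isolation (this is how the power engine
#'   spawns per-replicate streams). When `NULL` the current RNG state is used.
#' @return A `data.frame` (class `sim_dataset`) with columns `animal_id`,
#'   `sex` (`"female"`/`"male"`), `treatment` (`"control"`/`"treated"`),
#'   `outcome`.
#' @examples
#' d <- sample_dataset(make_cell_means(scenario_spec("one_sex_only",
#'                     interaction_effect = 1)), simulation_config(), seed = 1)
#' table(d$sex, d$treatment)
#' @export
sample_dataset <- function(means, config = simulation_config(), seed = NULL) {
  stopifnot(inherits(means, "cell_means"))
  n <- config$n_per_cell
  if (!is.null(seed)) set.seed(seed)
  mu <- c(means$mean_female_control, means$mean_female_treated,
          means$mean_male_control, means$mean_male_treated)
  y <- stats::rnorm(4L * n, mean = rep(mu, each = n), sd = sqrt(means$noise_variance))
  ids <- c(paste0("f", seq_len(2L * n)), paste0("m", seq_len(2L * n)))
  structure(
    list(animal_id = ids,
         sex = rep(c("female", "male"), each = 2L * n),
         treatment = rep(rep(c("control", "treated"), each = n), times = 2L),
         outcome = y),
    class = c("sim_dataset", "data.frame"),
    row.names = c(NA_integer_, -(4L * n))
  )
}

#' Write / read a dataset in the canonical CSV dialect
#'
#' The on-disk dialect is a plain CSV with header
#' `animal_id,sex,treatment,outcome`; `sex` takes exactly the strings
#' `male`/`female` and `treatment` exactly `control`/`treated` (lowercase).
#' `read_dataset_csv()` validates every row and reports the first offending
#' row number in a classed parse error.
#'
#' @param data A dataset data frame in the canonical long format.
#' @param path File path.
#' @return `read_dataset_csv()` returns a validated `sim_dataset` data frame;
#'   `write_dataset_csv()` returns `path` invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(is.data.frame(data))
  utils::write.csv(data[, c("animal_id", "sex", "treatment", "outcome")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path))
    stop_sabv("sabv_error_parse", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "sex", "treatment", "outcome")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_sabv("sabv_error_parse", "missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  bad_sex <- which(!df$sex %in% c("male", "female"))
  if (length(bad_sex))
    stop_sabv("sabv_error_parse",
              "row %d: invalid sex value '%s' (expected 'male' or 'female')",
              bad_sex[1], df$sex[bad_sex[1]])
  bad_trt <- which(!df$treatment %in% c("control", "treated"))
  if (length(bad_trt))
    stop_sabv("sabv_error_parse",
              "row %d: invalid treatment value '%s' (expected 'control' or 'treated')",
              bad_trt[1], df$treatment[bad_trt[1]])
  bad_out <- which(!is.finite(suppressWarnings(as.numeric(df$outcome))))
  if (length(bad_out))
    stop_sabv("sabv_error_parse", "row %d: non-numeric outcome '%s'",
              bad_out[1], as.character(df$outcome[bad_out[1]]))
  df$outcome <- as.numeric(df$outcome)
  class(df) <- c("sim_dataset", "data.frame")
  df
}
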