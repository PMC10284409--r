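# Analysis pipelines for balanced 2x2 sex-by-treatment data.
#
# The factorial fit uses the closed-form balanced-design sum-of-squares
# decomposition (for 2-level factors the Type I/II/III sums of squares
# coincide; the test suite asserts equality with an explicit design-matrix
# least-squares oracle). Closed form matters: the power engine calls these
# functions ~10^5 times per sweep.

# common validation: required columns, both levels of both factors
check_dataset <- function(data, require_balance = TRUE) {
  need <- c("sex", "treatment", "outcome")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop_sabv("sabv_error_design", "dataset lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  for (lev in c("male", "female"))
    if (!any(data$sex == lev))
      stop_sabv("sabv_error_design", "sex level '%s' absent from data", lev)
  for (lev in c("control", "treated"))
    if (!any(data$treatment == lev))
      stop_sabv("sabv_error_design", "treatment level '%s' absent from data", lev)
  if (require_balance) {
    male <- data$sex == "male"
    trt <- data$treatment == "treated"
    counts <- c(sum(!male & !trt), sum(!male & trt), sum(male & !trt), sum(male & trt))
    if (any(counts < 2L))
      stop_sabv("sabv_error_design",
                "each sex-by-treatment cell needs >= 2 observations (got %s)",
                paste(counts, collapse = "/"))
    if (length(unique(counts)) != 1L)
      stop_sabv("sabv_error_design",
                "design is unbalanced (cell counts %s); the factorial pipeline requires balance",
                paste(counts, collapse = "/"))
  }
  invisible(TRUE)
}

# p-value of an F(1, df) test with a guard for the degenerate zero-residual
# fit: effect and error sums of squares both zero => report p = 1 (constant
# data carries no evidence); zero error with non-zero effect => p = 0.
f_pvalue <- function(ss_effect, ms_resid, df_resid) {
  if (ms_resid <= 0) return(if (ss_effect <= 0) 1 else 0)
  stats::pf(ss_effect / ms_resid, 1, df_resid, lower.tail = FALSE)
}

t_pvalue <- function(estimate, se, df) {
  if (se <= 0) return(if (estimate == 0) 1 else 0)
  2 * stats::pt(-abs(estimate / se), df)
}

#' Factorial (two-way ANOVA) analysis of a balanced 2x2 dataset
#'
#' Fits `outcome ~ treatment + sex + treatment:sex` by least squares and
#' returns two-sided F-test p-values for the treatment and sex main effects
#' and their interaction. For the balanced design the fit reduces to the four
#' cell means and an orthogonal sum-of-squares decomposition, so Type
#' I/II/III tests coincide. Constant data (all sums of squares zero) reports
#' p = 1 for every term.
#'
#' @param data A balanced 2x2 dataset with columns `sex`, `treatment`,
#'   `outcome` (see [sample_dataset()]).
#' @return An object of class `factorial_result` with elements
#'   `p_treatment`, `p_sex`, `p_interaction`, `estimates` (named fitted cell
#'   means), `residual_variance` (pooled error variance), `residual_df`
#'   (total rows minus 4) and `n_per_cell`.
#' @examples
#' d <- sample_dataset(make_cell_means(scenario_spec("baseline_sex",
#'        sex_effect = 1, treatment_effect = 1)), simulation_config(), seed = 1)
#' fit_factorial(d)$p_treatment
#' @export
fit_factorial <- function(data) {
  check_dataset(data, require_balance = TRUE)
  male <- data$sex == "male"
  trt <- data$treatment == "treated"
  y <- data$outcome
  y_fc <- y[!male & !trt]; y_ft <- y[!male & trt]
  y_mc <- y[male & !trt];  y_mt <- y[male & trt]
  n <- length(y_fc)
  m_fc <- mean(y_fc); m_ft <- mean(y_ft); m_mc <- mean(y_mc); m_mt <- mean(y_mt)

  diff_trt <- (m_ft + m_mt) / 2 - (m_fc + m_mc) / 2
  diff_sex <- (m_mc + m_mt) / 2 - (m_fc + m_ft) / 2
  c_int <- (m_mt - m_mc) - (m_ft - m_fc)
  ss_trt <- n * diff_trt^2
  ss_sex <- n * diff_sex^2
  ss_int <- n * c_int^2 / 4
  ss_res <- sum((y_fc - m_fc)^2) + sum((y_ft - m_ft)^2) +
            sum((y_mc - m_mc)^2) + sum((y_mt - m_mt)^2)
  df_res <- 4L * n - 4L
  ms_res <- ss_res / df_res

  structure(
    list(p_treatment = f_pvalue(ss_trt, ms_res, df_res),
         p_sex = f_pvalue(ss_sex, ms_res, df_res),
         p_interaction = f_pvalue(ss_int, ms_res, df_res),
         estimates = c(female_control = m_fc, female_treated = m_ft,
                       male_control = m_mc, male_treated = m_mt),
         residual_variance = ms_res,
         residual_df = df_res,
         n_per_cell = n),
    class = "factorial_result"
  )
}

#' @export
print.factorial_result <- function(x, ...) {
  cat("Factorial 2x2 analysis (two-way ANOVA)\n")
  cat(sprintf("  treatment   : p = %.4g\n", x$p_treatment))
  cat(sprintf("  sex         : p = %.4g\n", x$p_sex))
  cat(sprintf("  interaction : p = %.4g\n", x$p_interaction))
  cat(sprintf("  residual variance %.4g on %d df\n", x$residual_variance, x$residual_df))
  invisible(x)
}

#' Within-sex post-hoc treated-vs-control contrasts
#'
#' For each sex, tests the treated-minus-control contrast of the fitted cell
#' means using the full model's pooled residual variance and residual degrees
#' of freedom (the estimated-marginal-means convention:
#' se = sqrt(residual_variance * (1/n1 + 1/n2)), t on `residual_df`).
#' The two tests are two-sided and uncorrected for multiplicity.
#'
#' @param data The dataset the model was fitted to.
#' @param fit The [fit_factorial()] result for `data`.
#' @return An object of class `posthoc_result` with `p_male`, `p_female`,
#'   `estimate_male`, `estimate_female`, `se` (common to both contrasts) and
#'   `df`.
#' @export
posthoc_within_sex <- function(data, fit) {
  stopifnot(inherits(fit, "factorial_result"))
  n <- fit$n_per_cell
  est_m <- unname(fit$estimates["male_treated"] - fit$estimates["male_control"])
  est_f <- unname(fit$estimates["female_treated"] - fit$estimates["female_control"])
  se <- sqrt(fit$residual_variance * 2 / n)
  structure(
    list(p_male = t_pvalue(est_m, se, fit$residual_df),
         p_female = t_pvalue(est_f, se, fit$residual_df),
         estimate_male = est_m, estimate_female = est_f,
         se = se, df = fit$residual_df),
    class = "posthoc_result"
  )
}

# pooled-variance two-sample t test on raw vectors (Student, not Welch)
student_t2 <- function(x_treated, x_control) {
  n1 <- length(x_treated); n2 <- length(x_control)
  df <- n1 + n2 - 2L
  est <- mean(x_treated) - mean(x_control)
  sp2 <- (sum((x_treated - mean(x_treated))^2) +
          sum((x_control - mean(x_control))^2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(
    list(p_value = t_pvalue(est, se, df), estimate = est, se = se, df = df),
    class = "simple_test_result"
  )
}

#' @export
print.simple_test_result <- function(x, ...) {
  cat(sprintf("Student t test: estimate = %.4g, se = %.4g, df = %d, p = %.4g\n",
              x$estimate, x$se, x$df, x$p_value))
  invisible(x)
}

#' Pooled two-sample t test ignoring sex
#'
#' The pooling pipeline: a two-sided equal-variance Student's t test of
#' treated versus control after combining both sexes. Degrees of freedom are
#' total rows minus 2. Pooling leaves any sex-related variation in the error
#' term, which is the statistical mistake the factorial pipeline avoids.
#'
#' @param data Dataset with both treatment levels present (sex is ignored).
#' @return A `simple_test_result`: `p_value`, `estimate`
#'   (treated minus control), `se`, `df`.
#' @export
pooled_t_test <- function(data) {
  for (lev in c("control", "treated"))
    if (!any(data$treatment == lev))
      stop_sabv("sabv_error_design", "treatment level '%s' absent from data", lev)
  trt <- data$treatment == "treated"
  student_t2(data$outcome[trt], data$outcome[!trt])
}

#' Disaggregated per-sex t tests
#'
#' The disaggregation pipeline: the data are split by sex and each half gets
#' its own independent equal-variance Student's t test (df = rows of that sex
#' minus 2). This halves the n behind each test and offers no formal test of
#' the treatment-by-sex interaction.
#'
#' @param data Dataset with both sexes and both treatment levels present.
#' @return A list with elements `male` and `female`, each a
#'   `simple_test_result`.
#' @export
disaggregated_t_tests <- function(data) {
  check_dataset(data, require_balance = FALSE)
  male <- data$sex == "male"
  trt <- data$treatment == "treated"
  if (!sum(male & trt) || !sum(male & !trt) || !sum(!male & trt) || !sum(!male & !trt))
    stop_sabv("sabv_error_design", "every sex-by-treatment cell must be non-empty")
  list(
    male = student_t2(data$outcome[male & trt], data$outcome[male & !trt]),
    female = student_t2(data$outcome[!male & trt], data$outcome[!male & !trt])
  )
}

#' Single-sex design comparator
#'
#' Simulates the alternative design that spends the whole animal budget on
#' one sex: draws `n_per_group` control and `n_per_group` treated outcomes
#' from that sex's true cell means and applies a Student's t test. With the
#' default `n_per_group = 2 * n_per_cell` the total N matches the
#' sex-inclusive design (e.g. 10 males per group versus 5 females + 5 males).
#'
#' @param means A [make_cell_means()] result.
#' @param config A [simulation_config()].
#' @param sex `"male"` or `"female"`.
#' @param n_per_group Animals per treatment group (>= 2); default
#'   `2 * config$n_per_cell`.
#' @param seed Optional integer seed for the draw (see [sample_dataset()]).
#' @return A `simple_test_result`.
#' @export
single_sex_design_test <- function(means, config = simulation_config(),
                                   sex = c("male", "female"),
                                   n_per_group = 2L * config$n_per_cell,
                                   seed = NULL) {
  stopifnot(inherits(means, "cell_means"))
  sex <- match.arg(sex)
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L)
    stop_sabv("sabv_error_config", "n_per_group must be an integer >= 2")
  if (!is.null(seed)) set.seed(seed)
  mu <- if (sex == "male")
    c(means$mean_male_control, means$mean_male_treated)
  else
    c(means$mean_female_control, means$mean_female_treated)
  sd <- sqrt(means$noise_variance)
  y <- stats::rnorm(2L * n_per_group, mean = rep(mu, each = n_per_group), sd = sd)
  student_t2(y[(n_per_group + 1L):(2L * n_per_group)], y[seq_len(n_per_group)])
}
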