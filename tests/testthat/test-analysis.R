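cfg <- simulation_config()

test_that("factorial fit matches the design-matrix oracle and lm/anova", {
  for (seed in 1:20) {
    d <- random_dataset(seed, n_per_cell = sample(2:8, 1))
    fit <- fit_factorial(d)
    orc <- oracle_factorial(d)
    expect_equal(fit$p_treatment, orc$p_treatment, tolerance = 1e-10)
    expect_equal(fit$p_sex, orc$p_sex, tolerance = 1e-10)
    expect_equal(fit$p_interaction, orc$p_interaction, tolerance = 1e-10)
    expect_equal(fit$residual_variance, orc$residual_variance, tolerance = 1e-10)
    expect_identical(fit$residual_df, orc$residual_df)
  }

  # balanced design: sequential ANOVA p-values coincide for both factor
  # orders (Type I = II = III), and match the package's closed form
  d <- random_dataset(42)
  fit <- fit_factorial(d)
  a1 <- anova(lm(outcome ~ treatment * sex, data = d))
  a2 <- anova(lm(outcome ~ sex * treatment, data = d))
  expect_equal(a1["treatment", "Pr(>F)"], a2["treatment", "Pr(>F)"], tolerance = 1e-12)
  expect_equal(fit$p_treatment, a1["treatment", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(fit$p_sex, a1["sex", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(fit$p_interaction, a1["treatment:sex", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(unname(fit$estimates),
               as.vector(tapply(d$outcome, paste(d$sex, d$treatment), mean)[
                 c("female control", "female treated", "male control", "male treated")]),
               tolerance = 1e-12)
})

test_that("post-hoc contrasts and t-test pipelines match direct-formula oracles", {
  for (seed in 21:40) {
    d <- random_dataset(seed)
    fit <- fit_factorial(d)
    ph <- posthoc_within_sex(d, fit)
    orc <- oracle_posthoc(d)
    expect_equal(ph$p_male, orc$p_male, tolerance = 1e-10)
    expect_equal(ph$p_female, orc$p_female, tolerance = 1e-10)

    expect_equal(pooled_t_test(d)$p_value, oracle_pooled(d), tolerance = 1e-12)
    dis <- disaggregated_t_tests(d)
    orc_d <- oracle_disaggregated(d)
    expect_equal(dis$male$p_value, orc_d$male, tolerance = 1e-12)
    expect_equal(dis$female$p_value, orc_d$female, tolerance = 1e-12)

    # and against stats::t.test with var.equal = TRUE as a second reference
    tt <- t.test(outcome ~ treatment, data = d, var.equal = TRUE)
    expect_equal(pooled_t_test(d)$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate and noise-free datasets follow the stated contracts", {
  # constant data: all sums of squares zero, every p reported as 1
  d <- sample_dataset(make_cell_means(scenario_spec("baseline_sex"),
         simulation_config(noise_variance = 0)),
         simulation_config(noise_variance = 0), seed = 1)
  fit <- fit_factorial(d)
  expect_equal(c(fit$p_treatment, fit$p_sex, fit$p_interaction), c(1, 1, 1))
  ph <- posthoc_within_sex(d, fit)
  expect_equal(c(ph$p_male, ph$p_female), c(1, 1))
  expect_equal(pooled_t_test(d)$p_value, 1)

  # pure sex shift with no noise: sex term certain, interaction carries nothing
  cfg0 <- simulation_config(noise_variance = 0)
  d <- sample_dataset(make_cell_means(
         scenario_spec("baseline_sex", sex_effect = 1), cfg0), cfg0, seed = 1)
  fit <- fit_factorial(d)
  expect_equal(fit$p_sex, 0)
  expect_equal(fit$p_interaction, 1)  # zero interaction SS on zero residual

  # noise-free one-sex-only effect: certain in males, absent in females
  d <- sample_dataset(make_cell_means(
         scenario_spec("one_sex_only", interaction_effect = 1), cfg0), cfg0, seed = 1)
  ph <- posthoc_within_sex(d, fit_factorial(d))
  expect_equal(ph$p_male, 0)
  expect_equal(ph$p_female, 1)

  # pure treatment shift, no noise: pooled test certain
  d <- sample_dataset(make_cell_means(
         scenario_spec("baseline_sex", treatment_effect = 1), cfg0), cfg0, seed = 1)
  expect_equal(pooled_t_test(d)$p_value, 0)
})

test_that("pipelines are invariant to row order, shift, and sex symmetry", {
  d <- random_dataset(7)
  shuffled <- d[sample(nrow(d)), ]
  shifted <- d; shifted$outcome <- shifted$outcome + 100

  f0 <- fit_factorial(d); f1 <- fit_factorial(shuffled); f2 <- fit_factorial(shifted)
  for (term in c("p_treatment", "p_sex", "p_interaction")) {
    expect_equal(f0[[term]], f1[[term]], tolerance = 1e-12)
    expect_equal(f0[[term]], f2[[term]], tolerance = 1e-9)
  }
  expect_equal(pooled_t_test(d)$p_value, pooled_t_test(shuffled)$p_value,
               tolerance = 1e-12)
  expect_equal(pooled_t_test(d)$p_value, pooled_t_test(shifted)$p_value,
               tolerance = 1e-9)

  # identical male and female arms: within-sex results coincide exactly
  half <- d[d$sex == "female", ]
  mirror <- half; mirror$sex <- "male"; mirror$animal_id <- paste0("m", 1:10)
  sym <- rbind(half, mirror)
  ph <- posthoc_within_sex(sym, fit_factorial(sym))
  expect_identical(ph$p_male, ph$p_female)
  dis <- disaggregated_t_tests(sym)
  expect_identical(dis$male$p_value, dis$female$p_value)
})

test_that("F = t^2 identity holds and degrees of freedom are as designed", {
  d <- random_dataset(13)
  fit <- fit_factorial(d)
  # treatment main-effect contrast as a t test on the pooled error
  est <- (fit$estimates["female_treated"] + fit$estimates["male_treated"]) / 2 -
         (fit$estimates["female_control"] + fit$estimates["male_control"]) / 2
  se <- sqrt(fit$residual_variance / fit$n_per_cell)
  tstat <- unname(est / se)
  expect_equal(fit$p_treatment, 2 * pt(-abs(tstat), fit$residual_df),
               tolerance = 1e-12)
  expect_equal(fit$residual_df, nrow(d) - 4L)

  dis <- disaggregated_t_tests(d)
  expect_equal(dis$male$df, 8L)        # 10 animals of one sex, minus 2
  expect_equal(pooled_t_test(d)$df, 18L)  # 20 animals, minus 2

  sst <- single_sex_design_test(make_cell_means(scenario_spec("one_sex_only",
           interaction_effect = 1), cfg), cfg, sex = "male", seed = 5)
  expect_equal(sst$df, 18L)            # default n_per_group = 10 per arm
  expect_error(pooled_t_test(d[d$treatment == "control", ]),
               "treated", class = "sabv_error_design")
  expect_error(fit_factorial(d[-1, ]), class = "sabv_error_design")
  expect_error(disaggregated_t_tests(d[d$sex == "male", ]),
               "female", class = "sabv_error_design")
})

test_that("post-hoc p-values approach disaggregated p-values as n grows", {
  gap <- function(n_per_cell, seed) {
    d <- random_dataset(seed, n_per_cell = n_per_cell)
    ph <- posthoc_within_sex(d, fit_factorial(d))
    dis <- disaggregated_t_tests(d)
    mean(c(abs(ph$p_male - dis$male$p_value),
           abs(ph$p_female - dis$female$p_value)))
  }
  gaps_small <- vapply(1:30, function(s) gap(5L, 100 + s), 0)
  gaps_big <- vapply(1:30, function(s) gap(200L, 200 + s), 0)
  expect_lt(mean(gaps_big), mean(gaps_small))
  expect_lt(mean(gaps_big), 0.02)
})
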