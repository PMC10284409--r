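# Independent brute-force oracles, deliberately coded on a different path
# from the package: explicit design-matrix least squares (QR) with
# nested-model F ratios, and direct textbook t formulas.

# two-way ANOVA via effect-coded design matrix; for the balanced 2x2 the
# columns are orthogonal so dropping a column gives the term's F test
oracle_factorial <- function(data) {
  y <- data$outcome
  ts <- ifelse(data$treatment == "treated", 1, -1)
  sx <- ifelse(data$sex == "male", 1, -1)
  X <- cbind(1, ts, sx, ts * sx)
  qr_full <- qr(X)
  rss_full <- sum(qr.resid(qr_full, y)^2)
  df_res <- length(y) - 4L
  drop_p <- function(keep) {
    rss_r <- sum(qr.resid(qr(X[, keep, drop = FALSE]), y)^2)
    f <- (rss_r - rss_full) / (rss_full / df_res)
    stats::pf(f, 1, df_res, lower.tail = FALSE)
  }
  list(p_treatment = drop_p(c(1, 3, 4)),
       p_sex = drop_p(c(1, 2, 4)),
       p_interaction = drop_p(c(1, 2, 3)),
       residual_variance = rss_full / df_res,
       residual_df = df_res)
}

# within-sex treated-vs-control contrast on the full model's pooled error
oracle_posthoc <- function(data) {
  fit <- oracle_factorial(data)
  one_sex <- function(sex) {
    trt <- data$outcome[data$sex == sex & data$treatment == "treated"]
    ctl <- data$outcome[data$sex == sex & data$treatment == "control"]
    est <- mean(trt) - mean(ctl)
    se <- sqrt(fit$residual_variance * (1 / length(trt) + 1 / length(ctl)))
    2 * stats::pt(-abs(est / se), fit$residual_df)
  }
  list(p_male = one_sex("male"), p_female = one_sex("female"))
}

# textbook pooled-variance two-sample t test
oracle_t2 <- function(treated, control) {
  n1 <- length(treated); n2 <- length(control)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(treated) + (n2 - 1) * stats::var(control)) / df
  tt <- (mean(treated) - mean(control)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tt), df)
}

oracle_pooled <- function(data) {
  oracle_t2(data$outcome[data$treatment == "treated"],
            data$outcome[data$treatment == "control"])
}

oracle_disaggregated <- function(data) {
  bysex <- function(sex) {
    sub <- data[data$sex == sex, ]
    oracle_t2(sub$outcome[sub$treatment == "treated"],
              sub$outcome[sub$treatment == "control"])
  }
  list(male = bysex("male"), female = bysex("female"))
}

# brute-force Monte-Carlo power of the two-sample Student t test (vectorised)
oracle_mc_power_t2 <- function(effect, n_per_group, sd, alpha = 0.05,
                               n_rep = 2e5, seed = 12345) {
  set.seed(seed)
  n <- n_per_group
  x <- matrix(stats::rnorm(n_rep * n, 0, sd), n_rep)
  y <- matrix(stats::rnorm(n_rep * n, effect, sd), n_rep)
  mx <- rowMeans(x); my <- rowMeans(y)
  sp2 <- (rowSums((x - mx)^2) + rowSums((y - my)^2)) / (2 * n - 2)
  tt <- (my - mx) / sqrt(sp2 * 2 / n)
  mean(abs(tt) > stats::qt(1 - alpha / 2, 2 * n - 2))
}

# random balanced dataset with arbitrary cell means/variance, for oracle loops
random_dataset <- function(seed, n_per_cell = 5L, sd = 1) {
  set.seed(seed)
  mu <- stats::rnorm(4, 0, 2)
  cm <- structure(
    list(mean_female_control = mu[1], mean_female_treated = mu[2],
         mean_male_control = mu[3], mean_male_treated = mu[4],
         noise_variance = sd^2),
    class = "cell_means")
  sample_dataset(cm, simulation_config(n_per_cell = n_per_cell), seed = seed + 1L)
}
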