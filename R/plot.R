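#' Plot power curves from a power table
#'
#' Draws the standard power-curve layout: one panel per pipeline/term, power
#' against the scenario's swept effect size, a ribbon for the Wilson
#' confidence interval, and a horizontal dashed reference line at the target
#' power (0.8 by convention, configurable). When the scenario sweeps a
#' secondary signal (the baseline sex-difference levels, or the interaction
#' levels of the same-direction scenario) one coloured curve is drawn per
#' level.
#'
#' @param table A complete `power_table` from [run_scenario_sweep()].
#' @param path Optional output file; written with [ggplot2::ggsave()]
#'   (extension selects the device: png/pdf/svg).
#' @param target_power Height of the dashed reference line; default 0.8.
#' @param width,height Device size in inches when `path` is given.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_power_curves <- function(table, path = NULL, target_power = 0.8,
                              width = 10, height = 7) {
  stopifnot(is.data.frame(table))
  if (!nrow(table))
    stop_sabv("sabv_error_plot", "power table is empty; nothing to plot")
  missing_cols <- setdiff(POWER_TABLE_COLS, names(table))
  if (length(missing_cols))
    stop_sabv("sabv_error_schema", "power table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  scen <- unique(table$scenario_id)
  if (length(scen) != 1L)
    stop_sabv("sabv_error_plot",
              "plot one scenario at a time (got: %s)", paste(scen, collapse = ", "))

  x_var <- if (scen %in% c("baseline_sex", "same_direction_interaction"))
    "treatment_effect" else "interaction_effect"
  group_var <- switch(scen,
    baseline_sex = "sex_effect",
    same_direction_interaction = "interaction_effect",
    NULL)

  # completeness: every pipeline/term must appear at every grid point
  grid_pts <- unique(table[, c("sex_effect", "treatment_effect", "interaction_effect")])
  combos <- unique(paste(table$pipeline, table$term, sep = ":"))
  counts <- table(paste(table$pipeline, table$term, sep = ":"))
  incomplete <- names(counts)[counts != nrow(grid_pts)]
  if (length(incomplete))
    stop_sabv("sabv_error_plot",
              "incomplete power table: %s missing at some grid points (expected %d each)",
              paste(incomplete, collapse = ", "), nrow(grid_pts))

  df <- as.data.frame(table)
  df$panel <- paste(df$pipeline, df$term, sep = " / ")
  df$.x <- df[[x_var]]
  if (!is.null(group_var)) {
    df$.level <- factor(df[[group_var]])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .x, y = power, colour = .level,
                                          fill = .level, group = .level)) +
      ggplot2::labs(colour = group_var, fill = group_var)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .x, y = power))
  }
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = target_power, linetype = "dashed") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = x_var, y = "estimated power",
                  title = sprintf("Scenario: %s (n_sim = %d)", scen, df$n_sim[1])) +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

utils::globalVariables(c(".x", ".level", "power", "ci_low", "ci_high"))
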