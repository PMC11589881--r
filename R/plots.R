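#' Violin/box summary of a cohort by orientation
#'
#' Plots the distribution of a C-tail metric for posttranslationally
#' inserting proteins, split by C-terminal orientation — the standard view
#' for comparing `C_cyt` and `C_ext` tails.
#'
#' @param profiles Tibble from [profile_cohort()].
#' @param metric Column to plot (default `"tail_dg"`).
#' @param posttranslational_only Restrict to posttranslational proteins
#'   (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_cohort <- function(profiles, metric = "tail_dg",
                        posttranslational_only = TRUE) {
  dat <- as_tibble(profiles)
  if (posttranslational_only) {
    dat <- filter(dat, .data$route == "posttranslational")
  }
  lab <- c(tail_dg = "C-tail hydrophilicity (summed ΔG app, kcal/mol)",
           tail_len = "C-tail length (residues)",
           penultimate_loop_dg = "penultimate loop hydrophilicity (kcal/mol)",
           n_tail_dg = "N-tail hydrophilicity (kcal/mol)")[metric]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$orientation,
                                    y = .data[[metric]],
                                    fill = .data$orientation)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5,
                          show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = lab %||% metric) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_cohort `autoplot` method for tail-profile cohorts
#'   carrying class `ctail_profiles`.
#' @param object,... Passed to [plot_cohort()].
#' @export
autoplot.ctail_profiles <- function(object, ...) plot_cohort(object, ...)

#' Plot a densitometry calibration fit
#'
#' @param object A `densitometry_calibration`.
#' @param ... Unused.
#' @return A ggplot object showing points and the through-origin fit line.
#' @export
autoplot.densitometry_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$amount,
                                            y = .data$band_intensity)) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "relative amount", y = "band intensity",
                  subtitle = sprintf("slope %.3g, R² %.4f", object$slope,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Bar plot of replicate-aggregated insertion
#'
#' @param summary Tibble from [run_insertion()]'s summary (or
#'   [aggregate_insertion()] with a `sample_id` column added).
#' @return A ggplot object: mean %insertion per sample with SEM error bars.
#' @export
plot_insertion <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$sample_id,
                                        y = .data$mean_insertion)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_insertion - .data$sem,
                                        ymax = .data$mean_insertion + .data$sem),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "% insertion (mean ± SEM)") +
    ggplot2::theme_minimal()
}
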