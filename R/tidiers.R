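# broom-style tidiers and ggplot2 autoplot methods for the package's result
# objects: solved spine states, calibrations, angle tables and mobility
# comparisons.

#' @exportS3Method generics::tidy
tidy.lumbokin_spine_state <- function(x, ...) {
  tibble::tibble(
    level = x$levels,
    ux_mm = x$q[1, ], uy_mm = x$q[2, ], uz_mm = x$q[3, ],
    flex_deg = rad2deg(x$q[4, ]),
    latbend_deg = rad2deg(x$q[5, ]),
    axrot_deg = rad2deg(x$q[6, ]),
    bulge_mm = x$b,
    nucleus_volume_change = x$e_v
  )
}

#' @exportS3Method generics::glance
glance.lumbokin_spine_state <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    residual = x$residual,
    iterations = x$iterations,
    load_steps = x$load_steps,
    energy_J = x$energy_nmm / 1000,
    movement = x$loadcase$movement %||% NA_character_,
    preload_N = x$loadcase$preload
  )
}

#' @exportS3Method generics::tidy
tidy.lumbokin_calibration <- function(x, ...) {
  x$magnitudes
}

#' @exportS3Method generics::glance
glance.lumbokin_calibration <- function(x, ...) {
  tibble::tibble(
    movement = x$movement,
    achieved_L1_deg = x$achieved$cumulative_deg[1],
    target_L1_deg = x$targets[1],
    max_residual_deg = max(abs(x$residual_deg)),
    total_work_J = x$energy_J,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Plot an angle table
#'
#' Cumulative vertebra-versus-sacrum angles by level, optionally with a
#' radiological mean +/- SD band.
#'
#' @param object A `lumbokin_angle_table`.
#' @param cohort Optional cohort statistics table (`mean_deg`, `sd_deg`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lumbokin_angle_table <- function(object, cohort = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$vertebra <- factor(df$vertebra, levels = c("L5", "L4", "L3", "L2", "L1"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$vertebra,
                                        y = .data$cumulative_deg, group = 1))
  if (!is.null(cohort)) {
    cf <- tibble::as_tibble(cohort)
    cf$vertebra <- factor(cf$vertebra, levels = levels(df$vertebra))
    p <- p +
      ggplot2::geom_ribbon(
        data = cf,
        ggplot2::aes(x = .data$vertebra, group = 1,
                     ymin = .data$mean_deg - .data$sd_deg,
                     ymax = .data$mean_deg + .data$sd_deg),
        inherit.aes = FALSE, alpha = 0.25) +
      ggplot2::geom_line(
        data = cf,
        ggplot2::aes(x = .data$vertebra, y = .data$mean_deg, group = 1),
        inherit.aes = FALSE, linetype = "dashed")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "cumulative angle vs sacrum (deg)",
                  title = unique(df$movement))
}

#' Plot a mobility comparison
#'
#' Healthy versus degenerated cumulative angles per vertebra.
#'
#' @param object A `lumbokin_mobility` tibble from [run_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lumbokin_mobility <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("healthy_deg", "degenerated_deg"),
                            names_to = "model", values_to = "angle_deg")
  df$model <- sub("_deg$", "", df$model)
  df$vertebra <- factor(df$vertebra, levels = c("L5", "L4", "L3", "L2", "L1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vertebra, y = .data$angle_deg,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cumulative angle (deg)",
                  title = paste0(unique(df$movement), ": healthy vs degenerated"))
}

#' Plot the global mobility report
#'
#' @param report A [global_mobility_report()] tibble.
#' @return A ggplot object of percent mobility increases by movement.
#' @export
plot_mobility_report <- function(report) {
  report$movement <- factor(report$movement, levels = report$movement)
  ggplot2::ggplot(report, ggplot2::aes(x = .data$movement,
                                       y = .data$percent_increase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "global mobility increase (%)",
                  title = "L5-S1 degeneration: mobility change at L1")
}
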