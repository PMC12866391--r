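#' Plot VOI-level time-activity curves
#'
#' Mean curve per VOI with a +/- 1 population-SD ribbon.
#'
#' @param object A `tac_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tac_matrix <- function(object, ...) {
  df <- voi_mean_tacs(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$midpoint_min, y = .data$mean_suv,
    colour = .data$voi, fill = .data$voi
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_suv - .data$sd_suv,
                   ymax = .data$mean_suv + .data$sd_suv),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time post-injection (min)", y = "SUV",
                  colour = "VOI", fill = "VOI") +
    ggplot2::theme_minimal()
}

#' Plot averaged cluster time-activity curves
#'
#' @param object A `cluster_report`.
#' @param ... Unused.
#' @return A ggplot of the averaged cluster TACs (+/- 1 SD ribbon),
#'   coloured by the cluster's majority VOI.
#' @export
autoplot.cluster_report <- function(object, ...) {
  df <- left_join(object$avg_tacs,
                  object$clusters[, c("cluster", "majority_voi")],
                  by = "cluster")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$midpoint_min, y = .data$mean_suv,
    group = .data$cluster, colour = .data$majority_voi
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_suv - .data$sd_suv,
                   ymax = .data$mean_suv + .data$sd_suv,
                   fill = .data$majority_voi),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time post-injection (min)", y = "SUV",
                  colour = "Majority VOI", fill = "Majority VOI") +
    ggplot2::theme_minimal()
}

#' Cluster composition bar chart
#'
#' Stacked per-cluster composition by source VOI.
#'
#' @param report A `cluster_report`.
#' @return A ggplot.
#' @export
plot_composition <- function(report) {
  stopifnot(inherits(report, "cluster_report"))
  ggplot2::ggplot(report$composition, ggplot2::aes(
    x = factor(.data$cluster), y = .data$fraction, fill = .data$voi
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Cluster", y = "Fraction of voxels", fill = "VOI") +
    ggplot2::theme_minimal()
}

#' Biodistribution bar chart
#'
#' Mean SUVmax and SUVmean per tissue with SD error bars, the standard
#' biodistribution display.
#'
#' @param summary A [biodistribution_summary()] table.
#' @return A ggplot.
#' @export
plot_biodistribution <- function(summary) {
  long <- dplyr::bind_rows(
    tibble(label = summary$label, metric = "SUVmax",
           mean = summary$suv_max_mean, sd = summary$suv_max_sd),
    tibble(label = summary$label, metric = "SUVmean",
           mean = summary$suv_mean_mean, sd = summary$suv_mean_sd)
  )
  long$label <- factor(long$label, levels = summary$label)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$mean,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "SUV", fill = NULL) +
    ggplot2::theme_minimal()
}
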