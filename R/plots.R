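#' Plot aggregated group statistics
#'
#' Draws the four traffic-organization statistics (group-size distribution;
#' laden proportion by group size, by within-group position; laden-led
#' proportion by size) as replicate means with min--max envelopes, faceted
#' on the statistic.
#'
#' @param x An `ant_experiment` or `replicate_aggregate`.
#' @param max_bin Truncate the x-axes at this bin to keep sparse tails
#'   readable (`Inf` keeps everything).
#' @return A ggplot object.
#' @export
plot_group_statistics <- function(x, max_bin = 30) {
  agg <- if (inherits(x, "ant_experiment")) x$aggregate else x
  stopifnot(inherits(agg, "replicate_aggregate"))
  panels <- dplyr::bind_rows(
    agg$size_distribution |>
      dplyr::transmute(
        statistic = "group size distribution",
        bin = .data$N, mean = .data$mean, min = .data$min, max = .data$max
      ),
    agg$prop_laden_by_size |>
      dplyr::transmute(
        statistic = "prop. laden by group size N",
        bin = .data$N, mean = .data$mean, min = .data$min, max = .data$max
      ),
    agg$prop_laden_by_position |>
      dplyr::transmute(
        statistic = "prop. laden at position P",
        bin = .data$P, mean = .data$mean, min = .data$min, max = .data$max
      ),
    agg$prop_led_by_laden |>
      dplyr::transmute(
        statistic = "prop. of size-N groups led by laden",
        bin = .data$N, mean = .data$mean, min = .data$min, max = .data$max
      )
  ) |>
    dplyr::filter(.data$bin <= max_bin)
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min, ymax = .data$max),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "firebrick") +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$mean),
      colour = "firebrick", size = 0.8
    ) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(
      x = "group size N / position P", y = "proportion",
      title = "Traffic group statistics (replicate mean, min-max envelope)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot central-zone proportions by particle type
#'
#' Boxplots of the per-replicate proportion of each particle type crossing
#' in the central zone of the wide trail -- the lane-segregation signature
#' (laden > outbound > unladen under the turning rule).
#'
#' @param x A wide-trail `ant_experiment`.
#' @return A ggplot object.
#' @export
plot_zone_proportions <- function(x) {
  stopifnot(inherits(x, "ant_experiment"))
  per_rep <- tidy(x)
  cols <- grep("^prop_central_", names(per_rep), value = TRUE)
  if (length(cols) == 0) {
    abort("no zone proportions: run a wide-trail experiment first")
  }
  long <- per_rep |>
    tidyr::pivot_longer(
      dplyr::all_of(cols),
      names_to = "type", names_prefix = "prop_central_",
      values_to = "prop_central"
    ) |>
    dplyr::mutate(type = factor(.data$type, levels = c("L", "O", "U")))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$type, y = .data$prop_central)
  ) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "particle type", y = "proportion crossing in central zone",
      title = sprintf(
        "Lane segregation (%s, %d replicates)",
        x$spec$name, x$spec$n_replicates
      )
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_group_statistics `autoplot()` draws the zone
#'   proportions for wide-trail experiments and the group statistics
#'   otherwise.
#' @param object An `ant_experiment`.
#' @param ... Unused.
#' @export
autoplot.ant_experiment <- function(object, ...) {
  if (object$spec$config$geometry == "wide" &&
      !is.null(object$aggregate$zone_props)) {
    plot_zone_proportions(object)
  } else {
    plot_group_statistics(object)
  }
}

#' @describeIn plot_group_statistics `autoplot()` on a single run shows the
#'   crossing raster: time against signed direction, coloured by type.
#' @export
autoplot.trail_run <- function(object, ...) {
  log <- object$crossings
  if (nrow(log) == 0) abort("no crossings to plot")
  ggplot2::ggplot(
    log,
    ggplot2::aes(
      x = .data$time_s, y = .data$direction, colour = .data$type
    )
  ) +
    ggplot2::geom_jitter(height = 0.15, width = 0, size = 0.4, alpha = 0.6) +
    ggplot2::scale_y_continuous(
      breaks = c(-1, 1), labels = c("inbound", "outbound")
    ) +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = "Midpoint crossings", colour = "type"
    ) +
    ggplot2::theme_minimal()
}
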