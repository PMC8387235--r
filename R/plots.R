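#' Plot a cage session
#'
#' Trajectories of both animals with the nest circle and detected/scripted
#' chase intervals marked along the time axis.
#'
#' @param object A `cage_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cage_session <- function(object, ...) {
  nest <- object$nest
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 120)) |>
    dplyr::mutate(x_cm = nest$center[1] + nest$radius_cm * cos(.data$theta),
                  y_cm = nest$center[2] + nest$radius_cm * sin(.data$theta))
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(.data$x_cm, .data$y_cm,
                               colour = .data$animal)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x_cm, .data$y_cm),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a modulation scan
#'
#' Per-unit modulation percentages, filled when the unit passed the
#' family-wise FDR flag, split by family.
#'
#' @param object A `modulation_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.modulation_scan <- function(object, ...) {
  r <- dplyr::arrange(object$results, .data$m_obs) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  significant = .data$direction %in%
                    c("activated", "suppressed"))
  ggplot2::ggplot(r, ggplot2::aes(.data$rank, .data$m_obs,
                                  fill = .data$significant)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "unit (sorted)",
                  y = sprintf("modulation during %s (%%)",
                              object$behaviour)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier style retrieval-onset curves
#'
#' Cumulative fraction of subjects having reached retrieval onset by each
#' day, per condition.
#'
#' @param onsets Output of [retrieval_onset()] joined with a `condition`
#'   column.
#' @return A ggplot.
#' @export
plot_onset_curves <- function(onsets) {
  stopifnot(all(c("onset_day", "censored", "condition") %in% names(onsets)))
  max_day <- max(onsets$last_day)
  curves <- onsets |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      tibble(condition = g$condition[1], day = 0:max_day,
             frac = vapply(0:max_day, function(d)
               mean(!g$censored & g$onset_day <= d), numeric(1)))
    }) |>
    purrr::list_rbind()
  ggplot2::ggplot(curves, ggplot2::aes(.data$day, .data$frac,
                                       colour = .data$condition)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(x = "day", y = "cumulative fraction retrieving") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
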