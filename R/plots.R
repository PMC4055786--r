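#' Plot a simulated trajectory
#'
#' Line plot of every state/output series over time; series are pivoted long
#' and coloured by name. For population runs (many per-subject columns) pass
#' a subset via `series`.
#'
#' @param object A `pk_trajectory`.
#' @param series Optional character vector of columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_trajectory
#' @export
autoplot.pk_trajectory <- function(object, series = NULL, ...) {
  cols <- series %||% setdiff(names(object), "time")
  long <- tidyr::pivot_longer(object[, c("time", cols)], -"time",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "amount / concentration", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot flare-free fraction curves
#'
#' Step curves of the per-arm flare-free fraction over the visit schedule.
#'
#' @param object A `flare_trial` or list of them (replicates are overlaid
#'   with transparency).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flare_trial
#' @export
autoplot.flare_trial <- function(object, ...) {
  curves <- flare_free_curves(object)
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time, .data$flare_free,
                               colour = factor(.data$arm),
                               group = interaction(.data$replicate, .data$arm))) +
    ggplot2::geom_step(alpha = if (max(curves$replicate) > 1) 0.3 else 1) +
    ggplot2::scale_colour_manual(values = c(`1` = "black", `2` = "red"),
                                 labels = c("continued", "withdrawn")) +
    ggplot2::labs(x = "time (days)", y = "flare-free fraction",
                  colour = "arm") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table
#'
#' Replicate success-percentage curves against dose, overlaid.
#'
#' @param object A `bp_dose_response` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bp_dose_response
#' @export
autoplot.bp_dose_response <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$dose, .data$success_percent,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "dose (mg)", y = "% patients successful") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot a least-squares fit
#'
#' Observed points with the fitted model curve.
#'
#' @param object A `pk_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_fit
#' @export
autoplot.pk_fit <- function(object, ...) {
  fitted <- fitted_observations(object)
  ggplot2::ggplot(fitted, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time", y = "observed / fitted") +
    ggplot2::theme_minimal()
}
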