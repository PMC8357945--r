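#' Plot a hypnogram
#'
#' Step trace of the vigilance state over Zeitgeber time, wake on top and
#' REM at the bottom, as hypnograms are conventionally drawn.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psg_hypnogram
#' @export
autoplot.psg_hypnogram <- function(object, ...) {
  df <- tibble::tibble(
    zt_h = object$zt_seconds / 3600,
    level = 4 - as.integer(object$state) # W=3, N=2, R=1
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zt_h, y = .data$level)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = 3:1, labels = c("Wake", "NREM", "REM"),
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = NULL,
                  title = attr(object, "animal_id") %||% NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.psg_hypnogram
#' @param x A [hypnogram()].
#' @param y Ignored.
#' @export
plot.psg_hypnogram <- function(x, y, ...) print(autoplot.psg_hypnogram(x, ...))

#' Plot per-epoch band powers
#'
#' Log-scale traces of the four EEG band powers, the sigma*theta product and
#' the EMG power over Zeitgeber time, faceted by channel.
#'
#' @param object A `psg_bands_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psg_bands_series
#' @export
autoplot.psg_bands_series <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      cols = c("delta", "theta", "sigma", "beta", "sigma_theta", "emg_power"),
      names_to = "channel", values_to = "power"
    )
  long$channel <- factor(long$channel, levels = c(
    "delta", "theta", "sigma", "beta", "sigma_theta", "emg_power"
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$zt_seconds / 3600,
                                     y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "power (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot hourly sleep dynamics
#'
#' Hourly wake/NREM/REM totals and, when present, the relative NREM-delta
#' power from [hourly_profiles()].
#'
#' @param hourly Tibble from [hourly_profiles()].
#' @return A ggplot.
#' @export
plot_hourly <- function(hourly) {
  long <- hourly |>
    tidyr::pivot_longer(cols = c("wake_s", "nrem_s", "rem_s"),
                        names_to = "state", values_to = "seconds")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hour, y = .data$seconds / 60,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "hour from ZT 0", y = "minutes per hour",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
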