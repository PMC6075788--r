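#' Plot a time-resolved noise ceiling
#'
#' Ribbon between the lower (leave-one-out) and upper (vs group mean)
#' bounds of the noise ceiling over time.
#'
#' @param ceiling Tibble from [noise_ceiling_series()].
#' @return A ggplot object.
#' @export
plot_noise_ceiling <- function(ceiling) {
  df <- ceiling[!is.na(ceiling$lower), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper)) +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = "Spearman correlation",
                  title = "Noise ceiling") +
    ggplot2::theme_minimal()
}

#' @export
glance.encoding_trace <- function(x, ...) {
  df <- x[!is.na(x$r2), ]
  peak <- df[which.max(df$r2), ]
  tibble(
    n_units = length(unique(x$unit)),
    n_times = length(unique(x$time)),
    peak_r2 = peak$r2,
    peak_time_ms = peak$time,
    peak_layer = peak$layer,
    n_significant = sum(x$sig, na.rm = TRUE)
  )
}
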