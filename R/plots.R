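# ggplot2 views of the main result types.

#' @export
autoplot.ecg_record <- function(object, leads = NULL, ...) {
  nms <- lead_names(object)
  if (!is.null(leads)) nms <- intersect(nms, leads)
  long <- tidyr::pivot_longer(tibble::as_tibble(unclass(object))[c("time", nms)],
                              -"time", names_to = "lead", values_to = "mV")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)")
}

#' @export
autoplot.band_power_series <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frame_time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$power), linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "integrated band power")
  if ("envelope" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$envelope),
                                colour = "firebrick", linewidth = 0.3)
  }
  p
}

#' @export
autoplot.gabor_spectrogram <- function(object, max_freq = 50, ...) {
  keep <- object$freqs <= max_freq
  d <- expand.grid(frame_time = object$frame_times,
                   freq = object$freqs[keep])
  d$power <- as.vector(object$power[, keep])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame_time, y = .data$freq,
                                  fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' Poincare plot of an NN-interval series
#'
#' @param rr an `rr_series` (or numeric intervals, ms).
#' @param ... ignored.
#' @return a ggplot.
#' @export
plot_poincare <- function(rr, ...) {
  iv <- if (is.data.frame(rr)) rr$interval_ms else as.numeric(rr)
  d <- tibble::tibble(x = iv[-length(iv)], y = iv[-1L])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(RR[n] ~ "(ms)"), y = expression(RR[n + 1] ~ "(ms)"))
}
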