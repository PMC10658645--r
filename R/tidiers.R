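# broom-style tidiers and ggplot2 autoplot methods

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_point
#'   labs scale_fill_viridis_c facet_wrap coord_equal theme_minimal
#' @export
ggplot2::autoplot

#' Tidy a spectral fit
#'
#' @param x an `mrsi_fit`
#' @param ... unused
#' @return tibble with one row per resonance: fitted amplitude, frequency,
#'   linewidth, phase and their CRLBs
#' @method tidy mrsi_fit
#' @export
tidy.mrsi_fit <- function(x, ...) {
  as_tibble(x)
}

#' One-row fit summary
#'
#' @param x an `mrsi_fit`
#' @param ... unused
#' @return tibble with `noise_sd`, `residual_norm`, `n_points`, `snr_pcr`
#'   (NA if the model has no PCr line)
#' @method glance mrsi_fit
#' @export
glance.mrsi_fit <- function(x, ...) {
  tibble(
    noise_sd = attr(x, "noise_sd"),
    residual_norm = attr(x, "residual_norm"),
    n_points = length(attr(x, "fid")),
    snr_pcr = if ("PCr" %in% x$name) compute_snr(x, "PCr") else NA_real_
  )
}

#' Tidy compartment spectra into long form
#'
#' @param x a `compartment_spectra`
#' @param ... unused
#' @return tibble with `compartment`, `frequency_hz`, `real`, `imag`,
#'   `magnitude`
#' @method tidy compartment_spectra
#' @export
tidy.compartment_spectra <- function(x, ...) {
  n <- ncol(x$spectra)
  freq <- spectral_axis_hz(n, x$dwell_s)
  ord <- order(freq)
  purrr::map_dfr(seq_along(x$compartment_ids), function(c) {
    sp <- x$spectra[c, ord]
    tibble(
      compartment = names(x$compartment_ids)[c],
      frequency_hz = freq[ord],
      real = Re(sp), imag = Im(sp), magnitude = Mod(sp)
    )
  })
}

# Frequency axis of an N-point spectrum under the package fft convention.
spectral_axis_hz <- function(n, dwell_s) {
  f <- (seq_len(n) - 1) / (n * dwell_s)
  f[f >= 1 / (2 * dwell_s)] <- f[f >= 1 / (2 * dwell_s)] - 1 / dwell_s
  f
}

#' @method autoplot compartment_spectra
#' @export
autoplot.compartment_spectra <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$frequency_hz, y = .data$real,
               colour = .data$compartment)) +
    geom_line() +
    ggplot2::scale_x_reverse() +
    labs(x = "frequency offset from PCr (Hz)", y = "signal (a.u.)",
         colour = "compartment") +
    theme_minimal()
}

#' @method autoplot mrsi_fit
#' @export
autoplot.mrsi_fit <- function(object, ...) {
  fid <- attr(object, "fid")
  fitted <- attr(object, "fitted")
  dwell <- attr(object, "dwell_s")
  n <- length(fid)
  freq <- spectral_axis_hz(n, dwell)
  ord <- order(freq)
  df <- dplyr::bind_rows(
    tibble(frequency_hz = freq[ord], value = Re(fft(fid)[ord]),
           series = "data"),
    tibble(frequency_hz = freq[ord], value = Re(fft(fitted)[ord]),
           series = "fit")
  )
  ggplot(df, aes(x = .data$frequency_hz, y = .data$value,
                 colour = .data$series)) +
    geom_line() +
    ggplot2::scale_x_reverse() +
    labs(x = "frequency offset from PCr (Hz)", y = "signal (a.u.)") +
    theme_minimal()
}

#' @method autoplot srf_map
#' @export
autoplot.srf_map <- function(object, slice = NULL, ...) {
  g <- object$eval_grid_shape
  if (is.null(slice)) slice <- ceiling(g[3] / 2)
  m <- Mod(object$values[, , slice])
  df <- tidyr::expand_grid(y = seq_len(g[2]), x = seq_len(g[1]))
  df$value <- as.vector(m) / max(Mod(object$values)) * 100
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "% of max") +
    coord_equal() +
    labs(title = sprintf("SRF (%s), slice %d", object$variant, slice)) +
    theme_minimal()
}

#' @method autoplot pe_scheme
#' @export
autoplot.pe_scheme <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$kx, y = .data$ky, size = .data$repeats)) +
    geom_point(alpha = 0.6) +
    facet_wrap(~ kz, labeller = ggplot2::label_both) +
    labs(x = "kx (cycles/FOV)", y = "ky (cycles/FOV)", size = "repeats") +
    theme_minimal()
}
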