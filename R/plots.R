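#' @importFrom graphics par image lines legend matplot abline
NULL

#' Plot a sampled waveform
#'
#' Two panels: RF amplitude and gradient versus time.
#'
#' @param x a [sampled_waveform()]
#' @param ... passed to [plot()]
#' @export
plot.sampled_waveform <- function(x, ...) {
  tm <- (seq_along(x$rf_amplitude) - 0.5) * x$dt / 1000
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(tm, x$rf_amplitude, type = "l", xlab = "time (ms)",
       ylab = expression(B[1] ~ (mu * T)), ...)
  plot(tm, x$gradient, type = "l", xlab = "time (ms)",
       ylab = "gradient (mT/m)", ...)
  invisible(x)
}

#' Plot a velocity waveform
#'
#' @param x a `velocity_waveform`
#' @param ... passed to [plot()]
#' @export
plot.velocity_waveform <- function(x, ...) {
  plot(x$time, x$samples, type = "l", xlab = "time (s)",
       ylab = "velocity (cm/s)", ...)
  abline(h = mean(x$samples), lty = 2)
  invisible(x)
}

#' Plot labeling efficiency across the flow ensemble
#'
#' Shift-averaged labeling efficiency per streamline fraction, one line per
#' off-resonance value.
#'
#' @param x an `efficiency_result`
#' @param ... passed to [matplot()]
#' @export
plot.efficiency_result <- function(x, ...) {
  a <- apply(x$alpha, c(1, 3), mean)            # db0 x streamline
  matplot(x$ensemble$fractions, t(a), type = "l", lty = 1,
          xlab = "streamline fraction of peak velocity",
          ylab = expression(alpha), ...)
  legend("bottomright", legend = paste0(x$db0_values, " Hz"),
         col = seq_along(x$db0_values), lty = 1, cex = 0.7)
  invisible(x)
}

#' Plot a static-tissue response
#'
#' Raw and slice-profile-convolved control-label difference, with the
#' inclusion threshold marked.
#'
#' @param x a `static_response`
#' @param threshold constraint threshold to mark
#' @param ... passed to [plot()]
#' @export
plot.static_response <- function(x, threshold = 0.001, ...) {
  plot(x$positions, x$delta_mz, type = "l", col = "grey60",
       xlab = "position (cm)", ylab = expression(Delta * M[z] / M[0]), ...)
  lines(x$positions, x$convolved, col = "black")
  abline(h = c(-threshold, threshold), lty = 3)
  abline(v = c(-1.8, 1.8), lty = 3, col = "red")
  legend("topright", c("raw", "convolved"), col = c("grey60", "black"),
         lty = 1, cex = 0.7)
  invisible(x)
}

#' Plot an inversion-efficiency map
#'
#' @param x an `inversion_map`
#' @param ... passed to [image()]
#' @export
plot.inversion_map <- function(x, ...) {
  image(x$b1_scales, x$db0_values, x$efficiency,
        xlab = "relative B1", ylab = "off-resonance (Hz)", ...)
  invisible(x)
}
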