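#' Reference pulsatile velocity waveform
#'
#' A parametric internal-carotid-like waveform describing the peak velocity
#' of a laminar flow profile over one cardiac cycle: a systolic peak of
#' 76 cm/s near 0.15 s, a small dicrotic bump near 0.40 s, and diastolic
#' decay to a 30 cm/s minimum, with a cycle-mean velocity of 40 cm/s. The
#' shape is a sum of two circularly wrapped Gaussians, min/max normalized so
#' the stated extremes are exact; the systolic width (0.074227 s) pins the
#' cycle mean to 40 cm/s. Substitute a digitized subject-specific waveform
#' via [velocity_waveform()] where one is available.
#'
#' @param period cardiac period, s
#' @param v_min,v_max minimum and maximum velocity of the peak streamline,
#'   cm/s
#' @param n number of samples over one period
#' @return a `velocity_waveform`: list with `period` (s), `time` (s) and
#'   `samples` (cm/s)
#' @export
reference_waveform <- function(period = 1.0, v_min = 30, v_max = 76,
                               n = 2000) {
  t <- seq(0, period, length.out = n + 1)[-(n + 1)]
  u <- t / period
  d1 <- pmin(abs(u - 0.15), 1 - abs(u - 0.15))
  d2 <- pmin(abs(u - 0.40), 1 - abs(u - 0.40))
  s <- exp(-d1^2 / (2 * 0.074227^2)) + 0.25 * exp(-d2^2 / (2 * 0.05^2))
  v <- v_min + (v_max - v_min) * (s - min(s)) / (max(s) - min(s))
  velocity_waveform(v, period)
}

#' Construct a velocity waveform from samples
#'
#' @param samples velocities over one period, cm/s; must be strictly positive
#' @param period cardiac period, s
#' @return a `velocity_waveform`
#' @export
velocity_waveform <- function(samples, period = 1.0) {
  if (any(samples <= 0)) stop("velocities must be strictly positive")
  structure(list(period = period,
                 time = seq(0, period, length.out = length(samples) + 1)[
                   -(length(samples) + 1)],
                 samples = samples),
            class = "velocity_waveform")
}

#' Read or write a velocity waveform as two-column tabular text
#'
#' Files carry a header and two columns: time (s) within one period and
#' velocity (cm/s).
#'
#' @param path file path
#' @return [read_velocity_waveform()] returns a `velocity_waveform`
#' @export
read_velocity_waveform <- function(path) {
  d <- read.csv(path)
  if (ncol(d) < 2) stop("expected two columns: time_s, velocity_cm_s")
  period <- d[[1]][nrow(d)] + diff(d[[1]])[1]
  velocity_waveform(d[[2]], period = period)
}

#' @param waveform a `velocity_waveform`
#' @rdname read_velocity_waveform
#' @export
write_velocity_waveform <- function(waveform, path) {
  write.csv(data.frame(time_s = waveform$time,
                       velocity_cm_s = waveform$samples),
            path, row.names = FALSE)
  invisible(path)
}

# periodic linear interpolation of the waveform onto a dt (us) raster
sample_velocity <- function(waveform, dt_us) {
  n_out <- round(waveform$period / (dt_us * 1e-6))
  tt <- (seq_len(n_out) - 1) * waveform$period / n_out
  v <- c(waveform$samples, waveform$samples[1])
  t_in <- c(waveform$time, waveform$period)
  approx(t_in, v, xout = tt)$y
}

#' Pulsatile laminar flow ensemble
#'
#' Laminar streamlines move at fixed fractions of the peak-velocity waveform
#' (streamline k's velocity is `fraction_k` times the waveform), with
#' fractions equally spaced between `frac_range[1]` and `frac_range[2]`.
#' Because the labeling efficiency depends on the cardiac phase at which a
#' spin crosses the labeling plane, the waveform is additionally applied at
#' `n_shifts` equally spaced circular time shifts. Streamline weights follow
#' the flow-weighted laminar distribution `p_k = V_k(0) / sum(V_l(0))`,
#' which reduces to the normalized fractions.
#'
#' @param waveform a `velocity_waveform`; default [reference_waveform()]
#' @param n_streamlines number of laminar streamlines
#' @param n_shifts number of circular waveform shifts
#' @param frac_range range of streamline velocity fractions
#' @return a `flow_ensemble`: list with `waveform`, `fractions`, `shifts`
#'   (fractions of the period) and `weights` (sum to 1)
#' @export
flow_ensemble <- function(waveform = reference_waveform(),
                          n_streamlines = 50, n_shifts = 10,
                          frac_range = c(0.1, 1.0)) {
  if (n_streamlines < 1 || n_shifts < 1)
    stop("n_streamlines and n_shifts must be >= 1")
  fr <- if (n_streamlines == 1) frac_range[2] else
    seq(frac_range[1], frac_range[2], length.out = n_streamlines)
  structure(list(waveform = waveform,
                 fractions = fr,
                 shifts = (seq_len(n_shifts) - 1) / n_shifts,
                 weights = fr / sum(fr)),
            class = "flow_ensemble")
}

#' @export
print.flow_ensemble <- function(x, ...) {
  cat(sprintf(
    "flow ensemble: %d streamlines (%.0f%%-%.0f%% of peak), %d shifts\n",
    length(x$fractions), 100 * min(x$fractions), 100 * max(x$fractions),
    length(x$shifts)))
  invisible(x)
}
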