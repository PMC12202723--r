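#' Propagate spin states through one hard-pulse step
#'
#' Rotates the magnetization about the effective field (RF + gradient x
#' position + off-resonance) for one time step `dt`, then applies T1/T2
#' relaxation for `dt` (operator splitting; the splitting error is second
#' order in `dt`). Accepts a single state `c(mx, my, mz)` or a batch as an
#' `n x 3` matrix; batching is element-wise.
#'
#' @param state numeric length-3 vector or `n x 3` matrix, fractions of M0
#' @param rf `c(amplitude_uT, phase_rad)`
#' @param gradient gradient amplitude, mT/m
#' @param position spin position, cm
#' @param settings a [sim_settings()] object (uses `dt`, `t1`, `t2`, `db0`)
#' @return the propagated state, same shape as the input
#' @export
bloch_propagate <- function(state, rf, gradient, position,
                            settings = sim_settings()) {
  m <- if (is.matrix(state)) state else matrix(state, ncol = 3)
  dt_s <- settings$dt * 1e-6
  bx <- rf[1] * cos(rf[2])
  by <- rf[1] * sin(rf[2])
  bz <- 10 * gradient * position + settings$db0 / GAMMA_HZ_PER_UT
  b <- sqrt(bx^2 + by^2 + bz^2)
  if (b > 0) {
    phi <- -2 * pi * GAMMA_HZ_PER_UT * b * dt_s
    nx <- bx / b; ny <- by / b; nz <- bz / b
    co <- cos(phi); si <- sin(phi); oc <- 1 - co
    dot <- m[, 1] * nx + m[, 2] * ny + m[, 3] * nz
    m <- cbind(m[, 1] * co + (ny * m[, 3] - nz * m[, 2]) * si + nx * dot * oc,
               m[, 2] * co + (nz * m[, 1] - nx * m[, 3]) * si + ny * dot * oc,
               m[, 3] * co + (nx * m[, 2] - ny * m[, 1]) * si + nz * dot * oc)
  }
  e1 <- exp(-dt_s / settings$t1)
  e2 <- exp(-dt_s / settings$t2)
  m <- cbind(m[, 1] * e2, m[, 2] * e2, 1 + (m[, 3] - 1) * e1)
  if (is.matrix(state)) m else drop(m)
}

#' Simulate a spin moving through a PCASL train
#'
#' Integrates the Bloch equations for a spin moving in one dimension through
#' the periodic pulse train, from the start to the end of the supplied
#' trajectory. The labeling plane is at z = 0; the trajectory must cross it.
#' The waveform is recycled periodically, so the train covers the whole
#' transit regardless of trajectory duration.
#'
#' @param train a [sampled_waveform()] (typically from [build_pcasl_train()]
#'   with two pulses, so the control phase alternation is periodic)
#' @param trajectory per-step positions in cm at the waveform raster, or a
#'   function of time (s) returning position (cm), evaluated at step starts
#' @param duration trajectory duration in s (required when `trajectory` is a
#'   function)
#' @param settings a [sim_settings()]
#' @return list with `state` (final `c(mx, my, mz)`), `crossing_time` (s, the
#'   final zero crossing of the labeling plane) and `end_time` (s)
#' @export
simulate_moving_spin <- function(train, trajectory, duration = NULL,
                                 settings = sim_settings()) {
  dt_s <- settings$dt * 1e-6
  if (is.function(trajectory)) {
    if (is.null(duration)) stop("duration required for a trajectory function")
    pos <- trajectory(seq(0, duration - dt_s / 2, by = dt_s))
  } else {
    pos <- trajectory
  }
  if (train$dt != settings$dt)
    stop("waveform raster and simulation dt differ")
  flips <- which(diff(pos >= 0) != 0)
  if (length(flips) == 0L) stop("trajectory never crosses the labeling plane")
  i <- flips[length(flips)]
  frac <- if (pos[i + 1] != pos[i]) -pos[i] / (pos[i + 1] - pos[i]) else 0
  crossing_time <- (i - 1 + frac) * dt_s
  m <- cpp_bloch_moving(train$rf_amplitude, train$rf_phase, train$gradient,
                        settings$dt, settings$t1, settings$t2, settings$db0,
                        pos, c(0, 0, 1))
  list(state = m, crossing_time = crossing_time,
       end_time = length(pos) * dt_s)
}

#' Longitudinal magnetization trace for a stationary spin
#'
#' Debug helper: simulates a stationary spin through a waveform and returns
#' the magnetization after every step.
#'
#' @param waveform a [sampled_waveform()]
#' @param position spin position, cm
#' @param settings a [sim_settings()]
#' @return a data.frame with `time_s`, `mx`, `my`, `mz`
#' @export
bloch_trace <- function(waveform, position = 0, settings = sim_settings()) {
  tr <- cpp_bloch_sim(waveform$rf_amplitude, waveform$rf_phase,
                      waveform$gradient, settings$dt, settings$t1,
                      settings$t2, settings$db0, position, c(0, 0, 1),
                      trace = TRUE)
  data.frame(time_s = seq_len(nrow(tr)) * settings$dt * 1e-6,
             mx = tr[, 1], my = tr[, 2], mz = tr[, 3])
}
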