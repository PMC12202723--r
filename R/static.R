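#' Bloch-simulated excitation slice profile
#'
#' Simulates the transverse-magnetization profile |Mxy(z)| of a 90-degree
#' Hann-windowed sinc excitation pulse (the imaging readout excitation) and
#' returns it as a unit-area convolution kernel on the static-tissue
#' position grid. The result is cached per parameter combination.
#'
#' @param dz kernel grid spacing, cm
#' @param z_max kernel half-width, cm
#' @param duration pulse duration, us
#' @param tbw time-bandwidth product
#' @param thickness slice thickness, cm
#' @param settings a [sim_settings()] (dt, relaxation)
#' @return list with `z` (cm) and `weights` (sum to 1)
#' @export
excitation_profile <- function(dz = 0.02, z_max = 4, duration = 2560,
                               tbw = 3.2, thickness = 0.5,
                               settings = sim_settings()) {
  key <- paste("exc", dz, z_max, duration, tbw, thickness, settings$dt,
               sep = "_")
  if (!is.null(.pcasl_cache[[key]])) return(.pcasl_cache[[key]])
  n <- round(duration / settings$dt)
  tt <- (seq_len(n) - 0.5) * settings$dt
  x <- tbw * (tt / duration - 0.5)            # sinc argument, cycles
  env <- 0.5 * (1 - cos(2 * pi * tt / duration))
  shape <- env * ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  # scale to a 90 degree on-resonance flip
  amp <- shape * (0.25 / GAMMA_HZ_PER_UT) / (sum(shape) * settings$dt * 1e-6)
  bw_hz <- tbw / (duration * 1e-6)
  g_ex <- bw_hz / (GAMMA_HZ_PER_UT * 10 * thickness)   # mT/m
  z <- seq(-z_max, z_max, by = dz)
  prof <- cpp_bloch_profile(amp, numeric(n), rep(g_ex, n), settings$dt,
                            settings$t1, settings$t2, 0, z)
  mxy <- sqrt(prof[, 1]^2 + prof[, 2]^2)
  out <- list(z = z, weights = mxy / sum(mxy))
  .pcasl_cache[[key]] <- out
  out
}

#' Static-tissue response to a PCASL labeling train
#'
#' Simulates stationary spins around the labeling plane through a labeling
#' train and returns the control-minus-label Mz difference, raw and after
#' convolution with the imaging excitation slice profile. The discrete pulse
#' train perturbs static tissue not only at the labeling plane but at
#' aliased labeling planes spaced `1/(gamma * G_ave * TR_PCASL)` apart; the
#' convolved response determines whether those perturbations reach the
#' imaging volume.
#'
#' The long train is propagated with a periodic-propagator acceleration: the
#' affine Bloch map of one two-pulse period is composed once per position
#' and raised to the number of periods by binary exponentiation
#' (`method = "brute"` steps through every sample instead and is provided as
#' a cross-check).
#'
#' The default time step here is 5 us rather than the 10 us used for moving
#' spins: a hard-pulse train sampled at dt aliases spins beyond the sampling
#' Nyquist position `1/(2 gamma G dt)` (about 15 cm for 8 mT/m at 10 us),
#' which contaminates the +/-16 cm window with spurious lobes for the
#' sharp-edged versed pulses. Halving dt moves the Nyquist position out of
#' the window and leaves the physical response, including the central-lobe
#' extent, unchanged.
#'
#' @param params a [pcasl_params()] object
#' @param label_duration labeling train duration, ms
#' @param settings a [sim_settings()]
#' @param positions static spin positions relative to the labeling plane, cm
#' @param verse apply minimum-SAR VERSE to the PCASL pulses?
#' @param limits [hardware_limits()]
#' @param profile excitation kernel from [excitation_profile()]; the default
#'   is computed on the same grid spacing as `positions`
#' @param method `"propagator"` (default) or `"brute"`
#' @return a `static_response`: list with `positions`, `delta_mz`,
#'   `convolved`, `params`
#' @export
static_response <- function(params, label_duration = 1800,
                            settings = sim_settings(dt = 5),
                            positions = seq(-16, 16, by = 0.02),
                            verse = TRUE, limits = hardware_limits(),
                            profile = NULL,
                            method = c("propagator", "brute")) {
  method <- match.arg(method)
  if (params$b1_ave == 0) {
    zero <- numeric(length(positions))
    return(structure(list(positions = positions, delta_mz = zero,
                          convolved = zero, params = params),
                     class = "static_response"))
  }
  lab <- params; lab$condition <- "label"
  ctl <- params; ctl$condition <- "control"
  wl <- build_pcasl_train(lab, 2, settings$dt, limits, verse)
  wc <- build_pcasl_train(ctl, 2, settings$dt, limits, verse)
  np <- length(wl$rf_amplitude)
  n_tot <- round(label_duration * 1000 / settings$dt)
  n_per <- n_tot %/% np
  rem <- n_tot %% np
  brute <- method == "brute"
  mzl <- cpp_static_mz(wl$rf_amplitude, wl$rf_phase, wl$gradient, settings$dt,
                       settings$t1, settings$t2, settings$db0, positions,
                       n_per, rem, brute)
  mzc <- cpp_static_mz(wc$rf_amplitude, wc$rf_phase, wc$gradient, settings$dt,
                       settings$t1, settings$t2, settings$db0, positions,
                       n_per, rem, brute)
  dmz <- mzc - mzl
  dz <- positions[2] - positions[1]
  if (is.null(profile)) profile <- excitation_profile(dz = dz,
                                                      settings = settings)
  w <- profile$weights
  if (length(w) %% 2 == 0) w <- c(w, 0)
  conv <- stats::convolve(dmz, rev(w), type = "open")
  half <- (length(w) - 1) / 2
  conv <- conv[(half + 1):(half + length(dmz))]
  structure(list(positions = positions, delta_mz = dmz, convolved = conv,
                 params = params),
            class = "static_response")
}

#' Central-lobe extent of a static-tissue response
#'
#' Scans outward from the labeling plane on the imaging-volume (positive)
#' side and returns the largest position at which the convolved |dMz| still
#' exceeds `threshold` before first falling below it.
#'
#' @param response a `static_response`
#' @param threshold fraction of M0
#' @return extent in cm (0 if the response is below threshold at the plane)
#' @export
lobe_extent <- function(response, threshold = 0.001) {
  pos <- response$positions >= 0
  z <- response$positions[pos]
  v <- abs(response$convolved[pos])
  below <- which(v < threshold)
  if (length(below) == 0L) return(max(z))
  if (below[1] == 1L) return(0)
  z[below[1] - 1L]
}

#' Static-tissue inclusion constraint
#'
#' TRUE iff the convolved perturbation stays at or below `threshold`
#' everywhere beyond `exclusion_distance` from the labeling plane (both
#' sides, so aliased labeling planes are caught wherever they fall).
#'
#' @param response a `static_response`
#' @param threshold fraction of M0
#' @param exclusion_distance cm
#' @return logical
#' @export
passes_constraint <- function(response, threshold = 0.001,
                              exclusion_distance = 1.8) {
  far <- abs(response$positions) > exclusion_distance
  all(abs(response$convolved[far]) <= threshold)
}

#' Aliased labeling-plane spacing
#'
#' Closed form `1/(gamma * G_ave * TR_PCASL)`: the spatial period at which
#' the discrete pulse train replicates the labeling plane.
#'
#' @param params a [pcasl_params()] object
#' @return spacing in cm (Inf when `g_ave = 0`)
#' @export
alias_spacing <- function(params) {
  if (params$g_ave == 0) return(Inf)
  1 / (GAMMA_HZ_PER_UT * 10 * params$g_ave * params$tr_pcasl * 1e-6)
}

#' Write a static-tissue response as tabular text
#'
#' @param response a `static_response`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_static_response <- function(response, path) {
  write.csv(data.frame(position_cm = response$positions,
                       delta_mz = response$delta_mz,
                       convolved_delta_mz = response$convolved),
            path, row.names = FALSE)
  invisible(path)
}
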