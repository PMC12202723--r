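#' Fixed-duration minimum-SAR VERSE transform
#'
#' Reshapes an RF pulse and its slice-select gradient in time so that the RF
#' amplitude is as constant as possible (constant B1 minimizes the RF energy
#' of a pulse at fixed duration and fixed flip) while preserving the
#' relationship between RF weighting and k-space position, and therefore the
#' on-resonance slice profile. The transform works in the cumulative
#' gradient-area (k-space) parameterization:
#'
#' 1. the per-k RF weighting `w(k) = B1(k) / g(k)` is computed from the input;
#' 2. for a trial constant amplitude `c`, the desired gradient is
#'    `g(k) = c / w(k)`, capped at the maximum gradient amplitude;
#' 3. forward/backward passes enforce slew-rate feasibility in k
#'    (`g' dg/dk <= slew`), with the boundary gradient pinned to the input's
#'    boundary values so the surrounding waveform (ramps, refocusing lobe)
#'    is untouched;
#' 4. `c` is adjusted by bisection until the total duration equals the input
#'    duration, then the result is resampled onto the raster.
#'
#' Where the slew or amplitude cap binds (always near the edges of a
#' windowed pulse, where `w -> 0`), the output RF is not constant; the energy
#' reduction achieved is reported as `energy_ratio`.
#'
#' @param waveform a [sampled_waveform()] covering exactly the RF pulse:
#'   strictly positive gradient, nonzero RF
#' @param target_duration pulse duration, us; must equal the input duration
#'   (only fixed-duration operation is supported) and defaults to it
#' @param limits [hardware_limits()]
#' @param n_k number of uniform k-space cells used internally
#' @return a list of class `verse_result` with `waveform` (the versed pulse,
#'   same raster and duration), `energy_ratio` (RF energy after / before,
#'   <= 1) and `iterations` (bisection iterations)
#' @export
verse_min_sar <- function(waveform, target_duration = NULL,
                          limits = hardware_limits(), n_k = 1024) {
  amp <- waveform$rf_amplitude
  ph <- waveform$rf_phase
  g <- waveform$gradient
  dt <- waveform$dt
  n <- length(amp)
  if (n == 0L || all(amp == 0)) stop("input RF pulse is zero")
  if (any(g <= 0)) stop("VERSE requires a strictly positive gradient")
  dur <- n * dt
  if (is.null(target_duration)) target_duration <- dur
  if (abs(target_duration - dur) > 1e-9)
    stop("only fixed-duration VERSE is supported: target_duration must ",
         "equal the input pulse duration")

  # fixed point: constant RF on a constant in-limit gradient
  if (diff(range(amp)) < 1e-12 * max(amp) && diff(range(g)) < 1e-12 * max(g) &&
      max(g) <= limits$max_grad + 1e-9) {
    return(structure(list(waveform = waveform, energy_ratio = 1,
                          iterations = 0L), class = "verse_result"))
  }

  # design with a 0.1% slew margin so the rastered result stays within the
  # true limit after resampling and renormalization
  s <- limits$max_slew / 1000 * 0.999        # mT/m per us
  gcap <- limits$max_grad
  k_nodes <- c(0, cumsum(g) * dt)            # mT/m us at sample boundaries
  K <- k_nodes[n + 1]
  k_mid <- (k_nodes[-1] + k_nodes[-(n + 1)]) / 2
  dk <- K / n_k
  kk <- (seq_len(n_k) - 0.5) * dk
  w <- approx(k_mid, amp / g, xout = kk, rule = 2)$y    # uT per (mT/m)
  ph_k <- approx(k_mid, ph, xout = kk, rule = 2)$y
  g_b0 <- g[1]; g_b1 <- g[n]

  g_of_c <- function(cc) {
    gd <- ifelse(w * gcap <= cc, gcap, cc / pmax(w, 1e-300))
    cpp_slew_pass(gd, g_b0, g_b1, s, dk)
  }
  dur_of_g <- function(gk) sum(dk / pmax(gk, 1e-12))

  # bracket: large c -> duration <= target
  c_hi <- max(amp)
  it <- 0L
  while (dur_of_g(g_of_c(c_hi)) > dur && it < 60L) {
    c_hi <- c_hi * 2; it <- it + 1L
  }
  if (dur_of_g(g_of_c(c_hi)) > dur)
    stop("VERSE failed to converge: cannot reach the target duration")
  c_lo <- 0
  iters <- it
  for (i in seq_len(200L)) {
    cc <- (c_lo + c_hi) / 2
    d <- dur_of_g(g_of_c(cc))
    if (d > dur) c_lo <- cc else c_hi <- cc
    iters <- iters + 1L
    if (abs(d - dur) < 1e-9 * dur) break
  }
  gk <- g_of_c(c_hi)
  gk <- gk * (dur_of_g(gk) / dur)            # exact duration

  # resample onto the raster
  t_nodes <- c(0, cumsum(dk / gk))
  t_nodes[n_k + 1] <- dur
  tm <- (seq_len(n) - 0.5) * dt
  k_t <- approx(t_nodes, c(0, seq_len(n_k)) * dk, xout = tm)$y
  g_out <- approx(kk, gk, xout = k_t, rule = 2)$y
  a_out <- approx(kk, w, xout = k_t, rule = 2)$y * g_out
  p_out <- approx(kk, ph_k, xout = k_t, rule = 2)$y
  # preserve the flip integral and the gradient area exactly
  a_out <- a_out * sum(amp) / sum(a_out)
  g_out <- g_out * sum(g) / sum(g_out)

  ratio <- sum(a_out^2) / sum(amp^2)
  if (ratio >= 1) {                          # no gain possible under limits
    return(structure(list(waveform = waveform, energy_ratio = 1,
                          iterations = iters), class = "verse_result"))
  }
  out <- sampled_waveform(dt, a_out, p_out, g_out)
  structure(list(waveform = out, energy_ratio = ratio, iterations = iters),
            class = "verse_result")
}

#' @export
print.verse_result <- function(x, ...) {
  cat(sprintf("VERSE result: energy ratio %.4f (%.1f%% RF power reduction)\n",
              x$energy_ratio, 100 * (1 - x$energy_ratio)))
  invisible(x)
}
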