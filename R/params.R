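#' PCASL pulse-train parameters
#'
#' The PCASL labeling train is parameterized by five quantities: the mean RF
#' amplitude over one inter-pulse period (`b1_ave`, uT), the RF pulse duration
#' (`t_rf`, us), the inter-pulse spacing (`tr_pcasl`, us), the slice-selective
#' gradient amplitude during the RF pulse (`g_max`, mT/m), and the mean
#' gradient amplitude over the period (`g_ave`, mT/m). The `condition`
#' distinguishes the label train (constant pulse-to-pulse RF phase, labeling
#' plane at z = 0) from the balanced control train (an additional pi phase on
#' every other RF pulse; identical gradients).
#'
#' `b1_ave` is the mean over the full inter-pulse period (not over the RF
#' pulse alone), so the nominal flip angle of each pulse is
#' `360 * gamma * b1_ave * tr_pcasl` degrees regardless of the RF duty cycle.
#'
#' @param b1_ave mean RF amplitude over one period, uT (>= 0)
#' @param t_rf RF pulse duration, us (0 < t_rf <= tr_pcasl)
#' @param tr_pcasl inter-RF-pulse spacing, us
#' @param g_max slice-selective gradient during the RF pulse, mT/m (> 0)
#' @param g_ave mean gradient over the period, mT/m (>= 0)
#' @param condition `"label"` or `"control"`
#' @return an object of class `pcasl_params`
#' @seealso [build_pcasl_period()], [pcasl_protocols()]
#' @export
pcasl_params <- function(b1_ave, t_rf, tr_pcasl, g_max, g_ave,
                         condition = c("label", "control")) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(b1_ave), length(b1_ave) == 1L,
            is.numeric(t_rf), is.numeric(tr_pcasl),
            is.numeric(g_max), is.numeric(g_ave))
  if (b1_ave < 0) stop("b1_ave must be >= 0")
  if (t_rf <= 0 || t_rf > tr_pcasl) stop("need 0 < t_rf <= tr_pcasl")
  if (g_max <= 0) stop("g_max must be > 0")
  if (g_ave < 0) stop("g_ave must be >= 0")
  structure(list(b1_ave = b1_ave, t_rf = t_rf, tr_pcasl = tr_pcasl,
                 g_max = g_max, g_ave = g_ave, condition = condition),
            class = "pcasl_params")
}

#' @export
print.pcasl_params <- function(x, ...) {
  cat(sprintf(
    "PCASL parameters (%s): B1ave %.3g uT, T_RF %g us, TR_PCASL %g us,\n",
    x$condition, x$b1_ave, x$t_rf, x$tr_pcasl))
  cat(sprintf("  Gmax %.3g mT/m, Gave %.3g mT/m (flip %.2f deg)\n",
              x$g_max, x$g_ave, flip_angle(x)))
  invisible(x)
}

#' Nominal per-pulse flip angle
#'
#' `360 * gamma * b1_ave * tr_pcasl` in degrees, with gamma = 42.577 MHz/T.
#'
#' @param params a [pcasl_params()] object
#' @return flip angle in degrees
#' @export
flip_angle <- function(params) {
  360 * GAMMA_HZ_PER_UT * params$b1_ave * params$tr_pcasl * 1e-6
}

#' Named PCASL protocol presets
#'
#' The four protocols compared throughout: the SNR-efficiency optimum, the
#' labeling-efficiency optimum, and a published 7 T protocol with and without
#' VERSE applied to its PCASL pulses. Each entry carries the parameter set and
#' the VERSE policy used when constructing its waveforms (the two optimized
#' protocols are always used with VERSE; the literature protocol was defined
#' without it).
#'
#' @return a named list; each element has fields `params` ([pcasl_params()])
#'   and `verse` (logical)
#' @export
pcasl_protocols <- function() {
  list(
    max_snr_efficiency = list(
      params = pcasl_params(0.6, 530, 1060, 5.5, 0.2), verse = TRUE),
    max_labeling_efficiency = list(
      params = pcasl_params(1.3, 400, 800, 8, 0.5), verse = TRUE),
    literature = list(
      params = pcasl_params(1.72, 300, 570, 5.9, 0.4), verse = FALSE),
    literature_verse = list(
      params = pcasl_params(1.72, 300, 570, 5.9, 0.4), verse = TRUE)
  )
}

#' Gradient hardware limits
#'
#' @param max_grad maximum gradient amplitude, mT/m
#' @param max_slew maximum slew rate, T/m/s
#' @return an object of class `hardware_limits`
#' @export
hardware_limits <- function(max_grad = 80, max_slew = 200) {
  stopifnot(max_grad > 0, max_slew > 0)
  structure(list(max_grad = max_grad, max_slew = max_slew),
            class = "hardware_limits")
}

#' Simulation settings for the Bloch engine
#'
#' Defaults are the study conditions for blood at 7 T: 10 us hard-pulse step,
#' T1 = 2.1 s, T2 = 0.06 s.
#'
#' @param dt time step, us
#' @param t1,t2 relaxation times, s
#' @param db0 off-resonance at the labeling plane, Hz
#' @return an object of class `sim_settings`
#' @export
sim_settings <- function(dt = 10, t1 = 2.1, t2 = 0.06, db0 = 0) {
  stopifnot(dt > 0, t1 > 0, t2 > 0)
  structure(list(dt = dt, t1 = t1, t2 = t2, db0 = db0),
            class = "sim_settings")
}
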