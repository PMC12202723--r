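#' PCASL parameter grid specification
#'
#' Defaults reproduce the study grid: TR_PCASL in {0.5, 0.6, 0.7, 0.8,
#' 1.06} ms, B1ave 0.1-2.0 uT in 0.1 uT steps, Gmax 3-15 mT/m in 0.5 mT/m
#' steps, Gave 0-2 mT/m in 0.1 mT/m steps, with T_RF fixed at half of
#' TR_PCASL (50 percent RF duty cycle): 52500 combinations.
#'
#' @param tr_pcasl inter-pulse spacings, us
#' @param b1_ave mean RF amplitudes, uT
#' @param g_max slice gradients, mT/m
#' @param g_ave mean gradients, mT/m
#' @param rf_duty RF duty cycle (T_RF = rf_duty * TR_PCASL)
#' @return a `grid_spec`
#' @export
grid_spec <- function(tr_pcasl = c(500, 600, 700, 800, 1060),
                      b1_ave = seq(0.1, 2.0, by = 0.1),
                      g_max = seq(3, 15, by = 0.5),
                      g_ave = seq(0, 2, by = 0.1),
                      rf_duty = 0.5) {
  if (!length(tr_pcasl) || !length(b1_ave) || !length(g_max) ||
      !length(g_ave)) stop("empty grid axis")
  structure(list(tr_pcasl = tr_pcasl, b1_ave = b1_ave, g_max = g_max,
                 g_ave = g_ave, rf_duty = rf_duty), class = "grid_spec")
}

#' Enumerate a parameter grid
#'
#' Cartesian product in deterministic order (`g_ave` varies fastest, then
#' `g_max`, `b1_ave`, `tr_pcasl`).
#'
#' @param spec a [grid_spec()]
#' @return a data.frame with columns `tr_pcasl`, `b1_ave`, `g_max`, `g_ave`,
#'   `t_rf`
#' @export
enumerate_grid <- function(spec = grid_spec()) {
  g <- expand.grid(g_ave = spec$g_ave, g_max = spec$g_max,
                   b1_ave = spec$b1_ave, tr_pcasl = spec$tr_pcasl,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("tr_pcasl", "b1_ave", "g_max", "g_ave")]
  g$t_rf <- spec$rf_duty * g$tr_pcasl
  rownames(g) <- NULL
  g
}

#' Gradient slew-rate screen of a parameter grid
#'
#' For every grid combination, constructs the PCASL period waveform, applies
#' the fixed-duration minimum-SAR VERSE transform, and checks the result
#' against the gradient hardware limits. Because the VERSE gradient solution
#' is invariant to the RF amplitude scale (only the pulse shape enters the
#' time reparameterization) and the versed pulse keeps the boundary
#' gradient at `g_max`, feasibility depends only on `(tr_pcasl, g_max,
#' g_ave)`; the screen evaluates each unique triple once and broadcasts
#' over `b1_ave`.
#'
#' Slew feasibility is validated on the analytic (pre-rasterized) waveform
#' segments: the versed gradient and the refocusing lobe are designed at the
#' slew limit, so testing the rastered samples would count quantization
#' noise on exactly-at-limit segments as violations.
#'
#' @param grid a data.frame from [enumerate_grid()]
#' @param dt raster, us
#' @param limits [hardware_limits()]
#' @param verse apply VERSE before checking (the screening condition)
#' @return logical vector, TRUE where the combination is feasible
#' @export
screen_slew <- function(grid, dt = 10, limits = hardware_limits(),
                        verse = TRUE) {
  key <- paste(grid$tr_pcasl, grid$g_max, grid$g_ave, sep = "|")
  uk <- !duplicated(key)
  feas <- logical(sum(uk))
  ukey <- key[uk]
  utr <- grid$tr_pcasl[uk]; ugm <- grid$g_max[uk]; uga <- grid$g_ave[uk]
  utf <- grid$t_rf[uk]
  for (i in seq_along(ukey)) {
    p <- pcasl_params(1, utf[i], utr[i], ugm[i], uga[i])
    feas[i] <- tryCatch({
      build_pcasl_period(p, dt, limits, verse = verse)  # errors if infeasible
      TRUE
    }, error = function(e) FALSE)
  }
  unname(feas[match(key, ukey)])
}

#' Static-tissue screen of one parameter combination
#'
#' @param params a [pcasl_params()] object
#' @param threshold perturbation threshold, fraction of M0
#' @param exclusion_distance cm
#' @param ... passed to [static_response()]
#' @return logical
#' @export
screen_static <- function(params, threshold = 0.001,
                          exclusion_distance = 1.8, ...) {
  passes_constraint(static_response(params, ...), threshold,
                    exclusion_distance)
}

#' Screen and rank a PCASL parameter grid
#'
#' Applies the screens in the study order -- gradient slew feasibility of
#' the versed waveforms first, then the static-tissue constraint -- and
#' computes the flow-weighted labeling efficiency, per-TR RF energy and
#' objective for the surviving combinations. Ranking objectives:
#' `snr_efficiency` = `alpha_final / sqrt(per-TR RF energy)` (the minimum TR
#' is SAR-limited and proportional to the per-TR RF energy), or
#' `labeling_efficiency` = `alpha_final`.
#'
#' The full study ensemble (50 streamlines x 10 shifts x 11 off-resonance
#' values) is expensive at grid scale; the default arguments use a reduced
#' ensemble suitable for interactive exploration, with the full ensemble
#' available through `ensemble`/`db0_values`.
#'
#' @param grid a data.frame from [enumerate_grid()], or a [grid_spec()]
#' @param objective ranking objective
#' @param ensemble a [flow_ensemble()]
#' @param db0_values off-resonance values, Hz
#' @param settings a [sim_settings()]
#' @param limits [hardware_limits()]
#' @param static_threshold,exclusion_distance static-tissue constraint
#' @param other_rf_energy fixed non-PCASL RF energy per TR added to the
#'   SNR-efficiency denominator, uT^2 s (0 ranks by PCASL power alone)
#' @param verse apply VERSE to the PCASL pulses
#' @param run_static,run_alpha stages to execute (both TRUE reproduces the
#'   full pipeline; disable for coarse exploration)
#' @return a data.frame (class `protocol_scores`), one row per grid point
#'   with `status` in included/slew_excluded/static_excluded, sorted by
#'   objective (ties broken on TR_PCASL desc, B1ave, Gmax, Gave asc)
#' @export
screen_and_rank <- function(grid = grid_spec(),
                            objective = c("snr_efficiency",
                                          "labeling_efficiency"),
                            ensemble = flow_ensemble(n_streamlines = 10,
                                                     n_shifts = 3),
                            db0_values = c(-50, 0, 50),
                            settings = sim_settings(),
                            limits = hardware_limits(),
                            static_threshold = 0.001,
                            exclusion_distance = 1.8,
                            other_rf_energy = 0,
                            verse = TRUE, run_static = TRUE,
                            run_alpha = TRUE) {
  objective <- match.arg(objective)
  if (inherits(grid, "grid_spec")) grid <- enumerate_grid(grid)
  n <- nrow(grid)
  status <- rep("included", n)
  ok <- screen_slew(grid, settings$dt, limits, verse)
  status[!ok] <- "slew_excluded"
  alpha <- rep(NA_real_, n)
  energy <- rep(NA_real_, n)
  for (i in which(ok)) {
    p <- pcasl_params(grid$b1_ave[i], grid$t_rf[i], grid$tr_pcasl[i],
                      grid$g_max[i], grid$g_ave[i])
    if (run_static &&
        !screen_static(p, static_threshold, exclusion_distance,
                       settings = settings, verse = verse,
                       limits = limits)) {
      status[i] <- "static_excluded"
      next
    }
    per <- build_pcasl_period(p, settings$dt, limits, verse)
    energy[i] <- rf_energy(per) / (p$tr_pcasl * 1e-6) + other_rf_energy
    if (run_alpha)
      alpha[i] <- alpha_final(p, ensemble, db0_values, settings, verse,
                              limits)$alpha_final
  }
  obj <- if (objective == "snr_efficiency") alpha / sqrt(energy) else alpha
  out <- cbind(grid, status = status, alpha_final = alpha,
               rf_energy_per_tr = energy, objective = obj)
  ord <- order(-replace(obj, is.na(obj), -Inf), -out$tr_pcasl, out$b1_ave,
               out$g_max, out$g_ave)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("protocol_scores", "data.frame")
  attr(out, "objective") <- objective
  out
}
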