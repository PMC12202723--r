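test_that("nominal flip angle follows 360*gamma*B1ave*TR for all presets", {
  # Table values: 9.7, 15.9, 15 degrees
  expected <- c(max_snr_efficiency = 9.7, max_labeling_efficiency = 15.9,
                literature = 15.0)
  for (nm in names(expected)) {
    p <- pcasl_protocols()[[nm]]$params
    expect_equal(flip_angle(p), expected[[nm]], tolerance = 0.005)
    # flip integral of the sampled waveform matches the closed form < 0.1%
    wf <- build_pcasl_period(p)
    flip_wf <- 360 * 42.577 * sum(wf$rf_amplitude) * wf$dt * 1e-6
    expect_equal(flip_wf, flip_angle(p), tolerance = 1e-3)
  }
})

test_that("period-mean gradient equals g_ave to raster precision", {
  combos <- list(c(0.6, 530, 1060, 5.5, 0.2), c(1.3, 400, 800, 8, 0.5),
                 c(1.72, 300, 570, 5.9, 0.4), c(0.5, 250, 500, 3, 0.0),
                 c(1.0, 400, 800, 4, 2.0))
  for (cc in combos) {
    p <- pcasl_params(cc[1], cc[2], cc[3], cc[4], cc[5])
    for (verse in c(FALSE, TRUE)) {
      wf <- build_pcasl_period(p, verse = verse)
      expect_equal(mean(wf$gradient), p$g_ave, tolerance = 1e-9)
      expect_true(all(wf$gradient[attr(wf, "pulse_idx")] > 0))
    }
  }
})

test_that("per-period RF energy of the Hann pulse matches the closed form", {
  # E = 1.5 * B1ave^2 * TR^2 / T_RF for a Hann envelope with period mean B1ave
  p <- pcasl_params(0.6, 530, 1060, 5.5, 0.2)
  wf <- build_pcasl_period(p)
  e_closed <- 1.5 * 0.6^2 * (1060e-6)^2 / 530e-6
  expect_equal(rf_energy(wf), e_closed, tolerance = 1e-10)
  expect_equal(e_closed, 1.145e-3, tolerance = 1e-3)
})

test_that("zero B1 gives an all-zero RF waveform with zero flip", {
  p <- pcasl_params(0, 400, 800, 8, 0.5)
  wf <- build_pcasl_period(p)
  expect_true(all(wf$rf_amplitude == 0))
  expect_equal(flip_angle(p), 0)
})

test_that("label and control trains differ only in RF phase", {
  p <- pcasl_protocols()$max_labeling_efficiency$params
  lab <- p; lab$condition <- "label"
  ctl <- p; ctl$condition <- "control"
  wl <- build_pcasl_train(lab, n_pulses = 4)
  wc <- build_pcasl_train(ctl, n_pulses = 4)
  expect_identical(wl$rf_amplitude, wc$rf_amplitude)
  expect_identical(wl$gradient, wc$gradient)
  expect_false(identical(wl$rf_phase, wc$rf_phase))
  # pi on every other pulse only
  n <- length(wl$rf_phase) / 4
  expect_true(all(wc$rf_phase[seq_len(n)] == 0))
  expect_true(all(wc$rf_phase[n + seq_len(n)] == pi))
})

test_that("infeasible refocusing geometry raises an explicit error", {
  # short TR, strong slice gradient, full rewind: lobe cannot fit
  p <- pcasl_params(1, 250, 500, 15, 0)
  expect_error(build_pcasl_period(p), "infeasible")
  expect_error(build_pcasl_period(pcasl_params(1, 333, 777, 5, 0.2)),
               "dt must divide")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(pcasl_params(-1, 400, 800, 8, 0.5), "b1_ave")
  expect_error(pcasl_params(1, 900, 800, 8, 0.5), "t_rf")
  expect_error(pcasl_params(1, 400, 800, 0, 0.5), "g_max")
  expect_error(pcasl_params(1, 400, 800, 8, -0.1), "g_ave")
})

test_that("hardware check reports amplitude and slew correctly", {
  # zero gradient: trivially passes
  wf0 <- sampled_waveform(10, rep(1, 10), numeric(10), numeric(10))
  expect_true(check_hardware(wf0)$pass)
  # ramp of 80 mT/m over 0.4 ms: slew exactly 200 T/m/s, boundary case passes
  n <- 40
  ramp <- 80 * (seq_len(n) - 0.5) / n
  wfr <- sampled_waveform(10, numeric(n), numeric(n), ramp)
  hw <- check_hardware(wfr)
  expect_equal(hw$max_slew, 200, tolerance = 1e-9)
  expect_true(hw$pass)
  # exceeding either limit fails
  expect_false(check_hardware(sampled_waveform(
    10, numeric(n), numeric(n), 1.1 * ramp))$pass)
  expect_error(check_hardware(sampled_waveform(10, numeric(0), numeric(0),
                                               numeric(0))), "empty")
})

test_that("waveform export writes two-column tabular text", {
  p <- pcasl_protocols()$max_snr_efficiency$params
  wf <- build_pcasl_period(p)
  pre <- file.path(tempdir(), "wf_test")
  files <- write_waveform(wf, pre)
  expect_true(all(file.exists(files)))
  rf <- read.csv(files[1])
  expect_equal(nrow(rf), length(wf$rf_amplitude))
  expect_named(rf, c("time_us", "rf_amplitude_uT", "rf_phase_rad"))
  unlink(files)
})
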