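test_that("zero B1 produces a null static response", {
  r <- static_response(pcasl_params(0, 400, 800, 8, 0.5))
  expect_true(all(r$delta_mz == 0))
  expect_true(all(r$convolved == 0))
  expect_true(passes_constraint(r))
  expect_equal(lobe_extent(r), 0)
})

test_that("periodic-propagator acceleration equals brute-force stepping", {
  p <- pcasl_protocols()$max_labeling_efficiency$params
  pos <- seq(-3, 3, by = 0.5)
  a <- static_response(p, label_duration = 120, positions = pos,
                       method = "propagator")
  b <- static_response(p, label_duration = 120, positions = pos,
                       method = "brute")
  expect_equal(a$delta_mz, b$delta_mz, tolerance = 1e-10)
})

test_that("perturbation lobes recur at the aliased labeling-plane spacing", {
  # the label comb recurs at dz = 1/(gamma*Gave*TR); the balanced control
  # (pi alternation, two-TR period) interleaves planes at half that spacing,
  # so control-label lobes appear at multiples of dz/2
  # zmin keeps the central lobe and its near sidelobes out of the search
  cases <- list(list(p = c(1.3, 400, 800, 8, 0.5), zmin = 2.0),
                list(p = c(1.0, 400, 800, 8, 1.0), zmin = 0.8))
  for (cc in cases) {
    p <- do.call(pcasl_params, as.list(cc$p))
    dz2 <- alias_spacing(p) / 2
    r <- static_response(p, positions = seq(-6.5, 6.5, by = 0.02))
    v <- abs(r$convolved); z <- r$positions
    pk <- which(diff(sign(diff(v))) < 0) + 1
    pk <- pk[v[pk] > 2e-4 & abs(z[pk]) > cc$zmin]
    expect_gt(length(pk), 0)
    off <- abs(z[pk] / dz2 - round(z[pk] / dz2))
    expect_true(all(off < 0.2))        # within 20% of a comb position
    expect_true(all(round(z[pk] / dz2) != 0))
  }
})

test_that("the central-lobe extent is stable under time-step halving", {
  p <- pcasl_protocols()$max_snr_efficiency$params
  pos <- seq(-4, 4, by = 0.02)
  e10 <- lobe_extent(static_response(p, settings = sim_settings(dt = 10),
                                     positions = pos))
  e5 <- lobe_extent(static_response(p, settings = sim_settings(dt = 5),
                                    positions = pos))
  expect_equal(e5, e10, tolerance = 0.05 / e10)
})

test_that("central lobe narrows as TR_PCASL increases", {
  ext <- sapply(c(500, 1060), function(tr) {
    p <- pcasl_params(0.6, tr / 2, tr, 5.5, 0.2)
    lobe_extent(static_response(p, positions = seq(-6, 6, by = 0.02)))
  })
  expect_gt(ext[1], ext[2])
})

test_that("inclusion constraint inspects both sides beyond the threshold", {
  z <- seq(-16, 16, by = 0.02)
  mk <- function(conv) structure(list(positions = z, delta_mz = conv,
                                      convolved = conv,
                                      params = NULL), class = "static_response")
  expect_true(passes_constraint(mk(numeric(length(z)))))
  bump <- 0.002 * exp(-(z - 3)^2)
  expect_false(passes_constraint(mk(bump)))
  central <- 0.5 * exp(-(z / 0.5)^2)  # large but confined inside 1.8 cm
  expect_true(passes_constraint(mk(central)))
})

test_that("excitation kernel is unit-area with the nominal slice width", {
  k <- excitation_profile()
  expect_equal(sum(k$weights), 1, tolerance = 1e-12)
  fwhm <- diff(range(k$z[k$weights > max(k$weights) / 2]))
  expect_equal(fwhm, 0.5, tolerance = 0.25)   # 5 mm slice
  expect_true(all(k$weights >= 0))
})

test_that("static responses serialize to tabular text", {
  p <- pcasl_protocols()$max_snr_efficiency$params
  r <- static_response(p, label_duration = 50,
                       positions = seq(-2, 2, by = 0.02))
  f <- file.path(tempdir(), "static.csv")
  write_static_response(r, f)
  d <- read.csv(f)
  expect_named(d, c("position_cm", "delta_mz", "convolved_delta_mz"))
  expect_equal(nrow(d), length(r$positions))
  unlink(f)
})
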