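# Independent reference implementations used as oracles in the tests.
# These deliberately avoid the package's C++ path.

# Affine map (A, b) of one hard-pulse step: rotation about the field
# (bx, by, bz) uT for dt us, then relaxation. Built from the closed-form
# Rodrigues rotation matrix in R.
step_affine_R <- function(bx, by, bz, dt_us, t1, t2) {
  dt_s <- dt_us * 1e-6
  gam <- 42.577
  b <- sqrt(bx^2 + by^2 + bz^2)
  R <- diag(3)
  if (b > 0) {
    phi <- -2 * pi * gam * b * dt_s
    n <- c(bx, by, bz) / b
    K <- matrix(c(0, -n[3], n[2], n[3], 0, -n[1], -n[2], n[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  }
  E <- diag(c(exp(-dt_s / t2), exp(-dt_s / t2), exp(-dt_s / t1)))
  list(A = E %*% R, b = c(0, 0, 1 - exp(-dt_s / t1)))
}

# N steps of a constant field as a single composed affine map.
const_field_affine_R <- function(bx, by, bz, dt_us, t1, t2, n) {
  st <- step_affine_R(bx, by, bz, dt_us, t1, t2)
  A <- diag(3); b <- c(0, 0, 0)
  for (i in seq_len(n)) {
    b <- st$A %*% b + st$b
    A <- st$A %*% A
  }
  list(A = A, b = as.vector(b))
}

# Plain-R plug-flow labeling efficiency: a spin at constant velocity through
# a label/control train, stepped with bloch_propagate(). Slow but entirely
# independent of the cpp_alpha_grid code path.
plug_flow_alpha_R <- function(params, velocity, settings = sim_settings(),
                              verse = TRUE, z0 = -5, z1 = 8) {
  lab <- params; lab$condition <- "label"
  ctl <- params; ctl$condition <- "control"
  wl <- build_pcasl_train(lab, 2, settings$dt, verse = verse)
  wc <- build_pcasl_train(ctl, 2, settings$dt, verse = verse)
  dt_s <- settings$dt * 1e-6
  np <- length(wl$rf_amplitude)
  run <- function(w) {
    m <- c(0, 0, 1); z <- z0; n <- 0; t_cross <- NA
    while (z < z1) {
      i <- n %% np + 1
      m <- bloch_propagate(m, c(w$rf_amplitude[i], w$rf_phase[i]),
                           w$gradient[i], z, settings)
      z_new <- z + velocity * dt_s
      if (z < 0 && z_new >= 0) t_cross <- (n + (-z) / (velocity * dt_s)) * dt_s
      z <- z_new; n <- n + 1
    }
    list(mz = m[3], t_cross = t_cross, t_end = n * dt_s)
  }
  l <- run(wl); c <- run(wc)
  labeling_alpha(l$mz, c$mz, l$t_cross, l$t_end, settings$t1)
}

# shared fixtures
reduced_ensemble <- function() flow_ensemble(n_streamlines = 10, n_shifts = 3)
reduced_db0 <- c(-50, 0, 50)
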