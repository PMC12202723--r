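// Hard-pulse Bloch integration kernels.
//
// Conventions shared by all kernels:
//   * RF amplitude in uT, RF phase in rad, gradient in mT/m, positions in cm,
//     off-resonance in Hz, time step dt in us, T1/T2 in s.
//   * Effective field in the rotating frame, expressed in uT:
//       Bx = amp*cos(phase), By = amp*sin(phase),
//       Bz = 10*G*z + db0/GAM   (1 mT/m at 1 cm = 10 uT)
//   * One step = rotation about the effective field for dt, then T1/T2
//     relaxation for dt (operator splitting).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GAM   = 42.577;                  // Hz per uT
static const double TWOPI = 6.28318530717958647692;

static inline void rot_vec(double* m, double bx, double by, double bz,
                           double dt_s) {
  double b2 = bx * bx + by * by + bz * bz;
  if (b2 <= 0.0) return;
  double b = std::sqrt(b2);
  double phi = -TWOPI * GAM * b * dt_s;
  double nx = bx / b, ny = by / b, nz = bz / b;
  double c = std::cos(phi), s = std::sin(phi), oc = 1.0 - c;
  double dot = nx * m[0] + ny * m[1] + nz * m[2];
  double rx = m[0] * c + (ny * m[2] - nz * m[1]) * s + nx * dot * oc;
  double ry = m[1] * c + (nz * m[0] - nx * m[2]) * s + ny * dot * oc;
  double rz = m[2] * c + (nx * m[1] - ny * m[0]) * s + nz * dot * oc;
  m[0] = rx; m[1] = ry; m[2] = rz;
}

static inline void relax_vec(double* m, double e1, double e2) {
  m[0] *= e2;
  m[1] *= e2;
  m[2] = 1.0 + (m[2] - 1.0) * e1;
}

// Simulate a stationary spin at position z through the full sampled waveform.
// Optionally record the Mz trace after every step.
// [[Rcpp::export]]
SEXP cpp_bloch_sim(NumericVector rf_amp, NumericVector rf_phase,
                   NumericVector grad, double dt_us, double t1_s, double t2_s,
                   double db0_hz, double z_cm, NumericVector m0,
                   bool trace = false) {
  int n = rf_amp.size();
  double dt_s = dt_us * 1e-6;
  double e1 = std::exp(-dt_s / t1_s), e2 = std::exp(-dt_s / t2_s);
  double dbz = db0_hz / GAM;
  double m[3] = { m0[0], m0[1], m0[2] };
  NumericMatrix tr;
  if (trace) tr = NumericMatrix(n, 3);
  for (int i = 0; i < n; ++i) {
    double bx = rf_amp[i] * std::cos(rf_phase[i]);
    double by = rf_amp[i] * std::sin(rf_phase[i]);
    double bz = 10.0 * grad[i] * z_cm + dbz;
    rot_vec(m, bx, by, bz, dt_s);
    relax_vec(m, e1, e2);
    if (trace) { tr(i, 0) = m[0]; tr(i, 1) = m[1]; tr(i, 2) = m[2]; }
  }
  if (trace) return tr;
  return NumericVector::create(m[0], m[1], m[2]);
}

// Final magnetization for a set of stationary spins at positions zs.
// [[Rcpp::export]]
NumericMatrix cpp_bloch_profile(NumericVector rf_amp, NumericVector rf_phase,
                                NumericVector grad, double dt_us, double t1_s,
                                double t2_s, double db0_hz, NumericVector zs) {
  int n = rf_amp.size(), nz = zs.size();
  double dt_s = dt_us * 1e-6;
  double e1 = std::exp(-dt_s / t1_s), e2 = std::exp(-dt_s / t2_s);
  double dbz = db0_hz / GAM;
  NumericMatrix out(nz, 3);
  std::vector<double> bx(n), by(n);
  for (int i = 0; i < n; ++i) {
    bx[i] = rf_amp[i] * std::cos(rf_phase[i]);
    by[i] = rf_amp[i] * std::sin(rf_phase[i]);
  }
  for (int k = 0; k < nz; ++k) {
    double m[3] = { 0.0, 0.0, 1.0 };
    double z = zs[k];
    for (int i = 0; i < n; ++i) {
      rot_vec(m, bx[i], by[i], 10.0 * grad[i] * z + dbz, dt_s);
      relax_vec(m, e1, e2);
    }
    out(k, 0) = m[0]; out(k, 1) = m[1]; out(k, 2) = m[2];
  }
  return out;
}

// Moving spin along an explicit position-per-step trajectory; the waveform
// arrays are recycled modulo their length.
// [[Rcpp::export]]
NumericVector cpp_bloch_moving(NumericVector rf_amp, NumericVector rf_phase,
                               NumericVector grad, double dt_us, double t1_s,
                               double t2_s, double db0_hz,
                               NumericVector pos_cm, NumericVector m0) {
  int np = rf_amp.size(), n = pos_cm.size();
  double dt_s = dt_us * 1e-6;
  double e1 = std::exp(-dt_s / t1_s), e2 = std::exp(-dt_s / t2_s);
  double dbz = db0_hz / GAM;
  double m[3] = { m0[0], m0[1], m0[2] };
  for (int i = 0; i < n; ++i) {
    int it = i % np;
    double bx = rf_amp[it] * std::cos(rf_phase[it]);
    double by = rf_amp[it] * std::sin(rf_phase[it]);
    double bz = 10.0 * grad[it] * pos_cm[i] + dbz;
    rot_vec(m, bx, by, bz, dt_s);
    relax_vec(m, e1, e2);
  }
  return NumericVector::create(m[0], m[1], m[2]);
}

// Labeling-efficiency grid: simulate label and control conditions for every
// (off-resonance, waveform shift, laminar streamline) combination.
//
// rf_amp/grad describe one two-pulse period (so the control pi alternation is
// periodic); ph_label/ph_control are the per-sample RF phases of the two
// conditions. vel holds the peak-streamline velocity waveform sampled at dt
// over one cardiac period (cm/s); streamline k moves with frac[k] * vel.
// Spins start at z_start and are integrated until they pass z_end, with the
// position updated from the running integral of the velocity at the start of
// each step. Label and control share the trajectory and |B| per step, so both
// are propagated inside one loop.
//
// Returns alpha (T1-corrected), the raw final Mz values, and the plane
// crossing / exit times, each as an (n_db0 x n_shift x n_frac) array.
// [[Rcpp::export]]
List cpp_alpha_grid(NumericVector rf_amp, NumericVector ph_label,
                    NumericVector ph_control, NumericVector grad,
                    double dt_us, double t1_s, double t2_s,
                    NumericVector db0_hz, NumericVector vel,
                    NumericVector fracs, IntegerVector shift_offsets,
                    double z_start_cm, double z_end_cm) {
  int np = rf_amp.size();
  int nv = vel.size();
  int ni = db0_hz.size(), nj = shift_offsets.size(), nk = fracs.size();
  double dt_s = dt_us * 1e-6;
  double e1 = std::exp(-dt_s / t1_s), e2 = std::exp(-dt_s / t2_s);

  std::vector<double> bxl(np), byl(np), bxc(np), byc(np), g10(np);
  for (int i = 0; i < np; ++i) {
    bxl[i] = rf_amp[i] * std::cos(ph_label[i]);
    byl[i] = rf_amp[i] * std::sin(ph_label[i]);
    bxc[i] = rf_amp[i] * std::cos(ph_control[i]);
    byc[i] = rf_amp[i] * std::sin(ph_control[i]);
    g10[i] = 10.0 * grad[i];
  }

  int ncell = ni * nj * nk;
  NumericVector alpha(ncell), mzl_out(ncell), mzc_out(ncell),
      tcross(ncell), tend(ncell);

  for (int k = 0; k < nk; ++k) {
    double f = fracs[k];
    for (int j = 0; j < nj; ++j) {
      int off = shift_offsets[j];
      for (int i = 0; i < ni; ++i) {
        double dbz = db0_hz[i] / GAM;
        double ml[3] = { 0.0, 0.0, 1.0 };
        double mc[3] = { 0.0, 0.0, 1.0 };
        double z = z_start_cm;
        double t_cross = NA_REAL;
        long n = 0;
        while (z < z_end_cm) {
          int it = (int)(n % np);
          double v = f * vel[(int)((n + off) % nv)];
          double bz = g10[it] * z + dbz;
          double bx = bxl[it], by = byl[it];
          double b2 = bx * bx + by * by + bz * bz;
          if (b2 > 0.0) {
            double b = std::sqrt(b2);
            double phi = -TWOPI * GAM * b * dt_s;
            double c = std::cos(phi), s = std::sin(phi), oc = 1.0 - c;
            double nx = bx / b, ny = by / b, nz = bz / b;
            // label
            double dot = nx * ml[0] + ny * ml[1] + nz * ml[2];
            double rx = ml[0] * c + (ny * ml[2] - nz * ml[1]) * s + nx * dot * oc;
            double ry = ml[1] * c + (nz * ml[0] - nx * ml[2]) * s + ny * dot * oc;
            double rz = ml[2] * c + (nx * ml[1] - ny * ml[0]) * s + nz * dot * oc;
            ml[0] = rx; ml[1] = ry; ml[2] = rz;
            // control: same |B|, possibly sign-flipped transverse axis
            double nxc = bxc[it] / b, nyc = byc[it] / b;
            dot = nxc * mc[0] + nyc * mc[1] + nz * mc[2];
            rx = mc[0] * c + (nyc * mc[2] - nz * mc[1]) * s + nxc * dot * oc;
            ry = mc[1] * c + (nz * mc[0] - nxc * mc[2]) * s + nyc * dot * oc;
            rz = mc[2] * c + (nxc * mc[1] - nyc * mc[0]) * s + nz * dot * oc;
            mc[0] = rx; mc[1] = ry; mc[2] = rz;
          }
          relax_vec(ml, e1, e2);
          relax_vec(mc, e1, e2);
          double z_new = z + v * dt_s;
          if (z < 0.0 && z_new >= 0.0) {
            double fr = (v > 0.0) ? (-z) / (v * dt_s) : 1.0;
            t_cross = (n + fr) * dt_s;
          }
          z = z_new;
          ++n;
          if (n > 100000000L) stop("trajectory did not reach z_end");
        }
        double t_end = n * dt_s;
        if (ISNA(t_cross)) stop("trajectory never crossed the labeling plane");
        double corr = std::exp((t_end - t_cross) / t1_s);
        double mzl_c = 1.0 - (1.0 - ml[2]) * corr;
        double mzc_c = 1.0 - (1.0 - mc[2]) * corr;
        int idx = i + ni * (j + nj * k);
        alpha[idx] = 0.5 * (mzc_c - mzl_c);
        mzl_out[idx] = ml[2];
        mzc_out[idx] = mc[2];
        tcross[idx] = t_cross;
        tend[idx] = t_end;
      }
    }
  }
  IntegerVector dims = IntegerVector::create(ni, nj, nk);
  alpha.attr("dim") = dims;
  mzl_out.attr("dim") = dims;
  mzc_out.attr("dim") = dims;
  tcross.attr("dim") = dims;
  tend.attr("dim") = dims;
  return List::create(_["alpha"] = alpha, _["mz_label"] = mzl_out,
                      _["mz_control"] = mzc_out, _["t_cross"] = tcross,
                      _["t_end"] = tend);
}

// ---- static-tissue response ------------------------------------------------

struct Affine { double A[9]; double b[3]; };

// out = f o g  (apply g first, then f)
static inline void compose(const Affine& f, const Affine& g, Affine& out) {
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) {
      out.A[3 * r + c] = f.A[3 * r + 0] * g.A[0 + c] +
                         f.A[3 * r + 1] * g.A[3 + c] +
                         f.A[3 * r + 2] * g.A[6 + c];
    }
    out.b[r] = f.A[3 * r + 0] * g.b[0] + f.A[3 * r + 1] * g.b[1] +
               f.A[3 * r + 2] * g.b[2] + f.b[r];
  }
}

static inline void apply_affine(const Affine& f, double* m) {
  double x = f.A[0] * m[0] + f.A[1] * m[1] + f.A[2] * m[2] + f.b[0];
  double y = f.A[3] * m[0] + f.A[4] * m[1] + f.A[5] * m[2] + f.b[1];
  double z = f.A[6] * m[0] + f.A[7] * m[1] + f.A[8] * m[2] + f.b[2];
  m[0] = x; m[1] = y; m[2] = z;
}

// One hard-pulse step as an affine map (rotation then relaxation).
static inline void step_affine(double bx, double by, double bz, double dt_s,
                               double e1, double e2, Affine& st) {
  double b2 = bx * bx + by * by + bz * bz;
  double R[9] = { 1, 0, 0, 0, 1, 0, 0, 0, 1 };
  if (b2 > 0.0) {
    double b = std::sqrt(b2);
    double phi = -TWOPI * GAM * b * dt_s;
    double nx = bx / b, ny = by / b, nz = bz / b;
    double c = std::cos(phi), s = std::sin(phi), oc = 1.0 - c;
    R[0] = c + nx * nx * oc;      R[1] = nx * ny * oc - nz * s; R[2] = nx * nz * oc + ny * s;
    R[3] = ny * nx * oc + nz * s; R[4] = c + ny * ny * oc;      R[5] = ny * nz * oc - nx * s;
    R[6] = nz * nx * oc - ny * s; R[7] = nz * ny * oc + nx * s; R[8] = c + nz * nz * oc;
  }
  // relaxation diag(e2, e2, e1) applied after the rotation
  for (int c = 0; c < 3; ++c) {
    st.A[0 + c] = e2 * R[0 + c];
    st.A[3 + c] = e2 * R[3 + c];
    st.A[6 + c] = e1 * R[6 + c];
  }
  st.b[0] = 0.0; st.b[1] = 0.0; st.b[2] = 1.0 - e1;
}

// Final Mz of stationary spins after n_periods repetitions of the sampled
// period plus rem_steps extra samples, via binary powering of the per-period
// affine propagator (brute = plain stepping, used as a cross-check).
// [[Rcpp::export]]
NumericVector cpp_static_mz(NumericVector rf_amp, NumericVector rf_phase,
                            NumericVector grad, double dt_us, double t1_s,
                            double t2_s, double db0_hz, NumericVector zs,
                            int n_periods, int rem_steps, bool brute = false) {
  int np = rf_amp.size(), nz = zs.size();
  double dt_s = dt_us * 1e-6;
  double e1 = std::exp(-dt_s / t1_s), e2 = std::exp(-dt_s / t2_s);
  double dbz = db0_hz / GAM;
  std::vector<double> bx(np), by(np);
  for (int i = 0; i < np; ++i) {
    bx[i] = rf_amp[i] * std::cos(rf_phase[i]);
    by[i] = rf_amp[i] * std::sin(rf_phase[i]);
  }
  NumericVector out(nz);

  if (brute) {
    long ntot = (long)n_periods * np + rem_steps;
    for (int k = 0; k < nz; ++k) {
      double z = zs[k];
      double m[3] = { 0.0, 0.0, 1.0 };
      for (long i = 0; i < ntot; ++i) {
        int it = (int)(i % np);
        rot_vec(m, bx[it], by[it], 10.0 * grad[it] * z + dbz, dt_s);
        relax_vec(m, e1, e2);
      }
      out[k] = m[2];
    }
    return out;
  }

  Affine st, per, tmp, pw, acc;
  for (int k = 0; k < nz; ++k) {
    double z = zs[k];
    // compose one period
    per.A[0] = per.A[4] = per.A[8] = 1.0;
    per.A[1] = per.A[2] = per.A[3] = per.A[5] = per.A[6] = per.A[7] = 0.0;
    per.b[0] = per.b[1] = per.b[2] = 0.0;
    for (int i = 0; i < np; ++i) {
      step_affine(bx[i], by[i], 10.0 * grad[i] * z + dbz, dt_s, e1, e2, st);
      compose(st, per, tmp);
      per = tmp;
    }
    // acc = per^n_periods by binary exponentiation
    acc.A[0] = acc.A[4] = acc.A[8] = 1.0;
    acc.A[1] = acc.A[2] = acc.A[3] = acc.A[5] = acc.A[6] = acc.A[7] = 0.0;
    acc.b[0] = acc.b[1] = acc.b[2] = 0.0;
    pw = per;
    int n = n_periods;
    while (n > 0) {
      if (n & 1) { compose(pw, acc, tmp); acc = tmp; }
      n >>= 1;
      if (n > 0) { compose(pw, pw, tmp); pw = tmp; }
    }
    double m[3] = { 0.0, 0.0, 1.0 };
    apply_affine(acc, m);
    for (int i = 0; i < rem_steps; ++i) {
      int it = i % np;
      rot_vec(m, bx[it], by[it], 10.0 * grad[it] * z + dbz, dt_s);
      relax_vec(m, e1, e2);
    }
    out[k] = m[2];
  }
  return out;
}

// ---- adiabatic inversion map -----------------------------------------------

// Final Mz over a (relative B1) x (off-resonance) grid for a non-selective
// pulse, starting from equilibrium.
// [[Rcpp::export]]
NumericMatrix cpp_inversion_mz(NumericVector rf_amp, NumericVector rf_phase,
                               double dt_us, double t1_s, double t2_s,
                               NumericVector b1_scales, NumericVector db0_hz) {
  int n = rf_amp.size();
  int nb = b1_scales.size(), nf = db0_hz.size();
  double dt_s = dt_us * 1e-6;
  double e1 = std::exp(-dt_s / t1_s), e2 = std::exp(-dt_s / t2_s);
  std::vector<double> ca(n), sa(n);
  for (int i = 0; i < n; ++i) {
    ca[i] = rf_amp[i] * std::cos(rf_phase[i]);
    sa[i] = rf_amp[i] * std::sin(rf_phase[i]);
  }
  NumericMatrix out(nb, nf);
  for (int f = 0; f < nf; ++f) {
    double bz = db0_hz[f] / GAM;
    for (int b = 0; b < nb; ++b) {
      double sc = b1_scales[b];
      double m[3] = { 0.0, 0.0, 1.0 };
      for (int i = 0; i < n; ++i) {
        rot_vec(m, sc * ca[i], sc * sa[i], bz, dt_s);
        relax_vec(m, e1, e2);
      }
      out(b, f) = m[2];
    }
  }
  return out;
}

// ---- VERSE slew passes -----------------------------------------------------

// Forward/backward slew-feasibility passes on a gradient-vs-k profile:
// enforces g[i+1]^2 <= g[i]^2 + 2*s*dk (and symmetrically backwards), with
// fixed boundary values. g in mT/m, dk in mT/m*us, s in mT/m/us.
// [[Rcpp::export]]
NumericVector cpp_slew_pass(NumericVector g_des, double g_start, double g_end,
                            double s, double dk) {
  int n = g_des.size();
  NumericVector g(n);
  double lim = g_start;
  g[0] = std::min(g_des[0], g_start);
  for (int i = 1; i < n; ++i) {
    lim = std::sqrt(lim * lim + 2.0 * s * dk);
    g[i] = std::min(g_des[i], lim);
    lim = g[i];
  }
  lim = g_end;
  g[n - 1] = std::min(g[n - 1], g_end);
  for (int i = n - 2; i >= 0; --i) {
    lim = std::sqrt(lim * lim + 2.0 * s * dk);
    if (g[i] > lim) g[i] = lim;
    lim = g[i];
  }
  return g;
}
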