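---
title: "Simulating and optimizing SAR-constrained PCASL labeling at 7 T"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and optimizing SAR-constrained PCASL labeling at 7 T}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcaslsim)
```

## The problem

Pseudo-continuous arterial spin labeling (PCASL) inverts arterial blood
water flowing through a labeling plane with a long train of short
slice-selective RF pulses. At 7 T the specific absorption rate (SAR) of
that train, not the physiology, sets the minimum repetition time: deadtime
has to be inserted into every TR to stay within RF power limits, and that
deadtime is wasted scan time. `pcaslsim` implements the simulation
machinery needed to choose PCASL parameters that maximize *SNR efficiency*
-- perfusion SNR per square root of scan time -- rather than labeling
efficiency alone, together with the design of low-SAR adiabatic
background-suppression (BGS) pulses.

The labeling train is parameterized by five quantities
(`pcasl_params()`): the mean RF amplitude over one inter-pulse period
$B_{1,\mathrm{ave}}$, the RF pulse duration $T_\mathrm{RF}$, the
inter-pulse spacing $TR_\mathrm{PCASL}$, the slice-select gradient during
the pulse $G_\mathrm{max}$, and the period-mean gradient $G_\mathrm{ave}$.
$B_{1,\mathrm{ave}}$ is a *period* mean, so the nominal per-pulse flip
angle is $360^\circ \gamma B_{1,\mathrm{ave}} TR_\mathrm{PCASL}$
independent of the duty cycle. The balanced control condition differs from
the label condition only by an additional $\pi$ phase on every other RF
pulse.

Because the SAR-limited minimum TR is proportional to the RF energy
deposited per TR, the optimization objective is

$$\theta_\mathrm{opt} \;=\; \arg\max_\theta \;
  \frac{\alpha_\mathrm{final}(\theta)}{\sqrt{\int B_1^+(t)^2\,dt}},$$

with $\alpha_\mathrm{final}$ the flow-weighted labeling efficiency defined
below. Maximizing $\alpha_\mathrm{final}$ alone is kept as the comparison
objective.

## The Bloch engine

All magnetization dynamics use a hard-pulse integrator
(`bloch_propagate()` in R, compiled kernels underneath): each raster step
rotates the magnetization about the effective field
$(B_{1x}, B_{1y}, 10\,G z + \Delta B_0/\gamma)$ and then applies $T_1/T_2$
relaxation (operator splitting; the error is second order in the step).
Study conditions are a 10 us step with blood values at 7 T, $T_1 = 2.1$ s
and $T_2 = 0.06$ s (`sim_settings()`). The engine is verified against a
closed-form rotation-plus-relaxation affine oracle ($<10^{-8}$ per
component) and, during development, against a continuous-ODE integration
of the same fields; halving the step changes the labeling efficiencies by
less than $5\times10^{-4}$.

Off-resonance is modeled as a constant frequency offset applied along the
whole trajectory: the dynamic-shimming workflow this package supports
corrects the field at the labeling plane, leaving only a small residual
(within $\pm 50$ Hz) whose spatial structure is not modeled. Transverse
magnetization is never reset between pulses; the train is simulated
continuously.

## Pulsatile laminar flow

Labeling efficiency depends on the velocity at which each spin crosses the
plane. The flow model (`flow_ensemble()`) is a laminar ensemble: 50
streamlines at 10--100% of a peak-velocity waveform, each weighted by its
flow contribution $p_k = V_k(0)/\sum_l V_l(0)$, and 10 circular time
shifts of the waveform so that spins cross the plane at different cardiac
phases. The efficiency of one parameter set is

$$\alpha_\mathrm{final} = \frac{1}{N_{\Delta B_0} N_\mathrm{shifts}}
  \sum_{i,j} \sum_k p_k\, \alpha(B_{0,i}, V_{j,k}),$$

the flow-weighted mean over 11 off-resonance values evenly spaced in
$\pm 50$ Hz, 10 shifts and 50 streamlines.

The reference peak-velocity waveform (`reference_waveform()`) is a
parametric internal-carotid-like curve: period 1 s, systolic peak of
76 cm/s at 0.15 s, a dicrotic bump at 0.40 s, diastolic minimum of
30 cm/s, built from two circularly wrapped Gaussians and min/max
normalized so the extremes are exact. The systolic width (0.074227 s) was
solved once so that the cycle-mean velocity is 40 cm/s, the value typical
of internal carotid arteries in young volunteers; it is not adjusted
thereafter. This stand-in reproduces the published protocol efficiencies
to about $\pm 0.01$, but it is not a measured waveform: it has a single
smooth systolic upstroke and no subject variability, beat-to-beat
variation, or vessel-specific shape. Simulations with substantially
different flow (older subjects, vertebral arteries) should substitute a
digitized waveform via `velocity_waveform()`.

Each spin travels from 5 cm below to 8 cm above the plane; positions come
from the running integral of its velocity, and every trajectory crosses
the plane exactly once because all velocities are positive. The final
$M_z$ of both conditions is corrected for $T_1$ relaxation between the
spin's plane crossing and the end of its trajectory -- deficits $(1-M_z)$
are rescaled by $e^{+\Delta t/T_1}$ -- and
$\alpha = (M_z^\mathrm{control} - M_z^\mathrm{label})/2$
(`labeling_alpha()`). Referencing the crossing rather than the train start
makes $\alpha$ comparable across velocities; the alternative convention
would fold each spin's transit time into its efficiency.

## Waveform construction and VERSE

`build_pcasl_period()` realizes one period as: ramp up to $G_\mathrm{max}$
at maximum slew (rounded up to the raster so the Hann pulse is
raster-aligned and its flip integral is exact), the Hann RF pulse on the
plateau, ramp down, and a symmetric triangular refocusing lobe spanning
the entire remaining window whose apex sets the period mean to
$G_\mathrm{ave}$. A triangle over the full window needs the least slew for
a given area, so this geometry is feasible exactly when any lobe is
($|A| \le s\,T^2/4$); parameter combinations violating it raise an
explicit infeasibility error. Feasibility decisions are made on the
analytic segment geometry; `check_hardware()` measures the rastered
waveform and therefore carries a 0.05% slew tolerance for segments
designed exactly at the limit.

The fixed-duration minimum-SAR VERSE transform (`verse_min_sar()`) works
in the cumulative-gradient-area (k-space) parameterization, where the
per-k RF weighting $w(k) = B_1(k)/g(k)$ is an invariant. Without
constraints the energy-optimal solution at fixed duration is constant
$B_1$ (Cauchy--Schwarz; exactly $2/3$ of the Hann pulse energy). The
implementation caps the gradient at the hardware maximum, enforces the
slew limit with forward/backward passes on $g(k)$
($g\,dg/dk \le s$), pins the boundary gradient to $G_\mathrm{max}$ so
ramps and refocusing stay valid, and bisects the constant-amplitude level
until the duration matches the input exactly. For the short pulses used
here the slew constraint binds over a large fraction of k-space, which is
why the realized energy reductions (22--25%) sit well short of the
unconstrained 33%. On-resonance slice profiles are preserved by
construction (each k-interval delivers the same rotation), which the test
suite verifies by Bloch simulation to $<1\%$; off-resonance robustness of
the sub-millisecond versed pulses is not separately optimized. A 0.1%
internal slew margin absorbs raster resampling noise. Repeated
application is idempotent up to that resampling (a few percent on a
30--50-sample pulse).

## Static tissue and aliased labeling planes

A pulsed train is a sampled waveform in time, so the labeling plane
replicates spatially: the label comb recurs every
$1/(\gamma G_\mathrm{ave} TR_\mathrm{PCASL})$, and the balanced control
train, whose period is two pulses, interleaves planes at *half* that
spacing. If a replica lands in the imaging volume it perturbs static
tissue and corrupts the subtraction. `static_response()` simulates
stationary spins from $-16$ to $16$ cm every 0.2 mm under an 1800 ms
train, takes the control$-$label $M_z$ difference, and convolves it with
the Bloch-simulated $|M_{xy}|$ profile of the imaging excitation pulse (a
90 degree Hann-windowed sinc, 2.56 ms, time-bandwidth 3.2, 5 mm slice,
normalized to unit area). Using the $|M_{xy}|$ profile treats the 2D
readout as sampling the convolved difference at slice centers; convolving
with the excitation's $M_z$ saturation profile instead would be the
alternative for the longitudinal state, and changes the extents
negligibly at this slice thickness.

Two numerical points matter here. First, the long train is not stepped
sample by sample: the affine Bloch map of one two-pulse period is
composed once per position and raised to the required power by binary
exponentiation, which turns an 1800 ms train into milliseconds of work
per position (a brute-force path is kept and tested for equivalence).
Second, the static simulations use a 5 us step: a hard-pulse train
sampled at $dt$ aliases spins beyond $1/(2\gamma G\,dt)$ -- about 14.7 cm
for 8 mT/m at 10 us, i.e. inside the $\pm 16$ cm window -- and the
sharp-edged versed pulses excite that numerical alias visibly. Halving
the step moves it out of the window and leaves the physical response,
including all lobe extents, unchanged.

A parameter set passes the static-tissue constraint
(`passes_constraint()`) if the convolved perturbation stays at or below
0.1% of $M_0$ everywhere beyond 1.8 cm from the plane, the margin
available between the labeling plane and the cerebellum. The central-lobe
extent reported by `lobe_extent()` scans outward on the imaging side
until the response first drops below threshold.

## The optimizer

`screen_and_rank()` follows the study order: enumerate the grid
($TR_\mathrm{PCASL} \in \{0.5, 0.6, 0.7, 0.8, 1.06\}$ ms,
$B_{1,\mathrm{ave}}$ 0.1--2 uT by 0.1, $G_\mathrm{max}$ 3--15 mT/m by
0.5, $G_\mathrm{ave}$ 0--2 mT/m by 0.1, $T_\mathrm{RF} =
0.5\,TR_\mathrm{PCASL}$; 52500 points), exclude combinations whose versed
waveform violates the 80 mT/m / 200 T/m/s gradient limits, exclude those
failing the static-tissue constraint, and rank the remainder. The slew
screen is evaluated once per $(TR, G_\mathrm{max}, G_\mathrm{ave})$
triple because the VERSE gradient solution is invariant to the RF
amplitude scale. Under this package's lobe geometry the screen excludes
22700 combinations; the published count with the (unprinted) original
geometry is 23040, a 1.5% difference concentrated at grid points where
the refocusing window is within a raster step of feasibility.

Energy in the ranking denominator is the versed PCASL RF energy per TR
plus a configurable fixed non-PCASL term (default 0, ranking by PCASL
power alone; rankings are insensitive to the additive term only when
label durations are equal, so both modes are exposed). Ties are broken
lexicographically (longest $TR_\mathrm{PCASL}$, then smallest
$B_{1,\mathrm{ave}}$, $G_\mathrm{max}$, $G_\mathrm{ave}$); none occur on
the default grid.

Problem sizes are chosen per task. The full flow ensemble
($50 \times 10 \times 11$) is used for per-protocol efficiencies (the
acceptance script recomputes them at that size, about half a minute per
protocol); the test suite pins a reduced $10 \times 3 \times 3$ ensemble
by regression instead, and grid-level examples in the tests use toy grids
-- ranking all 2621 surviving combinations at the full ensemble is a
cluster-scale computation by design. The full static screen over the
29800 slew-feasible points runs in under an hour on one CPU with the
propagator acceleration; a stratified 200-point subsample of its cached
statuses is re-verified by the test suite.

## Adiabatic background suppression

`sech_pulse()` constructs the hyperbolic-secant full passage:
$B_1(t) = B_{1,\max}\,\mathrm{sech}(\beta t')$ with frequency sweep
$-\mu\beta\tanh(\beta t')/2\pi$. The rate $\beta$ follows from the 4%
amplitude truncation of a 10.24 ms pulse in closed form
(`beta_from_truncation()`, 763.99 rad/s). The shaping factor $\mu$ trades
sweep bandwidth against adiabaticity; `optimize_mu()` maximizes the mean
inversion efficiency over the target range ($B_1$ $\pm 50\%$ every 1%,
$\Delta B_0$ $\pm 500$ Hz every 10 Hz) by coarse scan plus golden-section
refinement. The mean is the default objective -- "maximize efficiency
over the range" admits a minimax reading too, which is exposed via
`objective = "min"`; the two optima differ by less than the scan
resolution here because the map is flat near its top.

Efficiency is reported on two scales: $(1 - M_z)/2$ (0 = untouched, 1 =
inverted), the optimization objective, and the grid mean of $-M_z$, the
attenuation factor a BGS inversion applies to inverted label
magnetization, which is the scale on which BGS efficiencies enter
perfusion quantification and on which the published values are quoted.
At the optimized $\mu \approx 7.0$ the designed pulse reaches a mean
$-M_z$ of 0.944 over the target grid.

`verse_sech()` applies the same time-redistribution idea to this
non-selective pulse (a virtual unit gradient): local sampling rate
proportional to $|B_1|^p$, with $p$ bisected so the energy reduction
equals the 25% cap -- full flattening would give 40% but degrades
off-resonance behavior. `optimize_phase()` then re-optimizes the phase
waveform at fixed amplitude, parameterized as an additive cubic spline on
16 knots, with Nelder--Mead restarts from an unperturbed start plus
fixed-seed perturbations (the only stochastic component in the package;
the seed is hard-coded and documented). `bgs_timing()` places the two
inversions so that species with $T_1 = 1000$ and 2000 ms are nulled
100 ms before the readout, solving the two-pulse saturation-recovery
expression numerically to $|M_z| < 10^{-6}$; for an 1800 ms label and
1800 ms post-label delay the inversions land at about 1567 and 3037 ms
after the start of labeling.

## Sequence-level accounting

`pcasl_rf_power()` and `relative_rf_power()` compare protocols by RF
energy per unit labeling time; the VERSE policy is part of the comparison
because the optimized protocols are used versed while the literature
protocol was defined without VERSE. `optimal_label_duration()` multiplies
the SNR-efficiency objective by the consensus perfusion-signal factor
$(1 - e^{-LD/T_{1b}})e^{-PLD/T_{1b}}$ and maximizes over label durations;
the optimum depends on the ratio of fixed (BGS, presaturation,
excitation) to per-second PCASL RF energy. Those fixed terms are not
published individually, so `other_rf_energy_default()` anchors them to
the one stated piece of the RF budget -- each sech pulse carrying 19% of
the per-TR energy of the nominal optimized protocol at an 1800 ms label
duration -- and should be treated as an estimate: the tests exercise the
resulting ~3.8 s optimum, and its sensitivity can be explored by sweeping
`other_rf_energy` in `sequence_budget()`. The published "relative
sequence SNR efficiency" column depends on these unprinted terms and is
deliberately out of scope.

## Known limitations

* One spatial dimension: no vessel geometry, no Womersley profile, no
  oblique labeling planes; laminar weighting ignores the annular area of
  each shell (the flow-weight definition used here weights by velocity at
  $t = 0$ only).
* The reference velocity waveform is a parametric stand-in, as discussed
  above.
* B1 inhomogeneity enters only as the global flip-angle scaling used in
  the in vivo comparisons; no transmit-field maps are modeled.
* Static-tissue simulations use blood relaxation values; brain-tissue
  values change the responses little but are not the default.
* VERSE off-resonance robustness is asserted only through the short pulse
  durations, not optimized.
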