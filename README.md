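# pcaslsim

Bloch-simulation and optimization toolkit for SAR-constrained
pseudo-continuous arterial spin labeling (PCASL) at ultra-high field.

PCASL measures brain perfusion by inverting arterial blood water with a
train of short slice-selective RF pulses at a labeling plane in the neck.
At 7 T the RF power (SAR) of that train dictates the minimum TR, so the
parameters that maximize labeling efficiency are not the parameters that
maximize SNR per unit scan time. `pcaslsim` is for pulse-sequence
developers and ASL researchers who want to simulate and re-optimize the
labeling train and its background-suppression (BGS) pulses for their own
hardware limits, flow conditions, and field strength.

## What it computes

The PCASL train is parameterized by five quantities: mean RF amplitude
B1ave, RF pulse duration T_RF, inter-pulse spacing TR_PCASL, slice
gradient G_max, and mean gradient G_ave. For a candidate parameter set
the package computes the flow-weighted labeling efficiency

    alpha_final = mean over (dB0, shift) of sum_k p_k * alpha(B0_i, V_jk)

from hard-pulse Bloch simulations of spins on pulsatile laminar
streamlines (p_k are laminar flow weights), and ranks parameter sets by
the SAR-constrained SNR efficiency

    theta_opt = argmax  alpha_final / sqrt( integral B1+(t)^2 dt )

subject to gradient hardware feasibility of the VERSE-transformed
waveforms and to a static-tissue constraint on aliased labeling planes
(perturbation <= 0.1% of M0 beyond 1.8 cm from the plane). It also
designs hyperbolic-secant adiabatic inversion pulses for background
suppression: closed-form truncation rate beta, shaping factor mu
optimized over a B1/B0 robustness grid, a SAR-capped VERSE variant with
phase re-optimization, and two-pulse T1-nulling timing.

## Worked example

```r
library(pcaslsim)

proto <- pcasl_protocols()$max_snr_efficiency
print(proto$params)
#> PCASL parameters (label): B1ave 0.6 uT, T_RF 530 us, TR_PCASL 1060 us,
#>   Gmax 5.5 mT/m, Gave 0.2 mT/m (flip 9.75 deg)

# flow-weighted labeling efficiency, reduced ensemble for speed
ens <- flow_ensemble(n_streamlines = 10, n_shifts = 3)
alpha_final(proto$params, ens, c(-50, 0, 50), verse = TRUE)
#> flow-weighted labeling efficiency alpha_final = 0.6698
#>   (3 off-resonance x 3 shifts x 10 streamlines)

# static-tissue response after an 1800 ms train
resp <- static_response(proto$params, verse = TRUE)
lobe_extent(resp); passes_constraint(resp)
#> [1] 1.78
#> [1] TRUE

# RF power of the literature 7 T protocol relative to the optimized one
relative_rf_power(pcasl_protocols()$literature$params, proto$params,
                  verse_a = FALSE, verse_b = TRUE)
#> [1] 10.38022
```

The reduced ensemble above trades accuracy for speed; with the full study
ensemble (50 streamlines x 10 shifts x 11 off-resonance values,
`flow_ensemble()` defaults, about half a minute per protocol) the same
call gives alpha_final = 0.721 for this protocol and 0.822 for the
labeling-efficiency optimum. The static-tissue central lobe of 1.78 cm is
what allows the labeling plane to sit 1.8 cm below the imaging volume;
the relative-power ratio of 10.4 is the SAR headroom the optimized
protocol gains over the literature settings.

A thin command-line wrapper is installed at `inst/cli/pcaslsim`
(subcommands `efficiency`, `static`, `verse`, `optimize`, `sech-design`,
`sech-optimize`, `bgs-timing`, `timing`).

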