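---
title: "Models and processing choices in nirsdcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and processing choices in nirsdcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsdcs)
```

`nirsdcs` implements the processing chain of a hybrid frequency-domain
near-infrared spectroscopy (FD-NIRS) and diffuse correlation spectroscopy
(DCS) muscle monitor: intensity-modulated light at 730 and 830 nm
(139 and 149 MHz) and a long-coherence 852 nm flow channel, all at a
25 mm source–detector separation, sampled at 2 Hz and averaged to an
effective 0.5 Hz. This vignette explains the models behind each stage,
the tunable parameters and their defaults, what the synthetic-data
generators emulate, and the numerical choices and limitations a user
should know about.

## Forward models

### Frequency-domain diffuse reflectance

The diffusion forward model is the semi-infinite extrapolated-boundary
Green's function. For absorption $\mu_a$ and reduced scattering
$\mu_s'$ (both mm$^{-1}$), the diffusion coefficient is
$D = 1/3(\mu_a + \mu_s')$, the isotropic source sits at
$z_0 = 1/(\mu_a+\mu_s')$, and the extrapolated boundary at
$z_b = 2D\,(1+R_\mathrm{eff})/(1-R_\mathrm{eff})$, with
$R_\mathrm{eff}$ computed by numerical integration of the unpolarized
Fresnel reflectance over the fluence and flux angular moments for the
tissue index $n = 1.37$ against air ($R_\mathrm{eff} = 0.468$). At
angular modulation frequency $\omega$ the complex attenuation
coefficient is $k = \sqrt{(\mu_a + i\omega/v)/D}$ with $v$ the
in-medium speed of light, and the detected signal is the hybrid exit
current

$$R(\rho) \;=\; \frac{1-R_\Phi}{4}\,\Phi(\rho, z{=}0)
            \;+\; \frac{1-R_J}{2}\, J_z(\rho),$$

where $\Phi$ and $J_z$ are the dipole fluence and flux and $R_\Phi$,
$R_J$ the same Fresnel moments. Amplitude is $|R|$ and the reported
phase is the *lag* $-\arg R$, positive and increasing with separation
and frequency, zero at DC. This convention is used consistently by
calibration, the lookup tables and the simulators.

These formulation choices were made by comparing candidate standard
variants ($D$ with and without $\mu_a$; source depth $1/\mu_s'$ vs
$1/\mu_t'$; flux-only vs fluence-only vs hybrid exit current) against
the package's own Monte Carlo transport at high photon counts; the
combination above gave the best joint amplitude/phase agreement across
the physiological grid. The flux-only current matches phase slightly
better at very low $\mu_s'$ but overstates amplitude by up to 10% at
high absorption, and was rejected.

### Monte Carlo transport

`mc_time_resolved()` is a photon random walk in the semi-infinite
medium: Henyey–Greenstein scattering with $g = 0.9$, absorption as
single-scatter albedo weight attenuation, Fresnel partial reflection at
the boundary with the escaping weight tallied into an annular detector
band and time-resolved by total path length (10 ps bins to 10 ns). The
time histogram is Fourier-transformed at the modulation frequency to
give the complex reflectance on exactly the same footing as the
diffusion model; the comparison averages the diffusion solution over
the same annulus with $2\pi\rho$ weighting, because $R(\rho)$ varies by
a factor of about 1.6 across the band.

Two variance-control devices keep desk-scale runtimes: a classic
survival roulette (threshold $10^{-3}$, survival 1/10) and a
launch-normalized importance window — a photon's value is its weight
times $\exp(-\mu_\mathrm{eff}\, d)$ with $d$ its distance to the
detector ring; photons falling below the window survive a roulette with
probability proportional to their value and are reweighted exactly.
Both are unbiased in expectation. The detector band is $\pm 2$ mm
around the 25 mm separation, a choice trading radial resolution for
detected-event statistics; the matched band average on the diffusion
side keeps the comparison unbiased. The walk runs on a self-contained
xoshiro256++ generator, so a seed reproduces the histogram
bit-identically on any platform.

The diffusion-vs-transport validation grid is
$\mu_a \in \{0.005, 0.01, 0.03\}$, $\mu_s' \in \{0.5, 1.0, 1.5\}$
mm$^{-1}$ — the tissue range the synthetic generators emulate — at
$7\times10^5$ photons per cell, the package's validation problem size
(used by both the test suite and the acceptance script).

**Known limitation.** At $\mu_s' = 0.5$ mm$^{-1}$ the separation is
only ~12.5 transport mean free paths and the P1 diffusion
approximation's phase error becomes visible: high-statistics transport
runs (phase standard error 0.0005–0.001 rad) show the diffusion phase
lag is too small by +0.011 rad ($\mu_a=0.005$) to +0.014 rad
($\mu_a=0.03$) on that row, and by about +0.006 rad at
$\mu_s'=1.0, \mu_a=0.005$. This is model physics, not Monte Carlo
noise, and no standard semi-infinite formulation removes it without
breaking the amplitude agreement. Amplitude agreement is within 3.5%
everywhere measured. In practice the inversion pipeline is insensitive
to this: calibration against a reference phantom absorbs any constant
instrument phase offset, and the lookup table and measurements share
the same forward model.

### Correlation diffusion and the Siegert relation

The flow channel models the normalized field autocorrelation
$g_1(\tau)$ of a semi-infinite medium with Brownian scatterer dynamics:
the static absorption acquires a dynamic term
$2 \mu_s' k_0^2\, \alpha D_b\, \tau$, where $\alpha D_b$ is the blood
flow index (BFi, cm$^2$/s) and $k_0 = 2\pi n/\lambda$ the in-medium
wavenumber at 852 nm. The same $D$, $z_0$, $z_b$ as the FD model are
used, $g_1(0)=1$, and $g_1$ decreases strictly in lag and in BFi.
The measured intensity autocorrelation follows the Siegert relation
$g_2 = 1 + \beta g_1^2$ with coherence factor $\beta \in (0,1]$ set by
the detection optics.

## Inversion

`build_fd_lut()` tabulates amplitude and phase over a default grid of
60 log-spaced $\mu_a$ nodes on $[0.002, 0.05]$ and 60 linear $\mu_s'$
nodes on $[0.3, 2.5]$ mm$^{-1}$ — bracketing muscle and phantom ranges
with margin — for both wavelength channels, and verifies sign
consistency of the response Jacobian across the grid. `invert_fd()`
initializes at the nearest node of a coarse subsample, Newton-iterates
on the bilinearly interpolated (log-amplitude, phase) surfaces, and —
for tables built from the diffusion engine — polishes with a final
Newton step against the continuous model. The polish matters for the
crosstalk floor: bilinear interpolation alone leaves ~0.1–0.5%
parameter error, which would limit undesired-channel suppression to
roughly −30 dB; with the polish the round trip is exact to machine
precision and the floor drops below −100 dB. Out-of-range queries are
clamped to the table boundary and flagged (strict mode raises instead),
a robustness/strictness trade for streaming data.

Calibration determines one amplitude gain and one phase offset per
wavelength from a measurement of a phantom with known optical
properties, such that the calibrated phantom measurement reproduces the
forward model exactly; it is idempotent and transparent to the rest of
the chain.

`invert_dcs()` estimates $\beta$ from the small-lag plateau (mean of
$g_2-1$ over the first five lag bins) and fits BFi by a bracketed 1-D
optimization of the correlation-diffusion model conditioned on the
supplied optics, seeded by an 80-node log-spaced BFi grid on
$[10^{-9}, 10^{-5}]$ cm$^2$/s. Because a finite first lag makes the
raw plateau droop, $\beta$ is then updated by its conditional
least-squares value against the fitted decay and the pair is alternated
to convergence; a second start at $\beta = 0.5$ guards against fast
decays whose first lags are already off the plateau. In streaming use
the previous timepoint's BFi warm-starts the bracket, with a fallback
to the full grid if the solution pins at the bracket edge.
`fit_direct_fd()` and `fit_direct_dcs()` are deliberately independent
least-squares oracles used by the test suite to cross-check both
inversions.

## Chromophores and metabolism

Beer's law with decadic extinction coefficients: after subtracting the
water and lipid background (62.5% water, 20% lipid by volume — the
standard muscle assumption), the residual absorption at the two
wavelengths is solved as
$\mu_a^{res} = \ln(10)\, E\, C$ for $C = $ (oxy, deoxy) [Hb+Mb] in mM,
reported in µM. Hemoglobin and myoglobin are spectrally inseparable in
this band and are treated as one pool. The packaged constants (Prahl's
hemoglobin compilation, Segelstein-type water, van Veen-type lipid, read
at 730/830 nm) are cited in `chromophore_basis()`; negative
concentrations are flagged, never clipped, because they diagnose
calibration or coupling problems. Saturation is
$\mathrm{StO_2} = 100\,\mathrm{oxy}/\mathrm{total}$.

The metabolic rate of oxygen follows Fick's principle,

$$\mathrm{MRO_2} = \frac{\mathrm{HGB}\cdot \mathrm{BFi}\cdot
(\mathrm{SpO_2} - \mathrm{StO_2})}{\gamma \cdot \mathrm{mw_{Hb}}},$$

with HGB 14 (female) / 16 (male) g/dL, SpO$_2$ 0.98, venous ratio
$\gamma = 0.75$, and 64,500 g/mol. Units are tracked explicitly
(mol$_\mathrm{Hb}$·cm$^2$·dL$^{-1}$·s$^{-1}$) and attached to the
result. The one-line printed form of this equation is typographically
ambiguous about whether $\gamma$ divides the whole extraction term or
only StO$_2$; the first reading is the default and the second is
selectable (`grouping = "venous_scales_sto2"`), both unit-checked;
neither is asserted as the original authors' intent.

## Time traces

The six parameter traces (oxy, deoxy, total [Hb+Mb], StO$_2$, BFi,
MRO$_2$) are low-pass filtered with a second-order Butterworth at
0.02 Hz to remove breathing (0.2–0.3 Hz). Filtering is zero-phase
(forward–backward with odd-symmetric padding) by default because the
activation offsets are time-critical and a causal pass would delay
them by tens of seconds at this cutoff; a single causal pass is
available and starts in steady state, so constants are preserved
exactly either way. Note one discretization fact: at the native 2 Hz
rate the bilinear design's frequency warping makes the discrete filter
attenuate a 0.25 Hz tone about 10% more than the analog magnitude
$1/\sqrt{1+(f/f_c)^4}$; the filter-contract check therefore samples at
10 Hz, where the analog form holds to 0.4%.

Baseline is the mean over the first 50 s (the last 10 s before load
onset are excluded against anticipatory responses); traces are
normalized by it. Activation features are extracted per region —
defaults [60, 150) s and [150, 300) s, both configurable, chosen to
split the double-hump response seen within 240 s of load onset — as
the extremum of the configured polarity (valley for deoxy, peak
otherwise), reported as offset from load onset (60 s) and percent
change from baseline. An event must exceed 3× the baseline-window
residual standard deviation, so flat or noise-only traces report
`found = FALSE`.

Respiration is computed from the raw 730 nm amplitude: second-order
Butterworth high-pass at 0.03 Hz, then a gentle 0.6 Hz low-pass before
peak detection (without it, sample-level noise at realistic SNR seeds
spurious peaks and biases the rate high), peaks at least 2 s apart and
above 0.3× the 90th percentile envelope, and breaths per minute = 60 /
mean inter-peak period per 30 s window; windows with fewer than two
peaks are flagged undefined. The peak-detection details are this
package's choices — only the filter and the window arithmetic are
prescribed by the protocol.

g2 streams are averaged pointwise in non-overlapping blocks of four
(2 Hz → 0.5 Hz), which divides g2 noise variance by four; the FD
channels are block-averaged to the same timestamps.

## Titrations and crosstalk

The three liquid-phantom titrations follow the serial-replacement
recursion $C_{k+1} = C_k(1 - v/V) + C_\mathrm{stock}\,(v/V)$:
absorption (0.48 mL of 1.5 g/L nigrosin in matched 0.5% Intralipid per
step, 20 steps), scattering (2 mL of 20% Intralipid into a 0.39% batch,
10 steps), and flow (0.35% batch stirred from 64 rpm in 7 rpm steps,
BFi linear in rpm). The fill volume (1.0 L) and the dye/emulsion
optical constants (nigrosin 0.7 / 0.4 mm$^{-1}$ per g/L and Intralipid
1.8 / 1.5 mm$^{-1}$ per percent lipid at 730 / 830 nm) are package
choices pinned once to land the titrated-parameter changes in the
few-hundred-percent range such instruments are validated over; the
protocol's volumes and step structure are as published.

Crosstalk between a titrated (desired) and untouched (undesired)
parameter is the ratio of their baseline-normalized final changes in
decibels, $10\log_{10}(|\Delta_u|/|\Delta_d|)$ by default — this
power-style convention reproduces the printed worst pair near −11.8 dB
from the published per-wavelength changes, consistent with the quoted
"≤11 dB" bound; $20\log_{10}$ is available, and a slope-ratio variant
is reported alongside the endpoint definition because the published
definition is ambiguous between the two. A parameter's crosstalk with
itself is 0 dB; an exactly-zero undesired change reports −Inf as a
sentinel.

The *algorithmic* crosstalk floor is measured on noise-free synthetic
titrations pushed through the full forward-then-inverse pipeline, as
the excess of the recovered undesired change over the truth's own
change (`crosstalk_floor()`). The distinction matters because the
synthetic scattering titration is physically coupled: added Intralipid
displaces water, so true absorption drifts about −0.3% while μs′
doubles (the same sign of drift the real instrument titrations showed).
The raw recovered-value crosstalk therefore bottoms out at that real
coupling (≈ −25 dB), while the algorithm's own contribution sits below
−40 dB (machine-precision inversions put it near −100 dB or at the
−Inf sentinel); instrument crosstalk in practice is larger and
hardware-dominated.

## Synthetic data

The generators produce everything the pipeline reads, deterministically
per seed. Tissue emulation ranges: $\mu_a$ 0.005–0.03 mm$^{-1}$,
$\mu_s'$ 0.5–1.5 mm$^{-1}$, BFi $10^{-8}$–$10^{-6}$ cm$^2$/s,
$\beta = 0.5$. A loading session is 480 s at 2 Hz: baselines (defaults
oxy 60 µM, deoxy 30 µM, BFi $10^{-8}$ cm$^2$/s, $\mu_s'$ 0.9 / 0.8
mm$^{-1}$), plus two gamma-shaped activation bumps — unit-peak
$x^\kappa e^{\kappa(1-x)}$ with $\kappa = 3$, peaks at 100 s and 210 s
(within the 240 s post-onset window), rise scales 25 s and 40 s —
scaled per parameter (+8/+6% oxy, −10/−8% deoxy, +120/+90% BFi; total,
StO$_2$ and MRO$_2$ are derived, never independently planted, so the
traces stay internally consistent). Breathing at 0.25 Hz appears
multiplicatively on the raw 730 nm amplitude (1% depth), at half depth
on 830 nm, and weakly on the flow channel, mirroring where respiration
shows up in real raw signals. Noise defaults are instrument-grade:
0.5% multiplicative amplitude, 1 mrad phase, and a simplified
multi-tau Koppel g2 noise ($\mathrm{sd}(\tau_j) \propto
\sqrt{1+\beta g_1^2}/\sqrt{j}$, scale 0.002).

What passing the synthetic end-to-end checks shows: the chain recovers
what it planted — activation offsets within one effective sample (2 s
at 0.5 Hz), percent changes within one point after applying the same
filter to the truth, respiration within 1 BPM. What it does not show:
robustness to motion artifacts, cardiac pulsation, probe-coupling
drifts, multi-layer anatomy (skin/adipose over muscle), or myoglobin/
hemoglobin separation — none of which the generators emulate, and the
first three of which are prominent in real muscle recordings.

## Numerical notes

- Round trips: FD forward-then-invert on 50 random interior points is
  exact to well below the 2% bound (machine precision with the engine
  polish); BFi round trips are within 1% across
  $[10^{-8}, 10^{-6}]$ cm$^2$/s.
- Degenerate inputs: flat g2 curves, zero baselines, non-positive
  amplitudes, singular extinction bases, empty streams and uncovered
  windows all raise typed errors; out-of-range LUT queries clamp and
  flag by default.
- Ties in the LUT cell search resolve toward the smaller-$\mu_a$ node
  by the ordering of the coarse scan; with the engine polish the choice
  does not affect the solution.
- All simulators and the transport engine take integer seeds and are
  bit-reproducible; seeds are recorded in object metadata.
- Validation problem sizes (chosen once for desk-scale runtimes and
  used by both the test suite and `scripts/acceptance.R`): 60×60
  default LUT; 50-point FD and 10-point BFi round trips; 20-point
  oracle equivalence; the 3×3 transport grid at $7\times10^5$ photons
  per cell; 20 seeded sessions; 2 repeats per titration step.
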