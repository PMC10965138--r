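# nirsdcs

Processing chain for hybrid **frequency-domain near-infrared
spectroscopy (FD-NIRS) + diffuse correlation spectroscopy (DCS)**
monitoring of skeletal muscle — the instrument class used to watch
accessory inspiratory muscles such as the sternocleidomastoid respond
to a breathing load. It is written for researchers who have (or
simulate) raw streams from such a device: modulated-light amplitude and
phase at 730/830 nm (139/149 MHz, 25 mm source–detector separation)
plus intensity-autocorrelation curves g2(τ) at 852 nm, sampled at 2 Hz.

The chain implements, end to end:

1. **Optics inversion.** Amplitude/phase → (μa, μs′) per wavelength via
   a lookup table built from a forward engine — an extrapolated-boundary
   photon-diffusion model or a seeded Monte Carlo photon transport
   (Henyey–Greenstein g = 0.9, n = 1.37) — after removing the
   instrument response with a reference-phantom calibration.
2. **Chromophores.** Beer's law with known extinction coefficients
   (62.5% water / 20% lipid background) → oxy/deoxy/total [Hb+Mb] and
   StO₂ = 100·oxy/total.
3. **Flow.** g2(τ) with the recovered optics → blood flow index BFi
   (Brownian αD_b, cm²/s) through the semi-infinite correlation
   diffusion equation and the Siegert relation g2 = 1 + β·g1².
4. **Metabolism.** Fick's principle,
   MRO₂ = HGB·BFi·(SpO₂ − StO₂) / (γ·mw_Hb),
   with HGB 14/16 g/dL by sex, SpO₂ 0.98, venous ratio γ = 0.75,
   mw 64,500 g/mol.
5. **Time-trace analysis.** 0.02 Hz second-order Butterworth low-pass,
   50 s baseline, normalization, two-region activation features
   (offset from load onset at 60 s, percent change from baseline),
   and respiration rate from the high-passed (0.03 Hz) raw 730 nm
   amplitude.
6. **Validation.** Liquid-phantom titration simulators (nigrosin /
   Intralipid serial replacement, stirred-flow), crosstalk in decibels
   (10·log₁₀ of the undesired/desired normalized change), and seedable
   synthetic loading sessions so every stage runs without instrument
   data.

## Worked example

```r
library(nirsdcs)

lut <- build_fd_lut()                      # diffusion-engine table, 60x60

# crosstalk arithmetic on the published per-wavelength titration changes
pairs <- crosstalk_from_changes(published_titration_changes())
pairs[1:3, c("titration", "desired_wavelength_nm", "undesired", "crosstalk_db")]
#>   titration  desired_wavelength_nm undesired crosstalk_db
#> 1 absorption                   830 bfi              -11.8
#> 2 absorption                   830 musp             -13.4
#> 3 scattering                   830 mua              -13.5
```

The worst pair — the flow index moving 19% while absorption was
titrated 286% at 830 nm — is attenuated 11.8 dB; every other pair is
attenuated more.

```r
# a synthetic 8-minute loading session, processed end to end
scen <- subject_scenario(sex = "male", seed = 42)
sess <- simulate_scm_session(scen)
out <- process_stream(sess$fd, sess$dcs, identity_calibration(), lut,
                      run_config(), sess$assume)
out[1:3, c("time_s", "mua_730", "oxy_um", "deoxy_um", "sto2_pct",
           "bfi_cm2s", "mro2")]
#>   time_s mua_730 oxy_um deoxy_um sto2_pct      bfi_cm2s     mro2
#> 1   0.75  0.0143   60.0     29.9     66.7 0.0000000101  1.05e-12
#> 2   2.75  0.0144   59.8     30.1     66.5 0.00000000986 1.03e-12
#> 3   4.75  0.0143   60.1     29.9     66.8 0.0000000101  1.05e-12
```

Each row is one 0.5 Hz timepoint: absorption in 1/mm, concentrations
in µM (the session plants a 60/30 µM oxy/deoxy baseline, i.e. StO₂
≈ 67%), BFi in cm²/s around its 1e-8 baseline, and MRO₂ in
mol_Hb·cm²/(dL·s).

```r
an <- analyze_session(out, run_config(), fd_raw = sess$fd)
subset(an$features, parameter %in% c("deoxy_um", "bfi_cm2s"))
#>   parameter  region offset_s percent_change found
#> 1  deoxy_um region1    42.75          -8.7   TRUE
#> 2  deoxy_um region2   152.75          -7.5   TRUE
#> 3  bfi_cm2s region1    42.75         105.5   TRUE
#> 4  bfi_cm2s region2   152.75          87.4   TRUE
median(an$respiration$breaths_per_minute, na.rm = TRUE)
#> [1] 15
```

The analyzer finds both activation regions: deoxy [Hb+Mb] dips below
baseline (valley polarity) while the flow index roughly doubles, with
offsets measured from load onset at 60 s; the planted 0.25 Hz breathing
reads back as 15 breaths/min. `plot_session(out, an)`,
`plot_titration()`, and `autoplot()` methods for traces and g2 curves
draw the standard figures; `tidy()`/`glance()` summarize fits and
crosstalk reports.

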