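# coccobloom

Detection of coccolithophore blooms from the bio-optical sensors of
autonomous profiling (BGC-Argo-style) floats.

## The problem

Coccolithophores (calcifying phytoplankton such as *Emiliania huxleyi*)
form extensive blooms in temperate and subpolar oceans. In the bloom
decline phase the cells shed their calcite platelets (coccoliths):
non-chlorophyllous, high-refractive-index particles that backscatter light
strongly and turn the surface ocean milky-turquoise. Ocean-colour
satellites see this as elevated particulate inorganic carbon ([PIC]), but
they only see the surface, in cloud-free conditions. Profiling floats
measure the particulate backscattering coefficient b_bp (700 nm),
chlorophyll fluorescence (hence [Chl-a]), and — on a few floats — the
particulate beam attenuation coefficient c_p (660 nm), day after day, down
to 1000 m.

This package implements an end-to-end procedure that

1. quality-controls raw float profiles (optical despiking, transmissometer
   fouling-drift correction, non-photochemical quenching correction,
   chlorophyll calibration, mixed-layer depth);
2. builds gap-free satellite time series along the float trajectory by
   spatiotemporal compositing (9-day average of a 5×5 pixel box);
3. labels coccolithophore bloom periods on the satellite [PIC] series — a
   baseline-crossing phenology with the added constraints
   [PIC] > 0.7 mmol m⁻³ and %PIC = 100·PIC/(PIC+POC) > 10%;
4. derives optical thresholds by ROC analysis (Youden's J) against those
   satellite labels and classifies float profiles with the dual rule

   **bloom ⇔ b_bp/[Chl-a] > θ_ratio AND b_bp > θ_bbp**,

   with b_bp/c_p as an additional discriminant where a transmissometer is
   present. The bulk refractive index of the suspended particles is
   estimated from b_bp/c_p (as a proxy for the backscattering ratio b̃)
   with the Twardowski model
   n(b̃, γ) = 1 + b̃^(0.5377+0.4867γ²) (1.4676 + 2.2950γ² + 2.3113γ⁴).

A synthetic-ocean generator (`scenario_config()`,
`generate_float_series()`, `generate_satellite_grid()`) emulates the
seasonal diatom-then-coccolithophore succession, cloud gaps, quenching,
fouling drift and optical spikes — with the uncorrupted truth channels
returned alongside — so the whole pipeline is testable without any
download.

## Worked example

```r
library(coccobloom)
report <- run_pipeline(run_config(seed = 1))
print(report)
#> <bloom_run_report>
#>   profiles: 180   bloom periods: 1
#>     period 1: 2019-01-22 .. 2019-03-13 (peak [PIC] 0.97 mmol m-3)
#>   thresholds: b_bp/[Chl-a] > 0.007048 m2/mg AND b_bp > 0.003253 1/m (sens 98%, spec 100%)
#>   Kruskal-Wallis ratio_bbp_chl: H = 109.0, p = 1.59e-25
#>   Kruskal-Wallis ratio_bbp_cp: H = 109.0, p = 1.59e-25
#>   confusion vs satellite labels: TP 50 FP 0 FN 1 TN 129
```

The simulated season runs 180 daily float cycles through a chlorophyll
bloom and then a calcite bloom. The report shows: the bloom period found
on the composited satellite [PIC] series (here exactly the simulated
window, with peak [PIC] 0.97 mmol m⁻³ — a bloom of moderate intensity);
the dual optical thresholds fitted by two-stage ROC against those
satellite labels, with the combined rule's sensitivity/specificity; and
the Kruskal-Wallis contrast of both optical ratios inside vs outside the
bloom (the in-bloom b_bp/[Chl-a] is ~3× the non-bloom baseline, hence the
tiny p-values).

```r
refractive_index(mean(report$records$ratio_bbp_cp[report$records$bloom_label]))
#> [1] 1.136
```

An in-bloom b_bp/c_p around 0.013 maps to a bulk refractive index of
~1.14 — between living phytoplankton cells (~1.05) and pure calcite
(~1.2), i.e. a particle pool rich in suspended coccoliths.

Published regional thresholds (North Atlantic subpolar gyre, Patagonian
shelf, Indian/Atlantic sectors of the Southern Ocean) ship with the
package for apply-only use:

```r
published_thresholds()
classify_records(records, published_thresholds()[1, ])
```

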