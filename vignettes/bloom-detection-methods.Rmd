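---
title: "Detecting coccolithophore blooms from float bio-optics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coccolithophore blooms from float bio-optics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccobloom)
```

## The scientific problem

Coccolithophore blooms shed calcite platelets (coccoliths) in their
decline phase. Coccoliths are small, non-chlorophyllous and have a high
real refractive index relative to seawater, so a coccolith-rich surface
ocean backscatters strongly while containing comparatively little
chlorophyll. Two float-measurable ratios therefore separate
coccolithophore blooms from other particle regimes:

* **b_bp/c_p** — the particulate backscattering-to-attenuation ratio, a
  proxy for the particulate backscattering ratio and hence the bulk
  refractive index of the particle pool. Only floats carrying a
  transmissometer can measure it.
* **b_bp/[Chl-a]** — measurable by any float with the standard
  backscattering + fluorescence payload, and therefore the basis for
  global application.

Satellites provide the reference labels: the calcite concentration
product [PIC], composited along the float trajectory, tells us when the
float was inside a coccolithophore bloom. The package's job is to carry a
raw float + satellite data pair all the way to a fitted, validated
optical classifier.

## Pipeline and models

### Float quality control

1. **Despiking.** Transient spikes (aggregates or mesopelagic animals in
   the beam) are removed with a 5-point moving median followed by a
   7-point moving average. Edges use truncated (shrinking) windows rather
   than reflection or trimming: this preserves profile length and — more
   importantly — the surface values that feed the 0–15 m layer averages.
2. **Transmissometer fouling drift.** Sinking material settles on the
   upward-facing transmissometer window, inflating c_p cycle after cycle.
   Each profile is realigned with a single *additive* offset chosen so
   that the deep-band median b_bp / median c_p equals 0.02 at the 1000 m
   reference. Additive (not multiplicative) correction reflects the
   physical cause — a uniform attenuation bias from deposited material —
   and preserves the vertical structure of c_p. The reference statistic
   uses the 950–1050 m band median rather than the single 1000 m sample,
   for robustness to residual spikes. A sensitivity check (alignment
   constant 0.01–0.03) is part of the test suite: the induced surface-c_p
   change stays below the fleet's surface spread.
3. **Mixed layer depth.** A density-threshold rule: the shallowest depth
   where potential density (sigma-t at 0 dbar, EOS-80) exceeds its 10 m
   value by 0.03 kg m⁻³, linearly interpolated. Full
   pattern-recognition MLD algorithms exist, but the pipeline uses the
   MLD only to bound the quenching-correction search; the rule is
   isolated behind `estimate_mld()` so a richer method can be swapped in.
4. **Non-photochemical quenching.** Sunlight depresses fluorescence per
   unit chlorophyll near the surface. Following the
   backscattering-extrapolation family of corrections: the quench depth
   is the depth of maximum fchl/b_bp within the mixed layer, and above it
   fluorescence is rebuilt as b_bp(z) × (fchl/b_bp at the quench depth).
   This assumes fchl/b_bp is vertically uniform in the mixed layer —
   reasonable for actively mixing layers. The correction is applied to
   all profiles (the floats of interest cycle daily; a day/night gate
   would be easy to add upstream).
5. **Chlorophyll calibration.** chl = fchl × factory slope × satellite
   factor, where the satellite factor is the median over *non-bloom*
   matchups of satellite-to-float chlorophyll (clipped to [0.25, 4]).
   Bloom matchups are excluded because satellite chlorophyll retrievals
   are biased inside coccolithophore blooms — which forces the stage
   ordering described below.

### Satellite matchup

Persistent cloudiness (the Southern Ocean norm) makes narrow validation
matchups useless for time-series work; instead each cycle gets the mean
over a 5×5 box of 4-km pixels and 9 days of daily fields. The 9-day
window is *centred* (±4 days); the convention is configurable since
leading/trailing variants exist. The nearest pixel is chosen by
pixel-centre great-circle distance with ties broken to the south-west,
so grid-edge points are deterministic. Remaining gaps (fully cloudy
windows) are filled by linear interpolation in time and flagged;
leading/trailing gaps take the nearest valid value.

### Bloom phenology

Candidate periods are maximal runs where [PIC] exceeds 1.05× the series
median — a standard baseline-crossing construction — merged across gaps
shorter than 3 records and discarded below 3 records. The constants are
all exposed as parameters. A candidate is retained only if its
within-period maxima satisfy **[PIC] > 0.7 mmol m⁻³** and
**%PIC > 10 %**; these two constraints are the substantive filter that
separates coccolithophore calcite pulses from chlorophyll-driven events,
and they are evaluated per period (a period qualifies if it ever exceeds
them) because the labels are applied to whole bloom spans. Records are
labelled by closed-interval membership.

### Classifier

"Maximising sensitivity and specificity" is operationalised as Youden's
J = sensitivity + specificity − 1 on the full candidate grid (midpoints
of consecutive sorted unique scores, ±∞ sentinels), with ties broken
toward the higher threshold — the conservative direction, fewer false
bloom calls. The dual fit is two-stage: ROC on b_bp/[Chl-a] over all
records gives θ_ratio; ROC on b_bp restricted to the high-ratio records
gives θ_bbp, which rejects records whose high ratio comes from *low
chlorophyll* (oligotrophic waters) rather than *high backscatter*
(coccolith-laden waters). Bloom calls use strict inequalities. Group
contrasts use the Kruskal-Wallis rank test (tie-corrected H, chi-square
p); the degenerate all-identical case returns H = 0, p = 1.

The bulk refractive index uses the Twardowski (2001) relation
n(b̃, γ) = 1 + b̃^(0.5377+0.4867γ²)(1.4676 + 2.2950γ² + 2.3113γ⁴),
with b_bp/c_p standing in for b̃ and the particle-size-distribution slope
parameter γ defaulting to 0 (no published value accompanies the in-bloom
b̃ ≈ 0.013 ↦ n ≈ 1.13–1.14 usage; γ is exposed so any choice is
reproducible). The model is monotone in b̃ and valid for b̃ ∈ (0, 0.05].

### Stage ordering

There is an apparent circularity: chlorophyll calibration needs non-bloom
matchups, but bloom labels might seem to need chlorophyll. They do not —
phenology runs on [PIC]/%PIC alone. `run_pipeline()` therefore orders:
QC (without the satellite factor) → matchup → phenology → satellite-chl
masking + calibration factor → labelling → ROC fit → classification.

## The synthetic ocean

The generator is first-class, tested code defining the study conditions:

* 180 daily cycles across a 2°×2° grid at 0.05° (~4 km) pixels; a
  diatom-like chlorophyll bloom (days 30–80, peak 2 mg m⁻³) followed by
  a coccolithophore bloom (days 100–150, peak [PIC] 1.0 mmol m⁻³ —
  moderate intensity, matching bloom-average [PIC] ≈ 0.97 in the
  Southern Ocean cases this emulates); non-bloom [PIC] baseline 0.15
  mmol m⁻³.
* [POC] = 3.0 + 1.5·[Chl-a] mmol m⁻³, so %PIC crosses 10% only inside
  the calcite bloom.
* The surface b_bp/[Chl-a] ratio steps to 3.3× its 1/300 m² mg⁻¹
  baseline at the bloom-window edge and rises to 0.012 m² mg⁻¹ at peak
  (the reported in-bloom float mean). The step — rather than a smooth
  ramp from baseline — is deliberate: it makes the generator honour the
  contract that the ratio is ≥3× baseline *everywhere inside* the
  window, which is what the ≥3× observed contrast describes and what
  parameter-recovery tests require. b_bp/c_p rises from 0.008 to 0.013
  the same way.
* Verticals: uniform mixed layer (80 m shoaling to 40 m over the season)
  with a C¹ cosine taper over 150 m below it; deep optical floor
  b_bp = 4×10⁻⁴ m⁻¹ with b_bp/c_p = 0.02 at depth (so an undrifted
  profile is already aligned); temperature uniform in the mixed layer
  then ramping over 60 m, which puts the density-threshold MLD just
  below the true mixed layer.
* Corruptions: quadratic quenching depression (maximal at the surface,
  C¹-vanishing at 0.75×MLD), additive c_p drift proportional to cycle,
  ×2–×10 multiplicative spikes at isolated depths (≥5 samples apart, so
  a 5-point median window never holds two), and log-normal noise
  (5% optics, 3% c_p, 5% satellite — free parameters; no published
  distributional detail exists for the region's optical noise, so these
  are chosen as plausible sensor-grade values and not revisited).
* One RNG stream per product (profile noise, clouds, spikes, satellite
  noise) derived from the master seed, so changing the cloud fraction
  does not perturb profile noise.

The depth grid is 1 m to 240 m, coarsening to 10 m at depth. The fine
upper grid is not cosmetic: after the 5-median/7-mean despiking, a spike
sitting on a vertical gradient leaves a residual of order slope×spacing,
and the 1 m spacing keeps that residual within the generator's 1%
truth-recovery contract (measured ≤0.75% of each channel's range across
seeds at zero noise).

**What the generator does not emulate:** radiative transfer, advection
and eddies, correlated cloud systems (clouds are i.i.d. pixel-days),
real vertical structure such as deep chlorophyll maxima, day/night
cycling, or sensor dropouts. Passing the recovery suites therefore shows
the *procedure* is correct and self-consistent — not that the published
regional thresholds would re-derive from real archives, which would
require the real float + satellite data.

## Numerical choices and degenerate inputs

* Despiking: truncated windows at edges; even-length truncated medians
  average the middle pair; <7 finite samples flags the profile unusable.
* Drift correction: skipped (flagged) above 950 m max depth; abandoned
  (flagged, excluded from ratio work) if the offset would force
  c_p ≤ 0.
* MLD: returns max(depth) when the threshold is never crossed; errors
  without a sample at/below 10 m.
* Quenching: quench-depth ties resolve to the shallowest depth; b_bp ≤ 0
  in the mixed layer flags the profile and skips the correction. The
  correction never decreases fluorescence above the quench depth and
  never alters it at or below.
* ROC: both classes required; a single-class stage-2 subset falls back
  to the minimum bloom-class b_bp (flagged).
* %PIC undefined (flagged) when PIC + POC = 0.
* Phenology needs a gap-free series (≥15 records) — it errors otherwise
  rather than silently running over gaps.

## Problem sizes and test design

Unit tests run on a 60-day compact scenario; the recovery suites use the
full default scenario (180 cycles, ~405 depths) across 20 seeds, the
Kruskal-Wallis power check uses 100 draws of n = 50 per group, and the
despiking/compositing/ROC oracles use 1000 random profiles, 20 random
masked grids, and every labelling of up to 12 records respectively.
"Recovered within one composite step" means within 9 days — the
compositing window is the effective temporal resolution of the matched
series, even though records are daily.

## Known limitations

* The quenching correction is a single documented rule from the
  backscattering-extrapolation family; instrument- or region-specific
  variants exist and can replace it behind the same interface.
* Region polygons are editable rectangular approximations; the bundled
  regional thresholds are for apply-only use, not re-derived here.
* Sigma-t at 0 dbar stands in for potential density; for mixed-layer
  work in the upper few hundred metres the difference is negligible.
* File interfaces are flat CSV tables (long-format profiles, gridded
  fields, per-cycle records); NetCDF readers can be layered on without
  touching the analysis surface.
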