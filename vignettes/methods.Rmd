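---
title: "Methods: FRET calcium screening analysis with fretscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FRET calcium screening analysis with fretscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscreen)
```

## The assay and its model

`fretscreen` analyzes phenotypic drug screens built on ratiometric FRET
calcium imaging. HEK293 cells carrying a familial-Alzheimer presenilin-1
mutation and the Yellow Cameleon 3.6 sensor show an exaggerated ER calcium
release when stimulated with the muscarinic agonist carbachol (CCh); the
screen looks for compounds that normalize that release. The observable is
the YFP/CFP emission ratio \(F(t)\) of each cell over a short time-lapse;
calcium binding raises FRET and therefore the ratio.

Per cell, the pipeline computes

\[
\Delta F/F_0(t) \;=\; \frac{F(t) - F_0}{F_0},
\qquad
F_0 = \text{mean of the pre-stimulus frames},
\]

and reports the **peak amplitude** \(\max_{t \ge t_d} \Delta F/F_0(t)\),
with \(t_d\) the first post-dispense frame (the rise begins immediately
after dispensing, so the dispense frame itself is searched). Cells whose
peak stays below a responder threshold \(\theta\) (default 0.1, boundary
inclusive) are excluded; the well readout is the mean peak over responsive
cells. Well readouts are divided by the mean of the DMSO vehicle wells
("normalized ER calcium", vehicle mean exactly 1 by construction), replicate
wells are averaged per compound, and a compound is **active** iff its mean
normalized value is strictly below 0.9.

## Acquisition schedule

The default schedule has 13 frames: pre-stimulus at 0, 2.5, 5 s, then 1-s
resolution for 5 s (6–10 s) and 2.5-s resolution for 12.5 s (12.5–22.5 s).
The stated interval structure spans 22.5 s first-to-last, while the assay's
total per-well duration is quoted as 23.5 s; the difference is plausibly
dispensing dead time that is not imaged. We ship the 13-frame schedule as
the default because the intervals are specified more precisely than the
total, and the schedule is fully user-configurable (`acq_schedule()`).
Internally `dispense_index` is the 1-based index of the first post-stimulus
frame (4 for the default), i.e. three pre-stimulus frames enter \(F_0\).

## Segmentation

No R image-processing package is assumed: blur, Otsu thresholding,
connected components, chamfer distance and seeded growing are implemented
as vectorized whole-matrix operations (`R/imageops.R`), which is fast at
screening field sizes (a 256×256 field with 60 cells segments in well under
a second).

* **Nuclei** (far-red nuclear dye): Gaussian smoothing (σ = 2 px), Otsu
  threshold (so detection is invariant under uniform intensity scaling),
  connected components, and a distance-transform watershed split of fused
  nuclei. Split markers are the pixels at ≥ 80 % of a component's peak
  chamfer distance; the fraction is 0.8 rather than a more conventional
  0.5–0.6 because σ = 2 smoothing widens the neck between two disks
  overlapping by 20 % of their radius to ~0.75 of the peak distance — 0.8
  splits that dumbbell while leaving single disks whole. Minimum nucleus
  area defaults to 30 px at the synthetic scale.
* **Cells**: the cytoplasmic (CFP+YFP) frame of the first pre-stimulus time
  point is smoothed and thresholded into a foreground mask, and cell labels
  are grown from the nucleus seeds by synchronous multi-source propagation
  restricted to that mask. Cells therefore partition the foreground, each
  retained cell contains exactly one nucleus, and labels are reused across
  the ~23 s time-lapse (cell movement is negligible on that scale).
* **Edge rule**: any cell with a pixel on the outermost rows/columns is
  excluded, strictly — no tolerance is defined upstream, so none is
  invented.
* **TMRM**: mitochondrial membrane potential is quantified as the plain
  field-level mean intensity (optionally percentile-background-subtracted);
  no segmentation, matching how the assay is read.

## Ratio extraction and background

The per-cell ratio is mean(YFP)/mean(CFP) over the cell's pixels, per
frame. Because Otsu masks dilate cells by roughly the smoothing radius, a
thin rim of background pixels is typically included; uncorrected, this
biases the ratio by ~1 % and the peak amplitude by several percent. With
`background = "field"` the per-frame, per-channel mean of the unlabeled
pixels is subtracted first, after which background pixels cancel exactly:
for any mask overlapping the cell the subtracted ratio equals the true cell
ratio in the noiseless limit. The end-to-end pipeline then recovers true
per-cell amplitudes to better than 10⁻³ on noiseless synthetic wells.

## The synthetic world

The generator states, rather than estimates, its world; defaults are
declared here and not revisited:

* **Transient**: \(R(t) = R_0\,[1 + A\,g(t)/\max g]\) with
  \(g(t) = (1 - e^{-(t-t_d)/\tau_r})\,e^{-(t-t_d)/\tau_d}\),
  \(\tau_r = 0.5\) s, \(\tau_d = 4\) s. The product-of-saturating-rise-and-
  exponential-decay form is the simplest monotone rise-then-decay; the
  peak-normalization makes the noiseless peak \(\Delta F/F_0\) equal
  \(A\) exactly, which is what makes ground truth exact. Multiplicative
  Gaussian frame noise, CV 0.02 by default.
* **Amplitudes**: wild-type well amplitude 0.8; mutant-genotype enhancement
  factor 1.5 (the enhancement is shown but not quantified upstream;
  configurable); per-cell lognormal heterogeneity, CV 0.2; 10 % of cells
  nonresponsive (A = 0), which is what the responder filter is for.
* **Compound action**: a multiplicative peak scaling in (0, 1]; vehicle
  and untreated wells 1.0; positive-control presets TP 0.15, CPA 0.2,
  TMB-8 0.4, Bepridil 0.5 (invented, configurable).
* **Fields**: cells are disks with the nucleus strictly inside; the two
  FRET channels redistribute a frame-constant per-pixel sum so that
  YFP/CFP equals the cell's ratio, a uniform background is added to every
  pixel, and a requested fraction of cells intersects the border.
* **Dose–response / ELISA**: responses are a 4PL evaluated at the design
  concentrations with multiplicative noise; ELISA plates carry labeled
  calibration standards plus unknowns.

What the generator does **not** emulate: optics (PSF, vignetting),
photobleaching, cell movement/division, focus drift, nonresponder biology
beyond A = 0, or spatial plate effects. A green segmentation or screening
test therefore certifies the algorithms against this idealized world, not
robustness to those artifacts.

## Statistics

One-way ANOVA with a pooled equal-variance error term is followed by
Dunnett's two-sided many-to-one comparisons against the vehicle. The joint
law of the comparison t statistics is a central multivariate t with product
correlation \(\rho_{ij} = \lambda_i \lambda_j\),
\(\lambda_i = \sqrt{n_i/(n_i + n_0)}\); no multivariate-t package is
assumed, so the adjusted p-value is computed by direct 2-D numerical
integration — conditioning on the shared control-mean normal and the pooled
scale chi variable renders the comparisons independent — with a seeded
Monte-Carlo fallback. With one comparison the integral collapses to the
pooled t-test (verified to 10⁻⁶), and for k = 5 it agrees with a 10⁵-draw
Monte-Carlo reference within 0.01. Stars follow the usual convention
(\*, \*\*, \*\*\* at 0.05, 0.01, 0.001; else n.s.).

Null calibration is checked by simulating all-inert plates and testing each
of 200 compounds against the vehicle wells in its own family (one
comparison per family, as in per-figure many-to-one analyses); the fraction
reaching adjusted p < 0.05 must sit inside the 95 % binomial band around
0.05.

**Toxicity interference**: compounds that kill or stun cells corrupt the
calcium readout. The proxy here is the responsive-cell fraction: a well
with fewer than 20 % responders is excluded, and a compound left with no
valid well is annotated `toxicity_interference` rather than scored.

## Dose–response and ELISA

The four-parameter logistic
\(y = \text{bottom} + (\text{top}-\text{bottom})/(1 + (\text{EC}_{50}/c)^{h})\)
is fit by profiling: for fixed (log EC50, hill) the asymptotes enter
linearly and are solved exactly, leaving a 2-D Nelder-Mead search
(unweighted least squares on the linear response scale, concentrations on
the log scale). Noiseless data are recovered essentially to machine
precision. Fits are canonicalized to top > bottom — the mirrored
(top, bottom, −hill) triple is the same curve — so decreasing (IC50-style)
curves report hill < 0 with top at the vehicle asymptote. Flat data
(response range below 3× the pooled replicate noise) yield a degenerate-fit
flag instead of a meaningless EC50.

**EC50 identifiability caveat.** On the assay's six concentrations
(0.1–30 µM, ≈6× the 4.84 µM half-max of the TMRM preset) the upper plateau
is never observed. With multiplicative CV-10 % noise the fitted EC50 then
has a median absolute error near 36 % and a median bias near +8 % — a
property of the design, not the fitter (an independent `nls` fit reproduces
this fitter's estimates seed by seed). On a log-symmetric design spanning
100× either side of the EC50 the median signed bias is ~1 %. The unit suite
asserts the bias on the bracketing design; the acceptance suite keeps the
assay design and documents the resulting red criterion in the decisions
ledger.

ELISA back-calculation fits the 4PL to ≥ 6 calibration standards (a
< 3-log-unit span attaches a warning) and inverts replicate-mean signals
through the closed-form inverse. Signals at or beyond the asymptotes, and
concentrations outside the standard range, are flagged — never clipped.

## Mechanism classification

Vehicle-normalized analyte levels (DMSO = 1) are banded into down
(< 0.8), unchanged ([0.8, 1.25]) and up (> 1.25); the band is symmetric on
the log scale, since fold-changes live there. Rules apply first-match-wins:

1. **γ-inhibitor** — every Aβ species down in both the APP and the C99
   context (total block of γ-cleavage).
2. **γ-modulator** — Aβ42 down, Aβ38 up, Aβ42/40 ratio down (cleavage
   shifted to shorter species).
3. **inverse γ-modulator** — Aβ42/40 ratio up (judged in the C99 context
   when available, else APP).
4. **β-cleavage reduction** — Aβ down in the APP context with the ratio
   unchanged while γ-cleavage itself is intact: C99-context levels
   unchanged (when measured) and/or sAPPβ down with sAPPα unchanged.
   C99 evidence is optional by design — when it is absent the sAPP pattern
   is required, since Aβ-down alone cannot separate β- from γ-effects.
5. **no effect** — everything inside the band; otherwise **unclassified**.

Rule 1 requires the C99 context: without it a total-production drop is not
distinguishable from a β-effect, and falls through to rule 4's evidence
requirements. The Aβ42/40 ratio is computed after vehicle normalization;
the vehicle scale cancels, so it equals the raw concentration ratio
relative to the vehicle's raw ratio (asserted to 10⁻¹²).

## SAR summary

Compounds are grouped by substituent classes at the two variable positions
of the tetrahydrocarbazole scaffold. Electron-withdrawing R¹ groups
(nitro, halogen, trifluoromethyl, cyano) combined with
N-(1-benzylpiperidin-4-yl) or N-(1-phenethylpiperidin-4-yl) at R² are
labeled expected-active; hydrogen at R¹ or aliphatic R² expected-inactive;
other combinations unclassified. Measured per-assay group means are
reported alongside so expectation and measurement can disagree visibly.

## Reproducibility

Every stochastic generator funnels through a single seed helper that
restores RNG state, so all generators are pure functions of (parameters,
seed); per-well and per-stage child seeds derive deterministically from the
run seed and stay below 2³¹. `run_pipeline()` is byte-identical under a
fixed (config, seed), and the run manifest records the package version,
seed and an MD5 of the serialized config. Configuration is JSON
(`save_config()`/`load_config()`); stacks serialize to a plain-text format
(`write_stack_txt()`) rather than TIFF so no image library is required.

## Known limitations

* Segmentation fidelity is asserted against the synthetic world only; the
  upstream vendor software's exact algorithms are proprietary and
  unknowable from the outside.
* The responder threshold θ is assay-defined ("arbitrarily defined"
  upstream); results depending on it expose it as a parameter.
* The EC50 of weak-span curves on truncated designs is poorly identified
  (see above); confidence output (`$se`) is linearized and approximate.
* The toxicity-interference proxy (responder fraction < 0.2) is a declared
  stand-in for an unstated upstream criterion.
* No 5PL curves, no Z′-factor plate metrics, no decay-kinetics (τ)
  fitting.
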