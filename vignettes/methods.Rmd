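---
title: "Calibrating leaf nutrient predictions from NIR spectra: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating leaf nutrient predictions from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafnirs)
```

## The problem

Leaf nitrogen and phosphorus content are central plant functional traits,
classically measured by destructive wet-lab chemistry (combustion
analysis for N; acid digestion and chromatography for P). Near-infrared
reflectance spectroscopy offers a fast, non-destructive alternative: the
350–2500 nm diffuse reflectance of a leaf carries overtone and
combination bands of N–H, C–H and O–H bonds, so a statistical calibration
can map spectrum to trait. The appeal is greatest for herbarium
collections — millions of pressed, dried, archived specimens — but those
specimens have been dried, frozen, sprayed with pesticide, and stored for
years, and each of those steps could distort the spectrum–trait link.

`leafnirs` implements the full calibration chain (preprocessing,
calibration/validation splitting, PLS regression, spectral-region
selection, outlier screening, evaluation, and group-comparison
statistics) together with a synthetic-data generator that emulates three
designs: a factorial fertilization experiment that creates trait
variation and paired fresh/dried scans; a conservation-treatment
experiment with six treatment groups and untreated controls; and a
storage experiment in which the same dried specimens are re-scanned in a
later session by a different operator.

## Preprocessing

**Replicate averaging.** Each leaf is scanned several times on the same
spot and the scans are averaged wavelength-wise (`average_replicates()`).
Averaging is idempotent and never leaves the per-wavelength envelope of
the replicates.

**Splice correction.** Full-range spectroradiometers concatenate three
internal detectors; radiometric mismatch leaves artificial steps at the
boundaries. `splice_correct()` removes them additively: after each splice
point the whole later segment is shifted so its first value equals the
last value of the (already corrected) segment before it. The first
segment anchors the spectrum and corrections compose left to right. This
is the simplest correction that removes the steps while leaving every
within-segment difference — i.e. all band shapes — untouched. The default
splice points, 1000 and 1800 nm, are the conventional VNIR/SWIR1/SWIR2
boundaries of such instruments; manufacturers do not standardise them, so
they are configurable. Because an offset can push values past the
physical range, corrected values are clipped into (1e−6, 1] with a
warning that counts the clipped values; the lower bound keeps later
log/absorbance transforms defined.

## Kennard–Stone splitting

Calibration quality is judged by test-set validation, so the split must
span spectral space rather than sample it randomly. The Kennard–Stone
algorithm seeds with the two most distant spectra (Euclidean distance)
and then greedily adds the sample farthest from the selected set
(max–min), until half the samples (round half-up) are selected.

Three choices were genuinely open:

- *Distance space.* Distances are computed on the full preprocessed
  spectrum (post-averaging, post-splice, before any region subsetting),
  without autoscaling — reflectances share units, and a single split
  reused across all region-search iterations keeps their validation
  scores comparable.
- *Tie handling.* All ties (the seeding pair and every greedy argmax)
  break toward the smaller original row index. Any fixed rule would do;
  this one makes the split a pure function of the input ordering, which
  the tests exploit by checking exact agreement with an exhaustive greedy
  oracle.
- *Per-dataset splitting.* Fresh and dried spectra of the same leaves are
  split separately, mirroring the fact that each leaf state gets its own
  calibration model.

## The PLS1 engine

Partial least squares regression handles the p ≫ n, highly collinear
predictor structure of spectra. The implementation is NIPALS PLS1: for
each component the weight vector is the covariance direction
w ∝ Xᵀy between the deflated predictors and response, the score is
t = Xw, and X and y are deflated by the loading/score outer products.
With a single response the inner loop converges in one pass, so the
algorithm is a closed-form sequence of matrix products — deterministic to
the bit. The regression vector for k components is
B = W(PᵀW)⁻¹q, accumulated triangularly, so one fit at the maximum
component count yields predictions for every truncated count at almost no
cost.

Numerical choices: predictors are mean-centred only (a unit-variance
option exists but defaults off — autoscaling would inflate noisy
water-dominated regions); the rank/convergence tolerance is 1e−10 on
residual norms, with extraction truncating (and messaging) if the
deflated X collapses; the maximum component count defaults to 10, capped
at min(n−1, p), a typical chemometrics ceiling.

**Component selection.** No single selection rule is canonical in the
calibration literature; this package minimises validation RMSEP over
1..max components, breaking near-ties (relative 1e−8) toward fewer
components so that flat error curves yield the parsimonious model.

## Randomized region search

Whole-spectrum PLSR dilutes a localized trait signal across thousands of
mostly uninformative wavelengths. The optimizer therefore repeats, for a
configurable number of iterations (default 200): draw a random set of
wavelength intervals, restrict the predictors to them, select the
component count, fit on the calibration set, and score validation RMSEP
on the model's working scale. The winner is the candidate with the lowest
validation RMSEP (ties: higher R², then the earlier iteration).

Design choices worth stating:

- *The full-spectrum baseline is always a candidate* (logged as iteration
  0). Region selection is an attempted improvement; including the
  baseline guarantees the search never returns a model worse than no
  selection, at the cost of one extra fit.
- *Interval geometry.* A draw takes a region count uniform on 1..8, then
  for each interval a width uniform between the minimum width (20 nm) and
  span/8 (~269 nm on the default grid), and a uniform on-grid start;
  overlapping or touching intervals merge. Capping the width at span/8
  lets even eight intervals tile the spectrum without forced overlap, so
  the realized interval count actually covers the whole 1..8 range —
  with a freely drawn second boundary the mean interval spans a third of
  the spectrum and eight draws essentially always merge into few wide
  bands. The capped draw behaves like the window search of interval-PLS
  methods.
- *One split per run.* The Kennard–Stone split is drawn once on the full
  spectrum and reused by every iteration, so iteration scores differ only
  in the regions, not in the validation set.
- *Response transform.* Traits that saturate against their driver (leaf N
  against fertilization dose) are right-skewed; such responses are
  modelled as ln y (requiring y > 0) and predictions back-transformed
  with exp. Metrics are reported on the working (transformed) scale, the
  scale on which the model was selected.

## Outlier screening

The screen is a univariate residual test on the winning model's
calibration residuals: Fᵢ = eᵢ² / s²₍₋ᵢ₎, where s²₍₋ᵢ₎ is the mean
squared residual with sample i removed, compared against the 99.9th
percentile of F(1, n−2). The specific variance estimator and degrees of
freedom are a documented choice (the deletion variance makes the test
sensitive to single gross errors without the outlier inflating its own
yardstick; 1 numerator df for the single squared residual, n−2 accounting
for the fitted mean response). At the 99.9th percentile about 0.1% of
clean samples are flagged — the tests verify both the hit rate on
injected 100× residuals and the false-alarm rate on clean ones.

Flagged samples are *reported, never silently removed*: removal in
practice requires re-evaluation by the analyst, so it is modelled as an
explicit `remove_outliers = TRUE` request, after which the winning
configuration is refit without the flagged samples.

## Group statistics

Experiments 2 and 3 compare *predictions* across groups, so the
comparison statistics are implemented from their defining formulas (and
cross-checked in the tests against independent implementations):
Kruskal–Wallis with mid-ranks and the tie-correction factor
1 − Σ(t³−t)/(N³−N), p-values from the χ² approximation with k−1 df (a
Monte Carlo permutation p is available for very small groups, where the
χ² approximation is crudest); Dunn's pairwise z statistics with the tied
pooled-variance term, two-sided normal p-values, Holm-adjusted by default
(no adjustment is also available, and the choice is recorded in the
output); Pearson correlation from centred cross-products, erroring on
constant input rather than returning NA. When all pooled observations are
tied the Kruskal–Wallis 0/0 is defined as H = 0 (no evidence of
difference). Dunn's test is only invoked when the preceding
Kruskal–Wallis is significant at α = 0.05.

A deliberate replication quirk: the four-source comparison (predictions
from fresh, dried, treated spectra, plus laboratory values) treats paired
measurements of the same leaves as independent groups. That matches the
analysis being replicated; a repeated-measures design would be more
powerful and is out of scope.

## The synthetic generator

The generator exists so every stage — including the full pipelines — can
be exercised and falsified without external data. It emulates, with one
seed controlling everything:

- **Design.** 3 species × 80 individuals spread evenly (5 per species per
  cell) over the 4×4 factorial of N levels {5, 20, 100, 200} and P levels
  {1, 4, 20, 40} kg ha⁻¹ yr⁻¹; paired fresh and dried scans, 3 replicates
  each. The treatment experiment uses 40 specimens of one species: six
  treatment groups of 5 (freezing/drying/pesticide combinations) plus 10
  controls. The storage experiment re-scans 40 dried specimens.
- **Traits.** Ground truth follows a saturating (Michaelis–Menten-type)
  dose response per species with lognormal biological scatter; the P
  response has a smaller relative gain than N (its response to
  fertilization is less pronounced). The saturating design makes leaf N
  right-skewed and ln(leaf N) roughly symmetric — the motivation for the
  natural-log calibration transform.
- **Spectra.** Beer–Lambert-style forward model: absorbance = smooth
  baseline + Gaussian bands scaled by their driver (N bands at 1510,
  2054, 2180 nm; weak P bands at 1680, 2380 nm; water at 1450, 1940 nm,
  large in fresh leaves, small after drying; band centers are
  conventional NIR assignments and fully configurable). Reflectance is
  10^(−A) times a per-scan affine scatter term, plus additive noise, plus
  small per-detector step offsets at the splice points (so splice
  correction operates on realistic, discontinuous scans), clipped to
  (0, 1].
- **Reference values.** Wet-lab assays are ground truth times independent
  lognormal assay noise, so calibration R² is bounded below 1 even with
  perfect spectra — as with real reference chemistry.
- **Treatments.** The conservation treatments have *zero chemical effect*
  by default: treated spectra differ from dried ones only by idiosyncratic
  smooth per-leaf perturbations and scan noise. An effect-size knob adds
  an absorption feature to one group for power studies.
- **Operator drift.** The re-scan session scanned by a different operator
  carries an affine distortion with a session-common component and a
  per-sample probe-placement component of equal sd. A purely
  session-common distortion would barely move Pearson correlations
  (correlation is affine-invariant); the per-sample component is what
  degrades the between-session prediction correlation.

Default noise and amplitude levels were fixed once, by two calibrations
of realism: dried-leaf N calibrations at the full design size reach
validation R² around 0.7–0.8 (P around 0.5–0.6), the regime reported for
real greenhouse leaf calibrations; and the storage drift sd (0.4) is set
so the between-session prediction correlation collapses toward zero —
the regime observed when herbarium specimens are re-scanned years later
by different hands. Both are soft realism anchors, not tuned per-test
quantities.

**What passing tests do not show about real data.** The generator's
bands are few, Gaussian, and exactly linear in the traits; real leaf
spectra have hundreds of overlapping non-Gaussian features, nonlinear
water interactions, and scattering physics (which SNV/MSC-style
pretreatments address — deliberately out of scope here, as is any
radiative-transfer leaf model). Passing the recovery tests shows the
chain is implemented correctly and can find localized signal; it does
not certify any particular R² on real leaves.

## Degenerate inputs and numeric edges

- All-identical spectra make the Kennard–Stone seeding undefined → error.
- Zero-variance responses cannot be calibrated → error before fitting.
- All-zero residuals produce no outlier flags (0/0 guarded to 0).
- R² is refused (with RMSEP still computed) when the observed validation
  values are constant.
- Serialization uses 17 significant digits, the minimum that round-trips
  an IEEE double exactly, so save → load → apply is bit-identical, and
  two runs under one master seed produce byte-identical artifacts.
  Master-seed fan-out draws one 31-bit sub-seed per stage
  (`derive_seeds()`), so adding stages never perturbs earlier ones.

## Problem sizes in the test suite

Unit tests run on a reduced design (16 individuals per species, 2
replicates) chosen to exercise every code path in seconds. The
end-to-end property tests use the full 240-sample design with the
200-iteration region search for the headline recovery checks, 25–40
iterations for multi-seed comparisons, and a single-replicate design for
the 500-run type-I-error study of the treatment comparison — sizes at
which each property is already stable.

## Known limitations

- PLS1 only; correlated multi-trait calibration (PLS2) is out of scope.
- No spectral pretreatments beyond splice correction and averaging.
- The region search is randomized, not exhaustive; with few iterations it
  can miss narrow signal (the full-spectrum baseline bounds the damage).
- The χ² approximation for Kruskal–Wallis is crude below ~5 observations
  per group; use the permutation option there.
- The generator does not emulate species-specific spectral shapes beyond
  trait levels, so per-species breakdowns on synthetic data are
  structurally optimistic.
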