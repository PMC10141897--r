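---
title: "Classifying annotated tissue from DESI-MSI spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying annotated tissue from DESI-MSI spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Desorption electrospray ionization mass spectrometry imaging (DESI-MSI)
profiles small molecules — predominantly lipids and metabolites — across a
tissue section on a pixel grid, here 100 µm pixels over m/z 50–1500 in
negative-ionization mode. After imaging, the same section is stained and
annotated by pathologists, so every pixel can be assigned a tissue label:
adenocarcinoma (AdC), benign mucosa (BM), submucosa (Sub), smooth muscle
(SM), serosa (Ser), or inflammatory cells (IC). The analytical questions
are (i) whether the spectra predict the annotation, especially tumour
versus non-neoplastic tissue, when evaluated across patients rather than
across pixels; (ii) which individual ions carry that signal; and (iii)
whether ions track clinical covariates such as lymphovascular invasion
(LVI) or sex.

`desiclass` implements the full chain — imzML input, lockmass
recalibration, top-N peak selection, TIC normalization, kernel-density
m/z binning, region-of-interest (ROI) extraction, PCA/LDA classification
under leave-one-patient-out cross-validation (LOPO-CV), per-ion
statistics, and putative lipid annotation — together with a synthetic
cohort generator so that every stage is testable without instrument
data.

## The synthetic cohort generator

`generate_cohort(synth_config(...))` emulates a 10-patient surgical
cohort: per patient one full-thickness cross section (40×60 pixels by
default) and one simulated endoscopic biopsy (20×20). Cross sections are
a background frame around four layered bands (BM | Sub | SM | Ser) with
an AdC ellipse and two IC infiltrates; biopsies contain only BM, AdC and
IC. Clinical metadata reproduce a reference 10-patient table (six
LVI-positive, one MMR-deficient).

Each pixel spectrum is a centroided peak list containing:

* **Background ions.** A cohort-wide library of 850 species at uniform
  random m/z; each appears in a pixel with probability 0.35 (about 300
  peaks per pixel), with log-normal species base intensities
  (meanlog = log 100, sdlog = 1) and mean-one log-normal pixel noise
  (CV 0.5). Presence is per pixel, not per slide, so that with no
  planted patient effect the patients are statistically exchangeable —
  a property the adversarial experiment (below) relies on.
* **Region markers.** `default_markers()` plants the C20–C26 saturated
  and monounsaturated fatty-acid elongation series in AdC at fold
  changes 2.6–17.5 (base intensity 120, per-pixel CV 0.35), a lyso-PE
  and two PE/plasmalogen species in BM, a phosphatidylserine group in
  IC, and one modest invented marker in each of Sub/SM/Ser so the six
  regions are separable. Every marker carries a +1.00336 Da
  one-substitution ¹³C isotopologue at the natural carbon-count fraction
  (0.0107 per carbon).
* **Lockmass.** A leucine-enkephalin peak at m/z 554.2615 in every
  pixel.
* **Distortions.** A per-slide mass drift (SD 0.002 Da) added to every
  m/z; per-peak m/z jitter (SD 5×10⁻⁴ Da, well inside the binning
  bandwidth); a mean-one per-pixel TIC multiplier (CV 0.25); and,
  optionally, mean-one log-normal per-patient, per-marker level effects
  with log-scale SD `patient_effect_sd` (default 0), shared between a
  patient's cross section and biopsy.

The per-pixel peak count, noise distributions and the invented
connective-tissue markers are modelling choices, not measurements; they
were fixed once at values that give realistic volcano p-value spread and
are all settable. What passing tests show is therefore that the
*algorithms* behave correctly under a controlled generative model — not
that real tissue is this simple. In particular the generator does not
model ionization or chromatographic physics, profile-mode peak shapes,
spatial intensity gradients, or annotation error.

A useful consequence of TIC normalization worth knowing when reading
calibration numbers: a planted fold change F is observed as roughly
F / (1 + e), where e is the enriched markers' own share of the pixel
TIC (~10% for the default AdC block), because enrichment inflates the
denominator. The calibration tests account for this dilution.

## Preprocessing

* **Lockmass correction** finds all peaks within ±0.05 Da of 554.2615
  in the slide's pooled spectrum and applies the constant additive
  shift that puts their intensity-weighted mean exactly on the
  reference. A single-point additive model (not ppm-proportional) is
  used because one reference mass is available; the operation is
  idempotent and the shift is recorded in the slide metadata. 554.2615
  is retained as the reference value by instrument convention even
  though the formula-derived [M−H]⁻ mass of C28H37N5O7 is 554.2620.
* **Top-N selection** groups a slide's pooled pixel peaks into species
  by the same kernel-density clustering used for cohort alignment and
  keeps the 2000 species with the largest slide-wide summed intensity
  (interpreted per slide, not per pixel, so that bin presence is
  consistent across pixels). Correction precedes selection.
* **TIC normalization** divides each pixel's intensities by their sum;
  normalized pixels sum to one within 10⁻⁹. ROI values are means of
  normalized pixels.

## Cross-slide m/z binning

Peaks pooled over slides are clustered by a Gaussian kernel density
(kernel SD = bandwidth, default 0.003 Da — the kernel itself is a
conventional choice). The density is evaluated on a grid of step
bandwidth/10 padded by ±4 bandwidths; runs of peaks separated by more
than 8 bandwidths are processed independently since their kernels
cannot interact. Each grid-local minimum between modes is refined by
one-dimensional optimisation of the exact density and becomes a bin
boundary; a bin's centre is the unweighted mean m/z of its members, and
a mode wider than the nominal 0.003 Da is *not* split — the bin records
its true half-open interval, with outermost edges padded by half a
bandwidth. The test suite proves this partition identical to a
brute-force fine-grid (10⁻⁴ Da) valley-finding oracle on randomized
instances.

Bins are then filtered by slide prevalence with the strict rule
`n_slides_present > floor(fraction × n_slides)` (40% of 20 slides means
"present in more than 8"); `fraction = 1` is read as "present in all
slides" since the strict form would be unsatisfiable.

## ROI sampling

ROIs are 3×3 pixel squares ("nine-pixel" ROIs) whose pixels all carry
one region label. Placements are drawn uniformly at random among
feasible anchors by rejection sampling with non-overlap enforced and a
10,000-proposal cap, returning fewer (with a warning) when a region
cannot host the request; disjoint ROIs keep cross-validation folds
honest. Whether real ROIs were hand-placed is unknowable from a method
description; seeded random placement is the testable stand-in.

## Classification models

`pcalda()` is the core estimator: mean-centred PCA followed by Fisher
LDA on the scores. The pipeline requests 1000 components; since that
exceeds the data rank in every fold, components are capped at
min(n−1, p) and the effective count is recorded. The LDA uses the
pooled within-class covariance with an automatic ridge escalation
(λ from 10⁻⁸ upward on a scaled identity) whenever the scatter is
numerically singular — class counts can be smaller than the retained
dimension — and discriminants are scaled to unit within-class variance,
with Gaussian class scores using empirical priors. `predict()` returns
both the class and the LDA-space embedding. PCA is refit inside every
training fold (leakage-safe); refitting once globally would leak test
pixels into the rotation and is deliberately not done.

`lopo_cv()` makes one fold per patient. In biopsy-transfer mode the
model trains only on the *cross sections* of the other patients and
tests on the held-out patient's biopsy ROIs. Confusion counts
accumulate over folds; sensitivity/specificity are reported for binary
tasks. `adversarial_patient_cv()` instead predicts the *patient* from
tumour ROIs under ROI-stratified 10-fold CV with 1-D LDA: accuracy
near 1/n_patients indicates exchangeable patients, accuracy well above
it indicates patient-level batch structure. `single_ion_cv()` runs the
same LOPO design on each bin alone (for binary tasks this reduces to a
class-conditional-mean threshold rule), ranking ions by prospective
prediction power; `kmeans_explore()` provides the unsupervised view
with the adjusted Rand index against the annotation.

Evaluation designs in the tests and the acceptance script balance the
two classes (24 tumour vs 24 pooled non-neoplastic ROIs per cross
section) so that the chance level of every control is 0.5 and
label-shuffle nulls are interpretable; with the natural imbalance the
chance level would be the majority share.

## Univariate statistics

`volcano()` computes, per bin, the fold change of raw group means and a
Welch t-test on log10(x + ε), ε = half the smallest positive value in
the matrix (a Mann–Whitney variant is available), and flags bins with
max(FC, 1/FC) ≥ 2 and p < 0.001. No multiple-testing correction enters
the flag — the design applies a raw-p gate jointly with the fold-change
gate — but Benjamini–Hochberg q-values are emitted for information.
For comparisons with few expected differences (biological sex) the
fold-change gate is dropped (`fc_threshold = 1`). ROIs are treated as
independent observations in these tests although they cluster within
patients; this mirrors the analysis design it reimplements and
overstates significance in the presence of patient effects — the
pseudoreplication caveat applies to any volcano result from clustered
ROIs, and the patient-aware single-ion LOPO ranking is the
complementary view that respects clustering.

## Putative annotation

Theoretical m/z values are monoisotopic neutral masses from CODATA/IUPAC
atomic masses minus the proton mass (1.00727646688 Da); only the [M−H]⁻
adduct is modelled, matching negative-mode DESI. ppm errors are
reported against theoretical values at their printed 4-decimal
precision, which is how published delta columns are reproduced. The
bundled reference table carries the fatty-acid series with exact
formulas; complex lipids whose published identities are class labels
only carry *putative* elemental compositions found by constrained
search against the published masses and are flagged as such. Ambiguous
identities (e.g. succinylacetoacetate vs ethyl aconitate) are kept as
separate candidate rows, never collapsed. `pair_isotopes()` links each
bin to a bin 1.00336 Da heavier (tolerance 0.005 Da, closest-delta
wins, each heavy bin claimed at most once); these species are
isotopologues, though the looser term "¹³C isomer" appears in some
sources.

## Calibration of the single-ion regime

A lone tumour marker at fold change 4.5 should classify tumour ROIs at
roughly the mid-80% level under LOPO — strong but imperfect. For the
balanced threshold rule on log ROI intensity the expected accuracy is
Φ(ln 4.5 / 2σ) with σ² = 0.35²/9 + s², where 0.35 is the per-pixel
marker CV (averaged over 9 ROI pixels) and s the patient-level log-SD.
Setting s = 0.65 gives ≈0.87, so `patient_effect_sd = 0.65` defines
this regime in the tests; an independent Monte-Carlo simulation of the
reduced model (patients, ROI averaging, estimated threshold) pins the
acceptance band [0.80, 0.95] and the pipeline's measured accuracy is
required to fall inside the simulation's dispersion.

## Numerical choices and degenerate inputs

Slide-level seeds derive from the cohort seed as
`(seed + 7919·index) mod 2³¹`, so any cohort is a pure function of its
configuration. Exact m/z ties within a pixel (probability ~0) are
collapsed to keep strict ascent. Prediction ties in LDA scores resolve
to the first class. All-zero spectra refuse TIC normalization ("empty
TIC"); empty pixels pass through preprocessing untouched. Constant ions
fall back to the majority-class rule in single-ion CV. Bin centres that
collide after 3-decimal rounding are rejected rather than silently
merged. Readers reject non-monotone m/z, negative intensities and
unmapped palette indices with the offending coordinate or index named.

## Problem sizes

The test suite exercises most modules on a 3-patient, 24×36-pixel
cohort with a 200-species background, and calibration checks on
2-patient cohorts at the full default acquisition scale; the end-to-end
recovery checks use the full 10-patient default cohort, and the
single-ion regime uses three replicate 10-patient cohorts at 30×45
pixels with a 400-species background. These sizes are the package's
choice of a desk-scale experiment: large enough for ≥500 pixels per
region in calibration checks and stable LOPO estimates, small enough to
iterate on.

## Known limitations

Classification numbers obtained on synthetic cohorts characterise the
implementation under a known model; they are not predictions of
instrument-data performance. The generator's six-region geometry is
stylised; connective-tissue regions are intentionally near-identical
spectrally, so overview images separate the tumour but not the triad.
Only the [M−H]⁻ adduct is annotated, complex-lipid formulas are
putative, and identification by tandem MS or ion mobility is out of
scope, as are vendor raw formats and histology image processing.
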