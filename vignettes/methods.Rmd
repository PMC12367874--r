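---
title: "Methods: signature discovery for structural cardiotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery for structural cardiotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotoxsig)
```

`cardiotoxsig` analyses hybrid metabolomics studies of drug-induced
structural cardiotoxicity (SCT) in 3D cardiac microtissues. This vignette
is the package's account of its models and the choices behind them. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Study design and data model

The analysis assumes a multi-batch exposure design
(`default_study_design()`): twelve xenobiotics — eight structural
cardiotoxins, four non-cardiotoxins — split over four exposure batches so
that every batch pairs two cardiotoxins with one non-cardiotoxin. Each
compound is dosed at a nominal low and high concentration (the low dose is
nominally a half-log dilution of the high; `half_log_check()` verifies this
and genuinely flags two compounds in the default table whose printed
nominals deviate from the half-log rule by more than 5%) for 6, 48 and 72 h,
with duration-matched vehicle controls in every batch. Concentrations are in
µM, durations in hours, retention times in seconds, m/z in Da throughout.

All stages exchange a single container, the `PeakMatrix`: a features ×
samples intensity matrix with feature metadata (m/z, optional RT, polarity,
assay) and sample metadata (batch, xenobiotic, concentration level,
duration, replicate, sample type, injection order). Missing peaks are `NA`,
never zero: a zero is a legal measured intensity, and conflating the two
corrupts detection-rate filters. On disk a matrix is a directory of three
delimited text files plus a JSON manifest; missing cells are empty fields.
Round-trip through `write_peak_matrix()`/`read_peak_matrix()` is the
identity for text-representable values.

## The synthetic-study generator

The raw data this analysis was designed for are not publicly deposited, so
the generator (`generate_study()`) is a first-class module: it produces the
statistical structure the pipeline assumes, with complete ground truth, so
that every downstream stage is testable end to end.

Per assay it emulates: log-normal baseline abundances (median 1e5 arbitrary
units, spread 1.2 on the log scale); per-feature batch offsets (log-SD
0.15); a smooth multiplicative injection-order drift (shared low-order
shape per run — linear, quadratic and one sinusoidal term — with
per-feature amplitude around 8% and random sign), which is exactly the
drift model the QC-based corrector assumes; residual log-normal noise at
20% CV for biological samples and 10% for pooled QCs; and
intensity-dependent missingness (logistic in log10 intensity, midpoint
10^3.7, width 0.3, plus a 1% floor), i.e. left-censoring-like — the
dominant missingness mechanism in MS peak matrices and the one that
exercises detection filters and KNN imputation nontrivially. QCs are
interleaved after every 6th (LC-MS) or 8th (DIMS) study sample; process
blanks sit at the start, middle and end of the acquisition sequence, and
ten contaminant features are planted at full intensity in the blanks to
give the blank filter real work.

Planted truth: 30 signature features per assay (20 decreased
"ceramide-like", 10 increased "AMP-like") whose log2 effect in
SCT-exposed samples reaches ±0.6 at 72 h/high and scales monotonically with
duration (0.25 / 0.8 / 1 at 6 / 48 / 72 h) and concentration (0.5 / 1 for
low / high); one parent-xenobiotic feature per compound at the [M+H]⁺ or
[M−H]⁻ m/z of its molecular formula, with response proportional to the free
concentration; and two one-step biotransformation products per compound at
rule mass shifts, predominantly phase I (hydroxylation, demethylation) with
glucuronidation for two compounds, mirroring a system with strong phase I
and weak phase II competency. Free concentrations are 70% of nominal for
most compounds; idarubicin decays with a 48-h half-life (chemical
instability), and doxorubicin's free fraction (0.2%) puts its parent below
the detection floor by construction, to exercise the quantitation-failure
path. Because that parent is undetectable by design, recovery statistics
count it out of the denominator; the ground-truth table carries an explicit
`detectable` flag. Intracellular assays default to N = 4 replicates
(configurable; the footprint default is N = 6, which yields the 504
biological-plus-control footprint samples, 72 exposure conditions and 18
assay × duration model datasets that the design arithmetic expects).

What the generator does **not** emulate: raw spectra, isotope envelopes,
chromatographic peak shapes, correlated feature blocks from shared
metabolic regulation, adduct/isotopologue degeneracy of the *endogenous*
features, matrix effects, or non-monotone dose-response. Passing tests on
synthetic data therefore demonstrate correctness of the algorithms under
the stated statistical assumptions — not performance on any real study.

## Quantitation

Calibration curves are weighted least squares (weights 1/x², x = nominal
concentration) — appropriate for the constant-relative-error noise of
LC-MS responses — linear by default with a quadratic option: the form is a
configuration choice because "non-linear regression" in bioanalytical
practice often denotes the weighted solver rather than genuine curvature,
and the acceptance rules are identical either way. Standards whose
back-calculated concentration deviates from nominal by more than 40% are
excluded one at a time (worst first, to avoid over-pruning from a single
leverage point) with refitting until all included standards pass or fewer
than five levels survive (an error carrying the exclusion trail).
LLOQ/ULOQ are the lowest/highest accepted nominals; responses outside the
calibrated response range are flagged (`below_lloq` / `above_uloq`) rather
than extrapolated, and the LLOQ boundary is inclusive. A quadratic whose
inversion is ambiguous inside the range yields a `quantitation_ambiguous`
flag. Accuracy is the mean back-calculated/nominal ratio (%) over accepted
quant-QCs; precision is the mean across levels of the RSD of duplicate
quant-QCs. Duration comparisons use two-sided t-tests Holm-corrected within
each family (pairwise between durations; pooled measured vs nominal).

## Preprocessing

The pipeline order is a contract, recorded in the output provenance:
blank removal → xenobiotic-feature removal → drift correction → QC-RSD and
detection filters → (multivariate branch) control normalisation → log2 →
KNN imputation → vector normalisation. The univariate branch stops at log2
of the filtered intensities, because its comparisons are made *against*
matched controls rather than on control-normalised responses.

Drift correction fits, per feature, a cubic smoothing spline to the log
intensities of QC injections versus injection order. Smoothing is selected
over an 11-value grid of smoothing parameters (linear in `spar`, i.e.
log-spaced in the penalty λ) by **exact leave-one-out cross-validation**
computed from the smoother leverages; the spline must beat the LOO error of
a constant (drift-free) model by 20% or the feature receives the identity
correction — an explicit no-harm rule, because at realistic QC counts a
freely optimised spline occasionally chases noise and any correction fitted
to the QCs mechanically shrinks their RSD. Robustness comes from up to
three Tukey-bisquare reweighting passes at the selected smoothing.
Correction divides by the interpolated drift multiplier (clamped beyond
the QC-covered range) and rescales so each feature's median is preserved
exactly; division by a positive multiplier can never create negative
intensities. Features with fewer than 5 QC observations pass through
uncorrected and flagged. The no-harm property is a cohort-level guarantee
(the tests require ≥ 95% of drift-free features to change QC RSD by less
than 1% absolute, median below 1%), since any data-driven detector has a
nonzero false-trigger rate on single features.

Default filter thresholds — blank fold 10, QC RSD 30%, detection rate 50%
within at least one exposure-condition class or the QCs — are community
defaults, declared rather than inferred, and all configuration-exposed.
"Vector normalisation" is per-sample scaling to unit Euclidean norm, the
standard chemometric reading; per-feature scaling was rejected because the
operation follows sample-wise transformations in the contracted order. KNN
imputation (k = 5) uses **samples** as neighbours, distances on log2 values
over features observed in both samples (scaled by the number of shared
features), and imputes the mean of the k nearest donors that observe the
feature; it sits between log2 and vector normalisation. A sample sharing no
observed features with any other falls back to feature medians and is
flagged. Control normalisation divides each exposed sample by the
per-feature median of its batch- and duration-matched controls (≥ 3
controls per stratum required), drops features with missing/zero control
medians, and consumes the controls.

## Xenobiotic fate

Xenobiotic-related features must be detected in at least two-thirds of a
compound's exposed samples, be ≥ 10-fold (median) above matched controls
and blanks, and fail the same test for every other compound (specificity).
Absent control/blank medians are replaced by a pseudo-floor of 1% of the
matrix's median observed intensity, so "10-fold above nothing" still
demands a clearly measurable signal; with a naive tiny floor, borderline
features near the missingness midpoint pass spuriously.

Biotransformation products are enumerated breadth-first from the parent
formula over an editable rule table (12 phase I, 4 phase II; shifts are
computed from elemental compositions at load, so they are consistent with
the element-mass table by construction) to at most 2 steps, with element
bookkeeping forbidding impossible losses. Duplicate masses merge keeping
all generating paths; a candidate is phase II if any step is. Matching
tests each feature's implied neutral mass over the polarity's adduct
hypotheses at the assay ppm tolerance (± 2 ppm DIMS, ± 5 ppm LC-MS); ppm
error is theoretical-referenced, (observed − theoretical)/theoretical ×
10⁶; ties rank by |ppm| then shortest path. Mass-shift enumeration replaces
structure-aware metabolite prediction deliberately: without MS/MS evidence
the package reports evidence tiers, never structures, and DIMS hits carry a
source-artifact caveat because without RT, in-source transformation
products are indistinguishable from biological ones.

## Annotation

Feature grouping builds a graph with edges requiring |ΔRT| ≤ 5 s **and**
Pearson r ≥ 0.7 **and** correlation p ≤ 0.01 (exact t-transform with n − 2
df; pairwise-complete observations, ≥ 5 pairs — the missing-data rule is
ours, and correlations run across QC plus biological samples, a choice
that is configuration-exposed). Groups are connected components;
singletons get the polarity's default ion form, flagged as assumed.
Ion-form annotation tests intra-group mass differences against adduct-pair
and ¹³C-isotopologue differences; isotopologue edges always point from
lower to higher m/z; conflicting assignments leave features unlabelled
with a note rather than picking an arbitrary winner, and group neutral
masses only propagate when the per-feature implied masses agree within
twice the ppm window. Library matching reports **all** compounds inside
the window ranked by |ppm| (ties all reported — annotation at this level
is putative by definition): mass-only matches are MSI level 3, an RT match
(± 10 s) upgrades to level 2, unmatched features are level 4; level 1
requires spectral matching, which is out of scope. The packaged library
(~66 compounds) covers energy metabolism, purine nucleotides, glutathione
forms, extracellular markers and a 26-member ceramide panel whose formulas
come from the shorthand convention Cer C:D;On → C_C H_(2C+1−2D) N O_(n+1).

## Univariate statistics

Each exposure condition is Welch-tested (two-tailed, Satterthwaite df)
feature-by-feature against its batch- and duration-matched controls on
log2 intensities (variance stabilisation); fold changes are medians of raw
intensities (robust, and consistent with the median-based control
normalisation) — the raw-vs-log and mean-vs-median choices are documented
splits, configuration-exposed. Zero-variance or under-replicated features
are flagged untestable and excluded from counts. Per-condition counts use
raw p < 0.01 with no multiple-testing correction — that is the declared
readout — with a Benjamini-Hochberg column emitted alongside, clearly
marked as supplementary. Conserved perturbations are features significant
(p < 0.05) with a consistent direction in at least `m_min` cardiotoxins at
48/72 h and in zero non-cardiotoxins.

## OPLS-DA, validation and the signature

The model is single-predictive-component OPLS: repeatedly, the PLS1 weight
w ∝ Xᵀy is computed on the current deflated matrix, the candidate loading
p is projected off w (w_orth ∝ p − (wᵀp)w, normalised), and X is deflated
by t_orth p_orthᵀ; after `n_orth` rounds a one-component PLS1 is fitted on
the filtered matrix. With n_orth = 0 the model is exactly PLS1 (verified
against an independent NIPALS implementation in the tests). n_orth
defaults to 1: a single orthogonal component is the typical and
interpretable choice for two-class designs of this size. Orthogonal scores
satisfy t_orthᵀy = 0 and tᵀt_orth = 0 to numerical precision by
construction. Degenerate inputs error out: single-class y, n_orth at or
above the rank bound, or vanishing orthogonal variation.

VIP is computed from the predictive component only — the orthogonal
components are class-orthogonal by construction and carry no
discriminative information — giving VIPⱼ = √p_feat·|wⱼ| with Σ VIP² =
p_feat. Refinement retains VIP ≥ 1 (inclusive) and refits. Cross-validation
is stratified k-fold (default k = 5; k is not prescribed by the analysis
and is configuration-exposed; k = n gives leave-one-out), and the full
pipeline — centering, orthogonal filtering, PLS fit and, when requested,
VIP selection — is re-fitted inside each training fold, so
refinement-induced selection bias does not inflate the reported
performance; the "refit on a pre-selected subset" view of a refined model
is available separately and should be read as optimistic. Q² = 1 −
PRESS/TSS on the 0/1 coding. Validity is a label-permutation test: the
cross-validated statistic (AUC by default — bounded and robust; Q²
optionally) is recomputed under B permutations and p = (1 + #{null ≥
observed})/(B + 1); the model is declared valid when p < 0.05. Note the
granularity: with B = 99 the smallest attainable p is 0.01 and the null
rejection probability at the 0.05 threshold is exactly 4/100, so null
rejection rates center near 4%, within the 2-9% band the calibration
checks allow. ROC points come from a threshold sweep over unique
predictions; trapezoidal AUC equals the Mann-Whitney statistic with half
credit for ties (verified against an exhaustive pairwise oracle and
against pROC). The 0/1 class threshold of 0.5 is reported for
completeness; ROC-based conclusions do not depend on it.

The signature table joins per-duration VIP scores of refined models with
the p < 0.05 log2 fold-change matrix and annotations; only features with
VIP ≥ 1 in at least one refined model appear. "Mean VIP per duration"
averages over the models in which the feature was measured —
absent-as-missing, not zero. Function groups come from library metadata;
unannotated features form their own group, because a biochemical grouping
of unidentified features cannot be computed. Duration overlap of VIP sets
is reported as Venn partitions and |A∩B|/|A∪B| percentages.

## Problem sizes and determinism

The documented default study used by the tests and the acceptance script is
one footprint assay with 1,000 endogenous features, 30 planted signature
features, 504 biological + control samples and planted parent/product
features; statistical calibration uses 5,000 null features for the Welch
type-I check and 200 null runs (24 samples × 30 features, B = 99, k = 3)
for permutation calibration; drift correction is checked on 100 features ×
300 injections with a planted monotone drift. These sizes make the whole
validation run in minutes on one CPU while keeping binomial error bars
tight enough for the stated bands. All generators and resampling routines
are seeded; the same seed reproduces every output bit for bit.

## Interfaces

The package is library-first: each pipeline stage is an exported function
over `PeakMatrix` objects, and `scripts/acceptance.R` is a worked example
of chaining the full analysis from the command line. Reference tables
(biotransformation rules, adducts, compound library) are packaged both as
functions and as delimited files under `inst/extdata/`, in the same schema
users would supply their own tables in.

## Known limitations

Annotation is putative (MSI ≥ 2): no spectral matching. Mass-shift
enumeration cannot distinguish isomeric products or confirm structures.
The OPLS-DA is binary and single-predictive-component by design; multi-class
and kernel variants are out of scope. Cross-validation at the sample level
(both concentrations of a compound can appear in training folds) measures
condition-level generalisation, not generalisation to unseen compounds; a
grouped mode holding out whole xenobiotics would measure the latter and is
a natural extension. Synthetic validation bounds what the tests can claim
about real data (see the generator section).
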