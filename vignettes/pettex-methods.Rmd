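---
title: "Methods: PET/CT texture analysis for interim response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET/CT texture analysis for interim response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Primary gastrointestinal diffuse large B-cell lymphoma is treated with
6–8 cycles of chemotherapy, with an interim PET/CT after 3–4 cycles.
The interim response is dichotomized by the PET-based Lugano criteria:
Deauville score 1–3 without FDG-avid marrow disease is a complete
response (CR), anything else non-CR. The question the workflow answers
is whether *pretreatment* PET/CT — the conventional semiquantitative
parameters plus histogram and co-occurrence texture features — predicts
that dichotomy, and whether a small combined logistic model does better
than any single marker.

The analysis chain is:

1. per-patient feature extraction (PET 3-D ROI, CT single-slice ROI);
2. a two-sided Mann–Whitney filter over all texture features at
   α = 0.05;
3. within each of four clinical categories — FDG uptake intensity,
   grey-level distribution, tumor size, intratumor heterogeneity — the
   surviving feature with the lowest p-value is selected;
4. ROC analysis (non-CR positive) of SUVmax, MTV and the selected
   features, with Youden-index cutoffs;
5. an unpenalized binary logistic model of non-CR on SUVmax,
   first-order entropy, ROI volume and intestinal involvement, whose
   fitted probability (the *prediction probability*) is itself evaluated
   by ROC and calibrated by the Hosmer–Lemeshow test;
6. Fisher exact contingency analysis of dichotomized clinical factors;
7. consistency of MTV vs. manual volume (Wilcoxon signed rank, DeLong);
8. interobserver agreement via ICC(2,1) per feature.

`interim_response_analysis()` runs 1–8 and returns a classed object with
`print`, `summary`, `plot`, `coef` and `predict` methods.

All evaluation is in-sample, as in the clinical design this reimplements:
with 30 patients there is no holdout, and the reported AUCs and accuracy
are apparent (optimistic) estimates. This is a faithful design choice,
not an oversight.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| MTV threshold fraction | 0.41 | of SUVmax | the clinical workstation's threshold; strict `>` at the cutoff |
| histogram / GLCM bins | 256 | — | equal-width over the ROI min–max; reproduces first-order entropies in the 6–8.5 bit range typical of clinical reports and is the most common radiomics default |
| entropy logarithm | base 2 | bits | same magnitude argument |
| GLCM distance | 1 | voxels | nearest-neighbour pairs |
| GLCM directions | 10–13 | — | the four in-plane offsets (0,1), (1,1), (1,0), (1,−1) in (row, col); exactly four directional variants of each statistic appear in clinical feature lists |
| filter α | 0.05 | — | two-sided Mann–Whitney retention threshold |
| logistic tolerance | 1e-10 | relative log-likelihood | Newton iterations, at most 100 |
| Hosmer–Lemeshow groups | 10 | — | deciles of risk, df = groups − 2 |

Every one of these is an argument (`discretization_spec()`,
`glcm_spec()`, and the function signatures), because none of them is
standardized across radiomics software and all of them change feature
values.

## Decisions where the design was genuinely open

**GLCM dimensionality.** Co-occurrences are accumulated per axial slice
and pooled, not with 3-D offsets. ROIs in this workflow are drawn slice
by slice and the CT arm is inherently single-slice; a 2-D accumulation
gives PET and CT one code path. The offset set is configurable, so a 3-D
variant reduces to adding offsets.

**MTV region.** The 41% threshold is applied inside the supplied mask.
The clinical alternative — a cropping sphere drawn interactively around
the lesion — is an artifact of the workstation and is not reproducible
from data; applying the threshold within the ROI is the deterministic
choice. Because the manual ROI can include low-uptake voxels, MTV ≤ ROI
volume by construction here, and the MTV-vs-volume signed-rank test
reflects that ordering.

**Fisher sidedness.** The contingency analysis defaults to one-sided
tail probabilities in the direction of the observed association: those
are the values that reproduce the published contingency table verbatim
(verified by enumeration for all five rows), even though the study
declares two-tailed testing throughout. Both modes are implemented
(`fisher_exact(..., sidedness)`), and `clinical_contingency()` takes the
sidedness as an argument, so the discrepancy is exposed rather than
hidden.

**Selection tie-break.** When two features tie at the minimum filter
p-value, the rank/percentile-type feature (percentiles, mode,
max-frequency, order statistics) wins if normality is rejected for the
tied features, otherwise the moment-type feature wins. This encodes the
published rationale for preferring the 50th percentile over the mean
under non-normal grey levels. Exact ties essentially occur only between
rank-equivalent features, which is precisely when the rule is needed.

**Cutoff convention.** Youden's J is maximized over observed marker
values with ties broken toward higher sensitivity; a positive (non-CR)
call is a value strictly beyond the cutoff, with the direction
auto-oriented so AUC ≥ 0.5. Whether the original workstation used ≥ or >
is unknowable; strict inequality is declared and used consistently.

**Logistic intercept.** Included (standard); the model is deliberately
unpenalized maximum likelihood. At n = 30 with four predictors,
perfect or quasi-perfect separation is possible: it is detected (fitted
probabilities at the numerical boundary together with a diverging fit),
the coefficients are flagged non-convergent, and the last iterate's
probabilities are still returned so the downstream ROC remains defined.

**Statistical conventions.** Mann–Whitney uses midranks, exact
enumeration for pooled n ≤ 12 without ties and a tie-corrected,
continuity-corrected normal approximation otherwise; the signed-rank
test enumerates all sign patterns below 10 nonzero pairs; ICC is fixed
to the two-way random, absolute agreement, single-measure form — the
canonical design for two raters scoring the same subjects — with the
qualitative bands cut at 0.2/0.4/0.6/0.8. Skewness is the
bias-uncorrected third standardized moment and kurtosis is excess; both
feed only rank tests, which are invariant within any monotone family of
conventions. Mode ties break toward the lowest grey level. No
multiple-testing correction is applied to the ~60 simultaneous feature
tests, matching the original analysis; `univariate_filter(fdr = TRUE)`
adds a Benjamini–Hochberg column for readers who want it.

## What the synthetic cohort emulates — and what it does not

No patient images are publicly available, so every stage is exercised on
phantoms. A phantom is a sphere of grey level `base_intensity` on a
proportional background; heterogeneity is log-normal multiplicative
noise built by smoothing a white Gaussian field with a kernel of width
`correlation_length_mm` (default 6 mm), standardizing it to
`heterogeneity_sd` on the log scale, and exponentiating. One knob
therefore moves first-order entropy and the co-occurrence statistics
together, in the direction observed clinically (more heterogeneous →
higher entropy, lower energy).

Cohort defaults are the published study conditions: 20 CR / 10 non-CR;
non-CR multipliers 1.8 (intensity), 1.75 (radius, ≈ 5.4× volume), 1.5
(heterogeneity); per-patient lognormal dispersions matched to the
published interquartile spreads (intensity sdlog 0.66, radius sdlog
0.42); intestinal involvement 30% vs 70%; Deauville scores drawn 3:8:9
over 1–3 (CR) and 3:7 over 4–5 (non-CR); voxels 4 mm isotropic on a 44³
grid, with the per-patient radius truncated to the grid (upper tail,
~3% of non-CR draws) and to a minimum 6 mm so the smallest tumors still
contain co-occurrence pairs. The second reader is simulated by eroding
and dilating the mask boundary with per-surface-voxel probability 0.15;
the CT slice is the central PET slice rescaled to an attenuation-like
window with independent noise.

What this deliberately does **not** emulate: anatomy (no GI geometry, no
adjacent organs), scanner physics (no point-spread function, no partial
volume, no reconstruction artifacts), genuinely independent CT contrast,
and reader disagreement beyond the boundary. Consequences worth knowing:
passing tests demonstrate the *algorithms*, not clinical performance;
and because only the boundary is perturbed, features dominated by
interior voxels (SUVmax above all) show near-perfect synthetic ICCs,
higher than the published interobserver values — the ICC machinery is
validated, the synthetic agreement level is not a clinical claim.
Absolute grey-level scales are matched only in order of magnitude.

## Numerical choices

Intensities are discretized as
`floor((v − min) / range · n_bins) + 1`, clamped to `n_bins`; a
zero-width range maps everything to bin 1 (entropy 0). Degenerate
first-order inputs (single voxel, zero variance) return sd/skewness/
kurtosis 0 with a `degenerate` attribute and a warning rather than NaN.
The GLCM is symmetrized by adding its transpose before normalizing; a
mask with no valid pair for an offset is an error naming the direction.
The maximal diameter prunes the all-pairs search to mask surface voxels
(which contain both endpoints of any diameter) and is checked against
the O(n²) scan in the tests. The logistic log-likelihood is computed in
the overflow-safe form, with step-halving when a Newton step worsens it.
Hosmer–Lemeshow risk groups with a zero expected cell are merged into
their neighbour with a warning. ROC, DeLong and the rank tests operate
on midranks throughout, so any strictly monotone transform of a marker
leaves their results unchanged.

## Problem sizes used by the tests

Unit and property tests run on 6×7×8 to 24³ grids; oracle equivalence is
checked against literal loop/sort implementations on random ≤ 8³
phantoms; the AUC ≡ U/(n₁n₂) identity on 500 random samples at 1e-12;
logistic recovery at n = 2000 within 3 standard errors; and the type-I
error of the Mann–Whitney, signed-rank, Hosmer–Lemeshow and DeLong tests
over 500 null replicates each, required to sit within a 3.29-σ binomial
band of α = 0.05. Generator-level checks (null configuration, effect
directions, combined-beats-single) use 10–100 replicate cohorts on
12³–24³ grids. These sizes are the package's chosen trade-off between
Monte-Carlo resolution and a test suite that runs in well under a
minute per file.

## Known limitations

- In-sample evaluation only; no cross-validation or external validation
  is implemented, by design.
- The 2-D (per-slice) GLCM convention and the 256-bin min–max
  discretization are *a* defensible convention, not *the* convention;
  results are not comparable across radiomics software without aligning
  these settings.
- The synthetic second reader bounds what the ICC table can show (see
  above).
- Exact Mann–Whitney enumeration is limited to pooled n ≤ 12; beyond
  that the tie-corrected normal approximation is used, which at the
  cohort's group sizes (20 vs 10) is standard practice but approximate.
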