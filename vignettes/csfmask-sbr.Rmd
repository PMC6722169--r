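---
title: "CSF-masked SBR quantification: model, assumptions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSF-masked SBR quantification: model, assumptions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striamask)
```

## The index and the correction

Striatal dopamine-transporter SPECT quantification with the Southampton
scheme rests on a deliberately oversized volume of interest: each
striatum is enclosed by a pentagonal prism much larger than the organ,
so that counts blurred out of the striatum by the scanner's
point-spread function are still collected, and the whole brain minus
the two prisms serves as the non-specific reference. The index is

$$\mathrm{SBR} \;=\; \frac{\mathrm{Ctc_{VOI}}/C_{cr} \;-\; \mathrm{Vc_{VOI}}}{V_s},$$

with $\mathrm{Ctc_{VOI}}$ the total striatal-VOI count, $C_{cr}$ the
reference count concentration (counts/ml), $\mathrm{Vc_{VOI}}$ the VOI
volume (ml), and $V_s = 11.2$ ml the assumed anatomical striatal
volume. The quantity $\mathrm{Ctc_{VOI}}/C_{cr} - \mathrm{Vc_{VOI}}$ is
the striatal count excess expressed as an equivalent volume of
background tissue; dividing by $V_s$ makes it a dimensionless binding
ratio.

The scheme's weakness is cerebrospinal fluid. CSF spaces carry almost
no tracer; when enlarged ventricles sit inside the reference region
they drag $C_{cr}$ down and inflate the index (and, less often, CSF
inside the VOI deflates it). The CSF mask removes those voxels by
thresholding: a Gaussian is fitted to the histogram of reference-region
voxel values, and every brain voxel below

$$\mathrm{Threshold} = \tilde{x} - \sigma \cdot k, \qquad k = 1.0$$

is excluded from *both* the striatal and the reference bookkeeping
($\tilde{x}$, $\sigma$: fitted median and SD; for a Gaussian the median
equals the fitted centre). Exclusion applies to all three measured
terms of the index — this matters, because implementations that mask
only the reference get a different correction.

Orientation conventions are fixed package-wide: parkinsonian syndromes
(PS) show reduced uptake, so PS is the low-score class, a subject is
called PS-positive below the cutoff, and AUC = P(NPS score > PS score)
with ties counting one half.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` | 1.0 | SD units | clinical threshold coefficient |
| `Vs` | 11.2 | ml | assumed striatal volume of the index |
| voxel size | 4.4 | mm | acquisition matrix of the emulated scanner (128 × 128, 4.4 mm slices) |
| pentagon circumradius | 25 | mm | "wide area" VOI: ≥ 3 × the nominal striatal volume |
| prism height | 44 | mm | covers the striatum with ≥ 8 mm axial margin |
| `psfFWHM` | 8.8 (cohorts), 0 (unit phantoms) | mm | two voxels; typical reconstructed SPECT resolution |
| `background` | 100 | counts/voxel | Poisson SNR 10, a realistic 30-min acquisition level |
| histogram bins | 100 | – | resolves the background peak without starving bins |
| summary rule | mean of sides | – | per-patient value; the clinical aggregation is unstated, the mean assumes least |

The exact pentagon dimensions of the clinical software are not public;
the defaults above are configurable, recorded in the VOI objects, and —
by the design of the method — the index is insensitive to VOI size as
long as the striatum is fully contained.

## What the phantom emulates, and what it does not

`buildPhantom()` produces an ellipsoidal brain (semiaxes 70 × 85 × 60
mm) with uniform non-specific uptake, two ellipsoidal striata whose
voxel concentration is calibrated analytically,

$$C_s = C_b\left(1 + \mathrm{SBR}_{true}\, V_{nom} / V_{act}\right),$$

with $V_{act}$ the voxelised striatal volume, so that exact Southampton
bookkeeping on the noiseless, unblurred volume returns the true SBR
identically (the calibration is analytic rather than search-based
precisely so the truth channel is exact). Two mirrored,
anterior-elongated ellipsoidal ventricles (base semiaxes 6 × 22 × 10 mm
at ±10, −25, +8 mm from the brain centre; about 5.5 ml per side at
scale 1) are zeroed before blur; a single scale factor multiplies all
three semiaxes, which makes the true Evans index analytic and strictly
monotone in the scale. Blur, then Poisson noise, are applied in that
order; an optional depth-dependent suppression $e^{-\mu d}$
($\mu = 0.11$/cm, $d$ measured along the ray from the brain centre)
emulates the count gradient of non-attenuation-corrected
reconstruction.

Simulated cohorts draw each subject's true SBR from its group's normal
law truncated at zero — PS 2.62 ± 1.02, NPS 4.72 ± 1.18, the group
statistics of the CSF-masked clinical index — the same value on both
sides (disease asymmetry is not modelled, so the left/right aggregation
rule is exercised but not stressed). The ventricle scale is drawn
uniformly on (0.2, 2.2) independently of the label; no per-group
ventricle-size distribution is published, so this range is a repository
choice set to span Evans indices from about 0.19 to 0.32, bracketing
the clinical tertile boundaries (0.265, 0.296).

Not emulated: projection/reconstruction (no sinograms, no OSEM, no
Butterworth filter — blur stands in for all resolution effects),
scatter, anatomical shape realism (no caudate/putamen subdivision, no
cortical folding, no sulcal CSF), asymmetric disease, and EI
measurement on CT/MR by a human rater. Consequently, passing phantom
tests demonstrates the *bookkeeping* and the *mechanism* of the CSF
correction — not clinical effect sizes. The simulated AUC gaps between
masked and unmasked indices are an order of magnitude smaller than the
clinical ones because sulcal/atrophic CSF, the dominant clinical
contributor, is absent; only the direction and the EI-gradient of the
effect are claimed.

## Numerical choices

* **Thresholding convention.** Voxels strictly below the threshold are
  excluded; ties retained (configurable). The histogram is computed on
  the reference region (brain minus striatal VOIs), not the whole
  brain, so striatal signal cannot skew the Gaussian.
* **Fit fallback.** The Levenberg-Marquardt Gaussian fit is rejected
  when it fails to converge, fewer than three bins are occupied, the
  centre leaves the data range, the width is non-positive or exceeds
  the whole range, or it explains under half the histogram variance
  (the signature of a strongly bimodal background). The fallback is the
  sample median and 1.4826 × MAD, flagged via `fitOK = FALSE` rather
  than failing hard. On a noiseless phantom the background histogram is
  a spike, the fallback yields threshold = background, and the strict
  inequality keeps background voxels while excluding the zero-count
  ventricles — exactly the intended behaviour.
* **Brain segmentation.** Otsu threshold (256 levels), largest
  6-connected 3-D component (per-slice labelling merged with
  union-find), slice-wise hole filling so interior ventricles stay
  inside the mask. VOIs are clipped to the brain mask so extracranial
  zeros never enter the striatal count; a flag disables clipping.
* **Auto VOI placement** smooths at 12 mm FWHM and takes each
  hemisphere's maximum, requiring it to exceed 1.1 × the median
  smoothed brain value; subjects with effectively no striatal signal
  (true SBR near zero) fail this check and are logged and excluded by
  `quantifyCohort()` rather than silently mis-placed. Voxel membership
  uses voxel centres throughout (deterministic, no partial-voxel
  weighting).
* **Evans index.** The frontal-horn region is the anterior half of the
  ventricle mask, cut at the ceiling of the centroid slice so the rule
  stays non-degenerate when a small ventricle is a single voxel thick;
  widths are inclusive voxel extents converted by the x voxel size.
  Tertiles are assigned by rank with ceil-then-floor sizes (275 →
  92/92/91) and stable tie-breaking into the lower group.
* **Statistics.** AUC by midranks (equal to U/(n₁n₂) identically);
  DeLong variance from structural components, CI on the AUC scale
  truncated to [0, 1]; Youden's J for the operating cutoff (ties toward
  higher specificity, i.e. the lower cutoff; maximum accuracy available
  as an option), cutoffs reported as midpoints between adjacent
  distinct scores. Mann-Whitney p values are exact for n₁n₂ ≤ 400
  (null distribution without ties, full enumeration with ties when
  feasible) and tie-corrected normal otherwise. No multiplicity
  adjustment is applied across EI strata, matching the unadjusted
  per-stratum reporting this analysis mirrors.
* **Seeds.** One master seed per cohort; subject *i* uses
  `(master + 1000003 · i) mod (2³¹ − 1)`, so subjects keep their
  identity under cohort subsetting and every stage is reproducible.

## Problem sizes

Unit phantoms run on a 48 × 48 × 32 grid and cohort simulations on
64 × 64 × 40, both at the native 4.4 mm voxel size — the default
anatomy fits either grid with ≥ 10 mm margins, and these sizes keep a
full 20-replicate, 60 + 60-subject stratified experiment in the
few-minute range on a single core while leaving the voxel-scale
discretisation identical to the 128 × 128 acquisition matrix (which
remains the `phantomSpec()` default).

## Known limitations

* The phantom's CSF is purely ventricular; atrophic sulcal CSF, the
  other clinical driver of the correction, is not modelled.
* The attenuation toggle is a depth heuristic, not Chang correction;
  NC/AC contrasts are qualitative only.
* Evans indices in simulation derive from the generating geometry, not
  from a rater on anatomical images; inter-rater subjectivity is out of
  scope.
* With `k` large enough to cut into the background peak itself the
  masked index loses its scale-invariance guarantee only through the
  histogram's finite bin width; `k` in the clinical range (0–2) is
  unaffected.

## A minimal end-to-end run

```{r, eval = FALSE}
report <- runExperiment(list(n_ps = 10, n_nps = 10, seed = 1,
                             grid_shape = c(64L, 64L, 40L)))
report$summary
subset(report$strata, stratum == "overall")
```
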