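# striamask

CSF-mask-corrected specific binding ratio (SBR) quantification for
striatal dopamine-transporter (DAT) SPECT, with a digital brain phantom
and an Evans-index-stratified diagnostic evaluation.

## The problem

Semi-quantitative DAT SPECT reading commonly uses the Southampton SBR: a
large pentagonal-prism volume of interest (VOI) encloses each striatum
with a wide margin, the rest of the brain serves as the non-specific
reference, and

```
SBR = ( Ctc_VOI / C_cr  -  Vc_VOI ) / Vs
```

where `Ctc_VOI` is the total count in the striatal VOI, `C_cr` the count
concentration (counts/ml) of the reference region, `Vc_VOI` the VOI
volume (ml), and `Vs = 11.2 ml` the assumed anatomical striatal volume.
Because the VOI is deliberately oversized, the index is robust to
partial-volume blur — but near-zero-count cerebrospinal-fluid spaces
(enlarged lateral ventricles, atrophic sulci) depress the reference
concentration and distort the index in patients with ventricular
dilatation.

The CSF-mask correction fits a Gaussian to the reference-background
count histogram and excludes every brain voxel below

```
Threshold = x̃ − σ · k        (k = 1.0)
```

(`x̃`, `σ`: fitted median and SD) from the striatal *and* reference
bookkeeping. This package implements both indices, a phantom generator
with exact ground truth for validating them, Evans-index (EI) grading of
ventricular dilatation, and the paired ROC machinery (midrank AUC,
DeLong test, Youden cut-offs, confusion-matrix metrics) used to compare
their diagnostic performance for parkinsonian syndromes (PS) versus
non-parkinsonian conditions (NPS).

Intended users: nuclear-medicine physicists and neuroimaging
methodologists studying semi-quantitative DAT SPECT indices and their
failure modes under brain atrophy.

## Worked example

A phantom with true SBR 4.0 on both sides, dilated ventricles
(scale 1.5), 8.8 mm reconstruction blur, and Poisson noise:

```r
library(striamask)

spec <- phantomSpec(trueSBR = 4, ventricleScale = 1.5, psfFWHM = 8.8,
                    noise = TRUE, seed = 42)
p <- buildPhantom(spec)
p$truth
#> GroundTruth: true SBR L/R = 4/4, true EI = 0.274, label ''

brain <- segmentBrain(p$volume)
vois  <- placeStriatalVOIs(p$volume, mode = "auto", brainMask = brain)
fit   <- csfMask(p$volume, vois, k = 1.0)
fit
#> ThresholdFit: xTilde = 96.34, sigma = 12.57, k = 1 -> threshold = 83.77
#>   fit converged; 4055 voxels excluded

computeSBR(p$volume, vois)$right
#> SBRResult (right, unmasked): SBR = 5.037
#>   Ctc = 136065 counts, Ccr = 1066.12 counts/ml, Vc = 71.21 ml, Vs = 11.2 ml
computeSBR(p$volume, vois, exclusion = fit@exclusionMask)$right
#> SBRResult (right, CSF-masked): SBR = 4.066
#>   Ctc = 134873 counts, Ccr = 1168.02 counts/ml, Vc = 69.94 ml, Vs = 11.2 ml

computeEvansIndex(p$truth@ventricleMask, p$truth@brainMask,
                  voxelSize(p$volume))
#> EvansResult: EI = 0.250 (horn 35.2 mm / skull 140.8 mm, slice 20)
```

The dilated ventricles inflate the conventional index (5.04 against a
truth of 4.0) mainly by depressing the reference concentration; the
CSF mask restores the reference (1066 → 1168 counts/ml) and brings the
index back to 4.07. `simulateCohort()` + `quantifyCohort()` +
`eiStratifiedComparison()` run the same comparison over whole two-group
cohorts, and `runExperiment()` drives everything from a single YAML/JSON
or list configuration.

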