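#' @import methods
NULL

# ---------------------------------------------------------------------------
# CountVolume
# ---------------------------------------------------------------------------

#' CountVolume: a 3-D grid of emission counts
#'
#' The container consumed by every quantification stage: a 3-D array of
#' non-negative voxel values together with the voxel dimensions in mm.
#' Axis convention: x = left to right, y = posterior to anterior,
#' z = inferior to superior. Voxel centers sit at `(index - 1) * voxelSize`
#' in world mm (0-based voxel indexing in world terms).
#'
#' @slot values 3-D numeric array of counts, all `>= 0`.
#' @slot voxelSize numeric(3), voxel edge lengths in mm, all `> 0`.
#' @export
setClass("CountVolume",
         slots = c(values = "array", voxelSize = "numeric"))

setValidity("CountVolume", function(object) {
  if (length(dim(object@values)) != 3L)
    return("'values' must be a 3-D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("'voxelSize' must be three positive finite numbers (mm)")
  if (any(object@values < 0, na.rm = TRUE))
    return("voxel values must be non-negative")
  TRUE
})

#' Construct a CountVolume
#'
#' @param values 3-D numeric array of non-negative counts.
#' @param voxelSize voxel dimensions in mm; a scalar is recycled to all axes.
#' @return A [CountVolume-class] object.
#' @export
CountVolume <- function(values, voxelSize = 4.4) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("CountVolume", values = values, voxelSize = as.numeric(voxelSize))
}

#' @describeIn CountVolume-class voxel values as a plain array
#' @param x,object a `CountVolume`
#' @export
voxelValues <- function(x) x@values

#' @describeIn CountVolume-class voxel dimensions in mm
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn CountVolume-class volume of one voxel in ml
#' @export
voxelVolumeML <- function(x) prod(x@voxelSize) / 1000

setMethod("show", "CountVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CountVolume: %d x %d x %d voxels @ %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@voxelSize), collapse = " x ")))
  cat(sprintf("  counts: total %.4g, range [%.4g, %.4g]\n",
              sum(object@values), min(object@values), max(object@values)))
})

setMethod("dim", "CountVolume", function(x) dim(x@values))

# ---------------------------------------------------------------------------
# PhantomSpec / GroundTruth / CohortSpec
# ---------------------------------------------------------------------------

#' PhantomSpec: generative parameters of a digital brain phantom
#'
#' Describes an ellipsoidal brain with uniform non-specific uptake, two
#' high-uptake ellipsoidal striatal bodies, near-zero-count lateral
#' ventricles of controllable size, optional Gaussian point-spread blur
#' (standing in for reconstruction resolution), optional Poisson count
#' noise, and an optional depth-dependent count suppression emulating
#' non-attenuation-corrected imaging.
#'
#' Structure positions are stored as offsets (mm) from the brain centre,
#' which defaults to the grid centre, so the same anatomy can be dropped
#' onto grids of different size. The default acquisition geometry is a
#' 128 x 128 matrix with 4.4 mm isotropic voxels.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot voxelSize numeric(3) voxel size in mm.
#' @slot brainSemiaxes numeric(3) brain ellipsoid semiaxes in mm.
#' @slot background expected counts per voxel in non-specific tissue.
#' @slot striatumOffsets 2 x 3 matrix, left/right striatal centres as mm
#'   offsets from the brain centre.
#' @slot striatumVolumeML true anatomical striatal volume per side (ml).
#' @slot striatumAspect numeric(3), relative semiaxis proportions of the
#'   striatal ellipsoids (scaled to match `striatumVolumeML`).
#' @slot trueSBR numeric(2) true specific binding ratio, left and right.
#' @slot ventricleScale unitless factor `>= 0` multiplying all three
#'   ventricle semiaxes; 0 removes the ventricles.
#' @slot ventricleOffsets 2 x 3 matrix of ventricle centres (mm offsets).
#' @slot ventricleSemiaxes numeric(3) base (scale = 1) semiaxes in mm;
#'   elongated along y so an anterior "frontal horn" is well defined.
#' @slot psfFWHM Gaussian blur FWHM in mm (0 = none).
#' @slot noise logical, apply Poisson count noise.
#' @slot attenuation logical, apply depth-dependent count suppression
#'   `exp(-mu * depth)` before noise (emulates non-attenuation-corrected
#'   reconstruction).
#' @slot attenuationMu linear coefficient in 1/mm (default 0.011 = 0.11/cm).
#' @slot seed integer seed for the stochastic stages.
#' @export
setClass("PhantomSpec",
         slots = c(gridShape = "integer", voxelSize = "numeric",
                   brainSemiaxes = "numeric", background = "numeric",
                   striatumOffsets = "matrix", striatumVolumeML = "numeric",
                   striatumAspect = "numeric", trueSBR = "numeric",
                   ventricleScale = "numeric", ventricleOffsets = "matrix",
                   ventricleSemiaxes = "numeric", psfFWHM = "numeric",
                   noise = "logical", attenuation = "logical",
                   attenuationMu = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("'gridShape' must be three integers >= 8")
  if (any(object@voxelSize <= 0)) return("voxel sizes must be positive")
  if (any(object@brainSemiaxes <= 0)) return("brain semiaxes must be positive")
  if (object@background <= 0) return("background concentration must be positive")
  if (any(dim(object@striatumOffsets) != c(2L, 3L)))
    return("'striatumOffsets' must be a 2 x 3 matrix (left, right)")
  if (object@striatumVolumeML <= 0) return("striatal volume must be positive")
  if (length(object@trueSBR) != 2L || any(object@trueSBR < 0))
    return("'trueSBR' must be two non-negative values (left, right)")
  if (object@ventricleScale < 0) return("'ventricleScale' must be >= 0")
  if (object@psfFWHM < 0) return("'psfFWHM' must be >= 0")
  if (object@attenuationMu < 0) return("'attenuationMu' must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults place an adult-sized brain (semiaxes 70 x 85 x 60 mm) at the
#' centre of a 128 x 128 x 40 grid of 4.4 mm voxels, striatal bodies of
#' 11.2 ml per side at (+-33, 15, 5) mm from the brain centre, and two
#' mirrored anterior-elongated ventricles at (+-10, -25, 8) mm with base
#' semiaxes 6 x 22 x 10 mm (about 5.5 ml per side at scale 1).
#'
#' @param gridShape voxels per axis (length 3).
#' @param voxelSize voxel size in mm (scalar or length 3).
#' @param brainSemiaxes brain ellipsoid semiaxes in mm.
#' @param background expected counts per voxel in non-specific tissue.
#' @param trueSBR true SBR per side; a scalar is used for both sides.
#' @param striatumVolumeML anatomical striatal volume per side in ml.
#' @param striatumOffsets 2 x 3 matrix of striatal centre offsets (mm).
#' @param striatumAspect relative striatal semiaxis proportions.
#' @param ventricleScale ventricle size factor (0 removes ventricles).
#' @param ventricleOffsets 2 x 3 matrix of ventricle centre offsets (mm).
#' @param ventricleSemiaxes base ventricle semiaxes in mm.
#' @param psfFWHM Gaussian blur FWHM in mm.
#' @param noise apply Poisson noise?
#' @param attenuation apply depth-dependent count suppression?
#' @param attenuationMu attenuation coefficient in 1/mm.
#' @param seed integer seed.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(gridShape = c(128L, 128L, 40L), voxelSize = 4.4,
                        brainSemiaxes = c(70, 85, 60), background = 100,
                        trueSBR = c(4, 4), striatumVolumeML = 11.2,
                        striatumOffsets = rbind(left = c(-33, 15, 5),
                                                right = c(33, 15, 5)),
                        striatumAspect = c(12, 17, 13.107),
                        ventricleScale = 0,
                        ventricleOffsets = rbind(left = c(-10, -25, 8),
                                                 right = c(10, -25, 8)),
                        ventricleSemiaxes = c(6, 22, 10),
                        psfFWHM = 0, noise = FALSE,
                        attenuation = FALSE, attenuationMu = 0.011,
                        seed = 1L) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (length(trueSBR) == 1L) trueSBR <- rep(trueSBR, 2L)
  new("PhantomSpec",
      gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
      brainSemiaxes = as.numeric(brainSemiaxes),
      background = as.numeric(background),
      striatumOffsets = striatumOffsets,
      striatumVolumeML = as.numeric(striatumVolumeML),
      striatumAspect = as.numeric(striatumAspect),
      trueSBR = as.numeric(trueSBR),
      ventricleScale = as.numeric(ventricleScale),
      ventricleOffsets = ventricleOffsets,
      ventricleSemiaxes = as.numeric(ventricleSemiaxes),
      psfFWHM = as.numeric(psfFWHM), noise = noise,
      attenuation = attenuation, attenuationMu = as.numeric(attenuationMu),
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: grid %s @ %s mm, background %g\n",
              paste(object@gridShape, collapse = "x"),
              paste(format(object@voxelSize), collapse = "x"),
              object@background))
  cat(sprintf("  true SBR L/R = %.3g/%.3g, ventricle scale %.3g, PSF %.3g mm\n",
              object@trueSBR[1], object@trueSBR[2], object@ventricleScale,
              object@psfFWHM))
  cat(sprintf("  noise %s, attenuation %s, seed %d\n",
              object@noise, object@attenuation, object@seed))
})

#' GroundTruth: the truth channel of a synthetic subject
#'
#' Carries what the generator knows exactly: the per-side true SBR, the
#' structure masks on the voxel grid, the analytic Evans index of the
#' generating ellipsoids, and the diagnostic group label (if the subject
#' came from a simulated cohort).
#'
#' @slot trueSBR numeric(2), left and right.
#' @slot brainMask,striatumLeft,striatumRight,ventricleMask logical arrays.
#' @slot trueEI analytic Evans index of the generating geometry;
#'   `NA` when `ventricleScale = 0`.
#' @slot label group label, `"PS"`, `"NPS"`, or `""`.
#' @export
setClass("GroundTruth",
         slots = c(trueSBR = "numeric", brainMask = "array",
                   striatumLeft = "array", striatumRight = "array",
                   ventricleMask = "array", trueEI = "numeric",
                   label = "character"))

setValidity("GroundTruth", function(object) {
  if (!is.na(object@trueEI) && (object@trueEI <= 0 || object@trueEI >= 1))
    return("'trueEI' must lie in (0, 1) (or NA when there are no ventricles)")
  if (any(object@striatumLeft & !object@brainMask) ||
      any(object@striatumRight & !object@brainMask) ||
      any(object@ventricleMask & !object@brainMask))
    return("structure masks must be subsets of the brain mask")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: true SBR L/R = %.3g/%.3g, true EI = %s, label '%s'\n",
              object@trueSBR[1], object@trueSBR[2],
              ifelse(is.na(object@trueEI), "NA", sprintf("%.3f", object@trueEI)),
              object@label))
})

#' CohortSpec: generative parameters of a two-group diagnostic cohort
#'
#' Per-group true-SBR normal laws (truncated at zero) and a
#' label-independent ventricular-dilatation distribution. Defaults follow
#' the clinical group statistics of the CSF-masked index without
#' attenuation correction: NPS 4.72 +- 1.18 versus PS 2.62 +- 1.02.
#'
#' @slot nPS,nNPS subjects per group.
#' @slot meanSBR,sdSBR named numeric(2) (`PS`, `NPS`).
#' @slot ventricleScaleRange uniform range of the per-subject ventricle
#'   scale factor, independent of the group label.
#' @slot phantom shared [PhantomSpec-class] template.
#' @slot seed master seed; per-subject seeds are derived from it by a
#'   fixed counter scheme so cohorts are reproducible under subsetting.
#' @export
setClass("CohortSpec",
         slots = c(nPS = "integer", nNPS = "integer",
                   meanSBR = "numeric", sdSBR = "numeric",
                   ventricleScaleRange = "numeric",
                   phantom = "PhantomSpec", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nPS < 1L || object@nNPS < 1L)
    return("need at least one subject per group")
  if (!all(c("PS", "NPS") %in% names(object@meanSBR)) ||
      !all(c("PS", "NPS") %in% names(object@sdSBR)))
    return("'meanSBR' and 'sdSBR' must be named with PS and NPS")
  if (any(object@sdSBR < 0)) return("SDs must be >= 0")
  if (length(object@ventricleScaleRange) != 2L ||
      any(object@ventricleScaleRange < 0) ||
      diff(object@ventricleScaleRange) < 0)
    return("'ventricleScaleRange' must be an increasing non-negative range")
  TRUE
})

#' Construct a CohortSpec
#'
#' @param nPS,nNPS subjects in the parkinsonian-syndrome (PS) and
#'   non-parkinsonian (NPS) groups.
#' @param meanSBR,sdSBR named per-group true-SBR mean and SD.
#' @param ventricleScaleRange uniform range of the ventricle scale factor.
#' @param phantom shared phantom template (grid, blur, noise, ...).
#' @param seed master seed.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nPS, nNPS,
                       meanSBR = c(PS = 2.62, NPS = 4.72),
                       sdSBR = c(PS = 1.02, NPS = 1.18),
                       ventricleScaleRange = c(0.2, 2.2),
                       phantom = phantomSpec(), seed = 1L) {
  new("CohortSpec", nPS = as.integer(nPS), nNPS = as.integer(nNPS),
      meanSBR = meanSBR, sdSBR = sdSBR,
      ventricleScaleRange = as.numeric(ventricleScaleRange),
      phantom = phantom, seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d PS + %d NPS subjects, seed %d\n",
              object@nPS, object@nNPS, object@seed))
  cat(sprintf("  true SBR: PS %.3g +- %.3g, NPS %.3g +- %.3g\n",
              object@meanSBR["PS"], object@sdSBR["PS"],
              object@meanSBR["NPS"], object@sdSBR["NPS"]))
  cat(sprintf("  ventricle scale ~ U(%.3g, %.3g)\n",
              object@ventricleScaleRange[1], object@ventricleScaleRange[2]))
})

# ---------------------------------------------------------------------------
# VOIs
# ---------------------------------------------------------------------------

#' StriatalVOI: one pentagonal-prism striatal volume of interest
#'
#' An in-plane pentagon (vertices in world mm) extruded over an axial
#' extent, rasterised to a boolean voxel mask. The pentagon is large by
#' design: it encompasses a wide area around the striatum so that blurred
#' striatal counts stay inside the VOI and the index is robust to the
#' partial-volume effect.
#'
#' @slot side `"left"` or `"right"`.
#' @slot vertices 5 x 2 matrix of in-plane (x, y) vertices in mm.
#' @slot zRange numeric(2), axial extent in mm.
#' @slot mask logical voxel mask.
#' @export
setClass("StriatalVOI",
         slots = c(side = "character", vertices = "matrix",
                   zRange = "numeric", mask = "array"))

setValidity("StriatalVOI", function(object) {
  if (!object@side %in% c("left", "right"))
    return("'side' must be 'left' or 'right'")
  if (any(dim(object@vertices) != c(5L, 2L)))
    return("'vertices' must be a 5 x 2 matrix")
  if (length(object@zRange) != 2L || diff(object@zRange) <= 0)
    return("'zRange' must be an increasing pair")
  TRUE
})

#' VOISet: striatal VOIs plus the whole-brain reference region
#'
#' @slot left,right [StriatalVOI-class] objects.
#' @slot brainMask logical array, the segmented brain.
#' @slot referenceMask logical array: brain minus both striatal VOIs, the
#'   non-specific-binding reference of the SBR definition.
#' @export
setClass("VOISet",
         slots = c(left = "StriatalVOI", right = "StriatalVOI",
                   brainMask = "array", referenceMask = "array"))

setValidity("VOISet", function(object) {
  if (any(object@left@mask & object@right@mask))
    return("left and right striatal VOIs must be disjoint")
  if (any(object@referenceMask & (object@left@mask | object@right@mask)))
    return("reference region must not intersect the striatal VOIs")
  if (!any(object@referenceMask))
    return("reference region is empty")
  TRUE
})

setMethod("show", "VOISet", function(object) {
  cat("VOISet (pentagonal-prism striatal VOIs + whole-brain reference)\n")
  cat(sprintf("  brain %d voxels; left VOI %d, right VOI %d, reference %d\n",
              sum(object@brainMask), sum(object@left@mask),
              sum(object@right@mask), sum(object@referenceMask)))
})

# ---------------------------------------------------------------------------
# CSF-mask threshold fit
# ---------------------------------------------------------------------------

#' ThresholdFit: the CSF-mask threshold and its provenance
#'
#' Holds the reference-background histogram, the Gaussian fit
#' (median `xTilde` and SD `sigma`; for a Gaussian the median equals the
#' mean), the coefficient `k`, the resulting threshold
#' `xTilde - sigma * k`, and the voxel exclusion mask (brain voxels with
#' counts strictly below the threshold).
#'
#' @slot breaks,counts histogram bin edges and counts.
#' @slot xTilde,sigma fitted median and SD of the background (counts).
#' @slot k threshold coefficient (clinical default 1.0).
#' @slot threshold `xTilde - sigma * k`.
#' @slot fitOK `FALSE` when the nonlinear fit failed and the robust
#'   median/MAD fallback was used.
#' @slot exclusionMask logical array, subset of the brain mask.
#' @export
setClass("ThresholdFit",
         slots = c(breaks = "numeric", counts = "numeric",
                   xTilde = "numeric", sigma = "numeric", k = "numeric",
                   threshold = "numeric", fitOK = "logical",
                   exclusionMask = "array"))

setValidity("ThresholdFit", function(object) {
  if (object@sigma < 0) return("'sigma' must be >= 0")
  tol <- 1e-8 * max(1, abs(object@xTilde))
  if (abs(object@threshold - (object@xTilde - object@sigma * object@k)) > tol)
    return("'threshold' must equal xTilde - sigma * k")
  TRUE
})

setMethod("show", "ThresholdFit", function(object) {
  cat(sprintf(
    "ThresholdFit: xTilde = %.4g, sigma = %.4g, k = %.3g -> threshold = %.4g\n",
    object@xTilde, object@sigma, object@k, object@threshold))
  cat(sprintf("  fit %s; %d voxels excluded\n",
              if (object@fitOK) "converged" else "fell back to median/MAD",
              sum(object@exclusionMask)))
})

# ---------------------------------------------------------------------------
# SBR result
# ---------------------------------------------------------------------------

#' SBRResult: one side's specific binding ratio with its count terms
#'
#' `sbr = (Ctc / Ccr - Vc) / Vs` where `Ctc` is the total count in the
#' striatal VOI, `Ccr` the count concentration (counts/ml) of the
#' reference region, `Vc` the striatal-VOI volume (ml), and `Vs` the
#' nominal anatomical striatal volume (11.2 ml). When the CSF mask is
#' applied, excluded voxels are removed from all three measured terms.
#'
#' @slot side `"left"` or `"right"`.
#' @slot masked was the CSF-mask exclusion applied?
#' @slot Ctc,Ccr,Vc,Vs the terms above.
#' @slot sbr the dimensionless index.
#' @export
setClass("SBRResult",
         slots = c(side = "character", masked = "logical",
                   Ctc = "numeric", Ccr = "numeric", Vc = "numeric",
                   Vs = "numeric", sbr = "numeric"))

setValidity("SBRResult", function(object) {
  if (object@Ccr <= 0) return("'Ccr' must be positive")
  expect <- (object@Ctc / object@Ccr - object@Vc) / object@Vs
  if (abs(object@sbr - expect) > 1e-8 * max(1, abs(expect)))
    return("'sbr' must equal (Ctc/Ccr - Vc)/Vs")
  TRUE
})

setMethod("show", "SBRResult", function(object) {
  cat(sprintf("SBRResult (%s, %s): SBR = %.4g\n", object@side,
              if (object@masked) "CSF-masked" else "unmasked", object@sbr))
  cat(sprintf("  Ctc = %.6g counts, Ccr = %.6g counts/ml, Vc = %.4g ml, Vs = %.3g ml\n",
              object@Ctc, object@Ccr, object@Vc, object@Vs))
})

# ---------------------------------------------------------------------------
# Evans index
# ---------------------------------------------------------------------------

#' EvansResult: the Evans index and the widths that define it
#'
#' EI = maximal frontal-horn width of the lateral ventricles divided by
#' the maximal internal skull diameter on the same axial slice.
#'
#' @slot EI dimensionless, in (0, 1) for valid anatomy.
#' @slot hornWidth,skullDiameter widths in mm.
#' @slot sliceIndex axial slice (1-based) where the maximum occurs.
#' @export
setClass("EvansResult",
         slots = c(EI = "numeric", hornWidth = "numeric",
                   skullDiameter = "numeric", sliceIndex = "integer"))

setValidity("EvansResult", function(object) {
  if (object@hornWidth <= 0 || object@skullDiameter <= 0)
    return("widths must be positive")
  tol <- 1e-10
  if (abs(object@EI - object@hornWidth / object@skullDiameter) > tol)
    return("'EI' must equal hornWidth / skullDiameter")
  TRUE
})

setMethod("show", "EvansResult", function(object) {
  cat(sprintf("EvansResult: EI = %.3f (horn %.1f mm / skull %.1f mm, slice %d)\n",
              object@EI, object@hornWidth, object@skullDiameter,
              object@sliceIndex))
})

# ---------------------------------------------------------------------------
# ROC results
# ---------------------------------------------------------------------------

#' ROCResult: AUC with DeLong variance and the ROC operating points
#'
#' Orientation is fixed package-wide: PS cases have lower SBR, so a
#' subject is called PS-positive when its score falls below the cutoff,
#' and the AUC equals the Mann-Whitney probability that an NPS score
#' exceeds a PS score (ties counting one half).
#'
#' @slot auc area under the curve.
#' @slot varAUC DeLong structural-component variance of the AUC.
#' @slot ci 95 percent confidence interval (normal approximation,
#'   truncated to `[0, 1]`).
#' @slot curve data.frame of candidate cutoffs with sensitivity and
#'   specificity.
#' @slot scores,labels the inputs (kept for cutoff selection).
#' @slot positive the label of the low-score (disease) class.
#' @export
setClass("ROCResult",
         slots = c(auc = "numeric", varAUC = "numeric", ci = "numeric",
                   curve = "data.frame", scores = "numeric",
                   labels = "character", positive = "character"))

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.3f (95%% CI %.3f-%.3f), %d subjects\n",
              object@auc, object@ci[1], object@ci[2], length(object@scores)))
  cat("  orientation: lower score => PS-positive\n")
})

#' ROCComparison: DeLong paired comparison of two AUCs
#'
#' @slot aucA,aucB the two paired AUC estimates (same subjects scored by
#'   two indices).
#' @slot varDiff DeLong variance of the AUC difference.
#' @slot z,p z statistic and two-sided normal p value.
#' @export
setClass("ROCComparison",
         slots = c(aucA = "numeric", aucB = "numeric", varDiff = "numeric",
                   z = "numeric", p = "numeric"))

setValidity("ROCComparison", function(object) {
  if (object@p < 0 || object@p > 1) return("'p' must lie in [0, 1]")
  TRUE
})

setMethod("show", "ROCComparison", function(object) {
  cat(sprintf("ROCComparison (DeLong): AUC A = %.3f vs B = %.3f\n",
              object@aucA, object@aucB))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", object@z, object@p))
})

# ---------------------------------------------------------------------------
# Diagnostic metrics
# ---------------------------------------------------------------------------

#' DiagnosticTable: confusion counts and derived metrics at a cutoff
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), accuracy = (TP+TN)/n, each reported as a percentage
#' with its defining fraction. Division-by-zero cells are `NA`
#' (undefined), never 0.
#'
#' @slot cutoff the operating cutoff (PS-positive below it).
#' @slot TP,FN,TN,FP integer confusion counts.
#' @slot metrics data.frame with columns `metric`, `percent`,
#'   `numerator`, `denominator`.
#' @export
setClass("DiagnosticTable",
         slots = c(cutoff = "numeric", TP = "integer", FN = "integer",
                   TN = "integer", FP = "integer", metrics = "data.frame"))

setMethod("show", "DiagnosticTable", function(object) {
  cat(sprintf("DiagnosticTable at cutoff %.4g (PS-positive below)\n",
              object@cutoff))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n",
              object@TP, object@FN, object@TN, object@FP))
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %s (%d/%d)\n", m$metric[i],
                ifelse(is.na(m$percent[i]), "undefined",
                       sprintf("%.1f%%", m$percent[i])),
                m$numerator[i], m$denominator[i]))
})
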