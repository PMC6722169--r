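# Digital brain phantom generation.
#
# The phantom is deliberately stylised: ellipsoidal brain, ellipsoidal
# striata and ventricles. The Southampton bookkeeping only needs volumes
# and containment, so mesh-level anatomical realism buys nothing for the
# questions the package answers.

# voxel-centre world coordinates along one axis (0-based index * voxel size)
.axisCoords <- function(n, vox) (seq_len(n) - 1) * vox

# squared normalised distance field of an ellipsoid, as a 3-D array
.ellipsoidField <- function(gridShape, voxelSize, center, semiaxes) {
  dx2 <- ((.axisCoords(gridShape[1], voxelSize[1]) - center[1]) / semiaxes[1])^2
  dy2 <- ((.axisCoords(gridShape[2], voxelSize[2]) - center[2]) / semiaxes[2])^2
  dz2 <- ((.axisCoords(gridShape[3], voxelSize[3]) - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

.ellipsoidMask <- function(gridShape, voxelSize, center, semiaxes)
  .ellipsoidField(gridShape, voxelSize, center, semiaxes) <= 1

# grid centre in world mm
.gridCenter <- function(gridShape, voxelSize) (gridShape - 1) / 2 * voxelSize

# striatal semiaxes: aspect proportions rescaled so the ellipsoid volume
# equals the requested anatomical volume (ml)
.striatumSemiaxes <- function(spec) {
  targetMM3 <- spec@striatumVolumeML * 1000
  aspectVol <- 4 / 3 * pi * prod(spec@striatumAspect)
  spec@striatumAspect * (targetMM3 / aspectVol)^(1 / 3)
}

# analytic Evans index of the generating ellipsoids: the frontal-horn
# width is widest at the ventricle-centre plane (2 * (|x offset| + a)),
# and the skull inner diameter is the brain width at that axial level
.analyticEI <- function(spec) {
  s <- spec@ventricleScale
  if (s <= 0) return(NA_real_)
  a <- spec@ventricleSemiaxes[1] * s
  xoff <- abs(spec@ventricleOffsets[, 1])
  horn <- sum(xoff) + 2 * a                    # left + right outer extents
  dz <- spec@ventricleOffsets[1, 3]            # both ventricles share z
  C <- spec@brainSemiaxes[3]
  if (abs(dz) >= C) stop("ventricle centre lies outside the brain in z")
  skull <- 2 * spec@brainSemiaxes[1] * sqrt(1 - (dz / C)^2)
  horn / skull
}

# approximate depth (mm) below the brain surface: distance along the ray
# from the ellipsoid centre, (1 - m) * R(theta), where m is the
# normalised radius and R the ellipsoid radius in that direction
.brainDepth <- function(spec, brainMask) {
  gs <- spec@gridShape; vs <- spec@voxelSize
  ctr <- .gridCenter(gs, vs)
  ax <- spec@brainSemiaxes
  dx <- .axisCoords(gs[1], vs[1]) - ctr[1]
  dy <- .axisCoords(gs[2], vs[2]) - ctr[2]
  dz <- .axisCoords(gs[3], vs[3]) - ctr[3]
  X <- array(dx, gs)
  Y <- aperm(array(dy, gs[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(dz, gs[c(3, 1, 2)]), c(2, 3, 1))
  r2 <- X^2 + Y^2 + Z^2
  m2 <- (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2
  depth <- array(0, gs)
  inside <- brainMask & m2 > 0
  # R(theta) = |p - c| / m, so depth = (1 - m) * R = |p - c| * (1/m - 1)
  m <- sqrt(m2[inside])
  depth[inside] <- sqrt(r2[inside]) * (1 / m - 1)
  depth[brainMask & m2 == 0] <- min(ax)   # exact centre
  depth
}

#' Build a digital SPECT brain phantom with known ground truth
#'
#' Paints uniform non-specific uptake over an ellipsoidal brain, sets the
#' striatal voxel concentration from the requested true SBR, zeroes the
#' ventricle voxels, and then (in this order) applies the optional
#' depth-dependent attenuation emulation, Gaussian point-spread blur, and
#' Poisson count noise.
#'
#' The striatal concentration is calibrated analytically:
#' `Cs = Cb * (1 + trueSBR * Vnom / Vact)`, where `Vnom` is the nominal
#' striatal volume (the `striatumVolumeML` of the spec, 11.2 ml by
#' default) and `Vact` the voxelised striatal volume actually painted.
#' Exact Southampton bookkeeping on the noiseless, unblurred volume then
#' returns `trueSBR` identically, which is what makes the phantom a
#' usable truth channel for parameter-recovery tests.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `volume` ([CountVolume-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' p <- buildPhantom(phantomSpec(gridShape = c(48, 48, 32), trueSBR = 4))
#' p$truth
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape; vs <- spec@voxelSize
  ctr <- .gridCenter(gs, vs)

  brain <- .ellipsoidMask(gs, vs, ctr, spec@brainSemiaxes)
  strAx <- .striatumSemiaxes(spec)
  strL <- .ellipsoidMask(gs, vs, ctr + spec@striatumOffsets[1, ], strAx)
  strR <- .ellipsoidMask(gs, vs, ctr + spec@striatumOffsets[2, ], strAx)

  vent <- array(FALSE, gs)
  if (spec@ventricleScale > 0) {
    vAx <- spec@ventricleSemiaxes * spec@ventricleScale
    vent <- .ellipsoidMask(gs, vs, ctr + spec@ventricleOffsets[1, ], vAx) |
            .ellipsoidMask(gs, vs, ctr + spec@ventricleOffsets[2, ], vAx)
    if (any(vent & !brain))
      stop("ventricle_scale too large: ventricles exit the brain ellipsoid")
    if (any(vent & (strL | strR)))
      stop("overlapping structures: ventricles intersect the striata")
  }
  if (any(strL & strR)) stop("overlapping structures: striata intersect")
  if (any((strL | strR) & !brain))
    stop("striata are not strictly inside the brain ellipsoid")

  vals <- array(0, gs)
  vals[brain] <- spec@background
  voxML <- prod(vs) / 1000
  for (m in list(strL, strR)) {
    side <- if (identical(m, strL)) 1L else 2L
    vact <- sum(m) * voxML
    if (vact <= 0) stop("striatal mask is empty on this grid")
    vals[m] <- spec@background *
      (1 + spec@trueSBR[side] * spec@striatumVolumeML / vact)
  }
  vals[vent] <- 0

  if (spec@attenuation) {
    depth <- .brainDepth(spec, brain)
    vals <- vals * exp(-spec@attenuationMu * depth)
  }
  vol <- CountVolume(vals, vs)
  if (spec@psfFWHM > 0) vol <- applyPSF(vol, spec@psfFWHM)
  if (spec@noise) vol <- applyPoissonNoise(vol, spec@seed)

  truth <- new("GroundTruth", trueSBR = spec@trueSBR, brainMask = brain,
               striatumLeft = strL, striatumRight = strR,
               ventricleMask = vent, trueEI = .analyticEI(spec),
               label = "")
  list(volume = vol, truth = truth)
}

# 1-D convolution along the first axis via banded dense matrix product
.convAxis1 <- function(arr, w) {
  d <- dim(arr); n <- d[1]; r <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n); j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- w[o + r + 1L]
  }
  out <- K %*% matrix(arr, nrow = n)
  dim(out) <- d
  out
}

#' Apply Gaussian point-spread blur to a count volume
#'
#' Separable Gaussian convolution with `sigma = fwhm / 2.3548` per axis
#' (in mm), using a sampled, normalised kernel truncated at four sigma.
#' Stands in for the finite reconstruction resolution of the scanner.
#' Total counts are conserved for structures away from the grid edge;
#' counts blurred past the boundary are lost (no wrap-around).
#'
#' @param vol a [CountVolume-class].
#' @param fwhm full width at half maximum of the Gaussian in mm
#'   (scalar, or one value per axis); 0 returns the input unchanged.
#' @return A blurred [CountVolume-class].
#' @export
applyPSF <- function(vol, fwhm) {
  stopifnot(is(vol, "CountVolume"))
  if (any(fwhm < 0)) stop("'fwhm' must be >= 0")
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3L)
  if (all(fwhm == 0)) return(vol)
  vals <- vol@values
  for (ax in 1:3) {
    if (fwhm[ax] == 0) next
    sigma <- fwhm[ax] / (2 * sqrt(2 * log(2)))
    vox <- vol@voxelSize[ax]
    r <- max(1L, ceiling(4 * sigma / vox))
    w <- stats::dnorm((-r:r) * vox, 0, sigma)
    w <- w / sum(w)
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    vals <- aperm(.convAxis1(aperm(vals, perm), w), order(perm))
  }
  vals[vals < 0] <- 0   # clip numerical noise
  CountVolume(vals, vol@voxelSize)
}

#' Apply Poisson count noise
#'
#' Each voxel becomes an independent Poisson draw with mean equal to its
#' current value, the count statistics of emission imaging. Output values
#' are integers.
#'
#' @param vol a [CountVolume-class] with non-negative voxel values.
#' @param seed integer seed; the same seed reproduces the same volume.
#' @return A noisy [CountVolume-class].
#' @export
applyPoissonNoise <- function(vol, seed = 1L) {
  stopifnot(is(vol, "CountVolume"))
  if (any(vol@values < 0)) stop("voxel values must be non-negative")
  set.seed(as.integer(seed))
  vals <- stats::rpois(length(vol@values), as.vector(vol@values))
  CountVolume(array(as.numeric(vals), dim(vol@values)), vol@voxelSize)
}

# deterministic per-subject seed: a fixed counter scheme off the master
# seed, so subject i is reproducible regardless of cohort size
.subjectSeed <- function(master, i)
  as.integer((as.numeric(master) + i * 1000003) %% 2147483647)

#' Simulate a two-group diagnostic cohort
#'
#' Draws each subject's true SBR from its group's normal law truncated at
#' zero (the same value on both sides; disease asymmetry is not
#' modelled), and a ventricle scale factor from the configured uniform
#' range, independent of the group label. Each subject gets its own
#' derived seed, so the cohort is fully reproducible and subjects keep
#' their identity under subsetting.
#'
#' @param cs a [CohortSpec-class].
#' @param materialize if `TRUE`, phantoms are built immediately and the
#'   result carries `volume`/`truth` per subject; otherwise only the
#'   per-subject [PhantomSpec-class] is stored and volumes are built on
#'   demand (e.g. by [quantifyCohort()]).
#' @return A list with `manifest` (data.frame: id, label, true SBR,
#'   ventricle scale, analytic true EI, seed) and `subjects` (list of
#'   per-subject specs, or built phantoms when materialised).
#' @export
simulateCohort <- function(cs, materialize = FALSE) {
  validObject(cs)
  n <- cs@nPS + cs@nNPS
  labels <- c(rep("PS", cs@nPS), rep("NPS", cs@nNPS))
  subjects <- vector("list", n)
  man <- data.frame(id = sprintf("S%03d", seq_len(n)), label = labels,
                    true_sbr = NA_real_, ventricle_scale = NA_real_,
                    true_ei = NA_real_, seed = NA_integer_,
                    stringsAsFactors = FALSE)
  rtrunc0 <- function(mu, sd) {
    if (sd == 0) return(mu)
    repeat { v <- stats::rnorm(1, mu, sd); if (v > 0) return(v) }
  }
  for (i in seq_len(n)) {
    sd_i <- .subjectSeed(cs@seed, i)
    set.seed(sd_i)
    g <- labels[i]
    sbr <- rtrunc0(cs@meanSBR[[g]], cs@sdSBR[[g]])
    vsc <- stats::runif(1, cs@ventricleScaleRange[1], cs@ventricleScaleRange[2])
    sp <- cs@phantom
    sp@trueSBR <- c(sbr, sbr)
    sp@ventricleScale <- vsc
    sp@seed <- sd_i
    man$true_sbr[i] <- sbr
    man$ventricle_scale[i] <- vsc
    man$true_ei[i] <- .analyticEI(sp)
    man$seed[i] <- sd_i
    if (materialize) {
      ph <- buildPhantom(sp)
      ph$truth@label <- g
      subjects[[i]] <- ph
    } else {
      subjects[[i]] <- sp
    }
  }
  list(manifest = man, subjects = subjects)
}
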