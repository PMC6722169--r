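# Southampton-style VOI construction: brain segmentation, the large
# pentagonal-prism striatal VOIs, and the whole-brain reference region.

# union-find over integer labels
.ufFind <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

# largest 6-connected 3-D component of a boolean mask, built from
# per-slice EBImage::bwlabel labels merged across adjacent slices
.largestComponent <- function(mask) {
  d <- dim(mask)
  lab <- EBImage::bwlabel(array(as.numeric(mask), d))
  lab <- array(as.integer(lab), d)
  # make per-slice labels globally unique
  offs <- integer(d[3])
  run <- 0L
  for (z in seq_len(d[3])) {
    mx <- max(lab[, , z])
    offs[z] <- run
    sl <- lab[, , z]
    sl[sl > 0L] <- sl[sl > 0L] + run
    lab[, , z] <- sl
    run <- run + mx
  }
  if (run == 0L) return(mask & FALSE)
  parent <- seq_len(run)
  for (z in seq_len(d[3] - 1L)) {
    a <- lab[, , z]; b <- lab[, , z + 1L]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    pairs <- unique(cbind(a[ok], b[ok]))
    for (r in seq_len(nrow(pairs))) {
      ra <- .ufFind(parent, pairs[r, 1]); rb <- .ufFind(parent, pairs[r, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(run), function(i) .ufFind(parent, i), integer(1))
  flat <- lab[lab > 0L]
  comp <- root[flat]
  sizes <- tabulate(comp, nbins = run)
  keep <- which.max(sizes)
  out <- array(FALSE, d)
  out[lab > 0L] <- comp == keep
  out
}

# global Otsu threshold on the voxel values (256 levels)
.otsuThreshold <- function(v) {
  mx <- max(v)
  if (mx <= 0) stop("cannot threshold an all-zero volume")
  th <- EBImage::otsu(EBImage::Image(matrix(v / mx, ncol = 1)), levels = 256L)
  th * mx
}

#' Segment the brain from a count volume
#'
#' Thresholds the volume (`"otsu"`, the default, or `"fraction"`: voxels
#' at or above `fraction` times the 99th-percentile count), keeps the
#' largest 6-connected component, and fills interior holes slice-wise so
#' that low-count ventricles remain inside the brain mask. The clinical
#' software does this semi-automatically; here it is a deterministic
#' stand-in with the same contract.
#'
#' @param vol a [CountVolume-class] with non-zero counts.
#' @param method `"otsu"` or `"fraction"`.
#' @param fraction threshold fraction for `method = "fraction"`.
#' @param fillHoles fill interior holes (default `TRUE`).
#' @return A logical array (brain mask).
#' @export
segmentBrain <- function(vol, method = c("otsu", "fraction"),
                         fraction = 0.15, fillHoles = TRUE) {
  stopifnot(is(vol, "CountVolume"))
  method <- match.arg(method)
  v <- vol@values
  if (all(v == 0)) stop("volume has no counts; cannot segment")
  mask <- if (method == "otsu") {
    v > .otsuThreshold(as.vector(v))
  } else {
    v >= fraction * stats::quantile(v, 0.99, names = FALSE)
  }
  if (!any(mask)) stop("brain mask is empty after thresholding")
  mask <- .largestComponent(mask)
  if (fillHoles) {
    filled <- EBImage::fillHull(array(as.numeric(mask), dim(mask)))
    mask <- array(filled > 0, dim(mask))
  }
  mask
}

# vertices of a regular pentagon, one vertex pointing anteriorly (+y)
.pentagonVertices <- function(center, radius) {
  ang <- (90 + 72 * 0:4) * pi / 180
  cbind(x = center[1] + radius * cos(ang),
        y = center[2] + radius * sin(ang))
}

# voxel-centre-in-convex-polygon test on the in-plane grid
.pentagonSliceMask <- function(gridShape, voxelSize, verts) {
  xs <- .axisCoords(gridShape[1], voxelSize[1])
  ys <- .axisCoords(gridShape[2], voxelSize[2])
  X <- matrix(xs, gridShape[1], gridShape[2])
  Y <- matrix(ys, gridShape[1], gridShape[2], byrow = TRUE)
  inside <- matrix(TRUE, gridShape[1], gridShape[2])
  nv <- nrow(verts)
  for (i in seq_len(nv)) {
    j <- i %% nv + 1L
    ex <- verts[j, 1] - verts[i, 1]; ey <- verts[j, 2] - verts[i, 2]
    # vertices run counter-clockwise; interior has non-negative cross product
    inside <- inside & (ex * (Y - verts[i, 2]) - ey * (X - verts[i, 1]) >= 0)
  }
  inside
}

.prismMask <- function(gridShape, voxelSize, verts, zRange) {
  slice <- .pentagonSliceMask(gridShape, voxelSize, verts)
  zs <- .axisCoords(gridShape[3], voxelSize[3])
  inz <- zs >= zRange[1] & zs <= zRange[2]
  out <- array(FALSE, gridShape)
  out[, , inz] <- slice
  out
}

#' Place the pentagonal-prism striatal VOIs and the reference region
#'
#' Each striatal VOI is a regular pentagon (inscribed in a 50 mm-diameter
#' circle by default, one vertex pointing anteriorly) extruded 44 mm
#' axially and centred on the striatum. The VOI is deliberately much
#' larger than the striatum (at least three times the nominal 11.2 ml) so
#' that counts blurred out of the striatum stay inside it. The reference
#' region is the segmented brain minus both striatal VOIs.
#'
#' Centre determination: `mode = "oracle"` uses the true striatal
#' centroids from a [GroundTruth-class]; `mode = "auto"` smooths the
#' volume (12 mm FWHM) and takes the per-hemisphere maximum, failing if a
#' hemisphere shows no maximum above the background level.
#'
#' @param vol a [CountVolume-class].
#' @param mode `"auto"` or `"oracle"`.
#' @param truth a [GroundTruth-class], required for `mode = "oracle"`.
#' @param brainMask optional precomputed brain mask; segmented from `vol`
#'   when missing.
#' @param pentagonRadius circumradius of the pentagon in mm (default 25).
#' @param prismHeight axial prism extent in mm (default 44).
#' @param clipToBrain clip the VOIs to the brain mask so extracranial
#'   zeros never enter the striatal count (default `TRUE`).
#' @param smoothFWHM smoothing width for auto placement (mm).
#' @return A [VOISet-class].
#' @export
placeStriatalVOIs <- function(vol, mode = c("auto", "oracle"), truth = NULL,
                              brainMask = NULL, pentagonRadius = 25,
                              prismHeight = 44, clipToBrain = TRUE,
                              smoothFWHM = 12) {
  stopifnot(is(vol, "CountVolume"))
  mode <- match.arg(mode)
  gs <- dim(vol@values); vs <- vol@voxelSize
  if (is.null(brainMask)) brainMask <- segmentBrain(vol)

  centroidOf <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    (colMeans(idx) - 1) * vs
  }
  if (mode == "oracle") {
    if (is.null(truth)) stop("mode 'oracle' requires a GroundTruth")
    centers <- rbind(centroidOf(truth@striatumLeft),
                     centroidOf(truth@striatumRight))
  } else {
    sm <- applyPSF(vol, smoothFWHM)@values
    midX <- centroidOf(brainMask)[1]
    xs <- .axisCoords(gs[1], vs[1])
    centers <- matrix(NA_real_, 2, 3)
    for (side in 1:2) {
      hemi <- if (side == 1) xs < midX else xs >= midX
      cand <- array(FALSE, gs); cand[hemi, , ] <- TRUE
      cand <- cand & brainMask
      v <- sm[cand]
      if (!length(v)) stop("empty hemisphere in auto VOI placement")
      if (max(v) <= 1.1 * stats::median(v))
        stop("no striatal maximum above background in one hemisphere")
      w <- which(cand)
      peak <- w[which.max(sm[cand])]
      ai <- arrayInd(peak, gs)
      centers[side, ] <- (ai - 1) * vs
    }
  }

  makeVOI <- function(side, ctr) {
    verts <- .pentagonVertices(ctr[1:2], pentagonRadius)
    zr <- ctr[3] + c(-1, 1) * prismHeight / 2
    m <- .prismMask(gs, vs, verts, zr)
    if (clipToBrain) m <- m & brainMask
    if (!any(m)) stop("striatal VOI is empty after clipping")
    new("StriatalVOI", side = side, vertices = verts, zRange = zr, mask = m)
  }
  left <- makeVOI("left", centers[1, ])
  right <- makeVOI("right", centers[2, ])
  if (any(left@mask & right@mask))
    stop("striatal VOIs overlap after clipping; check placement")
  ref <- brainMask & !left@mask & !right@mask
  if (!any(ref)) stop("reference region is empty")
  new("VOISet", left = left, right = right,
      brainMask = brainMask, referenceMask = ref)
}

#' Volume of a voxel mask in ml
#'
#' @param mask logical array.
#' @param voxelSizeMM voxel dimensions in mm (scalar or length 3).
#' @return Volume in ml (1 ml = 1000 mm^3).
#' @examples
#' voiVolume(array(TRUE, c(10, 10, 10)), 4.4)  # 1000 voxels -> 85.184 ml
#' @export
voiVolume <- function(mask, voxelSizeMM) {
  if (length(voxelSizeMM) == 1L) voxelSizeMM <- rep(voxelSizeMM, 3L)
  sum(mask) * prod(voxelSizeMM) / 1000
}
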