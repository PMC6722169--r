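# Evans index: frontal-horn width over internal skull diameter, and the
# tertile grading of ventricular dilatation.

#' Compute the Evans index from ventricle and skull masks
#'
#' The frontal-horn region is operationalised as the anterior half of the
#' ventricle mask (voxels anterior of the ventricle centroid) -- a
#' simplification of the manual radiological measurement that is adequate
#' for the phantom's mirrored, anterior-elongated ventricle geometry. Per
#' axial slice, the width is the inclusive left-right voxel extent of
#' that region in mm; the EI uses the slice maximising the width, with
#' the internal skull diameter measured on the same slice.
#'
#' @param ventricleMask,skullInnerMask non-empty logical arrays on the
#'   same grid (the phantom's brain mask serves as the inner skull
#'   boundary).
#' @param voxelSizeMM voxel dimensions in mm (scalar or length 3).
#' @return An [EvansResult-class].
#' @export
computeEvansIndex <- function(ventricleMask, skullInnerMask, voxelSizeMM) {
  if (length(voxelSizeMM) == 1L) voxelSizeMM <- rep(voxelSizeMM, 3L)
  if (!any(ventricleMask)) stop("ventricle mask is empty")
  if (!any(skullInnerMask)) stop("skull mask is empty")
  if (!identical(dim(ventricleMask), dim(skullInnerMask)))
    stop("masks must share a grid")
  d <- dim(ventricleMask)

  idx <- which(ventricleMask, arr.ind = TRUE)
  frontal <- ventricleMask
  # anterior half: voxels at or beyond the centroid slice (the ceiling
  # keeps the rule non-degenerate when the mask is only a voxel thick)
  cut <- ceiling(mean(idx[, 2]))
  if (cut > 1L) frontal[, seq_len(cut - 1L), ] <- FALSE
  if (!any(frontal)) stop("frontal-horn region is empty")

  widthOn <- function(mask, z) {
    sl <- which(mask[, , z], arr.ind = TRUE)
    if (!nrow(sl)) return(NA_real_)
    (max(sl[, 1]) - min(sl[, 1]) + 1) * voxelSizeMM[1]
  }
  horn <- vapply(seq_len(d[3]), function(z) widthOn(frontal, z), numeric(1))
  if (all(is.na(horn))) stop("frontal-horn region is empty")
  zBest <- which.max(horn)
  skull <- widthOn(skullInnerMask, zBest)
  if (is.na(skull)) stop("skull mask is empty on the frontal-horn slice")
  new("EvansResult", EI = horn[zBest] / skull, hornWidth = horn[zBest],
      skullDiameter = skull, sliceIndex = as.integer(zBest))
}

#' Assign Evans-index tertile groups
#'
#' Rank-based split into three approximately equally sized groups (low,
#' middle, high EI); sizes differ by at most one, the larger groups come
#' first (ceil-then-floor, so 275 subjects split 92/92/91), and ties are
#' broken by stable input order into the lower group.
#'
#' @param EIs numeric vector of Evans indices, length `>= 3`.
#' @return A factor with levels `low`, `middle`, `high`.
#' @examples
#' table(assignEIGroups(runif(275)))
#' @export
assignEIGroups <- function(EIs) {
  n <- length(EIs)
  if (n < 3L) stop("need at least 3 subjects for a tertile split")
  ord <- order(EIs)              # radix order: stable under ties
  n1 <- ceiling(n / 3)
  n2 <- ceiling((n - n1) / 2)
  g <- character(n)
  g[ord[seq_len(n1)]] <- "low"
  g[ord[n1 + seq_len(n2)]] <- "middle"
  g[ord[(n1 + n2 + 1):n]] <- "high"
  factor(g, levels = c("low", "middle", "high"))
}
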