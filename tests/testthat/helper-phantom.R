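# Small-grid phantom spec for fast unit tests: the default anatomy on a
# 48 x 48 x 32 grid of 4.4 mm voxels (brain fits with >= 10 mm margins).
smallSpec <- function(...) {
  phantomSpec(gridShape = c(48L, 48L, 32L), ...)
}

# full noiseless quantification of one phantom: oracle VOIs, CSF mask,
# masked and unmasked SBR (mean of sides)
quantifyPhantom <- function(p, k = 1, voiMode = "oracle") {
  brain <- segmentBrain(p$volume)
  vois <- placeStriatalVOIs(p$volume, mode = voiMode, truth = p$truth,
                            brainMask = brain)
  fit <- csfMask(p$volume, vois, k = k)
  sm <- computeSBR(p$volume, vois, exclusion = fit@exclusionMask)
  su <- computeSBR(p$volume, vois, exclusion = NULL)
  list(masked = (sm$left@sbr + sm$right@sbr) / 2,
       unmasked = (su$left@sbr + su$right@sbr) / 2,
       fit = fit, vois = vois, maskedLR = sm, unmaskedLR = su)
}

# uniform-ellipsoid CountVolume in a zero background
uniformEllipsoidVolume <- function(value = 100, gridShape = c(48, 48, 32),
                                   voxel = 4.4, semiaxes = c(70, 85, 60)) {
  p <- buildPhantom(phantomSpec(gridShape = gridShape, voxelSize = voxel,
                                brainSemiaxes = semiaxes,
                                background = value, trueSBR = 0))
  p
}
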