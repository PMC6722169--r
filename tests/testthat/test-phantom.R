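test_that("zero specific binding gives a uniform brain", {
  p <- buildPhantom(smallSpec(trueSBR = 0, background = 100))
  inside <- p$volume@values[p$truth@brainMask]
  expect_true(all(inside == 100))
  expect_true(all(p$volume@values[!p$truth@brainMask] == 0))
})

test_that("striatal concentration is calibrated analytically from true SBR", {
  p <- buildPhantom(smallSpec(trueSBR = 4, background = 100))
  vact <- voiVolume(p$truth@striatumLeft, p$volume@voxelSize)
  expected <- 100 * (1 + 4 * 11.2 / vact)
  expect_equal(max(p$volume@values), expected)
  # voxelised striatal volume is close to nominal, so Cs is close to
  # Cb * (1 + SBR) = 500
  expect_equal(expected, 500, tolerance = 0.05)
})

test_that("noiseless Southampton bookkeeping reproduces true SBR", {
  for (sbr in c(1, 4)) {
    p <- buildPhantom(smallSpec(trueSBR = sbr))
    q <- quantifyPhantom(p)
    expect_equal(q$unmasked, sbr, tolerance = 1e-3)
    expect_equal(q$masked, sbr, tolerance = 1e-3)
  }
})

test_that("noise is seeded and reproducible", {
  a <- buildPhantom(smallSpec(noise = TRUE, seed = 11))
  b <- buildPhantom(smallSpec(noise = TRUE, seed = 11))
  c <- buildPhantom(smallSpec(noise = TRUE, seed = 12))
  expect_identical(a$volume@values, b$volume@values)
  expect_false(identical(a$volume@values, c$volume@values))
})

test_that("impossible geometry is rejected", {
  expect_error(buildPhantom(smallSpec(ventricleScale = 8)),
               "exit|outside|overlap")
  overlapping <- smallSpec()
  overlapping@striatumOffsets <- rbind(c(-2, 15, 5), c(2, 15, 5))
  expect_error(buildPhantom(overlapping), "overlap|intersect")
})

test_that("PSF blur matches a sampled separable Gaussian and conserves counts", {
  vol <- CountVolume(array(0, c(33, 33, 33)), 4.4)
  vol@values[17, 17, 17] <- 1000
  out <- applyPSF(vol, 8.8)
  # independent oracle: normalised 1-D sampled kernels, outer product
  sigma <- 8.8 / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma / 4.4)
  k1 <- dnorm((-r:r) * 4.4, 0, sigma); k1 <- k1 / sum(k1)
  idx <- 17 + (-r:r)
  expected <- 1000 * outer(outer(k1, k1), k1)
  expect_equal(out@values[idx, idx, idx], expected, tolerance = 1e-12)
  expect_equal(sum(out@values), 1000, tolerance = 1e-6)

  expect_identical(applyPSF(vol, 0)@values, vol@values)
  expect_error(applyPSF(vol, -1), ">= 0")
})

test_that("PSF blur leaves a uniform interior uniform", {
  p <- uniformEllipsoidVolume(100)
  out <- applyPSF(p$volume, 8.8)
  # voxels more than 3 FWHM inside the brain are untouched by the edge
  gs <- dim(p$volume@values)
  ax <- c(70, 85, 60) - 27
  ctr <- (gs - 1) / 2 * 4.4
  co <- lapply(1:3, function(i) ((seq_len(gs[i]) - 1) * 4.4 - ctr[i]) / ax[i])
  shrunk <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+") <= 1
  expect_equal(out@values[shrunk], rep(100, sum(shrunk)), tolerance = 1e-6)
})

test_that("Poisson noise has the right moments and determinism", {
  vol <- CountVolume(array(100, c(100, 100, 100)), 1)
  out <- applyPoissonNoise(vol, seed = 3)
  expect_equal(mean(out@values), 100, tolerance = 0.5 / 100)
  expect_true(abs(stats::var(as.vector(out@values)) - 100) < 2)
  expect_identical(out@values, applyPoissonNoise(vol, seed = 3)@values)

  zeros <- CountVolume(array(0, c(5, 5, 5)), 1)
  expect_true(all(applyPoissonNoise(zeros, 1)@values == 0))
  bad <- CountVolume(array(1, c(2, 2, 2)), 1)
  bad@values[1] <- -1
  expect_error(applyPoissonNoise(bad, 1), "non-negative")
})

test_that("simulated cohorts follow the group SBR laws", {
  cs <- cohortSpec(nPS = 200, nNPS = 200, seed = 5)
  co <- simulateCohort(cs)
  m <- co$manifest
  expect_equal(nrow(m), 400)
  ps <- m$true_sbr[m$label == "PS"]; nps <- m$true_sbr[m$label == "NPS"]
  expect_lt(abs(mean(ps) - 2.62), 3 * 1.02 / sqrt(200))
  expect_lt(abs(mean(nps) - 4.72), 3 * 1.18 / sqrt(200))
  expect_true(all(m$true_sbr > 0))

  # SD = 0 collapses to the group means
  cs0 <- cohortSpec(nPS = 5, nNPS = 5, sdSBR = c(PS = 0, NPS = 0), seed = 5)
  m0 <- simulateCohort(cs0)$manifest
  expect_true(all(m0$true_sbr[m0$label == "PS"] == 2.62))
  expect_true(all(m0$true_sbr[m0$label == "NPS"] == 4.72))

  # seeded reproducibility, and identity under subsetting
  co2 <- simulateCohort(cs)
  expect_identical(co$manifest, co2$manifest)
  csSmall <- cohortSpec(nPS = 10, nNPS = 0L + 1L, seed = 5)
  expect_identical(simulateCohort(csSmall)$manifest$true_sbr[1:10],
                   m$true_sbr[1:10])
})

test_that("true Evans index grows with ventricle scale", {
  eis <- vapply(c(0.4, 0.8, 1.4, 2), function(s)
    buildPhantom(smallSpec(ventricleScale = s))$truth@trueEI, numeric(1))
  expect_true(all(diff(eis) > 0))
  expect_true(all(eis > 0 & eis < 1))
  expect_true(is.na(buildPhantom(smallSpec(ventricleScale = 0))$truth@trueEI))
})

test_that("attenuation emulation suppresses deep counts monotonically", {
  p <- buildPhantom(smallSpec(trueSBR = 0, attenuation = TRUE))
  ctr <- dim(p$volume@values) %/% 2
  centre <- p$volume@values[ctr[1], ctr[2], ctr[3]]
  edge <- max(p$volume@values[, , 2])
  expect_lt(centre, 100)
  expect_lt(centre, max(p$volume@values))
  expect_true(all(p$volume@values <= 100 + 1e-9))
})
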