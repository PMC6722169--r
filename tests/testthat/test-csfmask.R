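# A reference mask wrapping a vector of values into a minimal volume, so
# the histogram/fit stages can be driven with controlled samples.
vectorVolume <- function(values) {
  n <- length(values)
  d <- c(n, 1L, 1L)
  list(vol = CountVolume(array(values, d), 1),
       mask = array(TRUE, d))
}

test_that("background histogram bins as specified", {
  vv <- vectorVolume(c(1, 1, 2, 3))
  h <- backgroundHistogram(vv$vol, vv$mask, nBins = 3)
  expect_equal(h$counts, c(2, 1, 1))      # [1,1.67) [1.67,2.33) [2.33,3]
  expect_equal(h$breaks[c(1, 4)], c(1, 3))

  const <- vectorVolume(rep(5, 50))
  hc <- backgroundHistogram(const$vol, const$mask, nBins = 10)
  expect_equal(sum(hc$counts > 0), 1L)
  expect_equal(sum(hc$counts), 50)

  expect_error(backgroundHistogram(vv$vol, vv$mask, nBins = 0), "at least 1")
  expect_error(backgroundHistogram(vv$vol, array(FALSE, c(4, 1, 1))), "empty")
})

test_that("Gaussian fit recovers normal background parameters", {
  set.seed(101)
  vv <- vectorVolume(rnorm(1e5, 100, 10))
  h <- backgroundHistogram(vv$vol, vv$mask, 100)
  fit <- fitBackgroundGaussian(h)
  expect_true(fit$fitOK)
  expect_gt(fit$xTilde, 99.5); expect_lt(fit$xTilde, 100.5)
  expect_gt(fit$sigma, 9.5); expect_lt(fit$sigma, 10.5)
})

test_that("Gaussian fit is exact on a noise-free sampled Gaussian", {
  x <- seq(50, 150, length.out = 101)
  counts <- 1000 * exp(-(x - 98)^2 / (2 * 7.5^2))
  h <- list(breaks = c(x - 0.5, max(x) + 0.5), counts = counts, mids = x,
            values = rep(x, times = pmax(1, round(counts))))
  fit <- fitBackgroundGaussian(h)
  expect_true(fit$fitOK)
  expect_equal(fit$xTilde, 98, tolerance = 1e-3)
  expect_equal(fit$sigma, 7.5, tolerance = 1e-3)
})

test_that("pathological histograms fall back to median/MAD", {
  # far-separated bimodal background: a single Gaussian cannot explain it
  set.seed(7)
  vals <- c(rnorm(3000, 10, 0.5), rnorm(3000, 1000, 0.5))
  vv <- vectorVolume(vals)
  h <- backgroundHistogram(vv$vol, vv$mask, 100)
  fit <- fitBackgroundGaussian(h)
  expect_false(fit$fitOK)
  med <- median(vals)
  expect_equal(fit$xTilde, med)
  expect_equal(fit$sigma, 1.4826 * median(abs(vals - med)))

  # fewer than three occupied bins: fallback as well
  two <- vectorVolume(rep(c(0, 100), each = 100))
  fit2 <- fitBackgroundGaussian(backgroundHistogram(two$vol, two$mask, 100))
  expect_false(fit2$fitOK)
})

test_that("threshold formula is median minus k sigma", {
  expect_equal(computeThreshold(100, 10, 1), 90)
  expect_equal(computeThreshold(100, 10, 0), 100)
  expect_equal(computeThreshold(50, 5, 2), 40)
  expect_error(computeThreshold(10, -1, 1), ">= 0")
  # monotonically decreasing in k
  ks <- seq(-1, 3, by = 0.5)
  expect_true(all(diff(computeThreshold(100, 10, ks)) < 0))
})

test_that("exclusion fraction of a pure Gaussian background matches the normal CDF", {
  set.seed(202)
  vv <- vectorVolume(rnorm(1e5, 100, 10))
  h <- backgroundHistogram(vv$vol, vv$mask, 100)
  fit <- fitBackgroundGaussian(h)
  for (k in c(1, 0)) {
    thr <- computeThreshold(fit$xTilde, fit$sigma, k)
    frac <- mean(vv$vol@values < thr)
    expect_lt(abs(frac - pnorm(-k)), 0.01)   # 15.87% at k = 1, 50% at k = 0
  }
})

test_that("exclusion mask handles thresholds and grows monotonically", {
  vv <- vectorVolume(c(5, 10, 20, 30))
  expect_equal(sum(buildExclusionMask(vv$vol, vv$mask, 5)), 0)     # ties kept
  expect_equal(sum(buildExclusionMask(vv$vol, vv$mask, 4)), 0)
  m1 <- buildExclusionMask(vv$vol, vv$mask, 15)
  m2 <- buildExclusionMask(vv$vol, vv$mask, 25)
  expect_true(all(m1 <= m2))
  expect_equal(sum(m1), 2); expect_equal(sum(m2), 3)
})

test_that("ventricle voxels are excluded by the CSF mask", {
  # noiseless: all zero-count ventricle voxels fall below the threshold
  p <- buildPhantom(smallSpec(trueSBR = 4, ventricleScale = 1.5))
  q <- quantifyPhantom(p)
  vent <- p$truth@ventricleMask
  expect_true(all(q$fit@exclusionMask[vent]))

  # Poisson noise at background SNR 5 (mean 25): sensitivity >= 95%
  pn <- buildPhantom(smallSpec(trueSBR = 4, ventricleScale = 1.5,
                               background = 25, noise = TRUE, seed = 9))
  qn <- quantifyPhantom(pn)
  sens <- mean(qn$fit@exclusionMask[pn$truth@ventricleMask])
  expect_gte(sens, 0.95)
})
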