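# The CSF-mask threshold: a Gaussian is fitted to the reference-background
# count histogram and voxels below (median - k * SD) are excluded from all
# downstream count bookkeeping. This is the step that removes the
# low-count CSF spaces (enlarged ventricles, atrophic sulci) that
# otherwise bias the Southampton SBR.

#' Histogram of reference-background voxel values
#'
#' Bins the voxel values inside the reference mask into `nBins` equal
#' bins over their observed range. Bins are half-open `[lo, hi)` with the
#' last bin closed. The raw values are kept alongside the bins so that
#' the robust median/MAD fallback of [fitBackgroundGaussian()] can use
#' them directly.
#'
#' @param vol a [CountVolume-class].
#' @param referenceMask non-empty logical array.
#' @param nBins number of bins (default 100).
#' @return A list with `breaks`, `counts`, `mids`, and `values`.
#' @export
backgroundHistogram <- function(vol, referenceMask, nBins = 100L) {
  stopifnot(is(vol, "CountVolume"))
  if (nBins < 1L) stop("'nBins' must be at least 1")
  if (!any(referenceMask)) stop("reference mask is empty")
  vals <- vol@values[referenceMask]
  lo <- min(vals); hi <- max(vals)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }   # constant region: one spanning bin
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = nBins)
  list(breaks = breaks, counts = as.numeric(counts),
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2, values = vals)
}

#' Fit a Gaussian to the background histogram
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2))` to the
#' (bin centre, bin count) pairs via Levenberg-Marquardt. For a Gaussian
#' the median equals the mean, so the fitted `mu` is reported as the
#' background median `xTilde`. The fit is rejected (and a robust
#' fallback used: sample median and `1.4826 * MAD`) when the optimiser
#' fails, fewer than three bins are occupied, the fitted centre leaves
#' the data range, the fitted width is non-finite, non-positive or wider
#' than the whole range, or the fit explains less than half the
#' histogram variance -- the typical signature of a strongly bimodal
#' background for which a single Gaussian is meaningless.
#'
#' @param h a histogram as returned by [backgroundHistogram()].
#' @return A list with `xTilde`, `sigma`, and `fitOK`.
#' @export
fitBackgroundGaussian <- function(h) {
  occ <- h$counts > 0
  fallback <- function() {
    med <- stats::median(h$values)
    list(xTilde = med,
         sigma = 1.4826 * stats::median(abs(h$values - med)),
         fitOK = FALSE)
  }
  if (sum(occ) < 3L) {
    if (length(unique(h$values)) < 2L && length(h$values) < 3L)
      stop("degenerate background: too few distinct values to characterise")
    return(fallback())
  }
  df <- data.frame(x = h$mids, y = h$counts)
  rng <- max(h$values) - min(h$values)
  w0 <- sum(df$y)
  mu0 <- sum(df$x * df$y) / w0
  s0 <- sqrt(max(sum((df$x - mu0)^2 * df$y) / w0, (rng / 100)^2))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = list(A = max(df$y), mu = mu0, s = s0),
                      lower = c(A = 0, mu = -Inf, s = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  co <- stats::coef(fit)
  resid <- df$y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((df$y - mean(df$y))^2)
  bad <- !all(is.finite(co)) || co[["s"]] <= 0 || co[["s"]] > rng ||
    co[["mu"]] < min(h$values) || co[["mu"]] > max(h$values) ||
    !is.finite(r2) || r2 < 0.5
  if (bad) return(fallback())
  list(xTilde = unname(co[["mu"]]), sigma = unname(co[["s"]]), fitOK = TRUE)
}

#' The CSF-mask threshold
#'
#' `threshold = xTilde - sigma * k`, with `k = 1.0` as the clinical
#' default.
#'
#' @param xTilde fitted background median (counts).
#' @param sigma fitted background SD (counts), `>= 0`.
#' @param k threshold coefficient.
#' @return The threshold in counts.
#' @examples
#' computeThreshold(100, 10, 1)  # 90
#' @export
computeThreshold <- function(xTilde, sigma, k = 1.0) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  xTilde - sigma * k
}

#' Mark sub-threshold voxels for exclusion
#'
#' Brain voxels with counts strictly below the threshold are excluded;
#' ties are retained (configurable convention, fixed here). The mask
#' applies to both the striatal VOIs and the reference region in all
#' downstream SBR bookkeeping.
#'
#' @param vol a [CountVolume-class].
#' @param brainMask logical array.
#' @param threshold finite threshold in counts.
#' @param strict exclude strictly-below (`TRUE`, default) or
#'   at-or-below (`FALSE`).
#' @return Logical exclusion mask, a subset of `brainMask`.
#' @export
buildExclusionMask <- function(vol, brainMask, threshold, strict = TRUE) {
  stopifnot(is(vol, "CountVolume"), is.finite(threshold))
  if (strict) brainMask & (vol@values < threshold)
  else        brainMask & (vol@values <= threshold)
}

#' Fit the CSF-mask threshold on a volume and VOI set
#'
#' Convenience wrapper running the full threshold stage: histogram of
#' the reference region (brain minus striatal VOIs, so striatal signal
#' cannot skew the Gaussian), Gaussian fit, threshold, exclusion mask
#' over the whole brain.
#'
#' @param vol a [CountVolume-class].
#' @param vois a [VOISet-class].
#' @param k threshold coefficient (default 1.0).
#' @param nBins histogram bins (default 100).
#' @param strict strict-inequality exclusion convention (default `TRUE`).
#' @return A [ThresholdFit-class].
#' @export
csfMask <- function(vol, vois, k = 1.0, nBins = 100L, strict = TRUE) {
  h <- backgroundHistogram(vol, vois@referenceMask, nBins)
  fit <- fitBackgroundGaussian(h)
  thr <- computeThreshold(fit$xTilde, fit$sigma, k)
  excl <- buildExclusionMask(vol, vois@brainMask, thr, strict)
  new("ThresholdFit", breaks = h$breaks, counts = h$counts,
      xTilde = fit$xTilde, sigma = fit$sigma, k = k, threshold = thr,
      fitOK = fit$fitOK, exclusionMask = excl)
}
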