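# Diagnostic-performance statistics. Orientation is fixed package-wide:
# parkinsonian syndromes (PS) show reduced striatal uptake, so a subject
# is PS-positive when its SBR falls BELOW the cutoff, and the AUC is the
# probability that a random NPS score exceeds a random PS score (ties
# counting one half). Under this orientation the AUC equals the
# Mann-Whitney U statistic divided by n_PS * n_NPS.

.checkLabels <- function(labels, positive) {
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present")
  pos
}

# DeLong structural components under the low-score-positive orientation.
# Returns the AUC and the per-subject placement vectors V10 (positives)
# and V01 (negatives), computed with midranks.
.delongComponents <- function(scores, pos) {
  x <- -scores[pos]          # transformed so larger means "more positive"
  y <- -scores[!pos]
  m <- length(x); n <- length(y)
  rAll <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (rAll[seq_len(m)] - rx) / n
  v01 <- 1 - (rAll[m + seq_len(n)] - ry) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

# sensitivity/specificity at each candidate cutoff (score < cutoff => PS call)
.rocCurve <- function(scores, pos) {
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) s else
    c(s[1] - (s[2] - s[1]) / 2,
      (s[-1] + s[-length(s)]) / 2,
      s[length(s)] + (s[length(s)] - s[length(s) - 1]) / 2)
  sens <- vapply(cand, function(c) mean(scores[pos] < c), numeric(1))
  spec <- vapply(cand, function(c) mean(scores[!pos] >= c), numeric(1))
  data.frame(cutoff = cand, sensitivity = sens, specificity = spec)
}

#' ROC analysis of a diagnostic score
#'
#' Midrank (Mann-Whitney) estimate of the area under the ROC curve, with
#' the DeLong structural-component variance and a 95 percent normal
#' confidence interval truncated to `[0, 1]`.
#'
#' @param scores numeric diagnostic scores (e.g. SBR values).
#' @param labels class labels; `positive` marks the disease class.
#' @param positive label of the low-score (disease) class, default
#'   `"PS"`.
#' @return An [ROCResult-class].
#' @examples
#' rocAUC(c(1, 2, 3, 4), c("PS", "PS", "NPS", "NPS"))  # AUC = 1
#' @export
rocAUC <- function(scores, labels, positive = "PS") {
  pos <- .checkLabels(labels, positive)
  dc <- .delongComponents(scores, pos)
  v <- if (dc$m > 1 && dc$n > 1)
    stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n else NA_real_
  ci <- if (is.na(v)) c(NA_real_, NA_real_) else
    pmin(pmax(dc$auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v), 0), 1)
  new("ROCResult", auc = dc$auc, varAUC = v, ci = ci,
      curve = .rocCurve(scores, pos), scores = as.numeric(scores),
      labels = as.character(labels), positive = positive)
}

#' DeLong test for two paired AUCs
#'
#' The same subjects are scored by two indices (e.g. CSF-masked and
#' unmasked SBR); the covariance of the two AUC estimates is obtained
#' from the DeLong structural components (midranks), and the AUC
#' difference is referred to a standard normal.
#'
#' @param scoresA,scoresB paired score vectors over the same subjects.
#' @param labels class labels shared by both score sets.
#' @param positive label of the low-score class.
#' @return An [ROCComparison-class] with `aucA`, `aucB`, `varDiff`, `z`,
#'   and the two-sided `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels, positive = "PS") {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("scoresA, scoresB and labels must have equal length (paired design)")
  pos <- .checkLabels(labels, positive)
  a <- .delongComponents(scoresA, pos)
  b <- .delongComponents(scoresB, pos)
  if (a$m < 2 || a$n < 2)
    stop("need at least two subjects per class for the DeLong variance")
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  dAUC <- a$auc - b$auc
  if (varDiff <= 0) {
    if (abs(dAUC) < 1e-12) {
      z <- 0; p <- 1
    } else {
      stop("degenerate DeLong variance with unequal AUCs")
    }
  } else {
    z <- dAUC / sqrt(varDiff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new("ROCComparison", aucA = a$auc, aucB = b$auc, varDiff = varDiff,
      z = z, p = p)
}

#' Optimal operating cutoff on a ROC curve
#'
#' Maximises Youden's J (sensitivity + specificity - 1) over the
#' candidate cutoffs (midpoints between adjacent distinct scores plus
#' one candidate below and above all scores), the standard reading of
#' "optimal cut-off determined from the ROC curve". Ties are broken
#' toward higher specificity, i.e. the lower cutoff under the
#' low-score-positive orientation. `criterion = "accuracy"` maximises
#' overall accuracy instead.
#'
#' @param roc an [ROCResult-class].
#' @param criterion `"youden"` (default) or `"accuracy"`.
#' @return The cutoff value; when all scores are equal the single
#'   midpoint is returned with attribute `degenerate = TRUE`.
#' @export
optimalCutoff <- function(roc, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  cv <- roc@curve
  if (length(unique(roc@scores)) == 1L) {
    out <- roc@scores[1]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  nPos <- sum(roc@labels == roc@positive)
  nNeg <- length(roc@labels) - nPos
  obj <- switch(criterion,
    youden = cv$sensitivity + cv$specificity - 1,
    accuracy = (cv$sensitivity * nPos + cv$specificity * nNeg) /
      (nPos + nNeg))
  best <- which(obj == max(obj))
  cv$cutoff[best[1]]   # candidates ascend; first = lowest = most specific
}

#' Confusion-matrix metrics at a cutoff
#'
#' Calls a subject PS-positive when its score is strictly below the
#' cutoff, tabulates TP/FN/TN/FP against the labels, and reports
#' sensitivity, specificity, PPV, NPV, and accuracy as percentages with
#' their defining fractions. Cells with zero denominator are undefined
#' (`NA`), not zero.
#'
#' @param scores numeric scores.
#' @param labels class labels.
#' @param cutoff finite operating cutoff.
#' @param positive label of the low-score class.
#' @return A [DiagnosticTable-class].
#' @export
diagnosticMetrics <- function(scores, labels, cutoff, positive = "PS") {
  stopifnot(is.finite(cutoff))
  labels <- as.character(labels)
  pos <- labels == positive
  call <- scores < cutoff
  TP <- sum(call & pos); FN <- sum(!call & pos)
  FP <- sum(call & !pos); TN <- sum(!call & !pos)
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  metrics <- data.frame(
    metric = c("sensitivity", "specificity", "PPV", "NPV", "accuracy"),
    percent = c(frac(TP, TP + FN), frac(TN, TN + FP), frac(TP, TP + FP),
                frac(TN, TN + FN), frac(TP + TN, TP + FN + TN + FP)),
    numerator = c(TP, TN, TP, TN, TP + TN),
    denominator = c(TP + FN, TN + FP, TP + FP, TN + FN, TP + FN + TN + FP),
    stringsAsFactors = FALSE)
  new("DiagnosticTable", cutoff = cutoff, TP = as.integer(TP),
      FN = as.integer(FN), TN = as.integer(TN), FP = as.integer(FP),
      metrics = metrics)
}

#' Mann-Whitney U test
#'
#' Midrank U statistic under the convention U = number of `(x, y)` pairs
#' with `x > y` (ties counting one half), so `mannWhitney(c(1, 2),
#' c(3, 4))` gives U = 0. When `nx * ny <= 400`, the p value is exact:
#' from the null U distribution when there are no ties, or by full
#' enumeration of group assignments when there are ties and enumeration
#' is feasible. Otherwise a normal approximation with tie-corrected
#' variance is used (no continuity correction).
#'
#' @param x,y non-empty numeric samples.
#' @return A list with `U`, `p`, and `method`.
#' @export
mannWhitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  mu <- nx * ny / 2

  if (nx * ny <= 400 && !ties) {
    pLo <- stats::pwilcox(U, nx, ny)
    pHi <- 1 - stats::pwilcox(U - 1, nx, ny)
    return(list(U = U, p = min(1, 2 * min(pLo, pHi)), method = "exact"))
  }
  if (nx * ny <= 400 && ties && choose(nx + ny, nx) <= 1e5) {
    idx <- utils::combn(nx + ny, nx)
    all <- c(x, y)
    ra <- rank(all, ties.method = "average")
    Us <- colSums(matrix(ra[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "enumeration"))
  }
  N <- nx + ny
  tab <- table(c(x, y))
  tieTerm <- sum(tab^3 - tab) / (N * (N - 1))
  v <- nx * ny / 12 * ((N + 1) - tieTerm)
  if (v <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu) / sqrt(v)
  list(U = U, p = 2 * stats::pnorm(-abs(z)), method = "normal")
}

#' Evans-index-stratified comparison of masked and unmasked AUCs
#'
#' Assigns EI tertiles with [assignEIGroups()], then runs the paired
#' DeLong test of the CSF-masked versus unmasked SBR overall and within
#' each tertile. A stratum missing one of the diagnostic classes (or too
#' small for the DeLong variance) is flagged and reported as `NA`
#' without aborting the others.
#'
#' @param records data.frame with columns `label`, `sbr_masked`,
#'   `sbr_unmasked`, and the EI column named by `eiCol`.
#' @param eiCol name of the Evans-index column (default `"ei"`).
#' @return A data.frame with one row per stratum (`overall`, `low`,
#'   `middle`, `high`): group sizes, both AUCs, the AUC difference,
#'   `z`, `p`, and an `ok` flag.
#' @export
eiStratifiedComparison <- function(records, eiCol = "ei") {
  need <- c("label", "sbr_masked", "sbr_unmasked", eiCol)
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  ok <- stats::complete.cases(records[, need])
  records <- records[ok, , drop = FALSE]
  grp <- assignEIGroups(records[[eiCol]])

  oneStratum <- function(sel, name) {
    sub <- records[sel, , drop = FALSE]
    nPS <- sum(sub$label == "PS"); nNPS <- sum(sub$label == "NPS")
    cmp <- tryCatch(
      delongTest(sub$sbr_masked, sub$sbr_unmasked, sub$label),
      error = function(e) NULL)
    if (is.null(cmp)) {
      data.frame(stratum = name, n = nrow(sub), n_ps = nPS, n_nps = nNPS,
                 auc_masked = NA_real_, auc_unmasked = NA_real_,
                 auc_diff = NA_real_, z = NA_real_, p = NA_real_,
                 ok = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(stratum = name, n = nrow(sub), n_ps = nPS, n_nps = nNPS,
                 auc_masked = cmp@aucA, auc_unmasked = cmp@aucB,
                 auc_diff = cmp@aucA - cmp@aucB, z = cmp@z, p = cmp@p,
                 ok = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(
    oneStratum(rep(TRUE, nrow(records)), "overall"),
    oneStratum(grp == "low", "low"),
    oneStratum(grp == "middle", "middle"),
    oneStratum(grp == "high", "high"))
  rownames(out) <- NULL
  out
}
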