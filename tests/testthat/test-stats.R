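test_that("AUC handles separation, overlap, and ties", {
  expect_equal(rocAUC(c(1, 2, 3, 4), c("PS", "PS", "NPS", "NPS"))@auc, 1)
  expect_equal(rocAUC(c(1, 3, 2, 4), c("PS", "PS", "NPS", "NPS"))@auc, 0.75)
  expect_equal(rocAUC(c(1, 2, 1, 2), c("PS", "PS", "NPS", "NPS"))@auc, 0.5)
  expect_error(rocAUC(1:4, rep("PS", 4)), "both classes")
})

test_that("AUC equals the Mann-Whitney U over the pair count, exactly", {
  set.seed(44)
  for (i in 1:100) {
    nps <- sample(3:20, 1); nnps <- sample(3:20, 1)
    # integer scores force plenty of ties
    sPS <- sample(1:8, nps, replace = TRUE)
    sNPS <- sample(1:8, nnps, replace = TRUE)
    auc <- rocAUC(c(sPS, sNPS), rep(c("PS", "NPS"), c(nps, nnps)))@auc
    U <- mannWhitney(sNPS, sPS)$U   # pairs with NPS score above PS score
    expect_equal(auc, U / (nps * nnps), tolerance = 1e-14)
  }
})

test_that("DeLong test is null on identical scores and antisymmetric", {
  set.seed(9)
  lab <- rep(c("PS", "NPS"), each = 15)
  a <- c(rnorm(15, 2.6, 1), rnorm(15, 4.7, 1))
  b <- a + rnorm(30, 0, 0.4)
  same <- delongTest(a, a, lab)
  expect_equal(same@z, 0); expect_equal(same@p, 1)
  ab <- delongTest(a, b, lab); ba <- delongTest(b, a, lab)
  expect_equal(ab@z, -ba@z)
  expect_equal(ab@p, ba@p)
  expect_error(delongTest(a, b[-1], lab), "equal length")
})

test_that("DeLong agrees with the pROC reference implementation", {
  set.seed(10)
  lab <- rep(c("PS", "NPS"), c(20, 25))
  a <- c(rnorm(20, 2.6, 1.0), rnorm(25, 4.7, 1.2))
  b <- 0.8 * a + rnorm(45, 0, 0.8)
  mine <- delongTest(a, b, lab)
  ra <- pROC::roc(lab, a, levels = c("PS", "NPS"), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(lab, b, levels = c("PS", "NPS"), direction = "<",
                  quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(mine@aucA, as.numeric(ra$auc))
  expect_equal(abs(mine@z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
  expect_equal(mine@p, as.numeric(ref$p.value), tolerance = 1e-10)

  # single-AUC variance close to the Hanley-style closed form
  roc1 <- rocAUC(a, lab)
  A <- roc1@auc; m <- 20; n <- 25
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  hanley <- (A * (1 - A) + (m - 1) * (q1 - A^2) + (n - 1) * (q2 - A^2)) /
    (m * n)
  expect_lt(abs(roc1@varAUC - hanley) / hanley, 0.2)
})

test_that("DeLong p is close to a subject bootstrap at n = 40", {
  set.seed(11)
  lab <- rep(c("PS", "NPS"), each = 20)
  truth <- c(rnorm(20, 2.6, 1.0), rnorm(20, 4.7, 1.2))
  a <- truth + rnorm(40, 0, 0.5)
  b <- truth + rnorm(40, 0, 0.9)
  mine <- delongTest(a, b, lab)

  aucOf <- function(scores, pos) {
    r <- rank(scores)
    (sum(r[!pos]) - sum(!pos) * (sum(!pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  pos <- lab == "PS"
  set.seed(12)
  diffs <- replicate(10000, {
    i <- c(sample(which(pos), replace = TRUE),
           sample(which(!pos), replace = TRUE))
    aucOf(a[i], pos[i]) - aucOf(b[i], pos[i])
  })
  zBoot <- (mine@aucA - mine@aucB) / sd(diffs)
  pBoot <- 2 * pnorm(-abs(zBoot))
  expect_lt(abs(mine@p - pBoot), 0.02)
})

test_that("optimal cutoff maximises Youden's J", {
  roc <- rocAUC(c(1, 2, 3, 4), c("PS", "PS", "NPS", "NPS"))
  expect_equal(as.numeric(optimalCutoff(roc)), 2.5)

  rocD <- rocAUC(rep(2, 6), rep(c("PS", "NPS"), 3))
  cd <- optimalCutoff(rocD)
  expect_true(isTRUE(attr(cd, "degenerate")))

  # brute-force oracle over all candidate cutoffs
  set.seed(13)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    sc <- round(runif(n, 0, 10), 1)
    lb <- sample(c("PS", "NPS"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    roci <- rocAUC(sc, lb)
    got <- as.numeric(optimalCutoff(roci))
    s <- sort(unique(sc))
    cand <- c(s[1] - 0.05, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 0.05)
    J <- vapply(cand, function(cc)
      mean(sc[lb == "PS"] < cc) + mean(sc[lb == "NPS"] >= cc) - 1, numeric(1))
    best <- cand[which(J == max(J))]
    specAt <- function(cc) mean(sc[lb == "NPS"] >= cc)
    expect_equal(mean(sc[lb == "PS"] < got) + specAt(got) - 1,
                 max(J), tolerance = 1e-12)
    # tie-break toward higher specificity
    expect_equal(specAt(got), max(vapply(best, specAt, numeric(1))))
  }
})

test_that("diagnostic metrics reproduce the printed worked example", {
  # scores constructed to realise TP=144 FN=19 TN=128 FP=30 at cutoff 0
  scores <- c(rep(-1, 144), rep(1, 19), rep(1, 128), rep(-1, 30))
  labels <- rep(c("PS", "NPS"), c(163, 158))
  dt <- diagnosticMetrics(scores, labels, cutoff = 0)
  m <- setNames(dt@metrics$percent, dt@metrics$metric)
  expect_equal(round(m[["sensitivity"]], 1), 88.3)
  expect_equal(round(m[["specificity"]], 1), 81.0)
  expect_equal(round(m[["PPV"]], 1), 82.8)
  expect_equal(round(m[["NPV"]], 1), 87.1)
  expect_equal(round(m[["accuracy"]], 1), 84.7)
  # integer bookkeeping: sensitivity * (TP+FN) = TP exactly
  expect_equal(m[["sensitivity"]] / 100 * (dt@TP + dt@FN), dt@TP)

  # degenerate cells are undefined, not zero
  d0 <- diagnosticMetrics(c(1, 2), c("PS", "NPS"), cutoff = 0)
  expect_true(is.na(d0@metrics$percent[d0@metrics$metric == "PPV"]))
})

test_that("Mann-Whitney U conventions and exactness", {
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)                      # U counts pairs with x > y
  expect_equal(mannWhitney(c(3, 4), c(1, 2))$U, 4)

  same <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  # exact p equals the full permutation enumeration (no ties, 8 vs 8)
  set.seed(14)
  x <- rnorm(8); y <- rnorm(8, 0.8)
  mine <- mannWhitney(x, y)
  expect_equal(mine$method, "exact")
  all <- c(x, y); mu <- 32
  Us <- apply(combn(16, 8), 2, function(ii) {
    r <- rank(all)
    sum(r[ii]) - 36
  })
  pPerm <- mean(abs(Us - mu) >= abs(mine$U - mu) - 1e-9)
  expect_equal(mine$p, pPerm)

  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("EI stratification compares masked and unmasked indices per stratum", {
  set.seed(15)
  n <- 120
  label <- rep(c("PS", "NPS"), each = n / 2)
  truth <- ifelse(label == "PS", rnorm(n, 2.62, 1.02), rnorm(n, 4.72, 1.18))
  ei <- runif(n, 0.18, 0.40)                    # independent of label
  bias <- 8 * pmax(ei - 0.18, 0)^2              # dilatation-driven inflation
  rec <- data.frame(label = label,
                    sbr_masked = truth + rnorm(n, 0, 0.2),
                    sbr_unmasked = truth + bias + rnorm(n, 0, 0.2) +
                      bias * rnorm(n, 0, 1),
                    ei = ei)
  out <- eiStratifiedComparison(rec)
  expect_equal(out$stratum, c("overall", "low", "middle", "high"))
  expect_true(all(out$ok))
  expect_equal(sum(out$n[-1]), n)

  # no exclusion difference: identical indices give a null comparison
  rec0 <- rec; rec0$sbr_unmasked <- rec0$sbr_masked
  out0 <- eiStratifiedComparison(rec0)
  expect_true(all(out0$auc_diff == 0))
  expect_true(all(out0$p == 1))

  # a stratum missing one class is flagged, the others still computed
  rec2 <- rec
  rec2$label[rec2$ei <= sort(ei)[40]] <- "PS"
  out2 <- eiStratifiedComparison(rec2)
  expect_false(out2$ok[out2$stratum == "low"])
  expect_true(out2$ok[out2$stratum == "high"])
})
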