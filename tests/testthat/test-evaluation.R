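# Evaluation panel: confusion counting, metric arithmetic, ROC/AUC,
# DeLong variance and tests, Mann-Whitney U, confusion reconstruction.

test_that("confusionCounts thresholds against the enumeration oracle", {
  expect_equal(confusionCounts(c(0.9, 0.8, 0.1, 0.2),
                               c("pCR", "pCR", "non-pCR", "non-pCR")),
               c(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  # threshold 0 predicts everything positive
  cc0 <- confusionCounts(runif(10), rep(c("pCR", "non-pCR"), 5), 0)
  expect_equal(cc0[["tn"]], 0L)
  expect_equal(cc0[["fn"]], 0L)
  set.seed(1)
  for (rep in 1:10) {
    sc <- round(runif(20), 2)
    lb <- sample(c("pCR", "non-pCR"), 20, replace = TRUE)
    th <- runif(1)
    cc <- confusionCounts(sc, lb, th)
    brute <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (i in 1:20) {
      pred <- sc[i] >= th; pos <- lb[i] == "pCR"
      key <- if (pred && pos) "tp" else if (pred) "fp"
             else if (pos) "fn" else "tn"
      brute[key] <- brute[key] + 1L
    }
    expect_equal(cc, brute)
  }
  expect_error(confusionCounts(numeric(0), character(0)), "empty")
})

test_that("metric panel reproduces hand-worked confusion arithmetic", {
  m <- classificationMetrics(c(tp = 68, fp = 17, fn = 7, tn = 100))
  expect_equal(m$f1, 0.850, tolerance = 5e-4)
  expect_equal(m$accuracy, 0.875)
  expect_equal(m$sensitivity, 68 / 75)
  expect_equal(m$ppv, 0.800)
  expect_equal(m$npv, 100 / 107)

  perfect <- classificationMetrics(c(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv", "f1")]) == 1))

  ones <- classificationMetrics(c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(ones$accuracy, 0.5)
  expect_equal(ones$sensitivity, 0.5)
  expect_equal(ones$ppv, 0.5)
  expect_equal(ones$f1, 0.5)  # 2TP/(2TP+FP+FN) = 2/4

  # division-by-zero cells are NA, not 0
  degen <- classificationMetrics(c(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(is.na(degen$ppv))
  expect_equal(degen$specificity, 1)
})

test_that("F1 is the harmonic mean of PPV and sensitivity where defined", {
  set.seed(2)
  for (rep in 1:50) {
    cc <- c(tp = sample(0:30, 1), fp = sample(0:30, 1),
            fn = sample(0:30, 1), tn = sample(0:30, 1))
    m <- classificationMetrics(cc)
    if (!is.na(m$ppv) && !is.na(m$sensitivity) && !is.na(m$f1) &&
        (m$ppv + m$sensitivity) > 0) {
      expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC equals the exhaustive pair count and the U statistic", {
  expect_equal(rocCurve(c(0.9, 0.8, 0.2, 0.1),
                        c("pCR", "pCR", "non-pCR", "non-pCR"))$auc, 1)
  expect_equal(rocCurve(rep(0.5, 8),
                        rep(c("pCR", "non-pCR"), 4))$auc, 0.5)
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(6:20, 1)
    sc <- round(runif(n), 1)  # coarse scores force ties
    lb <- c(rep("pCR", 3), sample(c("pCR", "non-pCR"), n - 3, replace = TRUE,
                                  prob = c(0.4, 0.6)))
    lb <- c(lb[-(1:2)], "non-pCR", "non-pCR")
    roc <- rocCurve(sc, lb)
    expect_equal(roc$auc, brutePairAuc(sc, lb), tolerance = 1e-12)
    # AUC-U identity
    u <- mannWhitneyU(sc[lb == "pCR"], sc[lb == "non-pCR"])$U
    nP <- sum(lb == "pCR"); nN <- sum(lb == "non-pCR")
    expect_equal(roc$auc, u / (nP * nN), tolerance = 1e-12)
    # curve sanity: monotone from (0,0) to (1,1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(tail(roc$fpr, 1), tail(roc$tpr, 1)), c(1, 1))
  }
})

test_that("metrics are invariant under strictly increasing score transforms", {
  set.seed(4)
  sc <- runif(30)
  lb <- sample(c("pCR", "non-pCR"), 30, replace = TRUE)
  lb[1:2] <- c("pCR", "non-pCR")
  mono <- function(x) 1 / (1 + exp(-(3 * x - 1)))  # increasing map
  expect_equal(rocCurve(mono(sc), lb)$auc, rocCurve(sc, lb)$auc)
  expect_equal(confusionCounts(mono(sc), lb, mono(0.5)),
               confusionCounts(sc, lb, 0.5))
})

test_that("DeLong interval collapses for perfect separation and tracks the bootstrap", {
  ci <- delongCi(c(0.9, 0.95, 0.85, 0.2, 0.1, 0.15),
                 c("pCR", "pCR", "pCR", "non-pCR", "non-pCR", "non-pCR"))
  expect_equal(ci$auc, 1)
  expect_equal(ci$se, 0)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))

  # structural-components variance within 20% of a 2000-rep bootstrap
  set.seed(5)
  sc <- c(rnorm(30, 1), rnorm(30, 0))
  lb <- rep(c("pCR", "non-pCR"), each = 30)
  v <- delongCi(sc, lb)$se^2
  boots <- vapply(1:2000, function(i) {
    ip <- sample(30, replace = TRUE); iq <- sample(30, replace = TRUE)
    brutePairAucFast <- function(x, y) {
      r <- rank(c(x, y))
      (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
        (length(x) * length(y))
    }
    brutePairAucFast(sc[1:30][ip], sc[31:60][iq])
  }, numeric(1))
  expect_lt(abs(v - var(boots)) / var(boots), 0.2)
})

test_that("the paired DeLong test is antisymmetric and null at equality", {
  set.seed(6)
  lb <- rep(c("pCR", "non-pCR"), each = 15)
  a <- rnorm(30, ifelse(lb == "pCR", 0.8, 0.2), 0.4)
  b <- 0.7 * a + rnorm(30, 0, 0.2)
  same <- delongTest(a, a, lb)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delongTest(a, b, lb)
  ba <- delongTest(b, a, lb)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_error(delongTest(a[1:10], b, lb), "same items")
})

test_that("Mann-Whitney matches exact enumeration and the stats reference", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2/20 arrangements as extreme
  # identical samples are maximally null
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # all 3+3 splits of six distinct values agree with full enumeration
  vals <- c(1.2, 2.7, 3.1, 4.8, 5.5, 6.9)
  for (ix in utils::combn(6, 3, simplify = FALSE)) {
    x <- vals[ix]; y <- vals[-ix]
    got <- mannWhitneyU(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation vs the reference implementation
  set.seed(7)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  got <- mannWhitneyU(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_error(mannWhitneyU(numeric(0), 1), "nonempty")
})

test_that("confusion reconstruction inverts printed panels honestly", {
  rec <- reconstructConfusion(87.50, 90.67, 75, 117)
  expect_true(rec$unique)
  expect_equal(rec$counts, c(tp = 68, fp = 17, fn = 7, tn = 100))
  perfect <- reconstructConfusion(100, 100, 10, 10)
  expect_equal(perfect$counts, c(tp = 10, fp = 0, fn = 0, tn = 10))
  # inconsistent panels report failure rather than guessing
  none <- reconstructConfusion(87.50, 90.00, 75, 117)
  expect_false(none$unique)
  expect_equal(nrow(none$matches), 0L)
  # coarse rounding yields an honest multiplicity report
  multi <- reconstructConfusion(80, 80, 200, 200, decimals = 0L)
  expect_false(multi$unique)
  expect_gt(nrow(multi$matches), 1L)
})

test_that("reconstruction is a round-trip inverse of the metric panel", {
  set.seed(8)
  for (rep in 1:500) {
    nP <- sample(5:120, 1); nN <- sample(5:150, 1)
    tp <- sample(0:nP, 1); tn <- sample(0:nN, 1)
    m <- classificationMetrics(c(tp = tp, fp = nN - tn, fn = nP - tp,
                                 tn = tn))
    rec <- reconstructConfusion(100 * m$accuracy, 100 * m$sensitivity,
                                nP, nN, decimals = 6L)
    expect_true(rec$unique)
    expect_equal(rec$counts[["tp"]], tp)
    expect_equal(rec$counts[["tn"]], tn)
  }
})

test_that("metricsPanel degrades to a CI-free AUC on tiny class counts", {
  out <- metricsPanel(c(0.9, 0.4, 0.2), c("pCR", "non-pCR", "non-pCR"))
  expect_equal(out$auc, 1)
  expect_true(is.na(out$aucLower) && is.na(out$aucUpper))
})

test_that("patient-level aggregation averages pair scores", {
  preds <- data.frame(patient_id = c("A", "A", "B"),
                      frame_index = c(0L, 1L, 0L),
                      label = c("pCR", "pCR", "non-pCR"),
                      score = c(0.8, 0.6, 0.3))
  agg <- aggregateByPatient(preds)
  expect_equal(agg$score[agg$patient_id == "A"], 0.7)
  expect_equal(agg$n_pairs, c(2L, 1L))
})
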