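# Evaluation panel: confusion metrics, ROC/AUC, DeLong variance and CIs,
# paired DeLong test, Mann-Whitney U, and the confusion-reconstruction
# utility. The positive class is pCR throughout; the evaluation unit is the
# image pair (a patient-level aggregate is available separately).

.posLogical <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("pCR", "non-pCR"))) {
      stop("labels must be 'pCR' or 'non-pCR'", call. = FALSE)
    }
    return(labels == "pCR")
  }
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  stop("labels must be character pCR/non-pCR, logical, or 0/1", call. = FALSE)
}

#' Score a manifest split with a trained model
#'
#' One pCR probability per image pair, deterministic in eval mode.
#'
#' @param model a trained [DBNNModel-class].
#' @param manifest a manifest `data.frame`.
#' @param split split to score (default `"test"`).
#' @param baseDir optional base directory for relative paths.
#' @param stage `"both"` (dual-branch), `"pre"` or `"post"`
#'   (single-branch).
#' @return A `data.frame` with columns `patient_id`, `frame_index`, `label`,
#'   `score` (pCR probability).
#' @export
predictPairs <- function(model, manifest, split = "test", baseDir = NULL,
                         stage = c("both", "pre", "post")) {
  stopifnot(is(model, "DBNNModel"))
  stage <- match.arg(stage)
  .checkStage(model, stage)
  samples <- loadPairedSamples(manifest, split, baseDir)
  model <- evalMode(model)
  side <- model@config@inputSize
  scores <- numeric(length(samples))
  for (start in seq(1L, length(samples), by = 64L)) {
    idx <- start:min(start + 63L, length(samples))
    bi <- .batchInputs(samples[idx], side, stage)
    fwd <- .forwardInternal(model, bi$inputs, train = FALSE)
    scores[idx] <- fwd$probs[, "pCR"]
  }
  data.frame(
    patient_id = vapply(samples, `[[`, "", "patient_id"),
    frame_index = vapply(samples, `[[`, 0L, "frame_index"),
    label = vapply(samples, `[[`, "", "label"),
    score = scores, stringsAsFactors = FALSE)
}

#' Aggregate pair scores to the patient level
#'
#' Mean pCR score per patient (majority-style aggregate); not the default
#' evaluation unit.
#'
#' @param predictions output of [predictPairs()].
#' @return A `data.frame` with one row per patient.
#' @export
aggregateByPatient <- function(predictions) {
  sp <- split(predictions, predictions$patient_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(patient_id = d$patient_id[1], label = d$label[1],
               score = mean(d$score), n_pairs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Confusion counts at a threshold
#'
#' Positive class is pCR; a pair is predicted positive iff
#' `score >= threshold`.
#'
#' @param scores numeric pCR probabilities.
#' @param labels pair labels (`"pCR"`/`"non-pCR"`, logical, or 0/1).
#' @param threshold decision threshold (default 0.5).
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  pos <- .posLogical(labels)
  pred <- scores >= threshold
  c(tp = sum(pred & pos), fp = sum(pred & !pos),
    fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

#' Confusion-derived metric panel
#'
#' Accuracy, sensitivity (pCR recall), specificity, PPV, NPV and
#' F1 = 2TP / (2TP + FP + FN). Cells whose denominator is zero are reported
#' as `NA` (undefined), never silently as 0.
#'
#' @param counts named vector with `tp`, `fp`, `fn`, `tn` (see
#'   [confusionCounts()]).
#' @return A list with the six metrics plus `nPos`, `nNeg`.
#' @examples
#' classificationMetrics(c(tp = 68, fp = 17, fn = 7, tn = 100))$f1  # 0.85
#' @export
classificationMetrics <- function(counts) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts))) {
    stop("counts must carry tp, fp, fn, tn", call. = FALSE)
  }
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be >= 0", call. = FALSE)
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = sdiv(tp + tn, tp + fp + fn + tn),
       sensitivity = sdiv(tp, tp + fn),
       specificity = sdiv(tn, tn + fp),
       ppv = sdiv(tp, tp + fp),
       npv = sdiv(tn, tn + fn),
       f1 = sdiv(2 * tp, 2 * tp + fp + fn),
       nPos = tp + fn, nNeg = tn + fp)
}

# AUC as the Mann-Whitney pair statistic (midranks handle ties):
# (#concordant + 0.5 #tied) / (nPos * nNeg)
.aucStatistic <- function(scores, labels) {
  pos <- .posLogical(labels)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve and AUC
#'
#' The AUC equals the normalized Mann-Whitney pair statistic
#' `(#concordant + 0.5 #ties) / (nPos * nNeg)`; the curve is a threshold
#' sweep over the observed scores (thresholds decreasing, `fpr`/`tpr`
#' nondecreasing from 0 to 1).
#'
#' @param scores numeric pCR probabilities.
#' @param labels pair labels.
#' @return A list with `auc`, `thresholds`, `fpr`, `tpr`.
#' @export
rocCurve <- function(scores, labels) {
  pos <- .posLogical(labels)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  lev <- sort(unique(scores), decreasing = TRUE)
  f <- factor(scores, levels = lev)
  posAt <- tapply(pos, f, sum)
  negAt <- tapply(!pos, f, sum)
  list(auc = .aucStatistic(scores, labels),
       thresholds = c(Inf, lev),
       fpr = as.numeric(c(0, cumsum(negAt) / n)),
       tpr = as.numeric(c(0, cumsum(posAt) / m)))
}

# DeLong structural components: V10[i] = mean_j psi(x_i, y_j), V01[j]
.delongComponents <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(V10 = rowMeans(psi), V01 = colMeans(psi), auc = mean(psi),
       m = m, n = n)
}

#' DeLong confidence interval for an AUC
#'
#' Nonparametric structural-components variance with a normal-approximation
#' interval, clipped to `[0, 1]`. A perfectly separating score vector has
#' zero variance and interval `[1, 1]`.
#'
#' @param scores numeric pCR probabilities.
#' @param labels pair labels (>= 2 per class).
#' @param level confidence level (default 0.95).
#' @return A list with `auc`, `lower`, `upper`, `se`.
#' @export
delongCi <- function(scores, labels, level = 0.95) {
  pos <- .posLogical(labels)
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("DeLong CI needs at least 2 observations per class", call. = FALSE)
  }
  dc <- .delongComponents(scores, pos)
  v <- var(dc$V10) / dc$m + var(dc$V01) / dc$n
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = dc$auc, lower = max(0, dc$auc - z * se),
       upper = min(1, dc$auc + z * se), se = se)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two score vectors computed on the SAME items via the
#' covariance-corrected z-test. Swapping the score vectors negates `z`;
#' identical vectors give `z = 0`, `p = 1`.
#'
#' @param scoresA,scoresB score vectors of two models on the same items.
#' @param labels the shared labels.
#' @return A list with `z`, `p` (two-sided), `aucA`, `aucB`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels)) {
    stop("scoresA, scoresB and labels must share one length (same items)",
         call. = FALSE)
  }
  pos <- .posLogical(labels)
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("paired DeLong test needs at least 2 observations per class",
         call. = FALSE)
  }
  a <- .delongComponents(scoresA, pos)
  b <- .delongComponents(scoresB, pos)
  v <- (var(a$V10) + var(b$V10) - 2 * cov(a$V10, b$V10)) / a$m +
    (var(a$V01) + var(b$V01) - 2 * cov(a$V01, b$V01)) / a$n
  d <- a$auc - b$auc
  if (v <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(z = z, p = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)),
       aucA = a$auc, aucB = b$auc)
}

#' Mann-Whitney U test
#'
#' Exact enumeration of all `choose(m + n, m)` group assignments when both
#' samples have at most 8 observations; otherwise the normal approximation
#' with tie-corrected variance (no continuity correction). U counts pairs
#' where x exceeds y (ties count 0.5).
#'
#' @param x,y nonempty numeric samples.
#' @return A list with `U`, `p` (two-sided), `method`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  uStat <- function(isX) {
    r <- rank(pooled)
    sum(r[isX]) - sum(isX) * (sum(isX) + 1) / 2
  }
  obs <- uStat(seq_along(pooled) <= m)
  centre <- m * n / 2
  if (m <= 8L && n <= 8L) {
    combs <- utils::combn(m + n, m)
    r <- rank(pooled)
    dev <- abs(apply(combs, 2, function(id) sum(r[id])) -
                 m * (m + 1) / 2 - centre)
    p <- mean(dev >= abs(obs - centre) - 1e-9)
    return(list(U = obs, p = p, method = "exact enumeration"))
  }
  M <- m + n
  ties <- table(pooled)
  tieAdj <- sum(ties^3 - ties) / (M * (M - 1))
  v <- m * n / 12 * ((M + 1) - tieAdj)
  if (v <= 0) return(list(U = obs, p = 1, method = "normal approximation"))
  z <- (obs - centre) / sqrt(v)
  list(U = obs, p = 2 * pnorm(-abs(z)), method = "normal approximation")
}

#' Reconstruct confusion counts from a printed metric panel
#'
#' Exhaustively searches integer `tp` in `0..nPos` and `tn` in `0..nNeg`
#' for counts whose rounded accuracy and sensitivity match the printed
#' values (half-away-from-zero rounding at `decimals` places, percent
#' scale). Returns the unique solution, or reports multiplicity /
#' inconsistency - never a silent guess.
#'
#' @param accuracy,sensitivity printed values on the percent scale
#'   (e.g. 87.50).
#' @param nPos,nNeg class sizes of the evaluated set.
#' @param decimals printed precision (default 2).
#' @return An object of class `confusionReconstruction`: a list with
#'   `counts` (named vector, or `NULL` if not unique), `matches` (a
#'   `data.frame` of all solutions) and `unique`.
#' @examples
#' reconstructConfusion(87.50, 90.67, 75, 117)$counts
#' @export
reconstructConfusion <- function(accuracy, sensitivity, nPos, nNeg,
                                 decimals = 2L) {
  stopifnot(.isCount(nPos), .isCount(nNeg), nPos >= 1, nNeg >= 1)
  tpCand <- which(.roundHalfUp(100 * (0:nPos) / nPos, decimals) ==
                    .roundHalfUp(sensitivity, decimals)) - 1L
  total <- nPos + nNeg
  sols <- list()
  for (tp in tpCand) {
    tns <- 0:nNeg
    accs <- .roundHalfUp(100 * (tp + tns) / total, decimals)
    hit <- tns[accs == .roundHalfUp(accuracy, decimals)]
    for (tn in hit) {
      sols[[length(sols) + 1L]] <- data.frame(tp = tp, tn = tn,
                                              fp = nNeg - tn, fn = nPos - tp)
    }
  }
  matches <- if (length(sols)) do.call(rbind, sols) else
    data.frame(tp = integer(0), tn = integer(0), fp = integer(0),
               fn = integer(0))
  uniq <- nrow(matches) == 1L
  counts <- NULL
  if (uniq) {
    counts <- c(tp = matches$tp[1], fp = matches$fp[1], fn = matches$fn[1],
                tn = matches$tn[1])
  }
  structure(list(counts = counts, matches = matches, unique = uniq),
            class = "confusionReconstruction")
}

#' @export
print.confusionReconstruction <- function(x, ...) {
  if (x$unique) {
    cat("Unique confusion reconstruction:\n")
    print(x$counts)
  } else if (nrow(x$matches) == 0L) {
    cat("Inconsistent panel: no integer confusion counts reproduce the",
        "printed values.\n")
  } else {
    cat(sprintf("Ambiguous panel: %d candidate count sets.\n",
                nrow(x$matches)))
    print(x$matches)
  }
  invisible(x)
}

#' Full metric panel with AUC and DeLong CI
#'
#' Convenience wrapper combining [confusionCounts()],
#' [classificationMetrics()] and [delongCi()].
#'
#' @param scores numeric pCR probabilities.
#' @param labels pair labels.
#' @param threshold decision threshold (default 0.5).
#' @param level CI level (default 0.95).
#' @return A list with the six confusion metrics plus `auc`, `aucLower`,
#'   `aucUpper`.
#' @export
metricsPanel <- function(scores, labels, threshold = 0.5, level = 0.95) {
  mets <- classificationMetrics(confusionCounts(scores, labels, threshold))
  ci <- tryCatch(delongCi(scores, labels, level), error = function(e) NULL)
  if (is.null(ci)) {
    # fewer than 2 observations in a class: report the AUC without a CI
    auc <- tryCatch(.aucStatistic(scores, labels), error = function(e)
      NA_real_)
    ci <- list(auc = auc, lower = NA_real_, upper = NA_real_)
  }
  c(mets, list(auc = ci$auc, aucLower = ci$lower, aucUpper = ci$upper))
}
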