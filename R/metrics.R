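#' Murmur confusion matrix
#'
#' 3x3 count matrix of classifier output (rows) against expert label
#' (columns), in class order Present, Unknown, Absent.
#'
#' @param predicted,expert Character vectors of labels in
#'   `{Present, Unknown, Absent}`.
#' @return Integer matrix with dimnames classifier x expert.
#' @export
murmur_confusion <- function(predicted, expert) {
  predicted <- factor(as.character(predicted), levels = MURMUR_LEVELS)
  expert <- factor(as.character(expert), levels = MURMUR_LEVELS)
  if (anyNA(predicted) || anyNA(expert)) stop("labels must be Present/Unknown/Absent")
  m <- table(classifier = predicted, expert = expert)
  matrix(as.integer(m), 3L, 3L, dimnames = dimnames(m))
}

#' Challenge weighted accuracy for murmur classification
#'
#' `(5 m_PP + 3 m_UU + m_AA) / (5 colP + 3 colU + colA)` on the 3x3 murmur
#' confusion matrix: expert-Present patients weigh 5, expert-Unknown 3,
#' expert-Absent 1.
#'
#' @param confusion A 3x3 matrix (classifier x expert, order P, U, A) as from
#'   [murmur_confusion()].
#' @return Weighted accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(confusion) {
  m <- as.matrix(confusion)
  if (!all(dim(m) == c(3L, 3L))) stop("need a 3x3 confusion matrix")
  if (any(m < 0)) stop("confusion counts must be nonnegative")
  denom <- 5 * sum(m[, 1]) + 3 * sum(m[, 2]) + sum(m[, 3])
  if (denom <= 0) stop("weighted accuracy undefined for an all-zero matrix")
  (5 * m[1, 1] + 3 * m[2, 2] + m[3, 3]) / denom
}

#' Challenge clinical-outcome score
#'
#' `(5 nTP + nTN) / (5 (nTP + nFN) + (nFP + nTN))`: abnormal (positive)
#' patients weigh 5.
#'
#' @param nTP,nFP,nFN,nTN Nonnegative counts; alternatively pass a 2x2 matrix
#'   `rbind(c(nTP, nFP), c(nFN, nTN))` as `nTP`.
#' @return Outcome score in `[0, 1]`.
#' @export
outcome_score <- function(nTP, nFP = NULL, nFN = NULL, nTN = NULL) {
  if (is.matrix(nTP)) {
    m <- nTP
    if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 outcome matrix")
    nFP <- m[1, 2]; nFN <- m[2, 1]; nTN <- m[2, 2]; nTP <- m[1, 1]
  }
  counts <- c(nTP, nFP, nFN, nTN)
  if (any(counts < 0)) stop("outcome counts must be nonnegative")
  denom <- 5 * (nTP + nFN) + (nFP + nTN)
  if (denom <= 0) stop("outcome score undefined for an empty matrix")
  (5 * nTP + nTN) / denom
}

# step-function average precision (area under the precision-recall curve);
# tied scores are grouped so the result does not depend on sort order
average_precision <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  grp <- cumsum(!duplicated(scores[o]))
  tp <- tapply(lab, grp, sum)
  n_at <- tapply(lab, grp, length)
  ctp <- cumsum(tp)
  cn <- cumsum(n_at)
  precision <- ctp / cn
  recall_step <- tp / sum(lab)
  sum(precision * recall_step)
}

#' Binary classification metrics for murmur probabilities
#'
#' AUROC (rank-based, ties counted half), AUPRC (average precision),
#' F-measure and accuracy at an operating threshold.
#'
#' @param scores Numeric vector of murmur probabilities.
#' @param labels Binary vector (1/TRUE = murmur present).
#' @param threshold Operating point for F-measure and accuracy (default 0.5).
#' @return Named list with `auroc`, `auprc`, `f_measure`, `accuracy`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    stop("rank metrics undefined when only one class is present")
  }
  roc <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                   levels = c(0, 1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(
    auroc = as.numeric(pROC::auc(roc)),
    auprc = average_precision(scores, labels),
    f_measure = f,
    accuracy = mean(pred == labels)
  )
}

#' Aggregate per-site probabilities to one patient probability
#'
#' Takes the maximum murmur probability over a patient's auscultation sites.
#'
#' @param per_site_probs Numeric vector of per-recording probabilities.
#' @return The patient-level probability.
#' @export
aggregate_patient <- function(per_site_probs) {
  if (!length(per_site_probs)) stop("no per-site probabilities")
  max(per_site_probs)
}

#' Unknown-class probability band
#'
#' @param t_low,t_high Thresholds with `0 <= t_low <= t_high <= 1`. Patients
#'   with probability `>= t_high` are Present, in `[t_low, t_high)` Unknown,
#'   below `t_low` Absent.
#' @return A list with class `unknown_band`.
#' @export
unknown_band <- function(t_low, t_high) {
  if (t_low < 0 || t_high > 1 || t_low > t_high) {
    stop("need 0 <= t_low <= t_high <= 1")
  }
  structure(list(t_low = t_low, t_high = t_high), class = "unknown_band")
}

#' Classify a patient probability against an unknown band
#'
#' @param p Probability in `[0, 1]`.
#' @param band An [unknown_band].
#' @return `"Present"`, `"Unknown"` or `"Absent"`.
#' @export
classify_patient <- function(p, band) {
  if (p >= band$t_high) "Present" else if (p >= band$t_low) "Unknown" else "Absent"
}

#' Fit the unknown band by maximizing training weighted accuracy
#'
#' Grid search over `(t_low, t_high)` pairs on a regular grid, scoring the
#' induced 3-class confusion with [weighted_accuracy()]. Ties are broken
#' toward the widest Absent region (largest `t_low`), then the smallest
#' `t_high`.
#'
#' @param train_probs Per-patient probabilities on the training set.
#' @param train_labels Matching expert labels (`Present`/`Unknown`/`Absent`).
#' @param grid Grid resolution (default 0.01).
#' @return The best [unknown_band].
#' @export
fit_unknown_band <- function(train_probs, train_labels, grid = 0.01) {
  if (!length(train_probs)) stop("empty training probabilities")
  if (length(train_probs) != length(train_labels)) stop("length mismatch")
  levels_ <- seq(0, 1, by = grid)
  expert <- factor(as.character(train_labels), levels = MURMUR_LEVELS)
  if (anyNA(expert)) stop("labels must be Present/Unknown/Absent")
  w_col <- c(5, 3, 1)[as.integer(expert)]
  denom <- sum(w_col)
  best <- list(score = -Inf, t_low = 0, t_high = 0)
  for (tl in levels_) {
    for (th in levels_[levels_ >= tl]) {
      pred_p <- train_probs >= th
      pred_u <- !pred_p & train_probs >= tl
      num <- 5 * sum(pred_p & expert == "Present") +
        3 * sum(pred_u & expert == "Unknown") +
        sum(!pred_p & !pred_u & expert == "Absent")
      score <- num / denom
      better <- score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
           (tl > best$t_low ||
              (tl == best$t_low && th < best$t_high)))
      if (better) best <- list(score = score, t_low = tl, t_high = th)
    }
  }
  unknown_band(best$t_low, best$t_high)
}

#' Evaluate a trained model on a patient dataset
#'
#' Per-recording probabilities are aggregated to patients (maximum over
#' sites), classified against the unknown band, and scored: the 3-class
#' confusion and weighted accuracy, the clinical-outcome score (expert
#' abnormal = murmur Present, classifier abnormal = predicted Present;
#' expert-Unknown patients excluded from this 2x2), and binary metrics
#' (AUROC, AUPRC, F-measure, accuracy on Present-vs-Absent patients).
#'
#' @param model A trained [build_relcnn()] model.
#' @param ds A `pcg_dataset` (see [assemble_dataset()]).
#' @param band An [unknown_band], typically fitted on training data.
#' @return A list with class `mcheart_report`: `patient` (data frame of id,
#'   probability, prediction, expert label), `confusion`,
#'   `weighted_accuracy`, `outcome_score` and the binary metrics.
#' @export
evaluate_model <- function(model, ds, band) {
  probs <- predict_recordings(model, ds)
  agg <- aggregate_by_patient(probs, ds$patient_ids)$prob
  truth <- patient_labels(ds)[names(agg)]
  pred <- vapply(agg, classify_patient, character(1), band = band)
  cm <- murmur_confusion(pred, truth)

  bin_keep <- truth != "Unknown"
  bm <- if (length(unique(truth[bin_keep])) >= 2L) {
    binary_metrics(agg[bin_keep], truth[bin_keep] == "Present")
  } else {
    list(auroc = NA_real_, auprc = NA_real_, f_measure = NA_real_,
         accuracy = NA_real_)
  }
  oc <- if (any(bin_keep)) {
    expert_ab <- truth[bin_keep] == "Present"
    pred_ab <- pred[bin_keep] == "Present"
    outcome_score(sum(pred_ab & expert_ab), sum(pred_ab & !expert_ab),
                  sum(!pred_ab & expert_ab), sum(!pred_ab & !expert_ab))
  } else {
    NA_real_
  }
  structure(
    list(
      patient = data.frame(patient_id = names(agg), probability = unname(agg),
                           predicted = unname(pred),
                           expert = unname(as.character(truth)),
                           stringsAsFactors = FALSE),
      confusion = cm,
      weighted_accuracy = weighted_accuracy(cm),
      outcome_score = oc,
      auroc = bm$auroc, auprc = bm$auprc,
      f_measure = bm$f_measure, accuracy = bm$accuracy,
      band = band
    ),
    class = "mcheart_report"
  )
}

#' @export
print.mcheart_report <- function(x, ...) {
  cat("<mcheart_report>\n")
  cat(sprintf("  patients: %d   band: [%.2f, %.2f)\n",
              nrow(x$patient), x$band$t_low, x$band$t_high))
  tab <- data.frame(
    AUROC = x$auroc, AUPRC = x$auprc, `F-measure` = x$f_measure,
    Acc = x$accuracy, `Weighted Acc` = x$weighted_accuracy,
    check.names = FALSE
  )
  print(round(tab, 3), row.names = FALSE)
  cat("  murmur confusion (classifier x expert):\n")
  print(x$confusion)
  invisible(x)
}

#' Best constant-prediction weighted accuracy for a label set
#'
#' The weighted accuracy achieved by always predicting Present, Unknown or
#' Absent, whichever scores highest on the given expert labels — the
#' baseline a trained model must beat.
#'
#' @param expert Character vector of expert labels.
#' @return The best constant weighted accuracy.
#' @export
constant_baseline_wa <- function(expert) {
  max(vapply(MURMUR_LEVELS, function(cl) {
    weighted_accuracy(murmur_confusion(rep(cl, length(expert)), expert))
  }, numeric(1)))
}
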