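#' Area under the ROC curve (Mann-Whitney with midranks)
#'
#' Fraction of (positive, negative) pairs ordered correctly, ties counting
#' one half — computed from midranks, so tied scores are handled exactly.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_binary(labels, scores)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

check_binary <- function(labels, scores) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("AUROC undefined: only one class present", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  invisible(TRUE)
}

#' Area under the precision-recall curve (average precision)
#'
#' The precision-at-each-recall-increment summation: mean, over the
#' positives in score-descending order, of the precision at each positive.
#' Tied scores are processed as one block (precision evaluated at the end of
#' the block for every positive inside it), making the value
#' order-independent.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("AUPRC undefined: no positives", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  tp <- cumsum(y)
  k <- seq_along(y)
  # map each position to the last index of its tie block so tied scores are
  # scored as one retrieval step
  block_end <- k
  for (i in rev(seq_along(k)[-length(k)])) {
    if (s[i] == s[i + 1]) block_end[i] <- block_end[i + 1]
  }
  prec <- tp[block_end] / block_end
  sum(prec[y == 1]) / n_pos
}

#' Confusion matrix for multi-class predictions
#'
#' @param true integer vector of 0-based true classes.
#' @param predicted integer vector of 0-based predicted classes.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix, rows = true classes.
#' @export
confusion_matrix <- function(true, predicted, n_classes) {
  stopifnot(length(true) == length(predicted),
            all(true >= 0 & true < n_classes),
            all(predicted >= 0 & predicted < n_classes))
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              predicted = 0:(n_classes - 1)))
  for (i in seq_along(true)) {
    m[true[i] + 1L, predicted[i] + 1L] <- m[true[i] + 1L, predicted[i] + 1L] + 1L
  }
  m
}

#' Balanced accuracy (mean per-class recall)
#'
#' Classes with zero support are skipped with a warning.
#'
#' @param confusion square count matrix, rows = true classes.
#' @return unweighted mean of per-class recall.
#' @export
balanced_accuracy <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  support <- rowSums(confusion)
  if (sum(support) == 0) stop("empty confusion matrix", call. = FALSE)
  if (any(support == 0)) {
    warning("class(es) without support skipped in balanced accuracy: ",
            paste(which(support == 0) - 1L, collapse = ", "))
  }
  keep <- support > 0
  mean(diag(confusion)[keep] / support[keep])
}

#' Macro- and micro-averaged one-vs-rest AUROC
#'
#' Macro: unweighted mean of per-class one-vs-rest AUROCs (classes absent
#' from the labels are skipped with a warning). Micro: binary AUROC on the
#' pooled (one-hot label, class probability) pairs across all classes.
#'
#' @param diagnosis_scores numeric matrix, one row per scan, one column per
#'   class; rows sum to 1.
#' @param grade_labels integer vector of 0-based true classes.
#' @return list with elements `macro` and `micro`.
#' @export
macro_micro_auroc <- function(diagnosis_scores, grade_labels) {
  stopifnot(is.matrix(diagnosis_scores),
            nrow(diagnosis_scores) == length(grade_labels))
  G <- ncol(diagnosis_scores)
  present <- sort(unique(grade_labels))
  if (length(present) < 2L) {
    stop("macro/micro AUROC undefined: fewer than 2 classes present",
         call. = FALSE)
  }
  absent <- setdiff(0:(G - 1L), present)
  if (length(absent)) {
    warning("class(es) absent from labels skipped in macro AUROC: ",
            paste(absent, collapse = ", "))
  }
  per_class <- vapply(present, function(g) {
    auroc(diagnosis_scores[, g + 1L], as.numeric(grade_labels == g))
  }, numeric(1))
  onehot <- outer(grade_labels, 0:(G - 1L), `==`)
  micro <- auroc(as.numeric(diagnosis_scores), as.numeric(onehot))
  list(macro = mean(per_class), micro = micro,
       per_class = stats::setNames(per_class, present))
}

#' Youden-index operating threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over the finite candidate set
#' of observed scores under the decision rule `score >= threshold` =>
#' positive; ties are broken toward the smallest such threshold.
#'
#' @inheritParams auroc
#' @return the selected threshold (one of the observed scores).
#' @export
youden_threshold <- function(scores, labels) {
  check_binary(labels, scores)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    ss <- sens_spec_at_threshold(scores, labels, th)
    ss$sensitivity + ss$specificity - 1
  }, numeric(1))
  cand[which.max(j)]  # which.max returns the first (smallest) maximizer
}

#' Sensitivity and specificity at a fixed threshold
#'
#' Decision rule: `score >= threshold` predicts positive. A class missing
#' from `labels` makes the corresponding member `NA` with a warning.
#'
#' @inheritParams auroc
#' @param threshold finite decision threshold.
#' @return list with `sensitivity` and `specificity`.
#' @export
sens_spec_at_threshold <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold), length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  pred <- scores >= threshold
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- if (n_pos > 0) sum(pred & labels == 1) / n_pos else NA_real_
  spec <- if (n_neg > 0) sum(!pred & labels == 0) / n_neg else NA_real_
  if (n_pos == 0) warning("no positives in data; sensitivity undefined")
  if (n_neg == 0) warning("no negatives in data; specificity undefined")
  list(sensitivity = sens, specificity = spec)
}

#' Average per-scan probabilities across cross-validation models
#'
#' For every scan appearing in any of the inputs, the arithmetic mean of the
#' available models' probabilities (prognosis score and each diagnosis class
#' probability) is taken. In a cross-validation design each scan appears in
#' exactly one fold's test set; in an external-style evaluation all models
#' score all scans and the mean is over the models.
#'
#' @param per_fold list of prediction data frames, each with columns
#'   `scan_id`, `prognosis_score` and (optionally) `grade_prob_*` columns.
#' @return a single data frame with one row per distinct scan.
#' @export
ensemble_predictions <- function(per_fold) {
  if (length(per_fold) == 0L) stop("no prediction sets given", call. = FALSE)
  all_df <- do.call(rbind, per_fold)
  num_cols <- setdiff(names(all_df)[vapply(all_df, is.numeric, logical(1))],
                      "fold_index")
  agg <- stats::aggregate(all_df[num_cols], by = list(scan_id = all_df$scan_id),
                          FUN = mean)
  agg[order(agg$scan_id), , drop = FALSE]
}

#' DeLong test for two correlated ROC curves
#'
#' Paired two-sided test of the AUROC difference between two score vectors
#' on the same scans, using per-observation placement values (structural
#' components). The variance of the difference comes from the empirical
#' covariance of the placement values, so the correlation induced by shared
#' cases is accounted for.
#'
#' @param scores_a,scores_b numeric score vectors on the same scans.
#' @param labels binary 0/1 labels.
#' @return list with `auroc_a`, `auroc_b`, `z`, `p`, `n`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  check_binary(labels, scores_a)
  check_binary(labels, scores_b)
  stopifnot(length(scores_a) == length(scores_b))
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos)
  n <- length(neg)
  placements <- function(s) {
    # psi(x, y) = 1[x > y] + 0.5 * 1[x == y]
    psi <- outer(s[pos], s[neg], function(x, y) (x > y) + 0.5 * (x == y))
    list(a = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$a - pb$a
  if (var_diff <= 0) {
    if (isTRUE(all.equal(d, 0))) {
      warning("zero variance with equal AUROCs; p = 1")
      return(list(auroc_a = pa$a, auroc_b = pb$a, z = 0, p = 1, n = m + n))
    }
    stop("degenerate variance in DeLong test with unequal AUROCs",
         call. = FALSE)
  }
  z <- d / sqrt(var_diff)
  list(auroc_a = pa$a, auroc_b = pb$a, z = z,
       p = 2 * stats::pnorm(-abs(z)), n = m + n)
}

#' Subgroup AUROC report
#'
#' AUROC within each pre-defined subgroup (e.g. incidence-like vs
#' progression-like strata); subgroups with a single outcome class are
#' skipped with a warning, mirroring how underpowered strata are dropped.
#'
#' @param scores,labels pooled prediction scores and binary labels.
#' @param subgroups character/factor vector of subgroup names per scan.
#' @return data frame with columns `subgroup`, `auroc`, `n`.
#' @export
subgroup_report <- function(scores, labels, subgroups) {
  stopifnot(length(scores) == length(labels),
            length(subgroups) == length(labels))
  out <- lapply(unique(subgroups), function(sg) {
    idx <- which(subgroups == sg)
    if (length(unique(labels[idx])) < 2L) {
      warning("subgroup '", sg, "' has a single outcome class; skipped")
      return(NULL)
    }
    data.frame(subgroup = sg, auroc = auroc(scores[idx], labels[idx]),
               n = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Catastrophic-forgetting report for the diagnosis task
#'
#' Evaluates every strategy's diagnosis head on held-out graded scans and
#' reports, per strategy, balanced accuracy, its delta against the dedicated
#' diagnosis reference, the per-class recall vector (rare-class forgetting
#' shows up here), and the confusion matrix.
#'
#' @param strategy_scores named list; each element a numeric matrix of
#'   diagnosis class probabilities (rows = scans).
#' @param reference_scores the reference model's probability matrix on the
#'   same scans.
#' @param grade_labels integer vector of 0-based true grades.
#' @return list keyed by strategy, each with `balanced_accuracy`, `delta`,
#'   `per_class_recall`, `confusion`.
#' @export
forgetting_report <- function(strategy_scores, reference_scores,
                              grade_labels) {
  G <- ncol(reference_scores)
  eval_one <- function(probs) {
    pred <- max.col(probs, ties.method = "first") - 1L
    cm <- confusion_matrix(grade_labels, pred, G)
    support <- rowSums(cm)
    recall <- ifelse(support > 0, diag(cm) / support, NA_real_)
    list(balanced_accuracy = balanced_accuracy(cm),
         per_class_recall = recall, confusion = cm)
  }
  ref <- eval_one(reference_scores)
  out <- lapply(strategy_scores, function(p) {
    r <- eval_one(p)
    r$delta <- r$balanced_accuracy - ref$balanced_accuracy
    r
  })
  out$reference <- ref
  out$reference$delta <- 0
  out
}
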