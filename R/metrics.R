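check_scores_labels <- function(scores, labels, need_both_classes = TRUE) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  if (!all(is.finite(scores))) stop("non-finite scores")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (need_both_classes && (sum(labels) == 0 || sum(labels) == length(labels))) {
    stop("need at least one positive and one negative label")
  }
  invisible(TRUE)
}

# Per-distinct-threshold confusion counts, thresholds descending.
# Prediction rule everywhere: positive when score >= threshold.
threshold_counts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  is_last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[is_last_of_tie]
  predicted_pos <- seq_along(y)[is_last_of_tie]
  data.frame(threshold = s[is_last_of_tie],
             tp = tp, fp = predicted_pos - tp,
             fn = n_pos - tp, tn = n_neg - (predicted_pos - tp))
}

#' Precision-recall and ROC evaluation
#'
#' Computes AUROC (rank statistic with midrank tie handling), AUPR as average
#' precision (step-wise sum over distinct score thresholds, no interpolation)
#' and the full per-threshold curve of precision, recall, F1, sensitivity and
#' specificity, with the prediction rule `score >= threshold`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return list of class `eval_report` with `auroc`, `aupr` and `curve`.
#' @export
pr_roc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  r <- rank(scores)  # midranks for ties
  auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  cc <- threshold_counts(scores, labels)
  precision <- cc$tp / (cc$tp + cc$fp)
  recall <- cc$tp / n_pos
  aupr <- sum(diff(c(0, recall)) * precision)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  curve <- data.frame(threshold = cc$threshold, precision = precision,
                      recall = recall, f1 = f1, sensitivity = recall,
                      specificity = cc$tn / n_neg)
  structure(list(auroc = auroc, aupr = aupr, curve = curve),
            class = "eval_report")
}

#' Best threshold by F-beta score
#'
#' Scans every distinct score as a candidate threshold (`score >= threshold`
#' predicts positive) and returns the threshold maximising the F-beta score;
#' ties go to the smallest threshold, which favours recall.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (at least one positive required).
#' @param beta recall weight; `beta = 1` is F1, larger beta leans to recall.
#' @return list with `threshold`, `precision`, `recall`, `fbeta`.
#' @export
best_threshold_fbeta <- function(scores, labels, beta = 1) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(is.finite(scores))) stop("non-finite scores")
  if (sum(labels == 1) == 0) stop("no positive labels")
  cc <- threshold_counts(scores, labels)
  precision <- ifelse(cc$tp + cc$fp == 0, 0, cc$tp / (cc$tp + cc$fp))
  recall <- cc$tp / sum(labels == 1)
  b2 <- beta^2
  fbeta <- ifelse(b2 * precision + recall == 0, 0,
                  (1 + b2) * precision * recall / (b2 * precision + recall))
  # thresholds are descending; the last maximiser is the smallest threshold
  best <- max(which(fbeta == max(fbeta)))
  list(threshold = cc$threshold[best], precision = precision[best],
       recall = recall[best], fbeta = fbeta[best])
}

#' Agreement statistics at a fixed threshold
#'
#' Confusion-matrix summaries for the rule `score >= threshold`: sensitivity,
#' specificity, precision, F1, Cohen's kappa and Matthews correlation
#' coefficient. Empty-denominator conventions: an undefined precision or
#' sensitivity becomes 0, an MCC with any zero marginal becomes 0, and a
#' kappa with no chance-corrected room becomes 0; each case is flagged in the
#' result's `flags` element.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold.
#' @return list with the six statistics, the confusion counts and `flags`.
#' @export
agreement_stats <- function(scores, labels, threshold) {
  check_scores_labels(scores, labels, need_both_classes = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  n <- tp + fp + fn + tn
  flags <- character(0)
  divide <- function(num, den, flag) {
    if (den == 0) {
      flags <<- c(flags, flag)
      return(0)
    }
    num / den
  }
  sensitivity <- divide(tp, tp + fn, "sensitivity_undefined")
  specificity <- divide(tn, tn + fp, "specificity_undefined")
  precision <- divide(tp, tp + fp, "precision_undefined")
  f1 <- if (precision + sensitivity == 0) 0 else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  mcc_den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) {
    flags <- c(flags, "mcc_zero_marginal")
    0
  } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den)
  }
  po <- (tp + tn) / n
  pe <- (as.numeric(tp + fp) * (tp + fn) + as.numeric(fn + tn) * (fp + tn)) / n^2
  kappa <- if (1 - pe == 0) {
    flags <- c(flags, "kappa_undefined")
    0
  } else {
    (po - pe) / (1 - pe)
  }
  list(sensitivity = sensitivity, specificity = specificity,
       precision = precision, f1 = f1, kappa = kappa, mcc = mcc,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn), flags = flags)
}

#' AUPR per group of rows
#'
#' Evaluates the area under the precision-recall curve separately for each
#' group (disease, target or therapeutic area). Groups lacking either class
#' are reported as not evaluable; the positive fraction is always reported,
#' since prediction accuracy tracks the fraction of already-known indications.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param groups grouping vector, same length as `scores`.
#' @return data.frame with columns `group`, `n`, `n_pos`, `pos_fraction`,
#'   `aupr`, `evaluable`.
#' @export
groupwise_metrics <- function(scores, labels, groups) {
  check_scores_labels(scores, labels, need_both_classes = FALSE)
  if (length(groups) != length(scores)) stop("groups length mismatch")
  idx <- split(seq_along(scores), as.character(groups))
  rows <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    n_pos <- sum(labels[i])
    evaluable <- n_pos > 0 && n_pos < length(i)
    data.frame(group = g, n = length(i), n_pos = n_pos,
               pos_fraction = n_pos / length(i),
               aupr = if (evaluable) pr_roc(scores[i], labels[i])$aupr else NA_real_,
               evaluable = evaluable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap test
#'
#' One-sided upper-tail probability `P(X >= overlap)` that two sets of sizes
#' `size_a` and `size_b` drawn from a universe of `universe` elements share
#' at least the observed number of elements. Computed in log space for
#' stability at extreme significance.
#'
#' @param overlap observed intersection size.
#' @param size_a,size_b set sizes.
#' @param universe universe size.
#' @return list of class `overlap_test` with the counts, `p_value` and
#'   `log_p`.
#' @export
hypergeometric_overlap <- function(overlap, size_a, size_b, universe) {
  counts <- c(overlap, size_a, size_b, universe)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (overlap > min(size_a, size_b)) {
    stop("overlap exceeds the smaller set size")
  }
  if (max(size_a, size_b) > universe) stop("set larger than the universe")
  log_p <- phyper(overlap - 1, size_b, universe - size_b, size_a,
                  lower.tail = FALSE, log.p = TRUE)
  structure(list(overlap = overlap, size_a = size_a, size_b = size_b,
                 universe = universe, p_value = exp(log_p), log_p = log_p),
            class = "overlap_test")
}

#' Rank a target's candidate indications
#'
#' Sorts diseases by predicted score descending (ties broken lexicographically
#' by disease id). When labels are supplied the ranked-list AUROC is attached.
#'
#' @param model an [train()]ed model, or a numeric score vector.
#' @param features the target's [assemble_feature_table()] rows (ignored when
#'   `model` is already a score vector, in which case pass the disease ids).
#' @param labels optional 0/1 vector aligned with the rows/scores.
#' @param diseases disease ids when `model` is a score vector.
#' @return data.frame with `rank`, `disease_id`, `score`; attribute `auroc`
#'   when labels are given.
#' @export
rank_indications <- function(model, features = NULL, labels = NULL,
                             diseases = NULL) {
  if (is.numeric(model)) {
    scores <- model
    if (is.null(diseases)) diseases <- names(scores)
  } else {
    if (is.null(features) || nrow(features) == 0) stop("no feature rows to rank")
    scores <- predict(model, features)
    diseases <- features$disease_id
  }
  if (length(scores) == 0) stop("no scores to rank")
  if (is.null(diseases) || length(diseases) != length(scores)) {
    stop("need one disease id per score")
  }
  ord <- order(-scores, diseases)
  out <- data.frame(rank = seq_along(ord), disease_id = diseases[ord],
                    score = scores[ord])
  if (!is.null(labels)) {
    attr(out, "auroc") <- pr_roc(scores, labels)$auroc
  }
  out
}
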