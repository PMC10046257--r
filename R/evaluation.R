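#' Binarize risk scores at an operating threshold
#'
#' A patient is predicted `"cancer"` when the risk reaches the
#' threshold. The default threshold, 60, is the boundary of the
#' "potential case" warning state, so dubious cases count as negative.
#'
#' @param risks Numeric risk values in \[0, 100\].
#' @param threshold Operating point (default 60).
#' @return Character vector of `"cancer"` / `"non-cancer"`.
#' @export
binarize <- function(risks, threshold = 60) {
  stopifnot(all(risks >= 0 & risks <= 100))
  ifelse(risks >= threshold, "cancer", "non-cancer")
}

#' Confusion-matrix metrics for a labeled cohort
#'
#' @param predicted,truth Equal-length vectors of `"cancer"` /
#'   `"non-cancer"`; the truth must contain both classes.
#' @return List with counts `tp`, `fp`, `tn`, `fn` and percentages
#'   `sensitivity`, `specificity`, `fnr`, `fpr` (sensitivity + FNR =
#'   specificity + FPR = 100).
#' @export
confusion_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.character(predicted); truth <- as.character(truth)
  bad <- setdiff(unique(c(predicted, truth)), c("cancer", "non-cancer"))
  if (length(bad) > 0) stop("unknown class label(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  if (length(unique(truth)) < 2) {
    stop("truth contains a single class; metrics undefined", call. = FALSE)
  }
  tp <- sum(predicted == "cancer" & truth == "cancer")
  fn <- sum(predicted == "non-cancer" & truth == "cancer")
  tn <- sum(predicted == "non-cancer" & truth == "non-cancer")
  fp <- sum(predicted == "cancer" & truth == "non-cancer")
  sens <- tp / (tp + fn) * 100
  spec <- tn / (tn + fp) * 100
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       fnr = 100 - sens, fpr = 100 - spec)
}

#' Matthews correlation coefficient
#'
#' Standard MCC from the four confusion counts. When any marginal total
#' is zero the coefficient is undefined; the conventional value 0 is
#' returned with a warning.
#'
#' @param counts List with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_metrics()]).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    warning("MCC denominator is zero; returning 0 by convention", call. = FALSE)
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with half credit for tied scores:
#' the probability that a randomly chosen cancer case scores above a
#' randomly chosen non-cancer case.
#'
#' @param scores Numeric risk scores (higher = more suspicious).
#' @param truth Vector of `"cancer"` / `"non-cancer"`; both classes
#'   must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, truth) {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth))
  pos <- truth == "cancer"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("truth contains a single class; AUC undefined", call. = FALSE)
  }
  r <- rank(scores)  # midranks give the tie half-credit automatically
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC staircase from a threshold sweep over the observed scores
.roc_points <- function(scores, truth) {
  truth <- as.character(truth)
  pos <- truth == "cancer"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !pos) / sum(!pos), tpr = sum(pred & pos) / sum(pos))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Evaluate the full pipeline on a labeled cohort
#'
#' Runs the complete per-patient pipeline (Symbolic Risks, Statistical
#' Risk, aggregation, BI-RADS correction) and reports the system's
#' performance as a binary classifier twice: once scoring by the Global
#' Risk and once by the Corrected Global Risk.
#'
#' @param cohort A labeled `cohort`.
#' @param model A trained `risk_classifier`.
#' @param specs The three expert systems.
#' @param threshold Operating point for [binarize()] (default 60).
#' @param base_weights,correction,thresholds Passed to [risk_profile()].
#' @return List of two `evaluation_report`s (`global`, `corrected`),
#'   each holding the threshold, confusion counts, percentage metrics,
#'   MCC, AUC and the per-patient scores.
#' @export
evaluate_cohort <- function(cohort, model, specs = default_expert_systems(),
                            threshold = 60, base_weights = rep(1, 3) / 3,
                            correction = correction_params(),
                            thresholds = c(dubious = 40, potential = 60)) {
  df <- cohort$records
  if (anyNA(df$label)) stop("cohort must be fully labeled", call. = FALSE)
  n <- nrow(df)
  rg <- numeric(n); rgc <- numeric(n)
  for (i in seq_len(n)) {
    prof <- risk_profile(cohort_record(cohort, i), model, specs = specs,
                         base_weights = base_weights, correction = correction,
                         thresholds = thresholds)
    rg[i] <- prof$RG
    rgc[i] <- prof$RG_corrected
  }
  truth <- df$label
  report <- function(scores, variant) {
    cm <- confusion_metrics(binarize(scores, threshold), truth)
    structure(list(variant = variant, threshold = threshold,
                   counts = cm[c("tp", "fp", "tn", "fn")],
                   sensitivity = cm$sensitivity, specificity = cm$specificity,
                   fnr = cm$fnr, fpr = cm$fpr,
                   mcc = mcc(cm), auc = auc(scores, truth),
                   scores = scores),
              class = "evaluation_report")
  }
  list(global = report(rg, "Global Risk"),
       corrected = report(rgc, "Corrected Global Risk"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (threshold %.1f)\n", x$variant, x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts$tp, x$counts$fp,
              x$counts$tn, x$counts$fn))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  FNR %.2f%%  FPR %.2f%%\n",
              x$sensitivity, x$specificity, x$fnr, x$fpr))
  cat(sprintf("  MCC %.3f  AUC %.3f\n", x$mcc, x$auc))
  invisible(x)
}

#' Export an evaluation report as a plain list (for JSON serialization)
#' @param report An `evaluation_report`.
#' @return Named list without the per-patient score vector.
#' @export
report_summary <- function(report) {
  report$scores <- NULL
  unclass(report)
}
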