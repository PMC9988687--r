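#' Sample ids passing the RIN quality filter
#'
#' Headline cross-validation and ROC runs include only samples with RIN
#' strictly greater than the cutoff; samples at or below it, or with
#' unquantifiable RIN, are excluded (they remain scorable on demand for
#' bias analyses).
#'
#' @param ct A [ct_table()] carrying per-sample RIN.
#' @param cutoff RIN cutoff; default 8.0 (strictly greater-than).
#' @return Character vector of passing sample ids.
#' @export
filter_rin <- function(ct, cutoff = 8.0) {
  stopifnot(inherits(ct, "CtTable"))
  rownames(ct$ct)[!is.na(ct$rin) & ct$rin > cutoff]
}

#' Leave-one-out cross-validated bridging
#'
#' For each sample s, fits the bridge regressions and reweights the
#' original classifier on all samples except s, then scores s with that
#' inner model, so every out-of-fold score comes from a model independent
#' of the scored sample. Out-of-fold scores are pooled into a single
#' vector; original-model scores on the source platform are returned
#' alongside.
#'
#' A rank-deficient inner fold is recorded, its sample's score left
#' missing, and the run continues with a warning.
#'
#' @param x_src Samples x J source-feature matrix (the original model's
#'   features).
#' @param x_tgt Samples x K target-feature matrix (included delta-Ct
#'   features), same samples.
#' @param original `LinearClassifier` over the source features.
#' @return An object of class `CvResult`: list with `oof_scores` (named,
#'   NA for failed folds), `original_scores`, `n_folds`, `failed_folds`.
#' @export
loocv <- function(x_src, x_tgt, original) {
  x_src <- as.matrix(x_src); x_tgt <- as.matrix(x_tgt)
  n <- nrow(x_tgt); K <- ncol(x_tgt)
  if (n < K + 2)
    stop("leave-one-out needs n >= K + 2 (inner fits must be identifiable); ",
         "got n = ", n, ", K = ", K)
  ids <- rownames(x_tgt)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  oof <- stats::setNames(rep(NA_real_, n), ids)
  failed <- character()
  for (s in seq_len(n)) {
    inner <- try({
      br <- fit_bridge(x_src[-s, , drop = FALSE], x_tgt[-s, , drop = FALSE],
                       min_samples = K + 1)
      bridged <- reweight(original, br)
      score(bridged, x_tgt[s, , drop = FALSE])
    }, silent = TRUE)
    if (inherits(inner, "try-error")) failed <- c(failed, ids[s])
    else oof[s] <- inner
  }
  if (length(failed))
    warning("inner fold failure for sample(s): ", paste(failed, collapse = ", "))
  orig_scores <- score(original, x_src)
  attr(orig_scores, "representation") <- NULL
  structure(list(oof_scores = oof,
                 original_scores = orig_scores,
                 n_folds = n, failed_folds = failed),
            class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat("CvResult:", x$n_folds, "folds;", length(x$failed_folds),
      "failed fold(s)\n")
  invisible(x)
}

#' ROC curve, AUC with confidence interval, and Youden point
#'
#' Empirical ROC over all thresholds with higher scores indicating the
#' positive class; AUC and its confidence interval computed by the pROC
#' package (DeLong by default, stratified bootstrap optional); the Youden
#' operating point maximizes sensitivity + specificity - 1, with plateau
#' ties broken toward higher specificity.
#'
#' @param scores Numeric scores.
#' @param labels Class labels, same length; `positive` names the
#'   higher-score class.
#' @param positive Positive-class label; default `"KD"`.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level for the AUC interval; default 0.95.
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return An object of class `RocSummary`: list with `auc`, `ci`
#'   (low, high), `youden` (threshold, sensitivity, specificity, J),
#'   `curve` (data.frame of thresholds/sensitivities/specificities), `n_pos`,
#'   `n_neg`, `ci_method`.
#' @export
roc_metrics <- function(scores, labels, positive = "KD",
                        ci_method = c("delong", "bootstrap"),
                        conf_level = 0.95, boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  cls <- factor(ifelse(labels[keep] == positive, "pos", "neg"),
                levels = c("neg", "pos"))
  if (nlevels(droplevels(cls)) < 2)
    stop("both classes must be present to compute a ROC curve")
  r <- pROC::roc(response = cls, predictor = as.numeric(scores),
                 levels = c("neg", "pos"), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ci_method == "delong")
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  else
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "bootstrap",
                            boot.n = boot_n, progress = "none"))
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity"), transpose = FALSE)
  j <- co$sensitivity + co$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(co$specificity[best])]   # ties -> higher specificity
  structure(list(auc = auc, ci = c(low = ci[1], high = ci[3]),
                 youden = list(threshold = co$threshold[best],
                               sensitivity = co$sensitivity[best],
                               specificity = co$specificity[best],
                               J = j[best]),
                 curve = co, n_pos = sum(cls == "pos"),
                 n_neg = sum(cls == "neg"), ci_method = ci_method),
            class = "RocSummary")
}

#' @export
print.RocSummary <- function(x, digits = 3, ...) {
  cat(sprintf("RocSummary: AUC %.3f [%s %d%% CI: %.3f-%.3f], %d pos / %d neg\n",
              x$auc, x$ci_method, 95, x$ci["low"], x$ci["high"],
              x$n_pos, x$n_neg))
  cat(sprintf("Youden: threshold %.3f, sensitivity %.3f, specificity %.3f\n",
              x$youden$threshold, x$youden$sensitivity, x$youden$specificity))
  invisible(x)
}

#' Per-condition score summaries
#'
#' Median and interquartile range of classifier scores per condition,
#' using linear-interpolation quantiles (R default type 7).
#'
#' @param scores Numeric scores.
#' @param conditions Condition label per score.
#' @return data.frame with columns `condition`, `n`, `median`, `q1`, `q3`.
#' @export
condition_summaries <- function(scores, conditions) {
  keep <- !is.na(scores)
  scores <- scores[keep]; conditions <- as.character(conditions)[keep]
  conds <- sort(unique(conditions))
  do.call(rbind, lapply(conds, function(cc) {
    s <- scores[conditions == cc]
    q <- quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(condition = cc, n = length(s), median = q[2], q1 = q[1],
               q3 = q[3], stringsAsFactors = FALSE)
  }))
}

#' Test for RIN-related bias in classifier scores
#'
#' Two-sided Wilcoxon rank-sum test comparing scores of samples with RIN at
#' or below the cutoff (or unquantifiable) against samples above it. The
#' exact null distribution is used when group sizes permit and there are no
#' ties; otherwise the normal approximation with tie correction, and the
#' method actually used is reported.
#'
#' @param scores Numeric scores.
#' @param rin Per-sample RIN (NA = unquantifiable, grouped with low RIN).
#' @param cutoff RIN cutoff; default 8.0.
#' @return List with `p_value`, `statistic`, `method`, `n_low`, `n_high`.
#' @export
rin_bias_test <- function(scores, rin, cutoff = 8.0) {
  low <- scores[is.na(rin) | rin <= cutoff]
  high <- scores[!is.na(rin) & rin > cutoff]
  if (!length(low) || !length(high))
    stop("both RIN strata must be non-empty (<= ", cutoff, " and > ", cutoff, ")")
  ties <- anyDuplicated(c(low, high)) > 0
  exact_ok <- !ties && length(low) < 50 && length(high) < 50
  wt <- suppressWarnings(wilcox.test(low, high, alternative = "two.sided",
                                     exact = exact_ok, correct = !exact_ok))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = if (exact_ok) "exact" else "normal approximation (tie-corrected)",
       n_low = length(low), n_high = length(high))
}
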