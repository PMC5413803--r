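#' @title LOOCV, confusion metrics, ROC/AUC and group statistics
#'
#' @description
#' With cohorts of a few dozen subjects, leave-one-out cross-validation
#' is the evaluation of choice: each subject is held out once, the model
#' is refitted on the remaining subjects, and the held-out score and
#' class are recorded.  Feature selection can be placed outside the loop
#' (`pooled`: one subset chosen on all subjects, then applied in every
#' fold — optimistically biased but cheap) or inside it (`nested`:
#' selection reruns on every training fold — unbiased).
#'
#' @name pdt-evaluation
NULL

#' Leave-one-out cross-validation
#'
#' @param data a [labeled_dataset()] with `n >= 3` and both classes.
#' @param spec a [classifier_spec()].
#' @param fs feature-selection placement: `"none"`, `"pooled"` (fixed
#'   subset applied to every fold) or `"nested"` (selection rerun inside
#'   every training fold).
#' @param subset fixed feature indices for `fs = "pooled"`; computed by
#'   [best_first_select()] on the full data when omitted.
#' @param patience best-first patience for selection.
#' @param seed RNG seed; fold `i` trains with seed `seed + i` so a rerun
#'   reproduces every fold exactly.
#' @return A data frame with one row per subject: `subject`, `score`,
#'   `predicted`, `actual`, plus attributes `fs`, `subset` (pooled mode)
#'   and `fold_subsets` (nested mode).
#' @export
loocv <- function(data, spec, fs = c("none", "pooled", "nested"),
                  subset = NULL, patience = 5, seed = 1) {
  stopifnot(inherits(data, "pdt_dataset"))
  fs <- match.arg(fs)
  n <- nrow(data$X)
  if (n < 3L)
    stop_pdt("LOOCV needs at least 3 subjects", "pdt_data_error")
  check_two_classes(data$y)

  if (fs == "pooled" && is.null(subset)) {
    sel <- best_first_select(data, spec, patience = patience, seed = seed)
    subset <- sel$subset$indices
  }

  score <- predicted <- numeric(n)
  fold_subsets <- vector("list", n)
  for (i in seq_len(n)) {
    train <- labeled_dataset(data$X[-i, , drop = FALSE], data$y[-i],
                             data$feature_names)
    if (length(unique(train$y)) < 2L)
      stop_pdt(sprintf("training fold %d collapses to a single class", i),
               "pdt_training_error")
    idx <- switch(fs,
      none = seq_len(ncol(data$X)),
      pooled = subset,
      nested = {
        s <- best_first_select(train, spec, patience = patience,
                               seed = seed + i)
        s$subset$indices
      })
    fold_subsets[[i]] <- idx
    if (length(idx) == 0L) {
      # degenerate selection: fall back to the majority class of the fold
      maj <- if (mean(train$y == 1) > 0.5) 1 else -1
      predicted[i] <- maj
      score[i] <- if (maj == 1) 0.5 else -0.5
      next
    }
    model <- fit_classifier(subset_features(train, idx), spec,
                            seed = seed + i)
    xi <- data$X[i, idx, drop = FALSE]
    score[i] <- predict_score(model, xi)
    predicted[i] <- predict_class(model, xi)
  }
  out <- data.frame(
    subject = rownames(data$X) %||% as.character(seq_len(n)),
    score = score, predicted = predicted, actual = data$y,
    stringsAsFactors = FALSE)
  attr(out, "fs") <- fs
  attr(out, "subset") <- if (fs == "pooled") subset else NULL
  attr(out, "fold_subsets") <- if (fs == "nested") fold_subsets else NULL
  out
}

#' Confusion-matrix metrics
#'
#' Positive class = patient (+1).  Sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/n`, F-measure
#' `2 * precision * recall / (precision + recall)`.  A zero denominator
#' yields `NaN` with a warning.
#'
#' @param predicted,actual vectors of +1 / -1.
#' @return A list with `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`, `accuracy`, `f_measure`.
#' @export
confusion_metrics <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    stop_pdt("predicted and actual must be non-empty and equal length",
             "pdt_contract_error")
  if (!all(c(predicted, actual) %in% c(-1, 1)))
    stop_pdt("labels must be +1 / -1", "pdt_contract_error")
  tp <- sum(predicted == 1 & actual == 1)
  fn <- sum(predicted == -1 & actual == 1)
  tn <- sum(predicted == -1 & actual == -1)
  fp <- sum(predicted == 1 & actual == -1)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) {
    warning("F-measure undefined (zero denominator)")
    NaN
  } else 2 * prec * sens / (prec + sens)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(actual), f_measure = f)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds; the curve starts at (0, 0), ends at
#' (1, 1) and is monotone in both coordinates.  AUC is the trapezoidal
#' integral, equivalently the probability that a random positive
#' outranks a random negative with ties counted 1/2.
#'
#' @param actual vector of +1 / -1 with both classes present.
#' @param scores finite numeric scores, higher = more positive.
#' @return A list: `roc` data frame with columns `fpr`, `tpr`; `auc`.
#' @export
roc_auc <- function(actual, scores) {
  if (length(actual) != length(scores))
    stop_pdt("actual and scores must have equal length",
             "pdt_contract_error")
  if (!all(actual %in% c(-1, 1)) || length(unique(actual)) < 2L)
    stop_pdt("need both classes to compute a ROC curve",
             "pdt_contract_error")
  if (!all(is.finite(scores)))
    stop_pdt("scores must be finite", "pdt_contract_error")
  P <- sum(actual == 1); N <- sum(actual == -1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; a <- actual[ord]
  # one ROC point per distinct score value
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(a == 1)[last]
  fp <- cumsum(a == -1)[last]
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluate one classifier under LOOCV
#'
#' Runs [loocv()] and assembles the full evaluation report.
#'
#' @inheritParams loocv
#' @return A list of class `pdt_eval_report`: confusion counts, the four
#'   rates, `roc`, `auc`, `mode` (`"exFS"` / `"inFS"`), `fs_placement`,
#'   `family`, and the selected subset(s).
#' @export
evaluate_classifier <- function(data, spec, fs = "none", subset = NULL,
                                patience = 5, seed = 1) {
  res <- loocv(data, spec, fs = fs, subset = subset, patience = patience,
               seed = seed)
  cm <- confusion_metrics(res$predicted, res$actual)
  ra <- roc_auc(res$actual, res$score)
  structure(c(cm, list(
    roc = ra$roc, auc = ra$auc,
    mode = if (fs == "none") "exFS" else "inFS",
    fs_placement = if (fs == "none") NA_character_ else fs,
    family = spec$family,
    subset = attr(res, "subset"),
    fold_subsets = attr(res, "fold_subsets"),
    n = length(res$actual),
    predictions = res)),
    class = "pdt_eval_report")
}

#' @export
print.pdt_eval_report <- function(x, ...) {
  cat(sprintf(
    "<pdt_eval_report> %s-%s (n=%d): acc=%.3f sens=%.3f spec=%.3f F=%.3f AUC=%.3f\n",
    toupper(x$family), x$mode, x$n, x$accuracy, x$sensitivity,
    x$specificity, x$f_measure, x$auc))
  invisible(x)
}

#' Per-feature patient-vs-control comparison
#'
#' Welch two-sample t test for each of the 12 PDT features.
#'
#' @param df a feature matrix (see [validate_feature_matrix()]).
#' @return A data frame with 12 rows: `feature`, `patient_mean`,
#'   `patient_sd`, `control_mean`, `control_sd`, `t`, `p`.  Degenerate
#'   (zero-variance) features yield `NaN` with a warning.
#' @export
compare_groups <- function(df) {
  validate_feature_matrix(df)
  pat <- df$group == "patient"
  if (sum(pat) < 2L || sum(!pat) < 2L)
    stop_pdt("need at least 2 subjects per group", "pdt_data_error")
  rows <- lapply(pdt_feature_names, function(f) {
    xp <- df[[f]][pat]; xc <- df[[f]][!pat]
    tt <- tryCatch(t.test(xp, xc),
                   error = function(e) {
                     warning(sprintf("t test degenerate for %s: %s", f,
                                     conditionMessage(e)))
                     list(statistic = NaN, p.value = NaN)
                   })
    data.frame(feature = f,
               patient_mean = mean(xp), patient_sd = sd(xp),
               control_mean = mean(xc), control_sd = sd(xc),
               t = as.numeric(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Relative improvement of a metric, in percent
#'
#' @param before,after metric values; `before` must be positive.
#' @return `100 * (after - before) / before`, rounded to 2 decimals.
#' @export
relative_improvement <- function(before, after) {
  if (any(before <= 0))
    stop_pdt("baseline metric must be positive", "pdt_contract_error")
  round(100 * (after - before) / before, 2)
}
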