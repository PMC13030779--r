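# Decoding metrics: accuracy, macro-F1, Cohen's kappa, confusion matrices,
# and across-method inference (one-way ANOVA + Tukey HSD).

#' Confusion matrix and summary metrics
#'
#' Accuracy is the fraction of correct predictions; macro-F1 the unweighted
#' mean of per-class F1 (classes with undefined precision or recall
#' contribute 0, with a message); Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with expected agreement from the marginal
#' products.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes class vocabulary; defaults to the union of observed labels,
#'   sorted.
#' @return a `metrics_report`: `accuracy`, `macro_f1`, `kappa`, `confusion`
#'   (truth in rows), `per_class` F1, `n_blocks`.
#' @export
confusion_and_metrics <- function(truth, predicted, classes = NULL) {
  if (!length(truth) || length(truth) != length(predicted))
    abort_argument("need equal-length, non-empty label vectors")
  classes <- classes %||% sort(unique(c(truth, predicted)))
  if (!all(truth %in% classes) || !all(predicted %in% classes))
    abort_argument("labels outside the class vocabulary")
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  n <- length(truth)
  acc <- sum(diag(cm)) / n
  f1 <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    denom_p <- sum(cm[, i]); denom_r <- sum(cm[i, ])
    if (denom_p == 0 || denom_r == 0 || tp == 0) {
      if (denom_p == 0 && denom_r == 0)
        message(sprintf("class '%s' absent from truth and predictions: F1 = 0",
                        classes[i]))
      return(0)
    }
    prec <- tp / denom_p; rec <- tp / denom_r
    2 * prec * rec / (prec + rec)
  }, 0)
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (acc >= 1 - 1e-12) 1 else 0
  } else (acc - pe) / (1 - pe)
  structure(list(accuracy = acc, macro_f1 = mean(f1), kappa = kappa,
                 confusion = cm,
                 per_class = stats::setNames(f1, classes), n_blocks = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: n=%d acc=%.4f macro-F1=%.4f kappa=%.4f>\n",
              x$n_blocks, x$accuracy, x$macro_f1, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Kappa implied by an accuracy under balanced marginals
#'
#' For a balanced multi-class problem where chance agreement is `1/n`,
#' Cohen's kappa reduces to `(acc - 1/n) / (1 - 1/n)` — the consistency
#' relation between a mean accuracy and the kappa it implies.
#'
#' @param acc accuracy in `[0, 1]`.
#' @param n_classes number of classes (>= 2).
#' @return implied kappa.
#' @export
kappa_from_balanced_accuracy <- function(acc, n_classes) {
  if (any(acc < 0 | acc > 1)) abort_argument("acc must lie in [0, 1]")
  if (n_classes < 2) abort_argument("n_classes must be >= 2")
  (acc - 1 / n_classes) / (1 - 1 / n_classes)
}

#' Per-trial majority-vote metrics
#'
#' Secondary metric: block predictions are pooled by source trial and the
#' modal label (first mode on ties) is scored against the trial's label.
#'
#' @param truth,predicted per-block labels.
#' @param trial per-block source-trial index.
#' @param classes optional class vocabulary.
#' @return a `metrics_report` over trials.
#' @export
majority_vote_metrics <- function(truth, predicted, trial, classes = NULL) {
  if (length(unique(c(length(truth), length(predicted), length(trial)))) != 1)
    abort_argument("truth, predicted and trial must have equal length")
  per_trial <- split(seq_along(trial), trial)
  t_true <- vapply(per_trial, function(i) truth[i][1], "")
  t_pred <- vapply(per_trial, function(i) {
    tab <- table(predicted[i])
    names(tab)[which.max(tab)]
  }, "")
  confusion_and_metrics(t_true, t_pred, classes)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare per-subject scores across methods
#'
#' One-way ANOVA on subject-level scores grouped by method; when the main
#' effect is significant at `alpha`, all-pairs Tukey HSD (Tukey-Kramer for
#' unbalanced groups) with adjusted p-values and significance stars
#' (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param per_subject_scores named list: method -> numeric score vector
#'   (>= 2 methods, >= 2 scores each).
#' @param alpha significance level gating the post hoc test.
#' @return list with `F`, `p`, `alpha`, and `tukey` (data.frame of pairwise
#'   comparisons, or NULL when the ANOVA is not significant).
#' @export
compare_methods <- function(per_subject_scores, alpha = 0.05) {
  if (!is.list(per_subject_scores) || length(per_subject_scores) < 2)
    abort_argument("need scores for at least two methods")
  lens <- vapply(per_subject_scores, length, 0L)
  if (any(lens < 2))
    abort_argument("each method needs scores from at least two subjects")
  df <- data.frame(
    score = unlist(per_subject_scores, use.names = FALSE),
    method = factor(rep(names(per_subject_scores), lens)))
  fit <- aov(score ~ method, data = df)
  tab <- summary(fit)[[1]]
  Fv <- tab$`F value`[1]; pv <- tab$`Pr(>F)`[1]
  tukey <- NULL
  if (is.finite(pv) && pv < alpha) {
    tk <- TukeyHSD(fit)$method
    tukey <- data.frame(comparison = rownames(tk),
                        diff = tk[, "diff"], lwr = tk[, "lwr"],
                        upr = tk[, "upr"], p_adj = tk[, "p adj"],
                        stars = p_stars(tk[, "p adj"]),
                        row.names = NULL)
  }
  list(F = Fv, p = pv, alpha = alpha, tukey = tukey)
}
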