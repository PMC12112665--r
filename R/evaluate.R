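# Evaluation harness: confusion matrices, classification metrics
# (precision/recall/F1/one-vs-rest accuracy/AUC/mAP), exact pain-level
# accuracy, estimator comparison tables, and temporal pain profiles.

#' Confusion matrix
#'
#' Rows are truth, columns are predictions.
#'
#' @param truth,pred Equal-length label vectors.
#' @param levels Label set and order; defaults to the union of observed
#'   labels (canonical emotion order when all labels are emotions).
#' @return A `confusion_matrix`: integer matrix with dimnames
#'   `truth` x `pred`.
#' @export
#' @examples
#' confusion(c("a", "a", "b"), c("a", "b", "b"))
confusion <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred)) stop_invalid("truth and pred differ in length")
  if (is.null(levels)) {
    obs <- unique(c(as.character(truth), as.character(pred)))
    levels <- if (all(obs %in% .EMOTIONS)) intersect(.EMOTIONS, obs) else sort(obs)
  }
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(pred), levels = levels)
  if (anyNA(t_f) || anyNA(p_f)) stop_invalid("labels outside the declared level set")
  cm <- unclass(table(truth = t_f, pred = p_f))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Rank-based ROC AUC (one class vs rest)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, computed from the rank sum (ties credited 0.5). Equals the
#' concordant-pair fraction over all positive-negative pairs.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical vector marking the positive items.
#' @return AUC in \[0, 1\], or NA when either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  if (length(scores) != length(positive)) stop_invalid("length mismatch")
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise integration: AP = sum over score-ranked items of
#' `(R_k - R_{k-1}) * P_k`.
#'
#' @inheritParams auc_rank
#' @return AP in \[0, 1\], or NA with no positives.
#' @export
average_precision <- function(scores, positive) {
  if (length(scores) != length(positive)) stop_invalid("length mismatch")
  positive <- as.logical(positive)
  n_pos <- sum(positive)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Per-class classification metrics
#'
#' One-vs-rest precision, recall, accuracy and F1 from the confusion matrix;
#' ROC AUC and average precision when per-class scores are supplied.
#' Undefined ratios (zero support, nothing predicted) are reported as NA —
#' never coerced to 0 — and macro averages skip them.
#'
#' @param cm A `confusion_matrix`.
#' @param scores Optional data frame / matrix of per-class probability
#'   columns (one row per observation, columns named by class), required for
#'   AUC and mAP.
#' @param truth Truth labels aligned with `scores` rows.
#' @return A `classification_report`: list with `by_class` (tibble of
#'   per-class metrics), `macro` (named list of macro averages incl.
#'   overall accuracy). Use [tidy()] / [glance()].
#' @export
classification_metrics <- function(cm, scores = NULL, truth = NULL) {
  if (!inherits(cm, "confusion_matrix")) stop_invalid("cm must be a confusion_matrix")
  classes <- rownames(cm)
  n <- sum(cm)
  by_class <- purrr::map_dfr(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- n - tp - fp - fn
    support <- tp + fn
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (support == 0) NA_real_ else tp / (tp + fn)
    accuracy <- (tp + tn) / n
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
      NA_real_
    } else {
      2 * precision * recall / (precision + recall)
    }
    auc <- map_ap <- NA_real_
    if (!is.null(scores) && cl %in% colnames(scores)) {
      if (is.null(truth)) stop_invalid("truth labels required with scores")
      pos <- as.character(truth) == cl
      auc <- auc_rank(scores[, cl], pos)
      map_ap <- average_precision(scores[, cl], pos)
    }
    tibble(class = cl, support = as.integer(support),
           precision = precision, recall = recall, accuracy = accuracy,
           f1 = f1, auc = auc, ap = map_ap)
  })
  macro <- list(
    accuracy = sum(diag(cm)) / n,
    precision = mean(by_class$precision, na.rm = TRUE),
    recall = mean(by_class$recall, na.rm = TRUE),
    f1 = mean(by_class$f1, na.rm = TRUE),
    auc = if (all(is.na(by_class$auc))) NA_real_ else mean(by_class$auc, na.rm = TRUE),
    map = if (all(is.na(by_class$ap))) NA_real_ else mean(by_class$ap, na.rm = TRUE),
    n = n
  )
  structure(list(by_class = by_class, macro = macro, cm = cm),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d, accuracy = %.4f, macro F1 = %.4f\n",
              x$macro$n, x$macro$accuracy, x$macro$f1))
  print(x$by_class)
  invisible(x)
}

#' Exact pain-level agreement
#'
#' Percentage of frames whose predicted ordinal pain level equals the true
#' level exactly. (This is the accuracy definition used throughout the
#' package's accuracy tables.)
#'
#' @param pred_levels,true_levels Equal-length integer level vectors.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' pain_accuracy(c(0, 1, 2, 2), c(0, 1, 1, 2))  # 75
pain_accuracy <- function(pred_levels, true_levels) {
  if (length(pred_levels) == 0) stop_invalid("empty input")
  if (length(pred_levels) != length(true_levels)) stop_invalid("length mismatch")
  100 * mean(pred_levels == true_levels)
}

#' Accuracy table comparing the four pain estimators
#'
#' Runs the estimation pipeline on a synthetic dataset and scores, per true
#' expression class, the exact-level accuracy of four estimators against the
#' dataset's true levels:
#' \describe{
#'   \item{ple}{PSPI baseline score, binned.}
#'   \item{plew}{emotion-weighted PSPI score, binned.}
#'   \item{plez}{six-zone maximum score, binned.}
#'   \item{plewz}{emotion-weighted six-zone score, binned.}
#' }
#' The final `average` row is the unweighted mean over classes.
#'
#' @param data Dataset tibble from [simulate_faces()] (needs `true_emotion`
#'   and `true_level`).
#' @inheritParams estimate_pain
#' @return Tibble: `class`, `n`, `ple`, `plew`, `plez`, `plewz`
#'   (percentages), with a trailing `average` row.
#' @export
compare_estimators <- function(data,
                               config = default_zone_config(),
                               calibration = default_calibration(config),
                               weights = default_au_weights(),
                               weight_table = emotion_weights(),
                               thresholds = default_pain_thresholds(),
                               neutral_gate = 0.25) {
  if (!all(c("true_emotion", "true_level") %in% names(data))) {
    stop_schema("dataset needs true_emotion and true_level columns")
  }
  est <- estimate_pain(data, config = config, calibration = calibration,
                       weights = weights, weight_table = weight_table,
                       mode = "hard", thresholds = thresholds,
                       neutral_gate = neutral_gate)
  safe_bin <- function(score) {
    out <- rep(NA_integer_, length(score))
    ok <- is.finite(score)
    if (any(ok)) out[ok] <- bin_pain_level(score[ok], thresholds)
    out
  }
  est$lev_ple <- safe_bin(est$pspi)
  est$lev_plew <- safe_bin(est$pspi * est$emotion_weight)
  est$lev_plez <- safe_bin(est$ps)
  est$lev_plewz <- safe_bin(est$plew)
  per_class <- est |>
    dplyr::group_by(class = .data$true_emotion) |>
    dplyr::summarise(
      n = dplyr::n(),
      ple = pain_accuracy(.data$lev_ple, .data$true_level),
      plew = pain_accuracy(.data$lev_plew, .data$true_level),
      plez = pain_accuracy(.data$lev_plez, .data$true_level),
      plewz = pain_accuracy(.data$lev_plewz, .data$true_level),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$class, .EMOTIONS))
  avg <- tibble(class = "average", n = as.integer(sum(per_class$n)),
                ple = mean(per_class$ple), plew = mean(per_class$plew),
                plez = mean(per_class$plez), plewz = mean(per_class$plewz))
  dplyr::bind_rows(per_class, avg)
}

#' Temporal pain profile
#'
#' Runs the pipeline over a time-stamped series of frame pairs and returns
#' the per-timestamp raw and weighted scores, for plotting the weighted
#' score against the raw one over time (e.g. a 60 s observation of one
#' subject).
#'
#' @param data Tibble with a strictly increasing `t` column (seconds) plus
#'   `frame_id`, `neutral`, `active` (see [simulate_pain_series()]).
#' @inheritParams estimate_pain
#' @return A `pain_profile`: tibble `t`, `frame_id`, `emotion`, `ps`,
#'   `plew`, `level`, `level_name`. Has an [autoplot()] method.
#' @export
temporal_profile <- function(data,
                             config = default_zone_config(),
                             calibration = default_calibration(config),
                             weights = default_au_weights(),
                             weight_table = emotion_weights(),
                             mode = c("hard", "soft"),
                             thresholds = default_pain_thresholds(),
                             neutral_gate = 0.25) {
  if (!"t" %in% names(data)) stop_schema("data needs a t column (seconds)")
  if (any(diff(data$t) <= 0)) stop_invalid("timestamps must be strictly increasing")
  est <- estimate_pain(data, config = config, calibration = calibration,
                       weights = weights, weight_table = weight_table,
                       mode = mode, thresholds = thresholds,
                       neutral_gate = neutral_gate)
  out <- est |>
    dplyr::select(dplyr::all_of(c("t", "frame_id", "emotion", "ps", "plew",
                                  "level", "level_name")))
  structure(out, class = c("pain_profile", class(tibble())),
            thresholds = thresholds)
}
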