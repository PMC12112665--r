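# broom-style tidiers for the package's result objects.

#' Tidy a single-frame pain assessment
#'
#' @param x A `pain_score` from [compute_pain()].
#' @param ... Unused.
#' @return One-row tibble: `frame_id`, `emotion`, `p_emotion`,
#'   `emotion_weight`, `pspi`, `ps`, `plew`, `level`, `level_name`, `mode`.
#' @export
tidy.pain_score <- function(x, ...) {
  tibble(frame_id = x$frame_id, emotion = x$emotion, p_emotion = x$p_emotion,
         emotion_weight = x$emotion_weight, pspi = x$pspi, ps = x$ps,
         plew = x$plew, level = x$level, level_name = x$level_name,
         mode = x$mode)
}

#' @rdname tidy.pain_score
#' @export
glance.pain_score <- function(x, ...) {
  tibble(ps = x$ps, plew = x$plew, level = x$level, emotion = x$emotion)
}

#' Tidy a classification report
#'
#' `tidy()` returns the per-class metric table; `glance()` the macro
#' averages (one row).
#'
#' @param x A `classification_report` from [classification_metrics()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.classification_report <- function(x, ...) x$by_class

#' @rdname tidy.classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble(accuracy = x$macro$accuracy, precision = x$macro$precision,
         recall = x$macro$recall, f1 = x$macro$f1, auc = x$macro$auc,
         map = x$macro$map, n = x$macro$n)
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `truth`, `pred`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "pred", "n")
  as_tibble(df)
}
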