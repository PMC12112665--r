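# Pain scoring: PSPI baseline, six-zone maximum-activation score, the
# emotion-weighted score, and the six-level categorization.

#' PSPI pain score
#'
#' Prkachin-Solomon pain intensity:
#' `AU4 + max(AU6, AU7) + max(AU9, AU10) + AU43`, with AU4, AU6, AU7, AU9,
#' AU10 in \[0, 5\] and AU43 binary. The raw maximum of this sum is 16, yet
#' the scale's stated maximum is 15; with `clamp = TRUE` (default) the score
#' is capped at `range_max = 15`. Both behaviors are available.
#'
#' @param au Named numeric vector or `au_id`/`intensity` tibble providing
#'   AU4, AU6, AU7, AU9, AU10 and AU43 (missing entries default to 0).
#' @param clamp Cap the score at `range_max`.
#' @param range_max Upper bound of the scale (15).
#' @return A single pain score.
#' @export
#' @examples
#' pspi_ple(c(AU4 = 2, AU6 = 1, AU7 = 3, AU9 = 0, AU10 = 2, AU43 = 1))  # 8
pspi_ple <- function(au, clamp = TRUE, range_max = 15) {
  if (range_max <= 0) stop_invalid("range_max must be positive")
  v <- au_vector(au)
  get <- function(nm) if (nm %in% names(v)) v[[nm]] else 0
  vals <- vapply(c("AU4", "AU6", "AU7", "AU9", "AU10"), get, numeric(1))
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 5)) {
    stop_invalid("AU4, AU6, AU7, AU9, AU10 must lie in [0, 5]")
  }
  au43 <- get("AU43")
  if (!au43 %in% c(0, 1)) stop_invalid("AU43 must be 0 or 1")
  s <- vals[["AU4"]] + max(vals[["AU6"]], vals[["AU7"]]) +
    max(vals[["AU9"]], vals[["AU10"]]) + au43
  if (clamp) min(s, range_max) else s
}

#' Six-zone maximum-activation pain score
#'
#' Sums the strongest per-zone activation over the six pain zones:
#' `max(AU1) + max(AU6) + max(AU9) + max(AU15) + max(AU17) + max(AU44)`,
#' giving a score in \[0, 30\]. Selecting each zone's maximum keeps the
#' score sensitive to the most significant activation in every region.
#'
#' @param zi Per-point zone intensities (tibble with `au_id`, `intensity`,
#'   from [compute_zone_intensities()]), or an already-reduced
#'   `au_id`/`intensity` table / named vector of per-AU scalars.
#' @return A single pain score in \[0, 30\].
#' @export
zone_max_ple <- function(zi) {
  v <- if (is.numeric(zi) && !is.null(names(zi))) {
    zi
  } else {
    au_vector(reduce_to_vector(zi, mode = "max"))
  }
  miss <- setdiff(.ZONE_AUS, names(v))
  if (length(miss) > 0) {
    stop_schema(paste0("missing pain zones: ", paste(miss, collapse = ", ")))
  }
  sum(v[.ZONE_AUS])
}

#' Emotion-weighted pain score
#'
#' Hard mode (default) multiplies the raw score by the weight of the single
#' detected emotion, `ps * w[label]`. Soft mode weights by the full
#' expression distribution, `ps * sum_e p_e * w_e`, which is bounded between
#' `min(w) * ps` and `max(w) * ps` and reduces to hard mode for a one-hot
#' distribution.
#'
#' @param ps Raw pain score (>= 0).
#' @param emotion A label (hard mode) or an `emotion`/`prob` distribution
#'   tibble (soft mode).
#' @param table Emotion-pain weight table, see [emotion_weights()].
#' @param mode `"hard"` or `"soft"`; soft requires a distribution.
#' @return The weighted pain score.
#' @export
#' @examples
#' weighted_ple(10, "sadness")  # 17
weighted_ple <- function(ps, emotion, table = emotion_weights(),
                         mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  if (!is.finite(ps) || ps < 0) stop_invalid("ps must be non-negative")
  if (mode == "hard") {
    label <- if (is.character(emotion)) emotion else classify(emotion)
    ps * emotion_weight(label, table)
  } else {
    if (is.character(emotion)) {
      return(ps * emotion_weight(emotion, table))
    }
    i <- match(emotion$emotion, table$emotion)
    if (anyNA(i)) stop_invalid("distribution contains labels absent from the weight table")
    ps * sum(emotion$prob * table$weight[i])
  }
}

#' Default pain-level thresholds
#'
#' Equal-width bins over the \[0, 30\] range of the six-zone score.
#'
#' @return Numeric vector of 5 ascending thresholds: 6, 12, 18, 24, 30.
#' @export
default_pain_thresholds <- function() c(6, 12, 18, 24, 30)

#' Categorize a pain score into six ordinal levels
#'
#' Level 0 ("no pain") iff the score is exactly 0; otherwise
#' `level = 1 + #(thresholds < score)`, capped at 5, i.e. bins are
#' left-inclusive: a score of 6 under the default thresholds is level 1.
#' Scores above the top threshold (possible after emotion weighting) cap at
#' level 5.
#'
#' @param score Non-negative pain score(s).
#' @param thresholds Five strictly ascending positive thresholds.
#' @return Integer level(s) 0-5.
#' @export
#' @examples
#' bin_pain_level(c(0, 6, 6.5, 30))
bin_pain_level <- function(score, thresholds = default_pain_thresholds()) {
  if (any(!is.finite(score)) || any(score < 0)) {
    stop_invalid("pain scores must be non-negative")
  }
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0)) {
    stop_invalid("thresholds must be strictly ascending and positive")
  }
  lev <- vapply(score, function(s) {
    if (s == 0) 0L else min(1L + sum(thresholds < s), 5L)
  }, integer(1))
  lev
}

#' Full pain assessment for one neutral/activated frame pair
#'
#' Pipeline: canonical alignment (if needed), per-zone intensities, the
#' six-zone maximum score `ps`, expression classification, the
#' emotion-weighted score `plew`, the PSPI baseline `pspi`, and the binned
#' pain level (binned from `plew`, so emotional weighting can push a frame
#' into a higher level).
#'
#' @param neutral,active `landmark_set`s (aligned automatically when not
#'   canonical).
#' @param config A `zone_config`.
#' @param calibration Calibration tibble.
#' @param weights Expression weight matrix.
#' @param weight_table Emotion-pain weight table.
#' @param mode `"hard"` or `"soft"` emotion weighting.
#' @param thresholds Pain-level thresholds.
#' @param neutral_gate See [classify_expression()].
#' @param use_z Use 3-D displacements.
#' @return A `pain_score` object (list) with fields `frame_id`, `emotion`,
#'   `p_emotion`, `emotion_weight`, `pspi`, `ps`, `plew`, `level`,
#'   `level_name`, `mode`, plus the AU intensity vector and distribution.
#'   Use [tidy()] for a one-row tibble.
#' @export
compute_pain <- function(neutral, active,
                         config = default_zone_config(),
                         calibration = default_calibration(config),
                         weights = default_au_weights(),
                         weight_table = emotion_weights(),
                         mode = c("hard", "soft"),
                         thresholds = default_pain_thresholds(),
                         neutral_gate = 0.25,
                         use_z = FALSE) {
  mode <- match.arg(mode)
  if (!is_canonical(neutral)) neutral <- align_landmarks(neutral, config = config)
  if (!is_canonical(active))  active  <- align_landmarks(active, config = config)
  zi <- compute_zone_intensities(neutral, active, config = config,
                                 calibration = calibration, use_z = use_z)
  au <- reduce_to_vector(zi, mode = "max")
  v <- au_vector(au)
  ps <- zone_max_ple(v)
  fer_aus <- intersect(colnames(weights), names(v))
  cls <- classify_expression(v[fer_aus], weights = weights,
                             neutral_gate = neutral_gate)
  plew <- if (mode == "hard") {
    weighted_ple(ps, cls$label, table = weight_table, mode = "hard")
  } else {
    weighted_ple(ps, cls$distribution, table = weight_table, mode = "soft")
  }
  pspi <- if (all(.PSPI_AUS %in% names(v))) {
    pspi_ple(pmin(v[.PSPI_AUS], 5))
  } else {
    NA_real_
  }
  level <- bin_pain_level(plew, thresholds)
  structure(list(
    frame_id = frame_id(active),
    emotion = cls$label,
    p_emotion = cls$prob,
    emotion_weight = emotion_weight(cls$label, weight_table),
    pspi = pspi,
    ps = ps,
    plew = plew,
    level = level,
    level_name = .PAIN_LEVEL_NAMES[level + 1L],
    mode = mode,
    intensities = au,
    distribution = cls$distribution,
    zone_intensities = zi
  ), class = "pain_score")
}

#' @export
print.pain_score <- function(x, ...) {
  cat(sprintf(
    "<pain_score> frame '%s': ps = %.3f, plew = %.3f (%s, w = %.1f), level %d (%s)\n",
    x$frame_id, x$ps, x$plew, x$emotion, x$emotion_weight, x$level, x$level_name))
  invisible(x)
}

#' Per-frame pain estimation over a dataset
#'
#' Runs the full pipeline of [compute_pain()] over a tibble of frame pairs
#' and returns one record per frame.
#'
#' @param data Tibble with columns `frame_id`, `neutral`, `active` (the last
#'   two are list-columns of `landmark_set`s), e.g. from [simulate_faces()].
#'   Additional columns are carried through.
#' @inheritParams compute_pain
#' @return Tibble with columns `frame_id`, `emotion`, `p_emotion`,
#'   `emotion_weight`, `pspi`, `ps`, `plew`, `level`, `level_name`, plus any
#'   extra input columns.
#' @export
estimate_pain <- function(data,
                          config = default_zone_config(),
                          calibration = default_calibration(config),
                          weights = default_au_weights(),
                          weight_table = emotion_weights(),
                          mode = c("hard", "soft"),
                          thresholds = default_pain_thresholds(),
                          neutral_gate = 0.25,
                          use_z = FALSE) {
  mode <- match.arg(mode)
  if (!all(c("frame_id", "neutral", "active") %in% names(data))) {
    stop_schema("data needs frame_id, neutral and active columns")
  }
  res <- purrr::map2_dfr(data$neutral, data$active, function(n, a) {
    p <- compute_pain(n, a, config = config, calibration = calibration,
                      weights = weights, weight_table = weight_table,
                      mode = mode, thresholds = thresholds,
                      neutral_gate = neutral_gate, use_z = use_z)
    tibble(emotion = p$emotion, p_emotion = p$p_emotion,
           emotion_weight = p$emotion_weight, pspi = p$pspi, ps = p$ps,
           plew = p$plew, level = p$level, level_name = p$level_name)
  })
  extra <- data[setdiff(names(data), c("neutral", "active"))]
  dplyr::bind_cols(extra, res)
}
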