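# Expression classification from AU intensities.
#
# The expression score of each emotion is a weighted sum of AU intensities
# (one weight row per emotion); scores are turned into probabilities by a
# softmax and the argmax label is reported, with ties broken by the
# canonical category order.

#' Weighted-sum expression scores
#'
#' For each emotion e, `score_e = sum_i W[e, i] * AU_i`. The default weight
#' matrix puts weight 1 on each emotion's prototype AUs (see
#' [default_au_weights()]); any matrix with the same shape may be supplied.
#' Linear in the AU vector.
#'
#' @param au AU intensities: a tibble with `au_id`/`intensity` columns (as
#'   from [reduce_to_vector()]) or a named numeric vector.
#' @param weights Weight matrix, rows = the seven emotions, columns = AU ids.
#' @return Tibble with columns `emotion`, `score` (canonical row order).
#' @export
#' @examples
#' fer_scores(c(AU9 = 3))
fer_scores <- function(au, weights = default_au_weights()) {
  v <- au_vector(au)
  miss <- setdiff(names(v), colnames(weights))
  if (length(miss) > 0) {
    stop_config(paste0("weight matrix has no column for: ",
                       paste(miss, collapse = ", ")))
  }
  if (!setequal(rownames(weights), .EMOTIONS)) {
    stop_config("weight matrix must have the seven emotion rows")
  }
  W <- weights[.EMOTIONS, names(v), drop = FALSE]
  tibble(emotion = .EMOTIONS, score = as.numeric(W %*% v))
}

#' Convert expression scores to a probability distribution
#'
#' Softmax with temperature 1 (shift-invariant, sums to one). The package
#' reports probabilities rather than raw scores so that downstream soft
#' weighting and confidence reporting are well defined.
#'
#' @param scores Tibble with `emotion`/`score` columns (from [fer_scores()])
#'   or a named numeric vector.
#' @param method Only `"softmax"` is implemented.
#' @return Tibble with columns `emotion`, `prob`, summing to one.
#' @export
#' @examples
#' to_distribution(fer_scores(c(AU6 = 2)))
to_distribution <- function(scores, method = c("softmax")) {
  method <- match.arg(method)
  if (is.numeric(scores)) scores <- tibble(emotion = names(scores), score = scores)
  if (any(!is.finite(scores$score))) stop_invalid("scores must be finite")
  s <- scores$score - max(scores$score)
  e <- exp(s)
  tibble(emotion = scores$emotion, prob = e / sum(e))
}

#' Argmax expression label
#'
#' Returns the most probable category; exact ties are broken by the
#' canonical order (happiness, surprise, neutrality, disgust, fear, anger,
#' sadness).
#'
#' @param dist Tibble with `emotion`/`prob` columns, or a named numeric
#'   vector of probabilities.
#' @return A single character label.
#' @export
classify <- function(dist) {
  if (is.numeric(dist)) dist <- tibble(emotion = names(dist), prob = dist)
  ord <- match(.EMOTIONS, dist$emotion)
  ord <- ord[!is.na(ord)]
  dist <- dist[ord, , drop = FALSE]
  dist$emotion[which.max(dist$prob)]
}

#' Classify an expression from AU intensities
#'
#' Full classification path: weighted-sum scores, softmax, argmax. A
#' minimum-activation gate handles the neutral face: when the total AU
#' intensity falls below `neutral_gate` (0-5 scale units summed over AUs)
#' the frame is labeled `neutrality` with a degenerate (one-hot)
#' distribution. The gate is needed because a weighted sum without an
#' intercept scores every emotion 0 on an inactive face, and the canonical
#' tie-break would otherwise never select neutrality.
#'
#' @inheritParams fer_scores
#' @param neutral_gate Total-intensity threshold below which the face is
#'   declared neutral. Set to 0 to disable the gate.
#' @return List with elements `label` (character), `prob` (probability of
#'   the chosen label) and `distribution` (tibble `emotion`, `prob`).
#' @export
#' @examples
#' classify_expression(c(AU15 = 3, AU17 = 3, AU1 = 3))$label  # sadness
classify_expression <- function(au, weights = default_au_weights(),
                                neutral_gate = 0.25) {
  v <- au_vector(au)
  if (sum(v) < neutral_gate) {
    dist <- tibble(emotion = .EMOTIONS,
                   prob = as.numeric(.EMOTIONS == "neutrality"))
    return(list(label = "neutrality", prob = 1, distribution = dist))
  }
  dist <- to_distribution(fer_scores(v, weights))
  label <- classify(dist)
  list(label = label,
       prob = dist$prob[match(label, dist$emotion)],
       distribution = dist)
}
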