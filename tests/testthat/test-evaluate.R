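# Evaluation harness: confusion matrices, metrics, accuracy tables,
# temporal profiles.

test_that("confusion matrices tally predictions against truth", {
  truth <- c("a", "a", "b", "b", "b")
  expect_equal(diag(confusion(truth, truth)), c(a = 2, b = 3))
  cm_one <- confusion(truth, rep("a", 5), levels = c("a", "b"))
  expect_equal(unname(cm_one[, "b"]), c(0, 0))
  expect_equal(unname(cm_one[, "a"]), c(2, 3))
  # ten-item fixture, hand-tallied
  t10 <- c("x", "x", "x", "y", "y", "y", "y", "z", "z", "z")
  p10 <- c("x", "y", "x", "y", "y", "z", "y", "z", "x", "z")
  cm <- confusion(t10, p10)
  expect_equal(unname(cm["x", ]), c(2, 1, 0))
  expect_equal(unname(cm["y", ]), c(0, 3, 1))
  expect_equal(unname(cm["z", ]), c(1, 0, 2))
  expect_equal(sum(cm), 10)
  expect_error(confusion(t10, p10[-1]), class = "painface_invalid_argument")
})

test_that("per-class metrics reproduce hand arithmetic", {
  # binary fixture: TP = 2, FP = 1, FN = 2, TN = 5
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "neg", "neg", "pos", rep("neg", 5))
  rep_ <- classification_metrics(confusion(truth, pred, levels = c("pos", "neg")))
  row <- tidy(rep_)[tidy(rep_)$class == "pos", ]
  expect_equal(row$precision, 2 / 3)
  expect_equal(row$recall, 1 / 2)
  expect_equal(row$f1, 4 / 7)
  expect_equal(row$accuracy, 7 / 10)

  # perfect predictions with separable scores give all ones
  truth2 <- rep(c("a", "b"), each = 4)
  scores <- cbind(a = c(rep(0.9, 4), rep(0.1, 4)),
                  b = c(rep(0.1, 4), rep(0.9, 4)))
  perfect <- classification_metrics(confusion(truth2, truth2),
                                    scores = scores, truth = truth2)
  g <- glance(perfect)
  expect_equal(unlist(g[c("accuracy", "precision", "recall", "f1", "auc", "map")]),
               setNames(rep(1, 6), c("accuracy", "precision", "recall", "f1",
                                     "auc", "map")))
})

test_that("F1 is the harmonic mean and micro recall equals overall accuracy", {
  set.seed(40)
  truth <- sample(letters[1:4], 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.6, truth, sample(letters[1:4], 60, replace = TRUE))
  rep_ <- classification_metrics(confusion(truth, pred))
  bc <- tidy(rep_)
  ok <- !is.na(bc$f1)
  expect_equal(bc$f1[ok],
               2 * bc$precision[ok] * bc$recall[ok] /
                 (bc$precision[ok] + bc$recall[ok]),
               tolerance = 1e-12)
  micro_recall <- sum(bc$support * bc$recall) / sum(bc$support)
  expect_equal(micro_recall, rep_$macro$accuracy, tolerance = 1e-12)
})

test_that("zero-support classes report missing metrics, not zeros", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), levels = c("a", "b", "c"))
  bc <- tidy(classification_metrics(cm))
  expect_true(is.na(bc$recall[bc$class == "c"]))
  expect_true(is.na(bc$precision[bc$class == "c"]))
})

test_that("rank AUC equals the brute-force concordant-pair fraction", {
  brute_auc <- function(scores, pos) {
    ps <- scores[pos]; ns <- scores[!pos]
    acc <- 0
    for (a in ps) for (b in ns) acc <- acc + (a > b) + 0.5 * (a == b)
    acc / (length(ps) * length(ns))
  }
  # 4 vs 4 fixture
  s <- c(0.9, 0.8, 0.35, 0.3, 0.7, 0.6, 0.4, 0.2)
  p <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(auc_rank(s, p), brute_auc(s, p), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    sc <- round(runif(n), 2)  # rounding forces ties
    pos <- runif(n) < 0.4
    if (sum(pos) == 0 || sum(!pos) == 0) next
    expect_equal(auc_rank(sc, pos), brute_auc(sc, pos), tolerance = 1e-12)
  }
  expect_true(is.na(auc_rank(1:3, c(TRUE, TRUE, TRUE))))
})

test_that("average precision integrates the precision-recall steps", {
  # ranked: pos, neg, pos, neg -> AP = 0.5 * 1 + 0.5 * (2/3)
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6),
                                 c(TRUE, FALSE, TRUE, FALSE)),
               0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE)), 1)
  expect_true(is.na(average_precision(c(0.9, 0.8), c(FALSE, FALSE))))
})

test_that("pain accuracy is the exact-match percentage", {
  expect_equal(pain_accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(pain_accuracy(c(1, 2, 3, 4), c(1, 2, 0, 0)), 50)
  set.seed(42)
  pred <- sample(0:5, 20, replace = TRUE)
  truth <- sample(0:5, 20, replace = TRUE)
  hits <- 0
  for (i in 1:20) if (pred[i] == truth[i]) hits <- hits + 1
  expect_equal(pain_accuracy(pred, truth), 100 * hits / 20)
  expect_error(pain_accuracy(integer(0), integer(0)),
               class = "painface_invalid_argument")
})

test_that("the zone-max estimator scores 100 on every noiseless class", {
  d <- simulate_faces(35, seed = 50)
  tab <- compare_estimators(d)
  expect_true(all(tab$plez == 100))
  # with confounded truth the weighted zone estimator is the exact one
  dc <- simulate_faces(35, seed = 50, confound_emotion = TRUE)
  tabc <- compare_estimators(dc)
  expect_true(all(tabc$plewz == 100))
})

test_that("a single-class dataset yields a one-row table plus the average", {
  mix <- setNames(c(0, 0, 0, 0, 0, 0, 1), emotion_levels())
  d <- simulate_faces(10, emotion_mix = mix, seed = 51)
  tab <- compare_estimators(d)
  expect_equal(tab$class, c("sadness", "average"))
  expect_equal(tab$n[1], 10L)
})

test_that("the accuracy table equals an independent per-frame recomputation", {
  d <- simulate_faces(42, sigma = 0.005, seed = 52, confound_emotion = TRUE)
  tab <- compare_estimators(d)
  # oracle: recompute each frame individually and tally by class
  rows <- lapply(seq_len(nrow(d)), function(i) {
    p <- compute_pain(d$neutral[[i]], d$active[[i]])
    data.frame(class = d$true_emotion[i],
               plez_hit = bin_pain_level(p$ps) == d$true_level[i],
               plewz_hit = bin_pain_level(p$plew) == d$true_level[i])
  })
  oracle <- do.call(rbind, rows)
  for (cl in unique(oracle$class)) {
    sub <- oracle[oracle$class == cl, ]
    expect_equal(tab$plez[tab$class == cl], 100 * mean(sub$plez_hit))
    expect_equal(tab$plewz[tab$class == cl], 100 * mean(sub$plewz_hit))
  }
})

test_that("temporal profiles track the weighting direction of the emotion", {
  sad <- simulate_pain_series(20, emotion = "sadness", seed = 60)
  prof <- temporal_profile(sad)
  expect_equal(prof$t, 1:20)
  expect_equal(prof$plew, 1.7 * prof$ps, tolerance = 1e-9)
  happy <- simulate_pain_series(20, emotion = "happiness", seed = 61)
  hp <- temporal_profile(happy)
  expect_true(all(hp$plew <= hp$ps + 1e-12))
  # constant input frames give a constant series
  const <- sad[rep(1, 5), ]
  const$t <- 1:5
  cp <- temporal_profile(const)
  expect_equal(length(unique(round(cp$ps, 12))), 1)
  bad <- sad; bad$t[3] <- bad$t[2]
  expect_error(temporal_profile(bad), class = "painface_invalid_argument")
})

test_that("report and profile objects plot and tidy", {
  d <- simulate_pain_series(10, emotion = "fear", seed = 62)
  prof <- temporal_profile(d)
  expect_s3_class(autoplot(prof), "ggplot")
  cm <- confusion(c("a", "b"), c("a", "b"))
  expect_s3_class(autoplot(cm), "ggplot")
  expect_equal(sum(tidy(cm)$n), 2)
  expect_s3_class(plot_zones(make_face_template(1)$points), "ggplot")
})
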