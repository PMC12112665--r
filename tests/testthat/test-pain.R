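# Pain scores: PSPI, six-zone maximum, emotion weighting, level binning.

test_that("PSPI combines its action units with maxima and an optional cap", {
  expect_equal(pspi_ple(c(AU4 = 0, AU6 = 0, AU7 = 0, AU9 = 0, AU10 = 0, AU43 = 0)), 0)
  full <- c(AU4 = 5, AU6 = 5, AU7 = 3, AU9 = 4, AU10 = 5, AU43 = 1)
  expect_equal(pspi_ple(full), 15)                 # clamped scale maximum
  expect_equal(pspi_ple(full, clamp = FALSE), 16)  # raw sum of the maxima
  expect_equal(pspi_ple(c(AU4 = 2, AU6 = 1, AU7 = 3, AU9 = 0, AU10 = 2, AU43 = 1)), 8)
  expect_error(pspi_ple(c(AU4 = 6, AU6 = 0, AU7 = 0, AU9 = 0, AU10 = 0, AU43 = 0)),
               class = "painface_invalid_argument")
  expect_error(pspi_ple(c(AU4 = 1, AU6 = 0, AU7 = 0, AU9 = 0, AU10 = 0, AU43 = 0.5)),
               class = "painface_invalid_argument")
})

test_that("clamped PSPI stays within [0, 15] over random valid inputs", {
  set.seed(23)
  for (i in 1:25) {
    v <- c(setNames(runif(5, 0, 5), c("AU4", "AU6", "AU7", "AU9", "AU10")),
           AU43 = sample(0:1, 1))
    s <- pspi_ple(v)
    expect_gte(s, 0); expect_lte(s, 15)
    raw <- v[["AU4"]] + max(v[["AU6"]], v[["AU7"]]) +
      max(v[["AU9"]], v[["AU10"]]) + v[["AU43"]]
    expect_equal(pspi_ple(v, clamp = FALSE), raw)
  }
})

test_that("the six-zone score is the sum of per-zone maxima", {
  zeros <- tibble::tibble(au_id = rep(c("AU1", "AU6", "AU9", "AU15", "AU17", "AU44"), 2),
                          intensity = 0)
  expect_equal(zone_max_ple(zeros), 0)
  ones <- setNames(rep(1, 6), c("AU1", "AU6", "AU9", "AU15", "AU17", "AU44"))
  expect_equal(zone_max_ple(ones), 6)
  set.seed(24)
  zi <- tibble::tibble(
    au_id = rep(c("AU1", "AU6", "AU9", "AU15", "AU17", "AU44"), each = 4),
    intensity = runif(24, 0, 5))
  # brute-force oracle: scan every zone for its maximum, then sum
  want <- 0
  for (au in unique(zi$au_id)) {
    best <- -Inf
    for (v in zi$intensity[zi$au_id == au]) if (v > best) best <- v
    want <- want + best
  }
  expect_equal(zone_max_ple(zi), want, tolerance = 1e-12)
  # permutation of points within zones changes nothing
  perm <- zi[sample(nrow(zi)), ]
  expect_equal(zone_max_ple(perm), want, tolerance = 1e-12)
  # raising any single intensity never lowers the score
  zi2 <- zi; zi2$intensity[7] <- zi2$intensity[7] + 1
  expect_gte(zone_max_ple(zi2), want)
  expect_error(zone_max_ple(zi[zi$au_id != "AU17", ]),
               class = "painface_schema_error")
})

test_that("emotion weighting multiplies by the detected emotion's constant", {
  expect_equal(weighted_ple(10, "sadness"), 17)
  expect_equal(weighted_ple(3.21, "neutrality"), 3.21)
  uniform <- tibble::tibble(emotion = emotion_levels(), prob = rep(1 / 7, 7))
  expect_equal(weighted_ple(7, uniform, mode = "soft"),
               7 * (0.8 + 0.9 + 1.0 + 1.2 + 1.4 + 1.6 + 1.7) / 7)
  expect_equal(weighted_ple(7, uniform, mode = "soft"), 8.6)
  # ordering across labels follows the weight table
  out <- vapply(emotion_levels(), function(e) weighted_ple(5, e), numeric(1))
  expect_true(all(diff(out) > 0))
  expect_error(weighted_ple(5, "ennui"), class = "painface_invalid_argument")
  expect_error(weighted_ple(-1, "sadness"), class = "painface_invalid_argument")
})

test_that("soft weighting is bounded by the extreme weights", {
  set.seed(25)
  wt <- emotion_weights()
  for (i in 1:20) {
    p <- runif(7); p <- p / sum(p)
    dist <- tibble::tibble(emotion = emotion_levels(), prob = p)
    ps <- runif(1, 0, 30)
    s <- weighted_ple(ps, dist, mode = "soft")
    expect_gte(s, min(wt$weight) * ps - 1e-9)
    expect_lte(s, max(wt$weight) * ps + 1e-9)
  }
  # equality only for a one-hot distribution
  onehot <- tibble::tibble(emotion = emotion_levels(),
                           prob = as.numeric(emotion_levels() == "sadness"))
  expect_equal(weighted_ple(4, onehot, mode = "soft"), 4 * 1.7)
})

test_that("pain levels bin left-inclusively with an exact-zero floor", {
  expect_identical(bin_pain_level(0), 0L)
  expect_identical(bin_pain_level(6), 1L)     # boundary belongs to the lower bin
  expect_identical(bin_pain_level(6.5), 2L)
  expect_identical(bin_pain_level(30), 5L)
  expect_identical(bin_pain_level(51), 5L)    # weighted scores above 30 cap
  expect_identical(bin_pain_level(c(0.01, 12, 12.1, 24.0001)), c(1L, 2L, 3L, 5L))
  expect_error(bin_pain_level(-0.1), class = "painface_invalid_argument")
  expect_error(bin_pain_level(3, thresholds = c(5, 4, 6, 7, 8)),
               class = "painface_invalid_argument")
})

test_that("the full assessment matches a staged manual pipeline trace", {
  cfg <- default_zone_config()
  cal <- default_calibration(cfg)
  tpl <- make_face_template(seed = 26, config = cfg)
  spec <- c(AU15 = 4, AU17 = 4, AU1 = 4, AU6 = 1)
  active <- apply_activation(tpl, spec, calibration = cal)

  p <- compute_pain(tpl$points, active, config = cfg, calibration = cal)

  # stage-by-stage oracle
  zi <- compute_zone_intensities(tpl$points, active, config = cfg, calibration = cal)
  au <- reduce_to_vector(zi, "max")
  v <- setNames(au$intensity, au$au_id)
  ps <- zone_max_ple(v)
  cls <- classify_expression(v[colnames(default_au_weights())])
  plew <- ps * emotion_weight(cls$label)
  expect_equal(p$ps, ps, tolerance = 1e-12)
  expect_identical(p$emotion, cls$label)
  expect_identical(p$emotion, "sadness")
  expect_equal(p$plew, plew, tolerance = 1e-12)
  expect_equal(p$plew, 1.7 * p$ps, tolerance = 1e-12)
  expect_identical(p$level, bin_pain_level(plew))
  expect_equal(p$pspi, pspi_ple(pmin(v[c("AU4", "AU6", "AU7", "AU9", "AU10", "AU43")], 5)),
               tolerance = 1e-12)

  # identical frames yield a silent face
  p0 <- compute_pain(tpl$points, tpl$points, config = cfg, calibration = cal)
  expect_equal(p0$ps, 0)
  expect_equal(p0$plew, 0)
  expect_identical(p0$level, 0L)
  expect_identical(p0$emotion, "neutrality")
  expect_identical(p0$level_name, "no pain")

  # tidy() mirrors the object fields
  td <- tidy(p)
  expect_equal(td$plew, p$plew)
  expect_identical(td$level, p$level)
})
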