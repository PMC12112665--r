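# Displacement geometry and intensity calibration.

test_that("displacement is the Euclidean distance", {
  expect_equal(displacement(c(x = 1, y = 2), c(x = 4, y = 6)), 5)
  expect_equal(displacement(c(x = 3, y = -1), c(x = 3, y = -1)), 0)
  expect_equal(displacement(c(x = 0, y = 0), c(x = 0, y = 3)), 3)
  # z ignored by default, honored on request
  expect_equal(displacement(c(x = 0, y = 0, z = 0), c(x = 0, y = 0, z = 2)), 0)
  expect_equal(displacement(c(x = 0, y = 0, z = 0), c(x = 0, y = 0, z = 2),
                            use_z = TRUE), 2)
  expect_error(displacement(c(x = NaN, y = 0), c(x = 1, y = 1)),
               class = "painface_invalid_argument")
})

test_that("displacement is symmetric, definite and satisfies the triangle inequality", {
  set.seed(10)
  for (i in 1:20) {
    p <- lapply(1:3, function(.) c(x = runif(1, -2, 2), y = runif(1, -2, 2)))
    dab <- displacement(p[[1]], p[[2]])
    expect_equal(dab, displacement(p[[2]], p[[1]]))
    expect_gte(dab, 0)
    expect_lte(dab, displacement(p[[1]], p[[3]]) + displacement(p[[3]], p[[2]]) + 1e-12)
  }
  expect_identical(displacement(c(x = 0.3, y = 0.7), c(x = 0.3, y = 0.7)), 0)
})

test_that("calibration maps displacement linearly with saturation", {
  expect_equal(calibrate_intensity(0, 0.25), 0)
  expect_equal(calibrate_intensity(0.25, 0.25), 5)
  expect_equal(calibrate_intensity(0.5, 0.25), 5)
  # non-decreasing and invariant to joint rescaling
  d <- sort(runif(10, 0, 0.6))
  expect_true(all(diff(calibrate_intensity(d, 0.3)) >= 0))
  expect_equal(calibrate_intensity(d, 0.3), calibrate_intensity(7 * d, 7 * 0.3))
  expect_error(calibrate_intensity(0.1, 0), class = "painface_invalid_argument")
  expect_error(calibrate_intensity(-0.1, 0.3), class = "painface_invalid_argument")
})

test_that("zone displacements reduce to per-point distances", {
  cfg <- test_zone_config()
  lm <- random_landmarks(seed = 11)
  expect_equal(zone_displacements(lm, lm, "AU9", config = cfg), c(0, 0))
  # single-index zone equals a single displacement call
  act <- lm
  act$x[5] <- act$x[5] + 0.3  # point index 4 = AU4
  expect_equal(zone_displacements(lm, act, "AU4", config = cfg), 0.3)
  # hand-placed offsets on a three-point custom zone
  act2 <- lm
  act2$x[3] <- act2$x[3] + 3; act2$y[3] <- act2$y[3] + 4   # point 2
  act2$y[4] <- act2$y[4] - 1                               # point 3
  expect_equal(zone_displacements(lm, act2, c(2L, 3L, 4L), config = cfg),
               c(5, 1, 0))
  expect_error(zone_displacements(lm, act, 99L, config = cfg),
               class = "painface_schema_error")
})

test_that("zone intensities match a brute-force per-point oracle", {
  cfg <- test_zone_config()
  cal <- default_calibration(cfg, d_max = 0.2)
  neutral <- align_landmarks(random_landmarks(seed = 12), 0, 1, config = cfg)
  set.seed(13)
  active <- neutral
  active$x <- active$x + rnorm(24, 0, 0.05)
  active$y <- active$y + rnorm(24, 0, 0.05)
  zi <- compute_zone_intensities(neutral, active, config = cfg, calibration = cal)
  for (au in names(cfg$zones)) {
    for (idx in cfg$zones[[au]]$indices) {
      i <- idx + 1L
      d <- sqrt((active$x[i] - neutral$x[i])^2 + (active$y[i] - neutral$y[i])^2)
      want <- if (au == "AU43") {
        as.numeric(d >= cal$binary_threshold[match("AU43", cal$au_id)])
      } else {
        min(5 * d / 0.2, 5)
      }
      got <- zi$intensity[zi$au_id == au & zi$point == idx]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # identical frames give all-zero intensities
  zi0 <- compute_zone_intensities(neutral, neutral, config = cfg, calibration = cal)
  expect_true(all(zi0$intensity == 0))
  expect_error(
    compute_zone_intensities(neutral, active, config = cfg,
                             calibration = cal[cal$au_id != "AU9", ]),
    class = "painface_config_error")
})

test_that("an isolated activation saturates only its own zone", {
  cfg <- default_zone_config()
  cal <- default_calibration(cfg)
  tpl <- make_face_template(seed = 20, config = cfg)
  active <- apply_activation(tpl, c(AU9 = 5), calibration = cal)
  au <- reduce_to_vector(
    compute_zone_intensities(tpl$points, active, config = cfg, calibration = cal))
  v <- setNames(au$intensity, au$au_id)
  expect_equal(v[["AU9"]], 5, tolerance = 1e-9)
  expect_true(all(v[setdiff(names(v), "AU9")] == 0))
})

test_that("intensities are invariant under a common similarity transform", {
  cfg <- test_zone_config()
  cal <- default_calibration(cfg, d_max = 0.2)
  neutral <- random_landmarks(seed = 14)
  set.seed(15)
  active <- neutral
  active$x <- active$x + rnorm(24, 0, 0.03)
  active$y <- active$y + rnorm(24, 0, 0.03)
  base <- compute_zone_intensities(
    align_landmarks(neutral, 0, 1), align_landmarks(active, 0, 1),
    config = cfg, calibration = cal)
  tr <- function(lm) transform_landmarks(lm, theta = 1.1, s = 2.5, tx = 4, ty = -1)
  moved <- compute_zone_intensities(
    align_landmarks(tr(neutral), 0, 1), align_landmarks(tr(active), 0, 1),
    config = cfg, calibration = cal)
  expect_equal(moved$intensity, base$intensity, tolerance = 1e-9)
})

test_that("vector reduction agrees with exhaustive scans", {
  zi <- tibble::tibble(au_id = "AU1", intensity = c(1.2, 3.4, 2.0))
  expect_equal(reduce_to_vector(zi, "max")$intensity, 3.4)
  expect_equal(reduce_to_vector(tibble::tibble(au_id = "AU6",
                                               intensity = c(2, 2, 2)),
                                "mean")$intensity, 2)
  set.seed(16)
  zi2 <- tibble::tibble(au_id = rep(c("AU1", "AU9"), each = 5),
                        intensity = runif(10, 0, 5))
  red <- reduce_to_vector(zi2, "max")
  for (au in c("AU1", "AU9")) {
    vals <- zi2$intensity[zi2$au_id == au]
    best <- vals[1]
    for (v in vals) if (v > best) best <- v
    expect_equal(red$intensity[red$au_id == au], best)
  }
  expect_error(reduce_to_vector(tibble::tibble(au_id = character(0),
                                               intensity = numeric(0))),
               class = "painface_schema_error")
})
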