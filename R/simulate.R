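# Synthetic face-mesh generator.
#
# Generates neutral/activated landmark pairs with known per-AU intensities,
# an emotion label that selects which prototype AU pattern is activated, and
# optional additive coordinate noise, so that every downstream stage can be
# tested against analytic ground truth without any image data.

with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a synthetic canonical face template
#'
#' A deterministic (seeded) canonical point cloud: the two eye anchors sit
#' exactly at (-0.5, 0) and (0.5, 0) (unit interocular distance, midpoint at
#' the origin), remaining points are scattered over a face-sized region, and
#' every zone landmark carries a unit displacement direction used by
#' [apply_activation()].
#'
#' @param seed Integer seed; the same seed always yields the same template.
#' @param mesh_size Number of mesh points (must cover all configured
#'   indices).
#' @param config A `zone_config`.
#' @return A `face_template`: list with `points` (canonical
#'   `landmark_set`), `directions` (tibble `au_id`, `point`, `dx`, `dy`),
#'   `mesh_size`, `seed`.
#' @export
make_face_template <- function(seed = 1, mesh_size = NULL,
                               config = default_zone_config()) {
  mesh_size <- as.integer(mesh_size %||% config$mesh_size)
  needed <- max(c(unlist(lapply(config$zones, `[[`, "indices")),
                  config$left_eye, config$right_eye))
  if (mesh_size <= needed) {
    stop_config(sprintf("mesh_size %d too small for configured indices (max %d)",
                        mesh_size, needed))
  }
  with_seed_local(seed, {
    x <- runif(mesh_size, -1.1, 1.1)
    y <- runif(mesh_size, -1.0, 1.2)
    x[config$left_eye + 1L] <- -0.5; y[config$left_eye + 1L] <- 0
    x[config$right_eye + 1L] <- 0.5; y[config$right_eye + 1L] <- 0
    pts <- tibble(point = seq_len(mesh_size) - 1L, x = x, y = y, z = 0)
    dirs <- purrr::map_dfr(names(config$zones), function(au) {
      idx <- config$zones[[au]]$indices
      ang <- runif(length(idx), 0, 2 * pi)
      tibble(au_id = au, point = as.integer(idx),
             dx = cos(ang), dy = sin(ang))
    })
    structure(list(
      points = new_landmark_set(pts, frame_id = "template",
                                canonical = TRUE, scale_ref = 1),
      directions = dirs, mesh_size = mesh_size, seed = seed
    ), class = "face_template")
  })
}

#' Activate a template with known AU intensities
#'
#' Displaces each zone landmark along its template direction by
#' `(intensity / 5) * d_max`, inverting the displacement-to-intensity
#' calibration exactly: at zero noise the measurement pipeline recovers the
#' requested intensities to machine precision. Points outside the activated
#' zones are untouched.
#'
#' @param template A `face_template`.
#' @param spec Target intensities in \[0, 5\]: named numeric vector or
#'   `au_id`/`intensity` tibble. AUs absent from the spec stay at 0.
#' @param calibration Calibration tibble supplying each AU's `d_max`.
#' @param frame_id Frame id for the activated set.
#' @return A canonical `landmark_set`: the eye anchors are never zone
#'   members, so activation leaves the canonical frame intact. Generated
#'   coordinates (and any noise later added to them) live in canonical
#'   interocular units and are consumed as such by the pipeline.
#' @export
apply_activation <- function(template, spec,
                             calibration = default_calibration(),
                             frame_id = "active") {
  v <- au_vector(spec)
  if (any(v < 0 | v > 5)) stop_invalid("activation intensities must lie in [0, 5]")
  unknown <- setdiff(names(v), unique(template$directions$au_id))
  if (length(unknown) > 0) {
    stop_config(paste0("AU not in template: ", paste(unknown, collapse = ", ")))
  }
  pts <- template$points
  x <- pts$x; y <- pts$y
  for (au in names(v)) {
    if (v[[au]] == 0) next
    ci <- match(au, calibration$au_id)
    if (is.na(ci)) stop_config(paste0("no calibration entry for ", au))
    d <- (v[[au]] / 5) * calibration$d_max[ci]
    rows <- template$directions$au_id == au
    pos <- template$directions$point[rows] + 1L
    x[pos] <- x[pos] + d * template$directions$dx[rows]
    y[pos] <- y[pos] + d * template$directions$dy[rows]
  }
  new_landmark_set(tibble(point = pts$point, x = x, y = y, z = pts$z),
                   frame_id = frame_id, canonical = TRUE, scale_ref = 1)
}

largest_remainder_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

analytic_zone_max_ps <- function(spec_v) {
  sum(vapply(.ZONE_AUS, function(au) {
    if (au %in% names(spec_v)) spec_v[[au]] else 0
  }, numeric(1)))
}

#' Generate a synthetic neutral/activated landmark dataset
#'
#' Emulates the seven-expression-class structure of a facial-expression
#' corpus: each frame draws an emotion from the mix (stratified, so counts
#' are exact), a pain amplitude uniform on `amplitude_range`, and activates
#' the emotion's prototype AU pattern at that amplitude. Isotropic Gaussian
#' coordinate noise with standard deviation `sigma` (canonical interocular
#' units) is added to the active frame only; the neutral frame is the clean
#' template reference.
#'
#' Ground truth per frame: `true_ps` is the analytic six-zone maximum score
#' of the generated intensities. With `confound_emotion = FALSE` (default)
#' the frame's true pain score equals `true_ps`. With
#' `confound_emotion = TRUE` the true pain score is the emotion weight times
#' `true_ps` — emotional context amplifies the pain actually experienced
#' relative to the facial display — which is exactly the situation the
#' emotion-weighted estimator is designed to correct.
#'
#' @param n_frames Number of frames.
#' @param emotion_mix Named proportions over the seven emotions (must sum to
#'   1); default uniform.
#' @param sigma Coordinate noise SD in canonical units (>= 0).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param confound_emotion See above.
#' @param amplitude_range Range of the uniform pain amplitude (0-5 scale).
#' @param template A `face_template`; defaults to `make_face_template(seed)`.
#' @param config,calibration Zone configuration and calibration.
#' @param weight_table Emotion-pain weights used for the confounded truth.
#' @param thresholds Pain-level thresholds for `true_level`.
#' @return Tibble with columns `frame_id`, `true_emotion`, `amplitude`,
#'   `true_intensities` (list of `au_id`/`intensity` tibbles), `true_ps`,
#'   `true_score`, `true_level`, `neutral`, `active` (list-columns of
#'   `landmark_set`s).
#' @export
#' @examples
#' d <- simulate_faces(14, seed = 1)
#' table(d$true_emotion)
simulate_faces <- function(n_frames = 70,
                           emotion_mix = NULL,
                           sigma = 0,
                           seed = 1,
                           confound_emotion = FALSE,
                           amplitude_range = c(0, 5),
                           template = NULL,
                           config = default_zone_config(),
                           calibration = default_calibration(config),
                           weight_table = emotion_weights(),
                           thresholds = default_pain_thresholds()) {
  if (sigma < 0) stop_invalid("sigma must be non-negative")
  if (n_frames < 1) stop_invalid("n_frames must be positive")
  if (is.null(emotion_mix)) {
    emotion_mix <- setNames(rep(1 / 7, 7), .EMOTIONS)
  }
  if (!setequal(names(emotion_mix), .EMOTIONS)) {
    stop_config("emotion_mix must name exactly the seven emotions")
  }
  emotion_mix <- emotion_mix[.EMOTIONS]
  if (any(emotion_mix < 0) || abs(sum(emotion_mix) - 1) > 1e-9) {
    stop_config("emotion_mix proportions must be non-negative and sum to 1")
  }
  template <- template %||% make_face_template(seed = seed, config = config)
  proto <- emotion_prototypes()
  counts <- largest_remainder_counts(n_frames, emotion_mix)
  emotions <- rep(.EMOTIONS, counts)
  with_seed_local(seed, {
    amplitudes <- runif(n_frames, amplitude_range[1], amplitude_range[2])
    rows <- purrr::map(seq_len(n_frames), function(i) {
      emo <- emotions[i]
      amp <- amplitudes[i]
      aus <- proto[[emo]]
      spec_v <- if (length(aus) == 0) {
        setNames(numeric(0), character(0))
      } else {
        setNames(rep(amp, length(aus)), aus)
      }
      fid <- sprintf("f%04d", i)
      active <- apply_activation(template, spec_v, calibration = calibration,
                                 frame_id = fid)
      if (sigma > 0) {
        active$x <- active$x + rnorm(nrow(active), 0, sigma)
        active$y <- active$y + rnorm(nrow(active), 0, sigma)
      }
      neutral <- template$points
      attr(neutral, "frame_id") <- fid
      true_ps <- analytic_zone_max_ps(spec_v)
      w <- emotion_weight(emo, weight_table)
      true_score <- if (confound_emotion) w * true_ps else true_ps
      tibble(
        frame_id = fid, true_emotion = emo, amplitude = amp,
        true_intensities = list(tibble(au_id = names(spec_v),
                                       intensity = as.numeric(spec_v))),
        true_ps = true_ps, true_score = true_score,
        true_level = bin_pain_level(true_score, thresholds),
        neutral = list(neutral), active = list(active)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a time-stamped single-emotion frame series
#'
#' A 1 Hz sequence of frame pairs for one expression category, with the pain
#' amplitude following a smooth oscillation (period 30 s) plus optional
#' jitter — the synthetic analogue of a subject observed over a fixed
#' interval. Suitable input for [temporal_profile()].
#'
#' @param n_seconds Series length (one frame per second).
#' @param emotion The expression held throughout the series.
#' @inheritParams simulate_faces
#' @param amplitude_jitter SD of the Gaussian jitter on the amplitude.
#' @return As [simulate_faces()], plus a leading `t` column (seconds).
#' @export
simulate_pain_series <- function(n_seconds = 60,
                                 emotion = "sadness",
                                 sigma = 0,
                                 seed = 1,
                                 amplitude_jitter = 0.25,
                                 template = NULL,
                                 config = default_zone_config(),
                                 calibration = default_calibration(config),
                                 weight_table = emotion_weights(),
                                 thresholds = default_pain_thresholds()) {
  if (!emotion %in% .EMOTIONS) stop_invalid(paste0("unknown emotion: ", emotion))
  template <- template %||% make_face_template(seed = seed, config = config)
  proto <- emotion_prototypes()
  aus <- proto[[emotion]]
  with_seed_local(seed + 1L, {
    t <- seq_len(n_seconds)
    amp <- 2.5 + 2 * sin(2 * pi * t / 30) +
      rnorm(n_seconds, 0, amplitude_jitter)
    amp <- pmin(pmax(amp, 0), 5)
    rows <- purrr::map(seq_len(n_seconds), function(i) {
      spec_v <- if (length(aus) == 0) {
        setNames(numeric(0), character(0))
      } else {
        setNames(rep(amp[i], length(aus)), aus)
      }
      fid <- sprintf("t%03d", i)
      active <- apply_activation(template, spec_v, calibration = calibration,
                                 frame_id = fid)
      if (sigma > 0) {
        active$x <- active$x + rnorm(nrow(active), 0, sigma)
        active$y <- active$y + rnorm(nrow(active), 0, sigma)
      }
      neutral <- template$points
      attr(neutral, "frame_id") <- fid
      true_ps <- analytic_zone_max_ps(spec_v)
      tibble(t = t[i], frame_id = fid, true_emotion = emotion,
             amplitude = amp[i], true_ps = true_ps,
             true_level = bin_pain_level(true_ps, thresholds),
             neutral = list(neutral), active = list(active))
    })
    dplyr::bind_rows(rows)
  })
}

#' Write / read a synthetic dataset as plain-text files
#'
#' `write_face_dataset()` writes one landmark JSON per frame
#' (`<frame_id>.neutral.json`, `<frame_id>.active.json`) under
#' `dir/landmarks/`, plus `dir/labels.csv` with the ground truth (frame_id,
#' emotion, per-AU intensity columns, true_ps, true_score, true_level).
#' `read_face_dataset()` reloads such a directory into the tibble layout of
#' [simulate_faces()].
#'
#' @param data Dataset tibble from [simulate_faces()].
#' @param dir Output directory.
#' @param force Overwrite an existing directory.
#' @return The directory (write) or the dataset tibble (read), invisibly
#'   for write.
#' @export
write_face_dataset <- function(data, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop_invalid(paste0("output directory not empty (use force = TRUE): ", dir))
  }
  lmdir <- file.path(dir, "landmarks")
  dir.create(lmdir, recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(list(data$frame_id, data$neutral, data$active),
               function(fid, n, a) {
    write_landmarks(n, file.path(lmdir, paste0(fid, ".neutral.json")))
    write_landmarks(a, file.path(lmdir, paste0(fid, ".active.json")))
  })
  all_aus <- sort(unique(unlist(purrr::map(data$true_intensities, "au_id"))))
  labels <- data |>
    dplyr::select(dplyr::any_of(c("frame_id", "true_emotion", "amplitude",
                                  "true_ps", "true_score", "true_level")))
  for (au in all_aus) {
    labels[[paste0("intensity_", au)]] <- purrr::map_dbl(
      data$true_intensities,
      function(ti) {
        i <- match(au, ti$au_id)
        if (is.na(i)) 0 else ti$intensity[i]
      })
  }
  readr::write_csv(labels, file.path(dir, "labels.csv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_face_dataset
#' @param n_points Expected mesh size for validation (NULL skips).
#' @export
read_face_dataset <- function(dir, n_points = NULL) {
  lab_path <- file.path(dir, "labels.csv")
  lmdir <- file.path(dir, "landmarks")
  if (!file.exists(lab_path) || !dir.exists(lmdir)) {
    stop_parse(paste0("not a dataset directory: ", dir))
  }
  labels <- readr::read_csv(lab_path, show_col_types = FALSE, progress = FALSE)
  labels$neutral <- purrr::map(labels$frame_id, function(fid) {
    load_landmarks(file.path(lmdir, paste0(fid, ".neutral.json")),
                   n_points = n_points)
  })
  labels$active <- purrr::map(labels$frame_id, function(fid) {
    load_landmarks(file.path(lmdir, paste0(fid, ".active.json")),
                   n_points = n_points)
  })
  labels
}
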