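# Configuration objects: AU zone definitions, displacement calibration,
# expression weight matrix, and the emotion-pain weight table.

# The six zones entering the zone-max pain formula, and the auxiliary
# PSPI action units.
.ZONE_AUS <- c("AU1", "AU6", "AU9", "AU15", "AU17", "AU44")
.PSPI_AUS <- c("AU4", "AU6", "AU7", "AU9", "AU10", "AU43")

#' Read an AU zone configuration from JSON
#'
#' A zone configuration maps FACS action units to sets of face-mesh landmark
#' indices (0-based, standard 468-point mesh convention) and names the two
#' eye-anchor landmarks used for canonical alignment. The configuration file
#' is the single source of truth for zone membership; the bundled default is
#' `zone_config_mesh468.json` (see [default_zone_config()]).
#'
#' @param path Path to a JSON document with fields `mesh_size`, `left_eye`,
#'   `right_eye` and `zones` (a map `au_id -> {name, indices, color}`).
#' @return A `zone_config` object (validated list).
#' @export
read_zone_config <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("zone config not found: ", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$zones <- lapply(cfg$zones, function(z) {
    z$indices <- as.integer(z$indices)
    z
  })
  validate_zone_config(cfg)
}

#' @rdname read_zone_config
#' @param config A candidate configuration list.
#' @export
validate_zone_config <- function(config) {
  for (f in c("mesh_size", "left_eye", "right_eye", "zones")) {
    if (is.null(config[[f]])) stop_config(paste0("zone config missing field: ", f))
  }
  config$mesh_size <- as.integer(config$mesh_size)
  config$left_eye  <- as.integer(config$left_eye)
  config$right_eye <- as.integer(config$right_eye)
  if (config$mesh_size < 1L) stop_config("mesh_size must be positive")
  eyes <- c(config$left_eye, config$right_eye)
  if (any(eyes < 0L | eyes >= config$mesh_size)) {
    stop_config("eye anchor indices outside the mesh")
  }
  if (config$left_eye == config$right_eye) {
    stop_config("left and right eye anchors must differ")
  }
  missing_zones <- setdiff(.ZONE_AUS, names(config$zones))
  if (length(missing_zones) > 0) {
    stop_config(paste0("zone config must define the six pain zones; missing: ",
                       paste(missing_zones, collapse = ", ")))
  }
  for (au in names(config$zones)) {
    idx <- config$zones[[au]]$indices
    if (length(idx) == 0) stop_config(paste0(au, ": empty index list"))
    if (anyDuplicated(idx)) stop_config(paste0(au, ": duplicated indices"))
    if (any(idx < 0L | idx >= config$mesh_size)) {
      stop_config(paste0(au, ": indices outside the mesh"))
    }
  }
  structure(config, class = "zone_config")
}

#' Default AU zone configuration (468-point mesh)
#'
#' Loads the bundled zone configuration for the standard 468-point face mesh.
#' It defines the six pain zones (AU1 between-brow cluster, AU6 infraorbital,
#' AU9 nasal sidewall, AU15 mouth corners, AU17 chin, AU44 periocular ring)
#' plus the PSPI auxiliaries (AU4, AU7, AU10, AU43), and the eye-corner
#' anchors (33/263) used for alignment.
#'
#' @return A `zone_config` object.
#' @export
#' @examples
#' cfg <- default_zone_config()
#' names(cfg$zones)
default_zone_config <- function() {
  path <- system.file("extdata", "zone_config_mesh468.json", package = "painface")
  read_zone_config(path)
}

#' Zone configuration as a tibble
#'
#' @param config A `zone_config`.
#' @return Tibble with one row per (zone, landmark index).
#' @export
zone_table <- function(config = default_zone_config()) {
  purrr::map_dfr(names(config$zones), function(au) {
    z <- config$zones[[au]]
    tibble(au_id = au, name = z$name, point = as.integer(z$indices),
           color = z$color %||% NA_character_)
  })
}

#' Displacement-to-intensity calibration table
#'
#' Maps canonical-unit landmark displacements to the 0-5 FACS intensity
#' scale: a displacement of `d_max` (in interocular units) corresponds to
#' intensity 5, linearly and clipped. AU43 (eye closure) is binary and uses
#' `binary_threshold` (default half of its `d_max`). The default `d_max` of
#' 0.25 interocular units reflects the rough magnitude of a maximal facial
#' action; real deployments should supply their own calibration.
#'
#' @param config A `zone_config` whose zones need calibration entries.
#' @param d_max Displacement (interocular units) mapped to intensity 5.
#'   Either a single value for all AUs or a named vector by `au_id`.
#' @param binary_threshold Displacement above which AU43 scores 1.
#' @return Tibble with columns `au_id`, `d_max`, `binary_threshold`.
#' @export
#' @examples
#' default_calibration()
default_calibration <- function(config = default_zone_config(),
                                d_max = 0.25,
                                binary_threshold = NULL) {
  aus <- names(config$zones)
  if (is.null(names(d_max))) {
    dm <- rep_len(as.numeric(d_max), length(aus))
  } else {
    dm <- as.numeric(d_max[aus])
    if (anyNA(dm)) stop_config("named d_max must cover every configured AU")
  }
  if (any(!is.finite(dm)) || any(dm <= 0)) stop_config("d_max must be positive")
  bt <- ifelse(aus == "AU43",
               if (is.null(binary_threshold)) dm * 0.5 else binary_threshold,
               NA_real_)
  tibble(au_id = aus, d_max = dm, binary_threshold = bt)
}

#' Read a calibration table from JSON
#'
#' @param path JSON document: a map `au_id -> {d_max, binary_threshold?}`.
#' @return Calibration tibble as in [default_calibration()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("calibration file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cal <- purrr::map_dfr(names(raw), function(au) {
    tibble(au_id = au,
           d_max = as.numeric(raw[[au]]$d_max),
           binary_threshold = as.numeric(raw[[au]]$binary_threshold %||% NA_real_))
  })
  if (any(!is.finite(cal$d_max)) || any(cal$d_max <= 0)) {
    stop_config("calibration d_max must be positive for every AU")
  }
  cal
}

#' Emotion prototype action-unit patterns
#'
#' The declared mapping from each expression category to the set of action
#' units it prototypically activates. This map is the ground truth of the
#' synthetic generator and is mirrored by the default expression weight
#' matrix, making the weighted-sum classifier exactly testable. It is a
#' package convention consistent with the anatomical zone semantics, not a
#' learned model.
#'
#' @return Named list: emotion -> character vector of AU ids (empty for
#'   neutrality).
#' @export
#' @examples
#' emotion_prototypes()$sadness
emotion_prototypes <- function() {
  list(
    happiness  = "AU6",
    surprise   = "AU1",
    neutrality = character(0),
    disgust    = "AU9",
    fear       = c("AU1", "AU44"),
    anger      = c("AU44", "AU17"),
    sadness    = c("AU15", "AU17", "AU1")
  )
}

#' Default expression weight matrix
#'
#' Weight matrix for the weighted-sum expression score, built from the
#' prototype patterns of [emotion_prototypes()] as centered indicators:
#' emotion e's row is 1 on each of its k_e prototype AUs minus k_e/6 on all
#' six AUs. Centering makes each row orthogonal to a uniform intensity
#' offset, so an activation shared by every zone (e.g. measurement noise
#' lifting all zone maxima by a similar amount) cancels instead of favoring
#' emotions with larger prototype sets; plain 0/1 indicator rows would let
#' any emotion whose prototype is a superset of another's (fear vs surprise)
#' dominate it whenever all zones carry some activation. Each noiseless
#' prototype still scores highest on its own row. Any user-supplied matrix
#' with the same shape (7 emotion rows, one column per AU) is accepted by
#' [fer_scores()].
#'
#' @param aus AU ids to include as columns (default: the six pain zones).
#' @param centered Set to `FALSE` for plain 0/1 prototype indicator rows.
#' @return Numeric matrix, rownames = emotions in canonical order.
#' @export
#' @examples
#' default_au_weights()
default_au_weights <- function(aus = c("AU1", "AU6", "AU9", "AU15", "AU17", "AU44"),
                               centered = TRUE) {
  proto <- emotion_prototypes()
  W <- matrix(0, nrow = length(.EMOTIONS), ncol = length(aus),
              dimnames = list(.EMOTIONS, aus))
  for (e in .EMOTIONS) {
    hit <- intersect(proto[[e]], aus)
    W[e, hit] <- 1
    if (centered && length(hit) > 0) {
      W[e, ] <- W[e, ] - length(hit) / length(aus)
    }
  }
  W
}

#' Read an expression weight matrix from JSON
#'
#' @param path JSON document: a map `emotion -> {au_id: weight, ...}`; every
#'   emotion row must cover the same AU set.
#' @return Numeric matrix as in [default_au_weights()].
#' @export
read_au_weights <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("weight matrix file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  emos <- names(raw)
  if (!setequal(emos, .EMOTIONS)) {
    stop_config("weight matrix must have exactly the seven expression rows")
  }
  aus <- names(raw[[1]])
  W <- matrix(NA_real_, nrow = length(.EMOTIONS), ncol = length(aus),
              dimnames = list(.EMOTIONS, aus))
  for (e in emos) {
    row <- unlist(raw[[e]])
    if (!setequal(names(row), aus)) {
      stop_config("every emotion row must cover the same AU set")
    }
    W[e, names(row)] <- as.numeric(row)
  }
  if (any(!is.finite(W))) stop_config("weights must be finite")
  W
}

#' Emotion-pain weight table
#'
#' The per-emotion constants that multiply a raw pain score to reflect
#' emotional modulation of pain expression: happiness 0.8, surprise 0.9,
#' neutrality 1.0, disgust 1.2, fear 1.4, anger 1.6, sadness 1.7.
#'
#' @return Tibble with columns `emotion` and `weight`, in canonical order.
#' @export
#' @examples
#' emotion_weights()
emotion_weights <- function() {
  tibble(
    emotion = .EMOTIONS,
    weight  = c(0.8, 0.9, 1.0, 1.2, 1.4, 1.6, 1.7)
  )
}

#' Look up a single emotion-pain weight
#'
#' @param label One of the seven expression categories.
#' @param table A weight table as from [emotion_weights()].
#' @return The positive weight constant.
#' @export
#' @examples
#' emotion_weight("sadness")  # 1.7
emotion_weight <- function(label, table = emotion_weights()) {
  i <- match(label, table$emotion)
  if (is.na(i)) stop_invalid(paste0("unknown emotion label: ", label))
  w <- table$weight[i]
  if (!is.finite(w) || w <= 0) stop_config("emotion weights must be positive")
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
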