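# Shared fixtures built in code.

# A small mesh configuration for fast unit tests: 24 points, eye anchors at
# indices 0/1, compact zones.
test_zone_config <- function() {
  validate_zone_config(list(
    mesh_size = 24L, left_eye = 0L, right_eye = 1L,
    zones = list(
      AU1  = list(name = "inner brow raiser", indices = c(2L, 3L)),
      AU4  = list(name = "brow lowerer",      indices = 4L),
      AU6  = list(name = "cheek raiser",      indices = c(5L, 6L)),
      AU7  = list(name = "lid tightener",     indices = 7L),
      AU9  = list(name = "nose wrinkler",     indices = c(8L, 9L)),
      AU10 = list(name = "upper lip raiser",  indices = 10L),
      AU15 = list(name = "lip corner depressor", indices = c(11L, 12L)),
      AU17 = list(name = "chin raiser",       indices = c(13L, 14L)),
      AU43 = list(name = "eye closure",       indices = 15L),
      AU44 = list(name = "squint",            indices = c(16L, 17L))
    )
  ))
}

# Random canonical-ish landmark set on the test mesh.
random_landmarks <- function(seed = 1, n = 24, frame_id = "rand") {
  set.seed(seed)
  landmark_set(cbind(x = runif(n, -1, 1), y = runif(n, -1, 1)),
               frame_id = frame_id)
}

# Apply an in-plane similarity transform (rotation theta, scale s,
# translation tx/ty) to a landmark set.
transform_landmarks <- function(lm, theta = 0, s = 1, tx = 0, ty = 0) {
  x <- s * (cos(theta) * lm$x - sin(theta) * lm$y) + tx
  y <- s * (sin(theta) * lm$x + cos(theta) * lm$y) + ty
  landmark_set(cbind(x = x, y = y, z = lm$z * s), frame_id = frame_id(lm))
}
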