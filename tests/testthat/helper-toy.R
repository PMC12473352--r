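# In-code fixtures: deterministic toy clips with controllable motion,
# confidence patterns and detection masks.

# A clip whose 7 working keypoints move linearly: keypoint j sits at
# (j + t * vx, 2 * j - t * vy).  `detected` may be a function
# (frame, keypoint) -> logical; `conf` a function (frame, keypoint) ->
# numeric.
make_toy_clip <- function(n_frames = 120, vx = 0.01, vy = 0.005,
                          detected = function(t, kp) TRUE,
                          conf = function(t, kp) 0.9,
                          side = "right", id = "toy") {
  kps <- unname(reachgcn::right_side_keypoints)
  grid <- expand.grid(frame = 0:(n_frames - 1), keypoint = kps)
  j <- match(grid$keypoint, kps)
  det <- mapply(detected, grid$frame, grid$keypoint)
  frames <- tibble::tibble(
    frame = grid$frame,
    keypoint = grid$keypoint,
    joint = names(reachgcn::right_side_keypoints)[j],
    x = j + grid$frame * vx,
    y = 2 * j - grid$frame * vy,
    confidence = ifelse(det, mapply(conf, grid$frame, grid$keypoint),
                        NA_real_),
    detected = det
  )
  frames <- frames[order(frames$frame, frames$keypoint), ]
  structure(
    list(id = id, side = side, fps = 25, label = "unlabeled",
         error_modes = character(), metadata = list(), frames = frames),
    class = "skeleton_clip"
  )
}

# small labeled frame pool on a unit square, for self-train tests
make_frame_pool <- function(n_frames = 10, prefix = "f") {
  kps <- unname(reachgcn::right_side_keypoints)
  rows <- lapply(seq_len(n_frames), function(i) {
    tibble::tibble(
      frame_id = paste0(prefix, i),
      keypoint = kps,
      x = 0.1 * seq_along(kps) + 0.01 * i,
      y = 0.9 - 0.1 * seq_along(kps) + 0.005 * i
    )
  })
  dplyr::bind_rows(rows)
}

# detector that flags everything with confidence 1, zero error
oracle_detector <- function() {
  list(
    init_state = function() list(),
    train = function(examples, state) state,
    detect = function(state, frame) {
      tibble::tibble(keypoint = frame$keypoint, x = frame$x, y = frame$y,
                     confidence = 1, detected = TRUE)
    }
  )
}

# detector that never detects anything
inert_detector <- function() {
  list(
    init_state = function() list(),
    train = function(examples, state) state,
    detect = function(state, frame) {
      tibble::tibble(keypoint = frame$keypoint, x = frame$x, y = frame$y,
                     confidence = 0, detected = FALSE)
    }
  )
}
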