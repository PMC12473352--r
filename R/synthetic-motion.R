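#' Specification of a synthetic sit-and-reach clip
#'
#' Describes one simulated recording of the seated forward-flexion test:
#' a planar (sagittal) kinematic chain over the seven unilateral working
#' keypoints, animated through sit / reach / hold / return phases,
#' projected by a simple affine camera and corrupted by detector-like
#' noise and per-keypoint dropout.  All randomness derives from `seed`,
#' so a spec is a complete, reproducible description of its clip.
#'
#' The generator's correctness contract, evaluated on the noise-free
#' planar coordinates at the maximum-reach frame:
#' \itemize{
#'   \item knee angle (hip-knee-heel) at least 175 degrees;
#'   \item wrist-forearm collinearity deviation at most 5 degrees;
#'   \item hip-flexion angle (shoulder-hip-knee) at most 50 degrees.
#' }
#' Each scripted error mode violates exactly its own clause, by at
#' least the separation margin: `knee_flexion` drives the knee angle to
#' 160 degrees or below, `wrist_not_extended` bends the hand at least
#' 25 degrees out of the forearm line, and
#' `insufficient_lumbar_flexion` leaves the hip-flexion angle at 70
#' degrees or above.
#'
#' @param duration Clip length in seconds, in `[30, 60]`; `NULL` (the
#'   default) samples it uniformly from that range.
#' @param fps Frames per second; the recording convention is 25.
#' @param error_modes Character subset of `c("knee_flexion",
#'   "wrist_not_extended", "insufficient_lumbar_flexion")`; empty means
#'   a correct execution.
#' @param side `"right"` or `"left"` body side (sets keypoint indices).
#' @param camera_angle Camera azimuth in degrees, in `[15, 55]`; `NULL`
#'   samples it uniformly.
#' @param jitter_sd Standard deviation of the Gaussian coordinate
#'   jitter, in normalized image units (default 0.004).
#' @param conf_variance Variance of the Gaussian perturbation used for
#'   confidences: `confidence = clip(1 - |N(0, conf_variance)|, 0, 1)`
#'   (default 0.05).
#' @param dropout Named per-keypoint missingness probabilities (by
#'   joint name); the fingertip and heel are the most occlusion-prone
#'   by default.
#' @param seed Integer seed; every draw in the clip derives from it.
#' @return A `motion_spec` list.
#' @export
motion_spec <- function(duration = NULL,
                        fps = 25,
                        error_modes = character(),
                        side = c("right", "left"),
                        camera_angle = NULL,
                        jitter_sd = 0.004,
                        conf_variance = 0.05,
                        dropout = c(shoulder = 0.01, elbow = 0.01,
                                    wrist = 0.02, index = 0.06,
                                    hip = 0.01, knee = 0.01, heel = 0.05),
                        seed = 1L) {
  side <- match.arg(side)
  valid_modes <- c("knee_flexion", "wrist_not_extended",
                   "insufficient_lumbar_flexion")
  bad <- setdiff(error_modes, valid_modes)
  if (length(bad) > 0) {
    abort(paste0("Unknown error mode(s): ", paste(bad, collapse = ", "),
                 ". Valid modes: ", paste(valid_modes, collapse = ", ")),
          class = "reachgcn_invalid_argument")
  }
  if (!is.null(duration) && (duration < 30 || duration > 60)) {
    warn("`duration` outside the recording convention of 30-60 s.")
  }
  structure(
    list(duration = duration, fps = fps,
         error_modes = unique(error_modes), side = side,
         camera_angle = camera_angle, jitter_sd = jitter_sd,
         conf_variance = conf_variance, dropout = dropout,
         seed = as.integer(seed)),
    class = "motion_spec"
  )
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# reach parameter r(t) in [0,1] over normalized clip time
reach_profile <- function(tt) {
  r <- numeric(length(tt))
  up <- tt >= 0.18 & tt < 0.45
  hold <- tt >= 0.45 & tt < 0.62
  down <- tt >= 0.62 & tt < 0.92
  r[up] <- smoothstep((tt[up] - 0.18) / 0.27)
  r[hold] <- 1
  r[down] <- 1 - smoothstep((tt[down] - 0.62) / 0.30)
  r
}

deg2rad <- function(d) d * pi / 180

# Gaussian confidence perturbation (mean 0, given variance); clipping to
# [0,1] happens at the call site
conf_noise <- function(n, variance = 0.05) {
  rnorm(n, 0, sqrt(variance))
}

#' Generate one synthetic sit-and-reach clip
#'
#' Animates the seven-joint planar chain described by a [motion_spec()]
#' and returns a `skeleton_clip`: an object holding a long tibble of
#' per-frame keypoint records (`frame`, `keypoint`, `x`, `y`,
#' `confidence`, `detected`), the clip label (`"correct"` iff no error
#' mode is scripted), and metadata.  Frames are numbered from 0.
#'
#' Bone lengths are exactly constant across frames in the planar
#' coordinates; the camera projection and jitter are applied afterwards.
#'
#' @param spec A [motion_spec()].
#' @param keep_plane Also store the noise-free planar joint coordinates
#'   (list element `plane`, an array frames x 2 x 7) for kinematic
#'   checks.
#' @return A `skeleton_clip` object.
#' @examples
#' clip <- generate_clip(motion_spec(duration = 30, seed = 7))
#' nrow(clip$frames) / 7  # 750 frames
#' @export
generate_clip <- function(spec, keep_plane = FALSE) {
  stopifnot(inherits(spec, "motion_spec"))
  set.seed(spec$seed)
  duration <- if (is.null(spec$duration)) runif(1, 30, 60) else spec$duration
  n_f <- round(duration * spec$fps)
  cam <- if (is.null(spec$camera_angle)) runif(1, 15, 55) else spec$camera_angle

  sz <- runif(1, 0.9, 1.1)
  L <- c(thigh = 0.46, shank = 0.44, trunk = 0.50,
         upper_arm = 0.28, forearm = 0.26, hand = 0.17) * sz

  modes <- spec$error_modes
  # max-reach pose parameters (degrees), drawn inside the contract bands
  beta_max <- if ("knee_flexion" %in% modes) runif(1, 25, 40) else runif(1, 0, 1.5)
  # hip flexion at max reach is 90 - gamma_max - beta_max/2 degrees, so the
  # trunk target compensates any knee bend to keep the clauses independent
  hip_flex_target <- if ("insufficient_lumbar_flexion" %in% modes) {
    runif(1, 72, 82)   # trunk barely folds -> hip flexion >= 70
  } else {
    runif(1, 32, 45)   # deep forward fold -> hip flexion <= 50
  }
  gamma_max <- 90 - hip_flex_target - beta_max / 2
  wrist_max <- if ("wrist_not_extended" %in% modes) runif(1, 30, 50) else runif(1, 0, 2)
  elbow_bend <- runif(1, 3, 8)

  tt <- (seq_len(n_f) - 1) / (n_f - 1)
  r <- reach_profile(tt)
  # small physiological sway so no two frames are identical
  sway <- 0.6 * sin(2 * pi * tt * duration / 6)

  beta <- deg2rad(r * beta_max)                 # knee bend, 180 - knee angle
  gamma <- deg2rad(3 + r * (gamma_max - 3) + 0.3 * sway)  # trunk from vertical
  wdev <- deg2rad(r * wrist_max)                # hand off the forearm line

  hip <- cbind(0, 0)[rep(1, n_f), , drop = FALSE]
  knee <- cbind(L["thigh"] * cos(beta / 2), L["thigh"] * sin(beta / 2))
  heel <- knee + cbind(L["shank"] * cos(-beta / 2), L["shank"] * sin(-beta / 2))
  shoulder <- cbind(L["trunk"] * sin(gamma), L["trunk"] * cos(gamma))

  # arm sweeps from hanging to pointing at a spot just past the heel
  shoulder_max <- c(L["trunk"] * sin(deg2rad(gamma_max)),
                    L["trunk"] * cos(deg2rad(gamma_max)))
  target <- c(heel[which.max(r), 1] + 0.08, 0.04)
  a_reach <- atan2(target[2] - shoulder_max[2], target[1] - shoulder_max[1])
  a_hang <- deg2rad(-80)
  a_dir <- a_hang + r * (a_reach - a_hang)
  elbow <- shoulder + cbind(L["upper_arm"] * cos(a_dir),
                            L["upper_arm"] * sin(a_dir))
  f_dir <- a_dir + deg2rad(elbow_bend) * (1 - 0.5 * r)
  wrist <- elbow + cbind(L["forearm"] * cos(f_dir), L["forearm"] * sin(f_dir))
  h_dir <- f_dir - wdev
  index <- wrist + cbind(L["hand"] * cos(h_dir), L["hand"] * sin(h_dir))

  joints <- c("shoulder", "elbow", "wrist", "index", "hip", "knee", "heel")
  plane <- array(NA_real_, dim = c(n_f, 2, 7),
                 dimnames = list(NULL, c("x", "y"), joints))
  plane[, , "shoulder"] <- shoulder; plane[, , "elbow"] <- elbow
  plane[, , "wrist"] <- wrist; plane[, , "index"] <- index
  plane[, , "hip"] <- hip; plane[, , "knee"] <- knee
  plane[, , "heel"] <- heel

  # affine camera: azimuth compresses the forward axis; fixed image map
  cosc <- cos(deg2rad(cam))
  img_x <- 0.18 + 0.33 * plane[, "x", ] * cosc
  img_y <- 0.80 - 0.33 * plane[, "y", ]

  img_x <- img_x + matrix(rnorm(n_f * 7, 0, spec$jitter_sd), n_f, 7)
  img_y <- img_y + matrix(rnorm(n_f * 7, 0, spec$jitter_sd), n_f, 7)
  conf <- pmin(pmax(1 - abs(matrix(rnorm(n_f * 7, 0, sqrt(spec$conf_variance)),
                                   n_f, 7)), 0), 1)
  drop_p <- spec$dropout[joints]
  detected <- matrix(runif(n_f * 7), n_f, 7) >=
    matrix(drop_p, n_f, 7, byrow = TRUE)

  kp_index <- if (spec$side == "right") right_side_keypoints else left_side_keypoints
  frames <- tibble::tibble(
    frame = rep(0:(n_f - 1), times = 7),
    keypoint = rep(unname(kp_index[joints]), each = n_f),
    joint = rep(joints, each = n_f),
    x = as.vector(img_x),
    y = as.vector(img_y),
    confidence = ifelse(as.vector(detected), as.vector(conf), NA_real_),
    detected = as.vector(detected)
  ) |>
    dplyr::arrange(.data$frame, .data$keypoint)

  clip <- structure(
    list(
      id = sprintf("clip-%08x", spec$seed),
      side = spec$side,
      fps = spec$fps,
      label = if (length(modes) == 0) "correct" else "wrong",
      error_modes = modes,
      metadata = list(subject = sprintf("subj-%04d", spec$seed %% 10000L),
                      camera_angle = cam, duration = duration,
                      segment_lengths = L),
      frames = frames
    ),
    class = "skeleton_clip"
  )
  if (keep_plane) clip$plane <- plane
  clip
}

#' @export
print.skeleton_clip <- function(x, ...) {
  cat("<skeleton_clip>", x$id, "|", x$side, "side |",
      length(unique(x$frames$frame)), "frames @", x$fps, "fps | label:",
      x$label,
      if (length(x$error_modes)) paste0("(", paste(x$error_modes, collapse = "+"), ")")
      else "", "\n")
  invisible(x)
}

#' Joint angles of a clip
#'
#' Computes, per frame, the three angles that define sit-and-reach
#' form: the knee angle (at the knee, between hip and heel), the
#' wrist-extension deviation (180 degrees minus the angle at the wrist
#' between elbow and fingertip) and the hip-flexion angle (at the hip,
#' between shoulder and knee).  Angles are computed from whatever
#' coordinates are supplied, so camera projection distorts them
#' consistently for every frame of a clip.
#'
#' @param clip A `skeleton_clip`.
#' @param use_plane Use the stored noise-free planar coordinates
#'   (requires `generate_clip(..., keep_plane = TRUE)`).
#' @return A tibble with columns `frame`, `knee_angle`,
#'   `wrist_deviation`, `hip_flexion`, `reach_x` (fingertip forward
#'   coordinate), in degrees.
#' @export
clip_angles <- function(clip, use_plane = FALSE) {
  if (use_plane) {
    if (is.null(clip$plane)) {
      abort("Clip was generated without `keep_plane = TRUE`.",
            class = "reachgcn_invalid_argument")
    }
    get_xy <- function(j) clip$plane[, , j]
    n_f <- dim(clip$plane)[1]
    frames <- 0:(n_f - 1)
  } else {
    wide <- clip$frames
    get_xy <- function(j) {
      sub <- wide[wide$joint == j, ]
      cbind(sub$x, sub$y)
    }
    frames <- sort(unique(wide$frame))
  }
  ang_at <- function(b, a, c) {
    # interior angle at b between rays b->a and b->c, degrees
    u <- a - b; v <- c - b
    cosang <- rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  sh <- get_xy("shoulder"); el <- get_xy("elbow"); wr <- get_xy("wrist")
  ix <- get_xy("index"); hp <- get_xy("hip"); kn <- get_xy("knee")
  he <- get_xy("heel")
  tibble::tibble(
    frame = frames,
    knee_angle = ang_at(kn, hp, he),
    wrist_deviation = 180 - ang_at(wr, el, ix),
    hip_flexion = ang_at(hp, sh, kn),
    reach_x = ix[, 1]
  )
}

#' Maximum-reach frame of a clip
#'
#' The frame at which the fingertip is furthest forward, after a
#' 9-frame running-mean smoothing of its forward coordinate (ties break
#' to the earliest frame).
#'
#' @inheritParams clip_angles
#' @return A single frame number.
#' @export
max_reach_frame <- function(clip, use_plane = FALSE) {
  ang <- clip_angles(clip, use_plane = use_plane)
  x <- ang$reach_x
  sm <- stats::filter(x, rep(1 / 9, 9), sides = 2)
  sm[is.na(sm)] <- -Inf
  ang$frame[which.max(sm)]
}

#' Scripted angle-threshold form classifier
#'
#' A transparent reference rule, independent of the network: average
#' the three form angles over the hold window (frames whose smoothed
#' fingertip reach is within 2% of the maximum) and call the clip
#' correct iff the knee angle stays above 167.5 degrees, the wrist
#' deviation below 15 degrees and the hip flexion below 60 degrees
#' (threshold midpoints of the generator's separation bands).  Used to
#' certify that the synthetic two-class task is learnable.
#'
#' @param clip A `skeleton_clip`.
#' @return `"correct"` or `"wrong"`.
#' @export
rule_classify <- function(clip) {
  ang <- clip_angles(clip)
  sm <- stats::filter(ang$reach_x, rep(1 / 9, 9), sides = 2)
  sm[is.na(sm)] <- -Inf
  span <- max(sm) - stats::median(sm[is.finite(sm)])
  hold <- which(sm >= max(sm) - 0.02 * max(span, 1e-9))
  m <- ang[hold, , drop = FALSE]
  ok <- mean(m$knee_angle) > 167.5 &&
    mean(m$wrist_deviation) < 15 &&
    mean(m$hip_flexion) < 60
  if (ok) "correct" else "wrong"
}

#' Generate a labeled collection of synthetic clips
#'
#' Draws `n_correct` correct and `n_wrong` incorrect clips with
#' independent per-clip seeds derived from `seed`.  Incorrect clips
#' carry one, two or all three error modes, drawn from `mixture`
#' (probabilities of 1, 2 or 3 simultaneous modes; the modes themselves
#' are chosen uniformly).  The study-scale default is 1014 correct and
#' 186 wrong clips.
#'
#' @param n_correct,n_wrong Nonnegative clip counts.
#' @param mixture Length-3 numeric summing to 1: probabilities of a
#'   wrong clip exhibiting 1, 2 or 3 simultaneous error modes.
#' @param seed Master seed.
#' @param ... Further arguments passed to [motion_spec()] (e.g.
#'   `duration`, `jitter_sd`).
#' @return A list with elements `clips` (list of `skeleton_clip`) and
#'   `labels` (tibble `clip_id`, `label`, `side`, `error_modes`).
#' @export
generate_dataset <- function(n_correct = 1014L, n_wrong = 186L,
                             mixture = c(0.6, 0.3, 0.1), seed = 1L, ...) {
  if (n_correct < 0 || n_wrong < 0) {
    abort("Clip counts must be nonnegative.",
          class = "reachgcn_invalid_argument")
  }
  if (length(mixture) != 3 || abs(sum(mixture) - 1) > 1e-8 || any(mixture < 0)) {
    abort("`mixture` must be 3 nonnegative weights summing to 1.",
          class = "reachgcn_invalid_argument")
  }
  n <- n_correct + n_wrong
  set.seed(seed)
  clip_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_modes <- sample(1:3, n_wrong, replace = TRUE, prob = mixture)
  all_modes <- c("knee_flexion", "wrist_not_extended",
                 "insufficient_lumbar_flexion")
  wrong_modes <- lapply(n_modes, function(k) sample(all_modes, k))
  modes_list <- c(rep(list(character()), n_correct), wrong_modes)

  clips <- purrr::map2(modes_list, seq_len(n), function(modes, i) {
    clip <- generate_clip(motion_spec(error_modes = modes,
                                      seed = clip_seeds[i], ...))
    clip$id <- sprintf("clip-%04d", i)
    clip
  })
  labels <- tibble::tibble(
    clip_id = purrr::map_chr(clips, "id"),
    label = purrr::map_chr(clips, "label"),
    side = purrr::map_chr(clips, "side"),
    error_modes = purrr::map_chr(modes_list,
                                 ~ paste(.x, collapse = "+"))
  )
  list(clips = clips, labels = labels)
}

#' Affine test-time augmentation
#'
#' Applies a 2D affine map (rotation, anisotropic scale, shear,
#' translation) to every keypoint coordinate of a clip or model-input
#' tensor, simulating shooting-angle and scale variation, and perturbs
#' confidences with a Gaussian draw of mean 0 and variance 0.05,
#' clipped back to `[0, 1]`.
#'
#' @param x A `skeleton_clip` or a `model_input` (see
#'   [to_model_input()]).
#' @param rotation Rotation in degrees.
#' @param scale Length-2 scale factors (x, y).
#' @param shear Shear coefficient (x gains `shear * y`).
#' @param translation Length-2 offset.
#' @param conf_variance Variance of the confidence perturbation; 0
#'   disables it.
#' @param seed Seed for the confidence noise.
#' @return An object of the same type as `x`.
#' @export
affine_augment <- function(x, rotation = 0, scale = c(1, 1), shear = 0,
                           translation = c(0, 0), conf_variance = 0.05,
                           seed = NULL) {
  if (length(scale) == 1) scale <- rep(scale, 2)
  th <- deg2rad(rotation)
  m <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
    matrix(c(scale[1], 0, shear, scale[2]), 2, 2)
  if (abs(det(m)) < 1e-12) {
    abort("Singular affine transform.", class = "reachgcn_invalid_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  perturb <- function(conf) {
    if (conf_variance <= 0) return(conf)
    pmin(pmax(conf + conf_noise(length(conf), conf_variance), 0), 1)
  }
  if (inherits(x, "skeleton_clip")) {
    xy <- cbind(x$frames$x, x$frames$y) %*% t(m)
    x$frames$x <- xy[, 1] + translation[1]
    x$frames$y <- xy[, 2] + translation[2]
    det_idx <- x$frames$detected
    x$frames$confidence[det_idx] <- perturb(x$frames$confidence[det_idx])
    x$plane <- NULL  # planar kinematics no longer represent this clip
    x
  } else if (inherits(x, "model_input")) {
    for (g in seq_along(x$tensors)) {
      a <- x$tensors[[g]]  # (N, C, T, V)
      xs <- a[, 1, , ]
      ys <- a[, 2, , ]
      a[, 1, , ] <- m[1, 1] * xs + m[1, 2] * ys + translation[1]
      a[, 2, , ] <- m[2, 1] * xs + m[2, 2] * ys + translation[2]
      a[, 3, , ] <- perturb(as.vector(a[, 3, , ]))
      x$tensors[[g]] <- a
    }
    x
  } else {
    abort("`x` must be a skeleton_clip or model_input.",
          class = "reachgcn_invalid_argument")
  }
}
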