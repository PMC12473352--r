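# Self-training loop for keypoint pseudo-labeling, with OKS evaluation.
#
# A detector is a plain list with two functions:
#   train(examples, state)  -> new model state
#   detect(state, frame)    -> tibble(keypoint, x, y, confidence, detected)
# `detect` must be deterministic given (state, frame); any internal
# randomness is derived from seeds carried in the state.

# deterministic uniform in [0,1) from integer-ish inputs (splitmix-style
# LCG on doubles; all intermediates stay below 2^53)
det_unif <- function(...) {
  parts <- list(...)
  s <- 0
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    s <- (s * 33 + sum(as.numeric(p))) %% 2^31
  }
  for (i in 1:3) s <- (s * 69069 + 12345) %% 2^32
  s / 2^32
}

# standard-normal-ish deterministic draw (Box-Muller on two det_unif)
det_norm <- function(...) {
  u1 <- det_unif(..., 1L)
  u2 <- det_unif(..., 2L)
  sqrt(-2 * log(max(u1, 1e-12))) * cos(2 * pi * u2)
}

#' Augment labeled keypoint frames by rotation and scaling
#'
#' Emits every example under every rotation x scale combination,
#' applied to the keypoint coordinates about the example's keypoint
#' centroid.  Grayscale transformation acts on pixels, not keypoints,
#' so it is recorded as a pass-through tag for image-capable detectors
#' rather than changing coordinates.
#'
#' @param examples A tibble with columns `frame_id`, `keypoint`, `x`,
#'   `y` (one row per labeled keypoint).
#' @param rotations Rotation angles in degrees.
#' @param scales Scale factors.
#' @param seed Unused by the deterministic coordinate transforms; kept
#'   so callers can thread one seed through the loop.
#' @return A tibble of `nrow(examples) * length(rotations) *
#'   length(scales)` rows with an extra `augmentation` column; carries
#'   attribute `grayscale = "passthrough"`.
#' @export
augment_labeled <- function(examples, rotations = c(-10, 0, 10),
                            scales = c(0.9, 1, 1.1), seed = NULL) {
  if (nrow(examples) == 0) {
    abort("`examples` must be non-empty.",
          class = "reachgcn_invalid_argument")
  }
  if (length(rotations) == 0 || length(scales) == 0) {
    warn("Empty transform list; returning examples unchanged.")
    return(examples)
  }
  centroids <- examples |>
    dplyr::group_by(.data$frame_id) |>
    dplyr::summarise(cx = mean(.data$x), cy = mean(.data$y),
                     .groups = "drop")
  ex <- dplyr::left_join(examples, centroids, by = "frame_id")
  combos <- tidyr::expand_grid(rot = rotations, sc = scales)
  out <- purrr::pmap(combos, function(rot, sc) {
    th <- rot * pi / 180
    dx <- ex$x - ex$cx
    dy <- ex$y - ex$cy
    tibble::tibble(
      frame_id = paste0(ex$frame_id, "|rot", rot, "|sc", sc),
      keypoint = ex$keypoint,
      x = ex$cx + sc * (cos(th) * dx - sin(th) * dy),
      y = ex$cy + sc * (sin(th) * dx + cos(th) * dy),
      augmentation = sprintf("rot%+g_sc%g", rot, sc)
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "grayscale") <- "passthrough"
  res
}

#' Object keypoint similarity between a prediction and ground truth
#'
#' `OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0]`
#' with `d_i` the Euclidean displacement of keypoint `i`, `s` the
#' object scale and `k_i` the per-keypoint falloff constant.  By
#' default `k_i = 0.1` uniformly and `s` is the square root of the
#' ground-truth bounding-box area (the COCO convention supplies no
#' constants for the fingertip/heel working set used here).
#'
#' @param predicted Tibble with columns `keypoint`, `x`, `y` (missing
#'   keypoints count as infinitely displaced).
#' @param truth Tibble with columns `keypoint`, `x`, `y` and optional
#'   `visibility` (> 0 means visible; default all visible).
#' @param scale Object scale `s`; `NULL` computes the bounding-box
#'   root-area of `truth`.
#' @param falloff Per-keypoint `k`: a single number or a vector named
#'   by keypoint index.
#' @return An `oks_result`: list with `oks`, `per_keypoint` tibble,
#'   `scale`, `falloff`.
#' @export
compute_oks <- function(predicted, truth, scale = NULL, falloff = 0.1) {
  vis <- if ("visibility" %in% names(truth)) truth$visibility > 0 else
    rep(TRUE, nrow(truth))
  if (!any(vis)) {
    abort("OKS undefined: no visible ground-truth keypoints.",
          class = "reachgcn_undefined_result")
  }
  if (is.null(scale)) {
    scale <- sqrt(diff(range(truth$x[vis])) * diff(range(truth$y[vis])))
    if (scale <= 0) scale <- 1e-6
  }
  k <- if (length(falloff) == 1) {
    rep(falloff, nrow(truth))
  } else {
    unname(falloff[as.character(truth$keypoint)])
  }
  m <- match(truth$keypoint, predicted$keypoint)
  dx <- predicted$x[m] - truth$x
  dy <- predicted$y[m] - truth$y
  d2 <- dx^2 + dy^2
  d2[is.na(d2)] <- Inf
  sim <- exp(-d2 / (2 * scale^2 * k^2))
  per <- tibble::tibble(
    keypoint = truth$keypoint, visible = vis,
    displacement = sqrt(d2), similarity = sim
  )
  structure(
    list(oks = sum(sim[vis]) / sum(vis), per_keypoint = per,
         scale = scale, falloff = k),
    class = "oks_result"
  )
}

#' @export
print.oks_result <- function(x, ...) {
  cat(sprintf("<oks_result> OKS = %.4f over %d visible keypoints (s = %.4g)\n",
              x$oks, sum(x$per_keypoint$visible), x$scale))
  invisible(x)
}

#' Bundled simulated keypoint detector
#'
#' A detector whose per-keypoint detection probability and localization
#' accuracy grow with the coverage of its training pool, emulating how
#' retraining on more (pseudo-)labels improves a real detector.  All of
#' its draws are deterministic functions of `(seed, frame_id,
#' keypoint)`, so the whole self-training loop is reproducible
#' bit-for-bit.
#'
#' Detection probability for keypoint `j` after training on `c_j`
#' examples is `base_j + (ceiling_j - base_j) * c_j / (c_j + half_sat)`;
#' localization noise shrinks proportionally to the same saturation.
#'
#' @param base Named (by joint difficulty tier) or single baseline
#'   detection probability for untrained keypoints; default 0.45 for
#'   the occlusion-prone fingertip and heel, 0.8 otherwise.
#' @param ceiling Asymptotic detection probability (default 0.97).
#' @param half_sat Training-pool size at which half the possible gain
#'   is realized (default 50 examples per keypoint).
#' @param noise_sd Base localization noise, normalized units (default
#'   0.03).
#' @param seed Integer seed folded into every deterministic draw.
#' @return A detector interface list with elements `train`, `detect`,
#'   `init_state`.
#' @export
simulated_detector <- function(base = NULL, ceiling = 0.97, half_sat = 50,
                               noise_sd = 0.03, seed = 1L) {
  default_base <- function(kp) {
    hard <- c(right_side_keypoints[c("index", "heel")],
              left_side_keypoints[c("index", "heel")])
    ifelse(kp %in% hard, 0.45, 0.8)
  }
  list(
    init_state = function() {
      list(coverage = numeric(0), seed = as.integer(seed))
    },
    train = function(examples, state) {
      cov <- table(examples$keypoint)
      state$coverage <- setNames(as.numeric(cov), names(cov))
      state
    },
    detect = function(state, frame) {
      kp <- frame$keypoint
      cov <- state$coverage[as.character(kp)]
      cov[is.na(cov)] <- 0
      b <- if (is.null(base)) default_base(kp) else rep(base, length(kp))[seq_along(kp)]
      sat <- cov / (cov + half_sat)
      p <- b + (ceiling - b) * sat
      fid <- frame$frame_id[1]
      u <- vapply(kp, function(j) det_unif(state$seed, fid, j), numeric(1))
      detected <- u < p
      nx <- vapply(kp, function(j) det_norm(state$seed, fid, j, 11L), numeric(1))
      ny <- vapply(kp, function(j) det_norm(state$seed, fid, j, 22L), numeric(1))
      sd_eff <- noise_sd * (1 - 0.8 * sat)
      tibble::tibble(
        keypoint = kp,
        x = frame$x + nx * sd_eff,
        y = frame$y + ny * sd_eff,
        confidence = pmin(pmax(0.35 + 0.6 * p + 0.05 * (u - 0.5), 0), 1),
        detected = detected
      )
    }
  )
}

#' Run the keypoint self-training loop
#'
#' Per round: (1) augment the labeled + pseudo-labeled pools by
#' rotation/scaling, (2) retrain the detector, (3) detect on every
#' unlabeled frame, (4) promote to the pseudo pool each frame holding
#' at least one keypoint detected (confidence at or above `tau`) at a
#' (frame, keypoint) slot never detected in any earlier round, and (5)
#' stop when a round finds no new keypoint, or at `max_rounds`.
#'
#' @param detector A detector interface (see [simulated_detector()]).
#' @param labeled Ground-truth pool: tibble `frame_id`, `keypoint`,
#'   `x`, `y`.
#' @param unlabeled Unlabeled frames in the same layout (their
#'   coordinates are the scene content handed to `detect`, never used
#'   as labels directly).
#' @param max_rounds Hard cap on rounds (default 10).
#' @param tau Confidence threshold for a detection to count as a new
#'   keypoint (default 0.5).
#' @param rotations,scales Augmentation grids for [augment_labeled()].
#' @param holdout Optional labeled tibble (same layout) on which mean
#'   OKS is logged each round.
#' @param seed Seed threaded through augmentation.
#' @return A `self_train_state`: list with `round` (rounds run),
#'   `labeled`, `pseudo` (promoted pool), `log` (per-round tibble:
#'   `round`, `new_keypoints`, `n_labeled`, `n_pseudo_frames`,
#'   `n_pseudo_rows`, `holdout_oks`), `stopped` (TRUE iff the final
#'   round added zero new keypoints), and the final `state`.
#' @export
run_self_train <- function(detector, labeled, unlabeled, max_rounds = 10L,
                           tau = 0.5, rotations = c(-10, 0, 10),
                           scales = c(0.9, 1, 1.1), holdout = NULL,
                           seed = 1L) {
  if (nrow(labeled) == 0) {
    abort("The labeled pool must be non-empty.",
          class = "reachgcn_invalid_argument")
  }
  state <- detector$init_state()
  seen <- character(0)       # "(frame_id|keypoint)" slots ever detected
  pseudo <- labeled[0, ]
  log_rows <- list()
  stopped <- FALSE
  frames_split <- split(unlabeled, unlabeled$frame_id)
  round <- 0L
  holdout_frames <- if (!is.null(holdout)) split(holdout, holdout$frame_id)

  while (round < max_rounds) {
    round <- round + 1L
    pool <- dplyr::bind_rows(labeled, pseudo[, names(labeled)])
    aug <- augment_labeled(pool, rotations, scales, seed = seed)
    state <- tryCatch(
      detector$train(aug, state),
      error = function(e) {
        abort(sprintf("Detector training failed in round %d: %s",
                      round, conditionMessage(e)),
              class = "reachgcn_detector_error", parent = e)
      }
    )
    new_count <- 0L
    promoted <- list()
    for (fid in names(frames_split)) {
      det <- detector$detect(state, frames_split[[fid]])
      hits <- det$detected & det$confidence >= tau
      kp_hit <- det$keypoint[hits]
      slots <- if (length(kp_hit) > 0) paste(fid, kp_hit, sep = "|") else
        character(0)
      fresh <- setdiff(slots, seen)
      if (length(fresh) > 0) {
        new_count <- new_count + length(fresh)
        seen <- c(seen, fresh)
        # first promotion takes the whole frame's detections; later
        # rounds append only the newly detected keypoints of that frame
        keep <- if (fid %in% pseudo$frame_id) slots %in% fresh else
          rep(TRUE, sum(hits))
        hk <- which(hits)[keep]
        promoted[[paste0(fid, "@", round)]] <- tibble::tibble(
          frame_id = fid,
          keypoint = det$keypoint[hk],
          x = det$x[hk], y = det$y[hk]
        )
      }
    }
    pseudo <- dplyr::bind_rows(pseudo, dplyr::bind_rows(promoted))
    oks_mean <- NA_real_
    if (!is.null(holdout)) {
      vals <- vapply(holdout_frames, function(fr) {
        det <- detector$detect(state, fr)
        compute_oks(det[det$detected, ], fr)$oks
      }, numeric(1))
      oks_mean <- mean(vals)
    }
    log_rows[[round]] <- tibble::tibble(
      round = round, new_keypoints = new_count,
      n_labeled = length(unique(labeled$frame_id)),
      n_pseudo_frames = length(unique(pseudo$frame_id)),
      n_pseudo_rows = nrow(pseudo),
      holdout_oks = oks_mean
    )
    if (new_count == 0L) {
      stopped <- TRUE
      break
    }
  }
  structure(
    list(round = round, labeled = labeled, pseudo = pseudo,
         log = dplyr::bind_rows(log_rows), stopped = stopped,
         state = state),
    class = "self_train_state"
  )
}

#' @export
print.self_train_state <- function(x, ...) {
  cat("<self_train_state>", x$round, "rounds,",
      length(unique(x$pseudo$frame_id)), "pseudo-labeled frames,",
      if (x$stopped) "converged" else "hit max_rounds", "\n")
  invisible(x)
}

#' Extract per-frame labeled pools from synthetic clips
#'
#' Helper turning `skeleton_clip` frames into the flat
#' (`frame_id`, `keypoint`, `x`, `y`) layout the self-training loop
#' uses, subsampling every `stride`-th frame.
#'
#' @param clips List of `skeleton_clip` objects.
#' @param stride Keep every `stride`-th frame (default 25, one per
#'   second).
#' @return A tibble `frame_id`, `keypoint`, `x`, `y`.
#' @export
clips_to_frame_pool <- function(clips, stride = 25L) {
  rows <- purrr::map(clips, function(clip) {
    keep <- clip$frames$frame %% stride == 0
    sub <- clip$frames[keep, ]
    tibble::tibble(
      frame_id = paste0(clip$id, "#", sub$frame),
      keypoint = sub$keypoint,
      x = sub$x, y = sub$y
    )
  })
  dplyr::bind_rows(rows)
}
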