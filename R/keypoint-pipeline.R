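#' Select one representative frame per segment
#'
#' Partitions the raw frames of a clip into `n_segments` equal spans
#' (segment `i`, counted from 0, covers raw positions
#' `[floor(i*L/n), floor((i+1)*L/n))` over the `L` frames in order) and
#' picks, within each span, the frame with the highest aggregate
#' confidence over the seven working keypoints, undetected keypoints
#' contributing 0.  Ties break to the earliest frame.
#'
#' @param clip A `skeleton_clip`.
#' @param n_segments Number of segments (default 60, the model's
#'   temporal length).
#' @return An integer vector of `n_segments` frame numbers, strictly
#'   increasing.
#' @export
select_frames <- function(clip, n_segments = 60L) {
  frame_ids <- sort(unique(clip$frames$frame))
  l <- length(frame_ids)
  if (l < n_segments) {
    abort(sprintf("Clip has %d frames; at least %d required.", l, n_segments),
          class = "reachgcn_invalid_argument")
  }
  agg <- clip$frames |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      score = sum(ifelse(.data$detected, .data$confidence, 0)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$frame)
  score <- agg$score
  i <- 0:(n_segments - 1L)
  lo <- floor(i * l / n_segments) + 1L        # 1-based positions
  hi <- floor((i + 1L) * l / n_segments)
  picks <- vapply(seq_len(n_segments), function(s) {
    span <- lo[s]:hi[s]
    span[which.max(score[span])]              # which.max = earliest tie
  }, integer(1))
  frame_ids[picks]
}

#' Fill in undetected keypoints by linear interpolation
#'
#' For each selected frame and each working keypoint that was not
#' detected there, coordinates are interpolated linearly in raw
#' frame-index time between the nearest earlier and nearest later
#' frames of the full clip where that keypoint was detected.  At clip
#' boundaries the single nearest detection is copied.  The filled-in
#' confidence is the mean of the two donors (or the single donor's
#' value).  Frames that were already complete are returned bit-for-bit
#' unchanged.
#'
#' @param clip A `skeleton_clip` (the full clip; donors may come from
#'   unselected frames).
#' @param selected Frame numbers to complete, e.g. from
#'   [select_frames()]; defaults to all frames.
#' @return A tibble shaped like `clip$frames`, restricted to the
#'   selected frames, with `detected` reporting the original detection
#'   flag and no missing coordinates.
#' @export
interpolate_missing <- function(clip, selected = NULL) {
  fr <- clip$frames
  if (is.null(selected)) selected <- sort(unique(fr$frame))
  out <- fr[fr$frame %in% selected, ]
  for (kp in unique(fr$keypoint)) {
    kp_all <- fr[fr$keypoint == kp, ]
    donors <- kp_all[kp_all$detected, ]
    if (nrow(donors) == 0) {
      abort(sprintf("Keypoint %s was never detected in clip %s.",
                    kp, clip$id),
            class = "reachgcn_never_detected")
    }
    miss <- which(out$keypoint == kp & !out$detected)
    if (length(miss) == 0) next
    tmiss <- out$frame[miss]
    # nearest earlier / later donor in raw frame time
    prev_idx <- findInterval(tmiss, donors$frame)
    next_idx <- pmin(prev_idx + 1L, nrow(donors))
    has_prev <- prev_idx >= 1L
    prev_idx <- pmax(prev_idx, 1L)
    t0 <- donors$frame[prev_idx]; t1 <- donors$frame[next_idx]
    w <- ifelse(t1 == t0, 0, (tmiss - t0) / (t1 - t0))
    w <- ifelse(!has_prev, 1, w)               # before first donor: copy it
    out$x[miss] <- (1 - w) * donors$x[prev_idx] + w * donors$x[next_idx]
    out$y[miss] <- (1 - w) * donors$y[prev_idx] + w * donors$y[next_idx]
    both <- has_prev & t1 > tmiss
    out$confidence[miss] <- ifelse(
      both,
      (donors$confidence[prev_idx] + donors$confidence[next_idx]) / 2,
      ifelse(has_prev, donors$confidence[prev_idx],
             donors$confidence[next_idx])
    )
  }
  out
}

#' Lay out completed frames as model-input tensors
#'
#' Converts 60 completed frames into one `(C = 3, T = 60, V = 4)` array
#' per keypoint group, channels being (x, y, confidence) and the joint
#' axis following the group's chain order.  [stack_model_inputs()]
#' batches several clips along a leading N axis, giving the
#' `(N, C, T, V, M)` layout with `M = 1` person.
#'
#' @param completed A tibble from [interpolate_missing()] with exactly
#'   `n_frames` distinct frames.
#' @param groups Keypoint groups from [group_keypoints()].
#' @param n_frames Expected temporal length (default 60).
#' @return A `model_input` object: list with `tensors` (list of
#'   `(1, 3, T, V)` arrays, one per group), `group_names`, `clip_ids`.
#' @export
to_model_input <- function(completed, groups, n_frames = 60L) {
  frames <- sort(unique(completed$frame))
  if (length(frames) != n_frames) {
    abort(sprintf("Expected %d frames, got %d.", n_frames, length(frames)),
          class = "reachgcn_shape_error")
  }
  if (anyNA(completed$x) || anyNA(completed$y) || anyNA(completed$confidence)) {
    abort("Completed frames contain missing values; run interpolate_missing().",
          class = "reachgcn_shape_error")
  }
  tensors <- purrr::map(groups, function(g) {
    a <- array(NA_real_, dim = c(1, 3, n_frames, 4))
    for (v in seq_along(g$members)) {
      sub <- completed[completed$keypoint == g$members[v], ]
      sub <- sub[order(sub$frame), ]
      if (nrow(sub) != n_frames) {
        abort(sprintf("Keypoint %d missing from completed frames.",
                      g$members[v]),
              class = "reachgcn_shape_error")
      }
      a[1, 1, , v] <- sub$x
      a[1, 2, , v] <- sub$y
      a[1, 3, , v] <- sub$confidence
    }
    a
  })
  structure(
    list(tensors = unname(tensors),
         group_names = purrr::map_chr(groups, "name"),
         clip_ids = NA_character_),
    class = "model_input"
  )
}

#' @rdname to_model_input
#' @param inputs A list of single-clip `model_input` objects.
#' @param clip_ids Optional character vector of clip identifiers.
#' @export
stack_model_inputs <- function(inputs, clip_ids = NULL) {
  n_groups <- length(inputs[[1]]$tensors)
  tensors <- purrr::map(seq_len(n_groups), function(g) {
    mats <- purrr::map(inputs, function(mi) mi$tensors[[g]])
    d <- dim(mats[[1]])
    out <- array(NA_real_, dim = c(length(mats), d[2], d[3], d[4]))
    for (i in seq_along(mats)) out[i, , , ] <- mats[[i]][1, , , ]
    out
  })
  structure(
    list(tensors = tensors,
         group_names = inputs[[1]]$group_names,
         clip_ids = clip_ids %||% rep(NA_character_, length(inputs))),
    class = "model_input"
  )
}

#' @export
print.model_input <- function(x, ...) {
  d <- dim(x$tensors[[1]])
  cat("<model_input>", length(x$tensors), "groups; per-group tensor (N,C,T,V,M) =",
      paste0("(", d[1], ",", d[2], ",", d[3], ",", d[4], ",1)"), "\n")
  invisible(x)
}

#' Run the full clip-to-tensor pipeline
#'
#' Convenience wrapper: frame selection, interpolation of undetected
#' keypoints, and tensor layout, for a list of clips.
#'
#' @param clips A list of `skeleton_clip` objects.
#' @param groups Keypoint groups; defaults to the grouping for each
#'   clip's own side.
#' @param n_frames Temporal length (default 60).
#' @return A batched `model_input` with `clip_ids` set.
#' @export
clips_to_model_input <- function(clips, groups = NULL, n_frames = 60L) {
  inputs <- purrr::map(clips, function(clip) {
    g <- groups %||% group_keypoints(
      if (clip$side == "right") right_side_keypoints else left_side_keypoints)
    sel <- select_frames(clip, n_frames)
    comp <- interpolate_missing(clip, sel)
    to_model_input(comp, g, n_frames)
  })
  stack_model_inputs(inputs, clip_ids = purrr::map_chr(clips, "id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write the repo-standard keypoint JSONL format
#'
#' One JSON object per line, one line per frame:
#' `{"frame": <int>, "kp": {"<index>": [x, y, confidence], ...}}`;
#' absent indices mean the keypoint was undetected in that frame.
#' Clip-level labels travel in a sidecar CSV with columns
#' `clip_id,label,side`.
#'
#' @param clip A `skeleton_clip`.
#' @param path Output / input file path.
#' @param digits Significant digits written (default 6; writers are
#'   bit-stable given identical input).
#' @return `write_keypoints_jsonl()` returns `path` invisibly;
#'   `read_keypoints_jsonl()` returns a `skeleton_clip` (label and side
#'   taken from arguments, since the JSONL carries geometry only).
#' @export
write_keypoints_jsonl <- function(clip, path, digits = 6) {
  fr <- clip$frames[clip$frames$detected, ]
  lines <- vapply(sort(unique(clip$frames$frame)), function(t) {
    sub <- fr[fr$frame == t, ]
    kp <- setNames(
      lapply(seq_len(nrow(sub)), function(i) {
        round(c(sub$x[i], sub$y[i], sub$confidence[i]), digits)
      }),
      as.character(sub$keypoint)
    )
    jsonlite::toJSON(list(frame = t, kp = kp), auto_unbox = TRUE,
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_keypoints_jsonl
#' @param id,side,label,fps Clip attributes not stored in the JSONL.
#' @export
read_keypoints_jsonl <- function(path, id = basename(path), side = "right",
                                 label = "unlabeled", fps = 25) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  frame_no <- vapply(recs, function(r) as.integer(r$frame), integer(1))
  if (any(diff(frame_no) <= 0)) {
    abort("Frame indices must be strictly increasing.",
          class = "reachgcn_invalid_argument")
  }
  rows <- purrr::map2(recs, frame_no, function(r, t) {
    if (length(r$kp) == 0) return(NULL)
    tibble::tibble(
      frame = t,
      keypoint = as.integer(names(r$kp)),
      x = unname(vapply(r$kp, `[`, numeric(1), 1)),
      y = unname(vapply(r$kp, `[`, numeric(1), 2)),
      confidence = unname(vapply(r$kp, `[`, numeric(1), 3)),
      detected = TRUE
    )
  })
  detected <- dplyr::bind_rows(rows)
  # reinstate undetected slots for the side's working set
  kp_set <- if (side == "right") right_side_keypoints else left_side_keypoints
  full <- tidyr::expand_grid(frame = frame_no, keypoint = unname(kp_set)) |>
    dplyr::left_join(detected, by = c("frame", "keypoint")) |>
    dplyr::mutate(detected = !is.na(.data$x)) |>
    dplyr::arrange(.data$frame, .data$keypoint)
  joint_names <- names(kp_set)[match(full$keypoint, kp_set)]
  full$joint <- joint_names
  full <- full[, c("frame", "keypoint", "joint", "x", "y", "confidence",
                   "detected")]
  structure(
    list(id = id, side = side, fps = fps, label = label,
         error_modes = character(), metadata = list(), frames = full),
    class = "skeleton_clip"
  )
}

#' @rdname write_keypoints_jsonl
#' @param labels A tibble with columns `clip_id`, `label`, `side`.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels[, c("clip_id", "label", "side")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_keypoints_jsonl
#' @export
read_labels_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
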