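test_that("frame selection picks the top-confidence frame per segment", {
  # 1500 frames -> 60 blocks of 25; plant a confidence spike per block
  spikes <- sapply(0:59, function(i) 25 * i + (i %% 25))
  clip <- make_toy_clip(1500, conf = function(t, kp) {
    if (t %in% spikes) 0.99 else 0.5
  })
  sel <- select_frames(clip)
  expect_length(sel, 60)
  expect_equal(sel, spikes)
  expect_true(all(diff(sel) > 0))
  expect_true(all(sel %/% 25 == 0:59))        # one per block of 25

  # ties break to the segment start
  flat <- make_toy_clip(300, conf = function(t, kp) 0.7)
  sel_flat <- select_frames(flat)
  expect_equal(sel_flat, floor((0:59) * 300 / 60))

  # 750 frames: floor boundaries give alternating 12/13 segments
  clip750 <- make_toy_clip(750, conf = function(t, kp) 0.7)
  sel750 <- select_frames(clip750)
  expect_length(sel750, 60)
  expect_true(all(diff(sel750) > 0))
  starts <- floor((0:59) * 750 / 60)
  expect_equal(sel750, starts)
  expect_setequal(unique(diff(starts)), c(12, 13))

  # undetected keypoints contribute zero to the aggregate score
  clip_miss <- make_toy_clip(120,
    conf = function(t, kp) if (t %% 2 == 0) 0.99 else 0.6,
    detected = function(t, kp) t %% 2 == 1)
  sel_miss <- select_frames(clip_miss)
  expect_true(all(sel_miss %% 2 == 1))

  expect_error(select_frames(make_toy_clip(30)),
               class = "reachgcn_invalid_argument")
})

test_that("interpolation is linear in raw frame time with boundary copies", {
  # keypoint 16 missing at t = 5, donors at 4 and 6
  clip <- make_toy_clip(20, vx = 0, vy = 0,
    detected = function(t, kp) !(kp == 16 && t == 5))
  clip$frames$x[clip$frames$keypoint == 16 & clip$frames$frame == 4] <- 0
  clip$frames$y[clip$frames$keypoint == 16 & clip$frames$frame == 4] <- 0
  clip$frames$x[clip$frames$keypoint == 16 & clip$frames$frame == 6] <- 2
  clip$frames$y[clip$frames$keypoint == 16 & clip$frames$frame == 6] <- 2
  comp <- interpolate_missing(clip, 0:19)
  row <- comp[comp$keypoint == 16 & comp$frame == 5, ]
  expect_equal(c(row$x, row$y), c(1, 1))

  # asymmetric donors at t-1 and t+3: weights 3:1
  clip2 <- make_toy_clip(20, vx = 0, vy = 0,
    detected = function(t, kp) !(kp == 20 && t %in% 5:7))
  sel <- clip2$frames$keypoint == 20
  clip2$frames$x[sel & clip2$frames$frame == 4] <- 0
  clip2$frames$y[sel & clip2$frames$frame == 4] <- 0
  clip2$frames$x[sel & clip2$frames$frame == 8] <- 4
  clip2$frames$y[sel & clip2$frames$frame == 8] <- 0
  comp2 <- interpolate_missing(clip2, 0:19)
  row2 <- comp2[comp2$keypoint == 20 & comp2$frame == 5, ]
  expect_equal(c(row2$x, row2$y), c(1, 0))

  # boundary: earliest detection copied backwards
  clip3 <- make_toy_clip(20, detected = function(t, kp)
    !(kp == 30 && t < 7))
  comp3 <- interpolate_missing(clip3, 0:19)
  donor <- clip3$frames[clip3$frames$keypoint == 30 &
                          clip3$frames$frame == 7, ]
  first <- comp3[comp3$keypoint == 30 & comp3$frame == 0, ]
  expect_equal(c(first$x, first$y), c(donor$x, donor$y))
  expect_equal(first$confidence, donor$confidence)

  # a keypoint never detected is an explicit failure naming the clip
  clip4 <- make_toy_clip(20, detected = function(t, kp) kp != 26,
                         id = "clip-xyz")
  expect_error(interpolate_missing(clip4, 0:19),
               class = "reachgcn_never_detected")
  expect_error(interpolate_missing(clip4, 0:19), "clip-xyz")
})

test_that("complete frames pass through interpolation bit-unchanged", {
  clip <- make_toy_clip(200, conf = function(t, kp) 0.5 + 0.001 * t)
  sel <- select_frames(clip)
  comp <- interpolate_missing(clip, sel)
  orig <- clip$frames[clip$frames$frame %in% sel, ]
  expect_identical(comp$x, orig$x)
  expect_identical(comp$y, orig$y)
  expect_identical(comp$confidence, orig$confidence)
})

test_that("interpolation is exact for straight-line constant-velocity motion", {
  set.seed(77)
  for (rep in 1:5) {
    miss_p <- runif(1, 0.1, 0.5)
    mask <- matrix(runif(120 * 7) > miss_p, 120, 7)
    mask[1, ] <- TRUE; mask[120, ] <- TRUE    # keep donors at both ends
    kps <- unname(right_side_keypoints)
    clip <- make_toy_clip(120, vx = 0.02, vy = 0.01,
      detected = function(t, kp) mask[t + 1, match(kp, kps)])
    comp <- interpolate_missing(clip, 0:119)
    j <- match(comp$keypoint, kps)
    expect_equal(comp$x, j + comp$frame * 0.02, tolerance = 1e-12)
    expect_equal(comp$y, 2 * j - comp$frame * 0.01, tolerance = 1e-12)
  }
})

test_that("model-input layout is (N, 3, 60, 4, 1) per group and round-trips", {
  clip <- make_toy_clip(240)
  groups <- group_keypoints(right_side_keypoints)
  sel <- select_frames(clip)
  comp <- interpolate_missing(clip, sel)
  mi <- to_model_input(comp, groups)
  expect_length(mi$tensors, 3)
  expect_equal(dim(mi$tensors[[1]]), c(1, 3, 60, 4))
  expect_false(any(vapply(mi$tensors, anyNA, logical(1))))

  # round trip: tensor values equal the completed-frame records, in
  # the group's chain order
  for (g in 1:3) {
    for (v in 1:4) {
      kp <- groups[[g]]$members[v]
      sub <- comp[comp$keypoint == kp, ]
      sub <- sub[order(sub$frame), ]
      expect_equal(mi$tensors[[g]][1, 1, , v], sub$x)
      expect_equal(mi$tensors[[g]][1, 2, , v], sub$y)
      expect_equal(mi$tensors[[g]][1, 3, , v], sub$confidence)
    }
  }

  # batching stacks along N
  batch <- stack_model_inputs(rep(list(mi), 8))
  expect_equal(dim(batch$tensors[[1]]), c(8, 3, 60, 4))

  expect_error(to_model_input(comp[comp$frame != sel[1], ], groups),
               class = "reachgcn_shape_error")
})

test_that("JSONL keypoint files and label CSVs round-trip", {
  clip <- make_toy_clip(50, detected = function(t, kp)
    !(kp == 20 && t %% 7 == 0))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_keypoints_jsonl(clip, path)
  back <- read_keypoints_jsonl(path, id = "toy", side = "right")
  a <- clip$frames[clip$frames$detected, ]
  b <- back$frames[back$frames$detected, ]
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$x, a$x, tolerance = 1e-6)
  expect_equal(b$y, a$y, tolerance = 1e-6)
  expect_equal(b$keypoint, a$keypoint)
  # undetected slots are reinstated as undetected
  expect_equal(sum(!back$frames$detected), sum(!clip$frames$detected))

  # writer is bit-stable
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_keypoints_jsonl(clip, path2)
  expect_identical(readLines(path), readLines(path2))

  labels <- tibble::tibble(clip_id = c("a", "b"),
                           label = c("correct", "wrong"),
                           side = c("right", "left"))
  lpath <- withr::local_tempfile(fileext = ".csv")
  write_labels_csv(labels, lpath)
  expect_equal(read_labels_csv(lpath), labels)
})
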