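test_that("clip shape follows the recording convention", {
  expect_equal(nrow(generate_clip(motion_spec(duration = 60, seed = 3))$frames) / 7,
               1500)
  expect_equal(nrow(generate_clip(motion_spec(duration = 30, seed = 3))$frames) / 7,
               750)
  # unspecified duration lands in [750, 1500] frames
  n <- nrow(generate_clip(motion_spec(seed = 9))$frames) / 7
  expect_gte(n, 750); expect_lte(n, 1500)
  expect_error(motion_spec(error_modes = "bad_mode"),
               class = "reachgcn_invalid_argument")
})

test_that("the generator is a pure function of its spec", {
  s <- motion_spec(duration = 32, error_modes = "knee_flexion", seed = 42)
  expect_identical(generate_clip(s), generate_clip(s))
  d1 <- generate_dataset(5, 3, seed = 8, duration = 30)
  d2 <- generate_dataset(5, 3, seed = 8, duration = 30)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$clips[[4]]$frames, d2$clips[[4]]$frames)
})

test_that("correctness contract holds at the maximum-reach frame", {
  for (seed in c(5, 17, 23)) {
    clip <- generate_clip(motion_spec(duration = 30, seed = seed),
                          keep_plane = TRUE)
    ang <- clip_angles(clip, use_plane = TRUE)
    at <- ang[ang$frame == max_reach_frame(clip, use_plane = TRUE), ]
    expect_gte(at$knee_angle, 175)
    expect_lte(at$wrist_deviation, 5)
    expect_lte(at$hip_flexion, 50)
  }
})

test_that("each error mode violates exactly its own clause, by its margin", {
  modes <- c("knee_flexion", "wrist_not_extended",
             "insufficient_lumbar_flexion")
  for (seed in c(4, 31)) {
    ref <- generate_clip(motion_spec(duration = 30, seed = seed),
                         keep_plane = TRUE)
    ang_ref <- clip_angles(ref, use_plane = TRUE)
    at_ref <- ang_ref[ang_ref$frame == max_reach_frame(ref, use_plane = TRUE), ]
    for (mode in modes) {
      clip <- generate_clip(motion_spec(duration = 30, error_modes = mode,
                                        seed = seed), keep_plane = TRUE)
      expect_equal(clip$label, "wrong")
      ang <- clip_angles(clip, use_plane = TRUE)
      at <- ang[ang$frame == max_reach_frame(clip, use_plane = TRUE), ]
      if (mode == "knee_flexion") {
        expect_lte(at$knee_angle, 160)          # same-seed correct >= 175
        expect_gte(at_ref$knee_angle, 175)
        expect_lte(at$wrist_deviation, 5)       # other clauses untouched
        expect_lte(at$hip_flexion, 50)
      } else if (mode == "wrist_not_extended") {
        expect_gte(at$wrist_deviation, 25)
        expect_gte(at$knee_angle, 175)
        expect_lte(at$hip_flexion, 50)
      } else {
        expect_gte(at$hip_flexion, 70)
        expect_gte(at$knee_angle, 175)
        expect_lte(at$wrist_deviation, 5)
      }
    }
    # combined modes violate all named clauses at once
    all3 <- generate_clip(motion_spec(duration = 30, error_modes = modes,
                                      seed = seed), keep_plane = TRUE)
    ang3 <- clip_angles(all3, use_plane = TRUE)
    at3 <- ang3[ang3$frame == max_reach_frame(all3, use_plane = TRUE), ]
    expect_lte(at3$knee_angle, 160)
    expect_gte(at3$wrist_deviation, 25)
    expect_gte(at3$hip_flexion, 70)
  }
})

test_that("bone lengths are conserved across frames before projection", {
  clip <- generate_clip(motion_spec(duration = 30, seed = 12,
                                    error_modes = "knee_flexion"),
                        keep_plane = TRUE)
  p <- clip$plane
  bones <- list(c("shoulder", "elbow"), c("elbow", "wrist"),
                c("wrist", "index"), c("hip", "shoulder"),
                c("hip", "knee"), c("knee", "heel"))
  for (b in bones) {
    len <- sqrt(rowSums((p[, , b[1]] - p[, , b[2]])^2))
    expect_lt(max(len) - min(len), 1e-9)
  }
})

test_that("dataset generation respects counts, labels and mixtures", {
  ds <- generate_dataset(7, 5, seed = 5, duration = 30)
  expect_length(ds$clips, 12)
  expect_equal(sum(ds$labels$label == "correct"), 7)
  expect_equal(sum(ds$labels$label == "wrong"), 5)
  n_modes <- lengths(strsplit(ds$labels$error_modes[ds$labels$label == "wrong"],
                              "\\+"))
  expect_true(all(n_modes >= 1 & n_modes <= 3))

  ds0 <- generate_dataset(0, 4, seed = 5, duration = 30)
  expect_true(all(ds0$labels$label == "wrong"))

  expect_error(generate_dataset(2, 2, mixture = c(0.5, 0.4, 0.2)),
               class = "reachgcn_invalid_argument")
  expect_error(generate_dataset(-1, 2), class = "reachgcn_invalid_argument")
})

test_that("a scripted angle rule separates the two classes", {
  ds <- generate_dataset(50, 50, seed = 99, duration = 30)
  preds <- vapply(ds$clips, rule_classify, character(1))
  expect_gte(mean(preds == ds$labels$label), 0.95)
})

test_that("affine augmentation is a controlled isometry-or-not transform", {
  clip <- generate_clip(motion_spec(duration = 30, seed = 2))
  # identity transform with zero confidence noise: unchanged
  same <- affine_augment(clip, conf_variance = 0)
  expect_equal(same$frames$x, clip$frames$x)
  expect_equal(same$frames$y, clip$frames$y)
  expect_equal(same$frames$confidence, clip$frames$confidence)

  # pure translation preserves all inter-keypoint distances
  tr <- affine_augment(clip, translation = c(0.3, -0.2), conf_variance = 0)
  f0 <- clip$frames[clip$frames$frame == 100, ]
  f1 <- tr$frames[tr$frames$frame == 100, ]
  expect_equal(as.vector(dist(cbind(f1$x, f1$y))),
               as.vector(dist(cbind(f0$x, f0$y))),
               tolerance = 1e-12)

  # rotation by theta then -theta restores coordinates
  r1 <- affine_augment(clip, rotation = 37, conf_variance = 0)
  r2 <- affine_augment(r1, rotation = -37, conf_variance = 0)
  expect_equal(r2$frames$x, clip$frames$x, tolerance = 1e-9)
  expect_equal(r2$frames$y, clip$frames$y, tolerance = 1e-9)

  expect_error(affine_augment(clip, scale = c(0, 1)),
               class = "reachgcn_invalid_argument")
})

test_that("confidence perturbation draws have mean 0 and variance 0.05", {
  set.seed(123)
  draws <- reachgcn:::conf_noise(1e5, 0.05)
  se_mean <- sqrt(0.05 / 1e5)
  expect_lt(abs(mean(draws)), 3 * se_mean)
  se_var <- 0.05 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(draws) - 0.05), 3 * se_var)
})

test_that("augmented model inputs keep confidences in [0, 1]", {
  ds <- generate_dataset(2, 1, seed = 3, duration = 30)
  x <- clips_to_model_input(ds$clips)
  xa <- affine_augment(x, rotation = 5, scale = c(1.05, 0.95), seed = 1)
  for (g in 1:3) {
    expect_true(all(xa$tensors[[g]][, 3, , ] >= 0 &
                      xa$tensors[[g]][, 3, , ] <= 1))
    expect_equal(dim(xa$tensors[[g]]), dim(x$tensors[[g]]))
  }
})
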