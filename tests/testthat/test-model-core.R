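test_that("spatial graph convolution matches hand-evaluated cases", {
  # 1-node graph: A_hat = [[1]], identity weights -> identity map
  h1 <- array(rnorm(2 * 5 * 1), c(2, 5, 1))
  expect_equal(gcn_forward(h1, build_chain_graph(1), diag(2)), h1)

  # 2-node chain: all degrees 2, A_hat entries 0.5; values (1, 3),
  # unit weight, ReLU -> both nodes 0.5 * (1 + 3) = 2
  h2 <- array(c(1, 3), c(1, 1, 2))
  o2 <- gcn_forward(h2, build_chain_graph(2), matrix(1, 1, 1),
                    function(z) pmax(z, 0))
  expect_equal(as.vector(o2), c(2, 2))

  # channel expansion: (3, 60, 4) with 32 output channels
  h3 <- array(rnorm(3 * 60 * 4), c(3, 60, 4))
  o3 <- gcn_forward(h3, build_chain_graph(4), matrix(rnorm(32 * 3), 32, 3))
  expect_equal(dim(o3), c(32, 60, 4))

  expect_error(gcn_forward(h3, build_chain_graph(3), diag(3)),
               class = "reachgcn_shape_error")
})

test_that("temporal convolution preserves channels and strides frames", {
  h <- array(rnorm(3 * 60 * 4), c(3, 60, 4))
  expect_equal(dim(tcn_forward(h, rep(1 / 9, 9))), c(3, 60, 4))
  expect_equal(dim(tcn_forward(h, rep(1 / 9, 9), stride = 2)), c(3, 30, 4))

  # identity kernel (center tap 1) reproduces the input
  ident <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(tcn_forward(h, ident), h)

  # averaging kernel on constant input: interior frames stay constant
  hc <- array(7, c(2, 60, 4))
  oc <- tcn_forward(hc, rep(1 / 9, 9))
  expect_equal(oc[, 5:56, ], hc[, 5:56, ])
  # edge frames see zero padding, hence smaller magnitude
  expect_lt(oc[1, 1, 1], 7)

  expect_error(tcn_forward(h, rep(1, 9), stride = 0),
               class = "reachgcn_invalid_argument")
  expect_error(tcn_forward(h, rep(1, 4)),
               class = "reachgcn_invalid_argument")
})

test_that("ghost layer concatenates intrinsic and cheap channels in order", {
  h <- array(rnorm(32 * 10 * 4), c(32, 10, 4))
  out <- ghost_forward(h, ghost_spec(32, 32))
  expect_equal(dim(out), c(64, 10, 4))
  # intrinsic half passes through bit-identically
  expect_identical(out[1:32, , ], h)

  # identity cheap op: second half equals first half exactly
  oi <- ghost_forward(h, ghost_spec(32, 32, cheap_op = "identity"))
  expect_identical(oi[33:64, , ], oi[1:32, , ])

  # constant-1 channel, multiply-by-2 cheap op -> (1s, 2s)
  h1 <- array(1, c(1, 6, 4))
  o1 <- ghost_forward(h1, ghost_spec(1, 1), weights = 2)
  expect_true(all(o1[1, , ] == 1))
  expect_true(all(o1[2, , ] == 2))

  # over-wide input (c_in == c_out case) keeps the first half
  hw <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  ow <- ghost_forward(hw, ghost_spec(4, 4, cheap_op = "identity"))
  expect_identical(ow[1:4, , ], hw[1:4, , ])

  expect_error(ghost_forward(h, ghost_spec(12, 12)),
               class = "reachgcn_shape_error")
})

test_that("block forward obeys its shape and residual contracts", {
  g <- build_chain_graph(4)
  # zero main path + identity skip is the identity on nonnegative input
  spec <- block_spec(64, 64, 1)
  p <- reachgcn:::init_block_params(spec)
  p$gcn_w[] <- 0; p$tcn_w[] <- 0; p$tcn_b[] <- 0
  p$ghost_w[] <- 0; p$ghost_b[] <- 0
  h <- array(abs(rnorm(64 * 12 * 4)), c(64, 12, 4))
  expect_equal(block_forward(h, spec, g, params = p), h)

  # published shape examples
  expect_equal(dim(block_forward(array(rnorm(3 * 60 * 4), c(3, 60, 4)),
                                 block_spec(3, 64, 1), g)),
               c(64, 60, 4))
  expect_equal(dim(block_forward(array(rnorm(64 * 60 * 4), c(64, 60, 4)),
                                 block_spec(64, 128, 2), g)),
               c(128, 30, 4))

  expect_error(block_forward(array(1, c(32, 10, 4)), block_spec(64, 64, 1), g),
               class = "reachgcn_shape_error")
})

test_that("the backbone produces probabilities and the printed channel plan", {
  plan <- default_backbone_plan()
  expect_equal(vapply(plan, function(s) s$c_out, integer(1)),
               c(64, 64, 64, 128, 128, 128, 256, 256, 256))

  h <- array(rnorm(3 * 60 * 4), c(3, 60, 4))
  probs <- backbone_forward(h)
  expect_length(probs, 2)
  expect_equal(sum(probs), 1, tolerance = 1e-6)

  # pre-pool temporal length on T = 60: 60 -> 30 -> 15 via two strides
  cfg <- backbone_config(dropout = 0)
  params <- init_backbone_params(cfg, seed = 4)
  x <- reachgcn:::tb_from_array(array(h, c(1, dim(h))))
  tf <- reachgcn:::trunk_fwd(x, params, cfg, build_chain_graph(4), FALSE)
  expect_equal(unlist(tf$cache$h_dims), c(c = 256, t = 15, v = 4, n = 1))

  expect_error(backbone_forward(array(rnorm(3 * 3 * 4), c(3, 3, 4))),
               class = "reachgcn_invalid_argument")
})

test_that("ghost decomposition: intrinsic half equals the TCN output", {
  # run the main path manually and compare against the ghost split
  spec <- block_spec(16, 16, 1, use_residual = FALSE)
  p <- reachgcn:::init_block_params(spec)
  x <- reachgcn:::tb_new(matrix(abs(rnorm(16 * 40)), 16, 40), 16L, 10L, 4L, 1L)
  s <- reachgcn:::adjacency_operator(build_chain_graph(4)$normalized, 10L, 1L)
  gout <- reachgcn:::gcn_fwd(x, p$gcn_w, s)$out
  bout <- reachgcn:::bn_fwd(gout, p$bn_gamma, p$bn_beta, p$bn_rmean,
                            p$bn_rvar, FALSE)$out
  rout <- reachgcn:::relu_fwd(bout)$out
  tout <- reachgcn:::tcn_fwd(rout, p$tcn_w, p$tcn_b, 1L)$out
  gh <- reachgcn:::ghost_fwd(tout, p$ghost_w, p$ghost_b, "grouped1x1")$out
  expect_identical(gh$mat[1:8, ], tout$mat)
})

test_that("group streams share the trunk and fuse permutation-invariantly", {
  cfg <- backbone_config(dropout = 0)
  params <- init_backbone_params(cfg, seed = 2)
  hs <- lapply(1:3, function(i) array(rnorm(3 * 60 * 4), c(3, 60, 4)))

  pa <- multi_group_forward(hs, cfg, params = params)
  pb <- multi_group_forward(hs[c(2, 3, 1)], cfg, params = params)
  expect_equal(pa, pb)

  # identical tensors under mean fusion reduce to the single-stream pass
  same <- multi_group_forward(list(hs[[1]], hs[[1]], hs[[1]]), cfg,
                              params = params)
  single <- backbone_forward(hs[[1]], cfg, params = params)
  expect_equal(same, single, tolerance = 1e-12)

  # concat fusion triples the classifier input width
  cfg_cat <- backbone_config(dropout = 0, fusion = "concat")
  p_cat <- init_backbone_params(cfg_cat, seed = 2)
  expect_equal(ncol(p_cat$fc_w), 3 * 256)
  out_cat <- multi_group_forward(hs, cfg_cat, params = p_cat)
  expect_equal(sum(out_cat), 1, tolerance = 1e-6)

  expect_error(multi_group_forward(hs[1:2], cfg, params = params),
               class = "reachgcn_invalid_argument")

  # unshared trunks: three independent parameter sets, valid output
  plan2 <- list(block_spec(3, 8, 1), block_spec(8, 8, 1))
  cfg_us <- backbone_config(plan2, dropout = 0, shared_weights = FALSE)
  hs2 <- lapply(1:3, function(i) array(rnorm(3 * 20 * 4), c(3, 20, 4)))
  out_us <- multi_group_forward(hs2, cfg_us)
  expect_length(out_us, 2)
  expect_equal(sum(out_us), 1, tolerance = 1e-6)
})

test_that("checkpoints round-trip through the JSON archive", {
  plan <- list(block_spec(3, 8, 1), block_spec(8, 16, 2))
  cfg <- backbone_config(plan, dropout = 0)
  ds <- generate_dataset(4, 2, seed = 21, duration = 30)
  x <- clips_to_model_input(ds$clips)
  fit <- fit_ghost_stgcn(x, ds$labels$label, cfg, epochs = 1,
                         batch_size = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, fit$params, tolerance = 1e-12)
  expect_equal(predict(back, x, type = "prob"),
               predict(fit, x, type = "prob"), tolerance = 1e-10)
  expect_equal(capture.output(describe_model(back)),
               capture.output(describe_model(fit)))
})

test_that("optimization makes early progress for distinct seeds", {
  # loss decreases over the first 50 steps of default-backbone training
  ds <- generate_dataset(20, 20, seed = 606, duration = 30)
  x <- clips_to_model_input(ds$clips)
  for (seed in c(3, 14, 159)) {
    fit <- fit_ghost_stgcn(x, ds$labels$label,
                           backbone_config(dropout = 0.1), epochs = 10,
                           batch_size = 8, lr = 3e-3, seed = seed,
                           class_weights = NULL)
    sl <- fit$step_losses[1:50]
    expect_lt(mean(tail(sl, 5)), mean(head(sl, 5)))
  }
})

test_that("training is reproducible and tidiers summarize the fit", {
  plan <- list(block_spec(3, 8, 1), block_spec(8, 8, 1))
  cfg <- backbone_config(plan)
  ds <- generate_dataset(6, 4, seed = 31, duration = 30)
  x <- clips_to_model_input(ds$clips)
  f1 <- fit_ghost_stgcn(x, ds$labels$label, cfg, epochs = 2,
                        batch_size = 5, seed = 11)
  f2 <- fit_ghost_stgcn(x, ds$labels$label, cfg, epochs = 2,
                        batch_size = 5, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)

  td <- tidy(f1)
  expect_equal(nrow(td), 2)
  expect_named(td, c("block", "c_in", "c_out", "stride", "ghost",
                     "residual", "n_params"))
  gl <- glance(f1)
  expect_equal(gl$n_blocks, 2)
  expect_equal(gl$epochs, 2)
  expect_s3_class(autoplot(f1), "ggplot")
})
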