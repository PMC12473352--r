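test_that("block FLOP counts decompose term by term", {
  # hand count at c_in = c_out = T = V = 1, nnz = 1:
  # 2 * (1 [transform] + 1 [adjacency] + 9 [tcn]) = 22
  conv <- counting_convention(frames_t = 1, nodes_v = 1)
  g1 <- build_chain_graph(1)
  expect_equal(count_block_flops(block_spec(1, 1, 1, use_ghost = FALSE),
                                 g1, conv, with_ghost = FALSE), 22)

  # default convention: 2*(cin*cout*60*4 + 10*cout*60 + 9*cout^2*60*4)
  flops <- function(cin, cout) {
    2 * (cin * cout * 60 * 4 + 10 * cout * 60 + 9 * cout^2 * 60 * 4)
  }
  for (spec in list(c(64, 128), c(128, 128), c(3, 64))) {
    expect_equal(count_block_flops(block_spec(spec[1], spec[2], 1),
                                   with_ghost = FALSE),
                 flops(spec[1], spec[2]))
  }
  expect_error(count_block_flops(block_spec(4, 4, 1, use_ghost = FALSE),
                                 with_ghost = TRUE),
               NA) # even c_out is fine
  expect_error(block_spec(3, 7, 1, use_ghost = TRUE),
               class = "reachgcn_invalid_argument")
})

test_that("lightweight ratio follows its definition and guards its domain", {
  expect_equal(lightweight_ratio(100, 30), 70)
  expect_equal(lightweight_ratio(5, 5), 0)
  expect_error(lightweight_ratio(10, 20), class = "reachgcn_domain_error")
  expect_error(lightweight_ratio(0, 0), class = "reachgcn_invalid_argument")
})

test_that("parameter counts match term-by-term hand counts", {
  # identity residual (no projection parameters), no BN, no bias
  expect_equal(count_block_params(
    block_spec(3, 64, 1, use_ghost = FALSE, use_residual = FALSE)),
    3 * 64 + 9 * 64 * 64)                     # 37,056
  expect_equal(count_block_params(block_spec(64, 64, 1, use_ghost = FALSE)),
               4096 + 36864)                  # 40,960
  # ghost halves the TCN term; full 1x1 cheap op adds 32*32
  expect_equal(count_block_params(block_spec(64, 64, 1, use_ghost = TRUE),
                                  cheap_op = "conv1x1"),
               64 * 32 + 9 * 32 * 32 + 32 * 32)  # 12,288
  # grouped cheap op costs one multiplier per ghost channel
  expect_equal(count_block_params(block_spec(64, 64, 1, use_ghost = TRUE),
                                  cheap_op = "grouped1x1"),
               64 * 32 + 9 * 32 * 32 + 32)
  # channel/stride change adds the residual projection
  expect_equal(count_block_params(block_spec(64, 128, 2, use_ghost = FALSE)),
               64 * 128 + 9 * 128 * 128 + 64 * 128)
})

test_that("FLOPs are strictly monotone in width, frames and nodes", {
  base <- counting_convention()
  f0 <- count_block_flops(block_spec(64, 64, 1), convention = base,
                          with_ghost = FALSE)
  expect_gt(count_block_flops(block_spec(65, 64, 1), convention = base,
                              with_ghost = FALSE), f0)
  expect_gt(count_block_flops(block_spec(64, 66, 1), convention = base,
                              with_ghost = FALSE), f0)
  for (conv in list(counting_convention(frames_t = 61),
                    counting_convention(nodes_v = 5))) {
    expect_gt(count_block_flops(block_spec(64, 64, 1), convention = conv,
                                with_ghost = FALSE), f0)
  }
})

test_that("the backbone report is internally consistent", {
  for (cheap in c("conv1x1", "grouped1x1")) {
    conv <- counting_convention(ghost_cheap_op = cheap)
    rep <- report_backbone(convention = conv)
    per_block <- rep[!is.na(rep$block), ]
    expect_equal(nrow(per_block), 9)
    # ghost column strictly below the no-ghost column, for every block
    expect_true(all(per_block$flops_ghost < per_block$flops_no_ghost))
    # lightweighting lands in the published 65-75% band
    expect_true(all(per_block$lightweight_pct > 65 &
                      per_block$lightweight_pct < 75))
    # final two stages are identical specs, hence identical rows
    expect_equal(per_block$flops_no_ghost[8], per_block$flops_no_ghost[9])
    expect_equal(per_block$flops_ghost[8], per_block$flops_ghost[9])
  }
  # sparse-vs-dense adjacency costing never flips the ratio's sign
  for (adj in c("sparse-nnz", "dense", "none")) {
    rep <- report_backbone(convention = counting_convention(adjacency = adj))
    expect_true(all(rep$lightweight_pct[!is.na(rep$block)] > 0))
  }
})

# Independent oracle: literal loop-nest enumeration of multiply-accumulates
# performed by the block's convolutions (transform, aggregation, temporal).
enumerate_macs <- function(c_in, c_out, t, v, nnz_row, cheap = NULL) {
  macs <- 0
  for (tt in seq_len(t)) {
    for (vv in seq_len(v)) {
      macs <- macs + c_in * c_out            # 1x1 channel transform
      macs <- macs + 9 * c_out * c_out       # 9-tap temporal filter
    }
    for (vv in seq_len(v)) {
      macs <- macs + nnz_row[vv] * c_out     # aggregation over neighbors
    }
  }
  if (!is.null(cheap)) {
    for (tt in seq_len(t)) {
      for (vv in seq_len(v)) {
        macs <- macs + cheap
      }
    }
  }
  macs
}

test_that("ledger counts match brute-force MAC enumeration on tiny specs", {
  for (v in 1:2) {
    graph <- build_chain_graph(v)
    nnz_row <- rowSums(graph$adjacency_selfloop != 0)
    for (c_io in list(c(1, 2), c(2, 4), c(4, 4), c(3, 2))) {
      for (t in 1:3) {
        conv <- counting_convention(frames_t = t, nodes_v = v)
        spec <- block_spec(c_io[1], c_io[2], 1, use_ghost = FALSE)
        expect_equal(
          count_block_flops(spec, graph, conv, with_ghost = FALSE),
          2 * enumerate_macs(c_io[1], c_io[2], t, v, nnz_row)
        )
        # ghost variant: half-width main path plus the 1x1 cheap op
        gspec <- block_spec(c_io[1], c_io[2], 1, use_ghost = TRUE)
        expect_equal(
          count_block_flops(gspec, graph, conv, with_ghost = TRUE),
          2 * enumerate_macs(c_io[1], c_io[2] / 2, t, v, nnz_row,
                             cheap = (c_io[2] / 2)^2)
        )
      }
    }
  }
})

test_that("backbone plans truncate and extend around the nine-block default", {
  p9 <- default_backbone_plan(9)
  expect_equal(vapply(p9, function(s) s$c_out, integer(1)),
               c(64, 64, 64, 128, 128, 128, 256, 256, 256))
  expect_equal(vapply(p9, function(s) s$stride, integer(1)),
               c(1, 1, 1, 2, 1, 1, 2, 1, 1))
  p3 <- default_backbone_plan(3)
  expect_equal(length(p3), 3)
  expect_equal(p3[[3]]$c_out, 64L)
  p12 <- default_backbone_plan(12)
  expect_equal(length(p12), 12)
  expect_true(all(vapply(p12[10:12], function(s) s$c_in == 256 &&
                           s$c_out == 256 && s$stride == 1, logical(1))))
  expect_error(default_backbone_plan(7), class = "reachgcn_invalid_argument")
})
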