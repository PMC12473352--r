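#' Counting convention for the complexity ledger
#'
#' Fixes every choice that goes into a multiply-accumulate (MAC) count
#' for one GCN-TCN-ghost block: the tensor sizes the count is evaluated
#' at, how the adjacency aggregation is costed, whether temporal stride
#' is reflected in the frame count, and how the ghost layer's cheap
#' transform is costed.  The default convention (2 FLOPs per MAC,
#' T = 60 frames, V = 4 joints, sparse-nnz adjacency cost, all terms at
#' nominal T with stride ignored, convolution terms only) is the one
#' under which the ledger's late-block no-ghost counts line up with the
#' published figures for this architecture.
#'
#' @param flops_per_mac FLOPs charged per multiply-accumulate (default 2).
#' @param frames_t Nominal temporal length T (default 60).
#' @param nodes_v Number of joints V per group (default 4).
#' @param adjacency One of `"sparse-nnz"` (nnz(A~) * c_out * T MACs),
#'   `"dense"` (V^2 * c_out * T MACs) or `"none"`.
#' @param stride_handling `"nominal"` (all terms at input T; stride
#'   ignored) or `"strided"` (TCN and downstream terms at ceil(T/stride)).
#' @param ghost_cheap_op `"conv1x1"` (a full 1x1 convolution over the
#'   intrinsic half, (c_out/2)^2 * T * V MACs) or `"grouped1x1"` (one
#'   multiplier per channel, (c_out/2) * T * V MACs).
#' @return A `counting_convention` list.
#' @export
counting_convention <- function(flops_per_mac = 2L,
                                frames_t = 60L,
                                nodes_v = 4L,
                                adjacency = c("sparse-nnz", "dense", "none"),
                                stride_handling = c("nominal", "strided"),
                                ghost_cheap_op = c("conv1x1", "grouped1x1")) {
  adjacency <- match.arg(adjacency)
  stride_handling <- match.arg(stride_handling)
  ghost_cheap_op <- match.arg(ghost_cheap_op)
  stopifnot(flops_per_mac >= 1, frames_t >= 1, nodes_v >= 1)
  structure(
    list(flops_per_mac = as.numeric(flops_per_mac),
         frames_t = as.numeric(frames_t),
         nodes_v = as.numeric(nodes_v),
         adjacency = adjacency,
         stride_handling = stride_handling,
         ghost_cheap_op = ghost_cheap_op),
    class = "counting_convention"
  )
}

#' Block specification for one GCN-TCN-ghost block
#'
#' @param c_in,c_out Input / output channel counts.
#' @param stride Temporal stride, 1 or 2.
#' @param use_ghost Whether the block ends in a ghost expansion layer
#'   (then the GCN/TCN run at `c_out / 2` channels; `c_out` must be even).
#' @param use_residual Whether the block carries an additive skip path.
#' @return A `block_spec` list.
#' @export
block_spec <- function(c_in, c_out, stride = 1L, use_ghost = TRUE,
                       use_residual = TRUE) {
  if (c_in < 1 || c_out < 1) {
    abort("`c_in` and `c_out` must be positive.",
          class = "reachgcn_invalid_argument")
  }
  if (!stride %in% c(1L, 2L)) {
    abort("`stride` must be 1 or 2.", class = "reachgcn_invalid_argument")
  }
  if (use_ghost && c_out %% 2 != 0) {
    abort("With a ghost layer `c_out` must be even (intrinsic half + ghost half).",
          class = "reachgcn_invalid_argument")
  }
  structure(list(c_in = as.integer(c_in), c_out = as.integer(c_out),
                 stride = as.integer(stride), use_ghost = isTRUE(use_ghost),
                 use_residual = isTRUE(use_residual)),
            class = "block_spec")
}

#' The default nine-block backbone plan
#'
#' The stacked plan, as (c_in, c_out, stride) triples:
#' (3,64,1), (64,64,1), (64,64,1), (64,128,2), (128,128,1), (128,128,1),
#' (128,256,2), (256,256,1), (256,256,1).  Depths other than 9 truncate
#' the prefix (3, 6) or repeat the final (256,256,1) stage (12, 15).
#'
#' @param depth Number of stacked blocks; one of 3, 6, 9, 12, 15.
#' @param use_ghost,use_residual Flags applied to every block.
#' @return A list of `block_spec` objects.
#' @export
default_backbone_plan <- function(depth = 9L, use_ghost = TRUE,
                                  use_residual = TRUE) {
  if (!depth %in% c(3L, 6L, 9L, 12L, 15L)) {
    abort("`depth` must be one of 3, 6, 9, 12, 15.",
          class = "reachgcn_invalid_argument")
  }
  base <- list(
    c(3L, 64L, 1L), c(64L, 64L, 1L), c(64L, 64L, 1L),
    c(64L, 128L, 2L), c(128L, 128L, 1L), c(128L, 128L, 1L),
    c(128L, 256L, 2L), c(256L, 256L, 1L), c(256L, 256L, 1L)
  )
  plan <- if (depth <= 9L) {
    base[seq_len(depth)]
  } else {
    c(base, rep(list(c(256L, 256L, 1L)), depth - 9L))
  }
  lapply(plan, function(p) block_spec(p[1], p[2], p[3],
                                      use_ghost = use_ghost,
                                      use_residual = use_residual))
}

# MAC terms of one block under a convention; returns list(no_ghost, ghost)
block_mac_terms <- function(spec, graph, convention) {
  t_in <- convention$frames_t
  v <- convention$nodes_v
  t_eff <- if (convention$stride_handling == "strided") {
    ceiling(t_in / spec$stride)
  } else {
    t_in
  }
  nnz <- sum(graph$adjacency_selfloop != 0)
  adj_cost <- function(c_out) {
    switch(convention$adjacency,
      "sparse-nnz" = nnz * c_out * t_in,
      "dense" = v^2 * c_out * t_in,
      "none" = 0)
  }
  main <- function(c_out) {
    spec$c_in * c_out * t_in * v +   # 1x1 GCN channel transform
      adj_cost(c_out) +              # graph aggregation
      9 * c_out * c_out * t_eff * v  # 9-tap temporal convolution
  }
  cheap <- switch(convention$ghost_cheap_op,
    "conv1x1" = (spec$c_out / 2)^2 * t_eff * v,
    "grouped1x1" = (spec$c_out / 2) * t_eff * v)
  list(no_ghost = main(spec$c_out),
       ghost = main(spec$c_out / 2) + cheap)
}

#' Count forward-pass FLOPs of one block
#'
#' Under the default convention the no-ghost count is
#' `flops_per_mac * (c_in*c_out*T*V + nnz(A~)*c_out*T + 9*c_out^2*T*V)`:
#' the 1x1 GCN channel transform, the sparse adjacency aggregation over
#' the 4-chain with self-loops (10 nonzeros), and the 9-tap temporal
#' convolution.  With a ghost layer the GCN/adjacency/TCN terms run at
#' `c_out / 2` channels and the cheap-op term is added.  BN, ReLU,
#' Dropout and the residual path are excluded.
#'
#' @param spec A [block_spec()].
#' @param graph A [build_chain_graph()] result (used for the nnz of the
#'   self-loop adjacency); default the 4-chain.
#' @param convention A [counting_convention()].
#' @param with_ghost Count the ghost variant of the block?  Defaults to
#'   the spec's `use_ghost` flag.
#' @return FLOPs as a numeric scalar.
#' @examples
#' count_block_flops(block_spec(256, 256, 1), with_ghost = FALSE)  # 314880000
#' @export
count_block_flops <- function(spec, graph = build_chain_graph(4),
                              convention = counting_convention(),
                              with_ghost = spec$use_ghost) {
  if (with_ghost && spec$c_out %% 2 != 0) {
    abort("Ghost counting requires even `c_out`.",
          class = "reachgcn_invalid_argument")
  }
  terms <- block_mac_terms(spec, graph, convention)
  macs <- if (with_ghost) terms$ghost else terms$no_ghost
  convention$flops_per_mac * macs
}

#' Lightweight ratio of a ghost block
#'
#' The percentage FLOPs reduction obtained by embedding the ghost
#' layer: `100 * (no_ghost - ghost) / no_ghost`.
#'
#' @param flops_no_ghost,flops_ghost Positive FLOP counts with
#'   `flops_ghost <= flops_no_ghost`.
#' @return Percentage in `[0, 100)`, unrounded.
#' @examples
#' lightweight_ratio(299151360, 86875200)  # 70.959..., prints as 70.96%
#' @export
lightweight_ratio <- function(flops_no_ghost, flops_ghost) {
  if (any(flops_no_ghost <= 0) || any(flops_ghost <= 0)) {
    abort("FLOP counts must be positive.",
          class = "reachgcn_invalid_argument")
  }
  if (any(flops_ghost > flops_no_ghost)) {
    abort("`flops_ghost` must not exceed `flops_no_ghost`.",
          class = "reachgcn_domain_error")
  }
  100 * (flops_no_ghost - flops_ghost) / flops_no_ghost
}

#' Count learnable parameters of one block
#'
#' Term-by-term: GCN transform `c_in * c_mid`, TCN filters
#' `9 * c_mid * c_mid`, ghost cheap-op weights (full 1x1:
#' `c_mid * c_mid`; grouped: `c_mid`; identity: 0), residual projection
#' `c_in * c_out` when channels or stride differ, and optionally the BN
#' affine pairs.  `c_mid` is `c_out / 2` with ghost, else `c_out`.
#'
#' @inheritParams count_block_flops
#' @param cheap_op Ghost cheap-op kind: `"conv1x1"`, `"grouped1x1"` or
#'   `"identity"`.
#' @param include_bn Include the per-channel BN scale and shift?
#' @param include_bias Include TCN / ghost biases?
#' @return Integer parameter count.
#' @examples
#' count_block_params(block_spec(3, 64, 1, use_ghost = FALSE))  # 37056
#' @export
count_block_params <- function(spec, cheap_op = "conv1x1",
                               include_bn = FALSE, include_bias = FALSE) {
  c_mid <- if (spec$use_ghost) spec$c_out / 2 else spec$c_out
  n_ghost <- if (spec$use_ghost) spec$c_out - c_mid else 0
  p <- spec$c_in * c_mid + 9 * c_mid * c_mid
  if (spec$use_ghost) {
    p <- p + switch(cheap_op,
      conv1x1 = c_mid * n_ghost,
      grouped1x1 = n_ghost,
      identity = 0,
      abort("Unknown `cheap_op`.", class = "reachgcn_invalid_argument"))
  }
  if (spec$use_residual && (spec$c_in != spec$c_out || spec$stride != 1L)) {
    p <- p + spec$c_in * spec$c_out
  }
  if (include_bias) p <- p + c_mid + if (spec$use_ghost) n_ghost else 0
  if (include_bn) p <- p + 2 * c_mid
  as.integer(round(p))
}

#' Per-block and total complexity report for a backbone
#'
#' Emits, for every block of the plan, the no-ghost FLOPs, with-ghost
#' FLOPs, lightweight percentage and parameter counts, plus a totals
#' row, mirroring the published ledger layout for this architecture.
#'
#' @param plan A list of [block_spec()]s (default the nine-block plan).
#' @param graph Chain graph used for adjacency costing.
#' @param convention A [counting_convention()].
#' @return A tibble with columns `block`, `c_in`, `c_out`, `stride`,
#'   `flops_no_ghost`, `flops_ghost`, `lightweight_pct`,
#'   `params_no_ghost`, `params_ghost`.
#' @export
report_backbone <- function(plan = default_backbone_plan(),
                            graph = build_chain_graph(4),
                            convention = counting_convention()) {
  rows <- purrr::imap(plan, function(spec, i) {
    no_g <- count_block_flops(spec, graph, convention, with_ghost = FALSE)
    g <- count_block_flops(spec, graph, convention, with_ghost = TRUE)
    tibble::tibble(
      block = i,
      c_in = spec$c_in, c_out = spec$c_out, stride = spec$stride,
      flops_no_ghost = no_g,
      flops_ghost = g,
      lightweight_pct = lightweight_ratio(no_g, g),
      params_no_ghost = count_block_params(
        block_spec(spec$c_in, spec$c_out, spec$stride, use_ghost = FALSE,
                   use_residual = spec$use_residual)),
      params_ghost = count_block_params(
        block_spec(spec$c_in, spec$c_out, spec$stride, use_ghost = TRUE,
                   use_residual = spec$use_residual),
        cheap_op = convention$ghost_cheap_op)
    )
  })
  per_block <- dplyr::bind_rows(rows)
  totals <- per_block |>
    dplyr::summarise(dplyr::across(c("flops_no_ghost", "flops_ghost",
                                     "params_no_ghost", "params_ghost"),
                                   sum)) |>
    dplyr::mutate(block = NA_integer_, c_in = NA_integer_,
                  c_out = NA_integer_, stride = NA_integer_,
                  lightweight_pct = lightweight_ratio(.data$flops_no_ghost,
                                                      .data$flops_ghost))
  out <- dplyr::bind_rows(per_block, totals)
  class(out) <- c("complexity_report", class(out))
  out
}
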