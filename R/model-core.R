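# Ghost-ST-GCN layers: spatial graph convolution, 9-tap temporal
# convolution, ghost channel expansion, BN, residual blocks, backbone.
#
# Internal batch format ("tb"): a list(mat, c, t, v, n) where mat is a
# (C x T*V*N) matrix, column index (t, v, n) = t + T(v-1) + TV(n-1).
# All heavy lifting is BLAS matrix products; the adjacency aggregation
# is a sparse kronecker product I_N (x) A_hat (x) I_T acting on columns.

tb_new <- function(mat, c, t, v, n) list(mat = mat, c = c, t = t, v = v, n = n)

# (N, C, T, V) array -> tb
tb_from_array <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(2, 3, 4, 1))
  dim(m) <- c(d[2], d[3] * d[4] * d[1])
  tb_new(m, d[2], d[3], d[4], d[1])
}

# tb -> (N, C, T, V) array
tb_to_array <- function(x) {
  m <- x$mat
  dim(m) <- c(x$c, x$t, x$v, x$n)
  aperm(m, c(4, 1, 2, 3))
}

# sparse column operator applying A_hat along the joint axis; cached by
# (adjacency, T, N) since the same shapes recur every minibatch
.op_cache <- new.env(parent = emptyenv())

adjacency_operator <- function(a_hat, t, n) {
  key <- paste0("adj:", paste(signif(a_hat, 12), collapse = ","),
                ":", t, ":", n)
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  op <- Matrix::kronecker(
    Matrix::Diagonal(n),
    Matrix::kronecker(Matrix::Matrix(a_hat, sparse = TRUE),
                      Matrix::Diagonal(t))
  )
  .op_cache[[key]] <- op
  op
}

# ---- spatial graph convolution -------------------------------------------

gcn_fwd <- function(x, w, s_op) {
  u <- w %*% x$mat
  y <- as.matrix(u %*% s_op)
  list(out = tb_new(y, nrow(w), x$t, x$v, x$n),
       cache = list(x = x, w = w, s_op = s_op))
}

gcn_bwd <- function(dy, cache) {
  du <- as.matrix(dy %*% cache$s_op)       # A_hat is symmetric
  dw <- tcrossprod(du, cache$x$mat)
  dx <- crossprod(cache$w, du)
  list(dx = dx, dw = dw)
}

# ---- batch normalization --------------------------------------------------

bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.9, eps = 1e-5) {
  m <- x$mat
  if (training) {
    mu <- rowMeans(m)
    va <- rowMeans(m * m) - mu^2
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean
    va <- rvar
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- (m - mu) * inv_std      # length-C vectors recycle down columns
  y <- xhat * gamma + beta
  list(out = tb_new(y, x$c, x$t, x$v, x$n),
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  m <- ncol(dy)
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  dx <- cache$inv_std / m *
    (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- temporal convolution (9 taps, symmetric zero padding) ----------------

tcn_pad_index <- function(t, v, n, kernel) {
  key <- paste0("pad:", t, ":", v, ":", n, ":", kernel)
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (kernel - 1) / 2
  vn <- rep(0:(v * n - 1), each = t)
  idx <- (rep(seq_len(t), v * n) + pad) + (t + 2 * pad) * vn
  .op_cache[[key]] <- idx
  idx
}

tcn_tap_index <- function(t, v, n, kernel, stride) {
  key <- paste0("tap:", t, ":", v, ":", n, ":", kernel, ":", stride)
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (kernel - 1) / 2
  t_out <- ceiling(t / stride)
  vn <- rep(0:(v * n - 1), each = t_out)
  base <- (rep(seq_len(t_out), v * n) - 1) * stride
  idx <- lapply(seq_len(kernel), function(k) base + k + (t + 2 * pad) * vn)
  .op_cache[[key]] <- idx
  idx
}

# im2col formulation: stack the 9 temporal shifts as row blocks and run
# one GEMM against the flattened filter bank
tcn_fwd <- function(x, w, b, stride) {
  kernel <- dim(w)[3]
  pad <- (kernel - 1) / 2
  t_out <- ceiling(x$t / stride)
  n_pad_cols <- (x$t + 2 * pad) * x$v * x$n
  mp <- matrix(0, x$c, n_pad_cols)
  jp <- tcn_pad_index(x$t, x$v, x$n, kernel)
  mp[, jp] <- x$mat
  taps <- tcn_tap_index(x$t, x$v, x$n, kernel, stride)
  xcol <- matrix(0, kernel * x$c, t_out * x$v * x$n)
  for (k in seq_len(kernel)) {
    xcol[(k - 1) * x$c + seq_len(x$c), ] <- mp[, taps[[k]]]
  }
  c_out <- dim(w)[1]
  wflat <- matrix(w, c_out, x$c * kernel)
  y <- wflat %*% xcol + b
  list(out = tb_new(y, c_out, t_out, x$v, x$n),
       cache = list(xcol = xcol, taps = taps, jp = jp, wflat = wflat,
                    kernel = kernel, n_pad_cols = n_pad_cols,
                    dims = c(x$c, x$t, x$v, x$n)))
}

tcn_bwd <- function(dy, cache) {
  c_in <- cache$dims[1]
  kernel <- cache$kernel
  dwflat <- tcrossprod(dy, cache$xcol)
  dxcol <- crossprod(cache$wflat, dy)
  dmp <- matrix(0, c_in, cache$n_pad_cols)
  for (k in seq_len(kernel)) {
    idx <- cache$taps[[k]]
    dmp[, idx] <- dmp[, idx] + dxcol[(k - 1) * c_in + seq_len(c_in), ]
  }
  list(dx = dmp[, cache$jp], dw = array(dwflat, c(nrow(dy), c_in, kernel)),
       db = rowSums(dy))
}

# ---- ghost channel expansion ----------------------------------------------

ghost_fwd <- function(x, w, b, cheap_op) {
  y2 <- switch(cheap_op,
    grouped1x1 = x$mat * w + b,
    conv1x1 = w %*% x$mat + b,
    identity = x$mat)
  list(out = tb_new(rbind(x$mat, y2), 2L * x$c, x$t, x$v, x$n),
       cache = list(x = x, w = w, cheap_op = cheap_op))
}

ghost_bwd <- function(dy, cache) {
  m <- cache$x$c
  dy1 <- dy[seq_len(m), , drop = FALSE]
  dy2 <- dy[m + seq_len(nrow(dy) - m), , drop = FALSE]
  switch(cache$cheap_op,
    grouped1x1 = list(dx = dy1 + dy2 * cache$w,
                      dw = rowSums(dy2 * cache$x$mat), db = rowSums(dy2)),
    conv1x1 = list(dx = dy1 + crossprod(cache$w, dy2),
                   dw = tcrossprod(dy2, cache$x$mat), db = rowSums(dy2)),
    identity = list(dx = dy1 + dy2, dw = NULL, db = NULL))
}

# ---- dropout / relu -------------------------------------------------------

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- 1 - rate
  mask <- (matrix(runif(length(x$mat)), nrow(x$mat)) < keep) / keep
  list(out = tb_new(x$mat * mask, x$c, x$t, x$v, x$n), cache = mask)
}

relu_fwd <- function(x) {
  y <- x$mat
  y[y < 0] <- 0
  list(out = tb_new(y, x$c, x$t, x$v, x$n), cache = y > 0)
}

# strided column subset along T
stride_index <- function(t, v, n, stride) {
  t_sel <- seq(1, t, by = stride)
  vn <- rep(0:(v * n - 1), each = length(t_sel))
  rep(t_sel, v * n) + t * vn
}

# ---- parameter initialization ---------------------------------------------

he_init <- function(n_out, n_in, fan) {
  matrix(rnorm(n_out * n_in, 0, sqrt(2 / fan)), n_out, n_in)
}

init_block_params <- function(spec, kernel = 9L) {
  c_mid <- if (spec$use_ghost) spec$c_out / 2L else spec$c_out
  # residual blocks start as the identity: the branch's last convolution
  # (the TCN) is zero-initialized so activations cannot compound across
  # the stack; without a skip path the TCN gets a He init instead
  tcn_w <- if (spec$use_residual) {
    array(0, dim = c(c_mid, c_mid, kernel))
  } else {
    array(rnorm(c_mid * c_mid * kernel, 0, sqrt(2 / (c_mid * kernel))),
          dim = c(c_mid, c_mid, kernel))
  }
  p <- list(
    gcn_w = he_init(c_mid, spec$c_in, spec$c_in),
    bn_gamma = rep(1, c_mid), bn_beta = rep(0, c_mid),
    bn_rmean = rep(0, c_mid), bn_rvar = rep(1, c_mid),
    tcn_w = tcn_w,
    tcn_b = rep(0, c_mid)
  )
  if (spec$use_ghost) {
    p$ghost_w <- rep(1, c_mid)           # grouped 1x1: one multiplier/channel
    p$ghost_b <- rep(0, c_mid)
  }
  if (spec$use_residual && (spec$c_in != spec$c_out || spec$stride != 1L)) {
    p$res_w <- he_init(spec$c_out, spec$c_in, spec$c_in)
  }
  p
}

# ---- one GCN-TCN-ghost block ----------------------------------------------

# returns list(out, cache, params) -- params carries updated BN stats
block_fwd <- function(x, spec, p, s_op, training = FALSE, dropout = 0.5) {
  if (x$c != spec$c_in) {
    abort(sprintf("Block expects %d input channels, got %d.",
                  spec$c_in, x$c),
          class = "reachgcn_shape_error")
  }
  g <- gcn_fwd(x, p$gcn_w, s_op)
  b <- bn_fwd(g$out, p$bn_gamma, p$bn_beta, p$bn_rmean, p$bn_rvar, training)
  p$bn_rmean <- b$rmean; p$bn_rvar <- b$rvar
  r <- relu_fwd(b$out)
  d <- dropout_fwd(r$out, dropout, training)
  tc <- tcn_fwd(d$out, p$tcn_w, p$tcn_b, spec$stride)
  if (spec$use_ghost) {
    gh <- ghost_fwd(tc$out, p$ghost_w, p$ghost_b, "grouped1x1")
    main <- gh$out
  } else {
    gh <- NULL
    main <- tc$out
  }
  res_cache <- NULL
  if (spec$use_residual) {
    if (is.null(p$res_w)) {
      main$mat <- main$mat + x$mat
    } else {
      idx <- stride_index(x$t, x$v, x$n, spec$stride)
      xr <- x$mat[, idx, drop = FALSE]
      main$mat <- main$mat + p$res_w %*% xr
      res_cache <- list(xr = xr, idx = idx)
    }
  }
  out <- relu_fwd(main)
  list(out = out$out,
       cache = list(g = g$cache, b = b$cache, r = r$cache, d = d$cache,
                    tc = tc$cache, gh = if (!is.null(gh)) gh$cache,
                    res = res_cache, final_mask = out$cache,
                    spec = spec, x = x, dropout = dropout),
       params = p)
}

block_bwd <- function(dy, cache, p) {
  spec <- cache$spec
  dmain <- dy * cache$final_mask
  grads <- list()
  dx_res <- NULL
  if (spec$use_residual) {
    if (is.null(p$res_w)) {
      dx_res <- dmain
    } else {
      grads$res_w <- tcrossprod(dmain, cache$res$xr)
      dxr <- crossprod(p$res_w, dmain)
      dx_res <- matrix(0, cache$x$c, ncol(cache$x$mat))
      dx_res[, cache$res$idx] <- dxr
    }
  }
  if (spec$use_ghost) {
    gb <- ghost_bwd(dmain, cache$gh)
    grads$ghost_w <- gb$dw; grads$ghost_b <- gb$db
    dtc <- gb$dx
  } else {
    dtc <- dmain
  }
  tb_ <- tcn_bwd(dtc, cache$tc)
  grads$tcn_w <- tb_$dw; grads$tcn_b <- tb_$db
  dd <- tb_$dx
  if (!is.null(cache$d)) dd <- dd * cache$d
  dr <- dd * cache$r
  bb <- bn_bwd(dr, cache$b)
  grads$bn_gamma <- bb$dgamma; grads$bn_beta <- bb$dbeta
  gg <- gcn_bwd(bb$dx, cache$g)
  grads$gcn_w <- gg$dw
  dx <- gg$dx
  if (!is.null(dx_res)) dx <- dx + dx_res
  list(dx = dx, grads = grads)
}

# ---- backbone -------------------------------------------------------------

#' Configuration of the Ghost-ST-GCN backbone
#'
#' Bundles the block plan with the remaining architecture knobs.
#'
#' @param plan List of [block_spec()]s; default the nine-block plan.
#' @param kernel Temporal filter length (odd; default 9 frames).
#' @param dropout Dropout rate inside each block (default 0.5).
#' @param n_classes Number of output classes (default 2: correct/wrong).
#' @param fusion How the three group streams are fused after pooling:
#'   `"mean"` (default) or `"concat"`.
#' @param shared_weights Do the three group streams share one trunk?
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(plan = default_backbone_plan(), kernel = 9L,
                            dropout = 0.5, n_classes = 2L,
                            fusion = c("mean", "concat"),
                            shared_weights = TRUE) {
  fusion <- match.arg(fusion)
  if (kernel %% 2 != 1) {
    abort("`kernel` must be odd.", class = "reachgcn_invalid_argument")
  }
  for (i in seq_along(plan)[-1]) {
    if (plan[[i]]$c_in != plan[[i - 1]]$c_out) {
      abort("Consecutive blocks must chain: c_in[k+1] == c_out[k].",
            class = "reachgcn_invalid_argument")
    }
  }
  structure(list(plan = plan, kernel = as.integer(kernel), dropout = dropout,
                 n_classes = as.integer(n_classes), fusion = fusion,
                 shared_weights = isTRUE(shared_weights)),
            class = "backbone_config")
}

#' Initialize backbone parameters
#'
#' He-initialized weights, unit BN scales, zero biases.  The classifier
#' input width is the final block's `c_out` (times 3 under `"concat"`
#' fusion).  The input BN is kept per group stream (one set of running
#' statistics per chain), since the three chains occupy different
#' regions of the image and would otherwise never be centered.
#'
#' @param config A [backbone_config()].
#' @param d_in Input channel count (3: x, y, confidence).
#' @param seed RNG seed for the draws.
#' @param n_streams Number of group streams with their own input BN.
#' @return A parameter list (`input_bn`, `blocks`, `fc_w`, `fc_b`).
#' @export
init_backbone_params <- function(config, d_in = 3L, seed = 1L,
                                 n_streams = 3L) {
  set.seed(seed)
  d_feat <- config$plan[[length(config$plan)]]$c_out
  d_fc <- if (config$fusion == "concat") 3L * d_feat else d_feat
  one_bn <- function(i) {
    list(gamma = rep(1, d_in), beta = rep(0, d_in),
         rmean = rep(0, d_in), rvar = rep(1, d_in))
  }
  list(
    input_bn = setNames(lapply(seq_len(n_streams), one_bn),
                        paste0("s", seq_len(n_streams))),
    blocks = lapply(config$plan, init_block_params, kernel = config$kernel),
    fc_w = he_init(config$n_classes, d_fc, d_fc),
    fc_b = rep(0, config$n_classes)
  )
}

# per-stream input BN on a group-stacked batch: block j of the batch
# (contiguous column range) normalizes with bn_list[[streams[j]]]
stream_bn_fwd <- function(x, bn_list, training, streams = seq_along(bn_list)) {
  g <- length(streams)
  stopifnot(x$n %% g == 0)
  cpg <- ncol(x$mat) / g
  out <- x$mat
  caches <- vector("list", g)
  for (j in seq_len(g)) {
    cols <- (j - 1) * cpg + seq_len(cpg)
    bn <- bn_list[[streams[j]]]
    sub <- tb_new(x$mat[, cols, drop = FALSE], x$c, x$t, x$v, x$n / g)
    bf <- bn_fwd(sub, bn$gamma, bn$beta, bn$rmean, bn$rvar, training)
    bn_list[[streams[j]]]$rmean <- bf$rmean
    bn_list[[streams[j]]]$rvar <- bf$rvar
    out[, cols] <- bf$out$mat
    caches[[j]] <- bf$cache
  }
  list(out = tb_new(out, x$c, x$t, x$v, x$n), bn = bn_list,
       caches = caches, streams = streams)
}

stream_bn_bwd <- function(dh, sb_cache) {
  g <- length(sb_cache$streams)
  cpg <- ncol(dh) / g
  dx <- dh
  grads <- list()
  for (j in seq_len(g)) {
    cols <- (j - 1) * cpg + seq_len(cpg)
    bb <- bn_bwd(dh[, cols, drop = FALSE], sb_cache$caches[[j]])
    dx[, cols] <- bb$dx
    nm <- paste0("s", sb_cache$streams[j])
    if (is.null(grads[[nm]])) {
      grads[[nm]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    } else {
      grads[[nm]]$gamma <- grads[[nm]]$gamma + bb$dgamma
      grads[[nm]]$beta <- grads[[nm]]$beta + bb$dbeta
    }
  }
  list(dx = dx, grads = grads)
}

softmax_cols <- function(z) {
  z <- z - apply(z, 2, max)[col(z)]
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# pooling operator: mean over T*V per sample
gap_operator <- function(t, v, n) {
  key <- paste0("gap:", t, ":", v, ":", n)
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  op <- Matrix::kronecker(Matrix::Diagonal(n),
                          Matrix::Matrix(rep(1 / (t * v), t * v), ncol = 1))
  .op_cache[[key]] <- op
  op
}

# trunk: blocks + GAP on an (already input-normalized) tb; returns
# pooled (d x N)
trunk_fwd <- function(x, params, config, graph, training) {
  h <- x
  caches <- vector("list", length(config$plan))
  for (i in seq_along(config$plan)) {
    spec <- config$plan[[i]]
    # the adjacency operator depends on the current temporal length
    s_i <- adjacency_operator(graph$normalized, h$t, h$n)
    bf <- block_fwd(h, spec, params$blocks[[i]], s_i, training,
                    config$dropout)
    params$blocks[[i]] <- bf$params
    caches[[i]] <- bf$cache
    h <- bf$out
  }
  p_op <- gap_operator(h$t, h$v, h$n)
  pooled <- as.matrix(h$mat %*% p_op)       # d x N
  list(pooled = pooled, params = params,
       cache = list(blocks = caches, p_op = p_op,
                    h_dims = h[c("c", "t", "v", "n")]))
}

trunk_bwd <- function(dpooled, cache, params, config) {
  dh <- as.matrix(dpooled %*% Matrix::t(cache$p_op))
  grads <- list(blocks = vector("list", length(config$plan)))
  for (i in rev(seq_along(config$plan))) {
    bb <- block_bwd(dh, cache$blocks[[i]], params$blocks[[i]])
    grads$blocks[[i]] <- bb$grads
    dh <- bb$dx
  }
  list(grads = grads, dx = dh)
}

#' Forward pass of the single-stream backbone
#'
#' Input BN, the stacked blocks, global average pooling over frames and
#' joints, a linear classifier and softmax.  Accepts one `(C, T, V)`
#' array (one clip, one group) or an `(N, C, T, V)` batch.
#'
#' @param h Input array, `(3, T, V)` or `(N, 3, T, V)`.
#' @param config A [backbone_config()].
#' @param graph The group chain graph (default 4-node chain).
#' @param params Parameters from [init_backbone_params()]; freshly
#'   initialized (seed 1) if omitted.
#' @return An `(N, n_classes)` matrix of class probabilities (rows sum
#'   to 1); a single input returns a length-`n_classes` vector.
#' @export
backbone_forward <- function(h, config = backbone_config(),
                             graph = build_chain_graph(4), params = NULL) {
  single <- length(dim(h)) == 3
  if (single) h <- array(h, c(1, dim(h)))
  d <- dim(h)
  n_stride2 <- sum(vapply(config$plan, function(s) s$stride, integer(1)) == 2)
  if (d[3] < 2^n_stride2) {
    abort(sprintf("Temporal length %d too short for %d stride-2 blocks.",
                  d[3], n_stride2),
          class = "reachgcn_invalid_argument")
  }
  if (is.null(params)) params <- init_backbone_params(config, d_in = d[2])
  x <- tb_from_array(h)
  sb <- stream_bn_fwd(x, params$input_bn, training = FALSE, streams = 1L)
  tf <- trunk_fwd(sb$out, params, config, graph, training = FALSE)
  logits <- params$fc_w %*% tf$pooled + params$fc_b
  probs <- t(softmax_cols(logits))
  if (single) drop(probs) else probs
}

#' Forward pass over the three keypoint-group streams
#'
#' Each group tensor runs through the backbone trunk — one trunk with
#' shared weights by default, or three independent trunks when the
#' config sets `shared_weights = FALSE`; pooled features are fused by
#' averaging (or concatenation) before the classifier.
#'
#' @param h_list List of exactly three input arrays, each `(3, T, V)`
#'   or `(N, 3, T, V)`.
#' @inheritParams backbone_forward
#' @param params For the shared trunk, a parameter list from
#'   [init_backbone_params()].  For unshared trunks, a list with
#'   elements `trunks` (three `input_bn`/`blocks` parameter sets),
#'   `fc_w`, `fc_b`; freshly initialized if omitted.
#' @param fusion Overrides the config's fusion mode if given.
#' @return Class-probability matrix as in [backbone_forward()].
#' @export
multi_group_forward <- function(h_list, config = backbone_config(),
                                graph = build_chain_graph(4), params = NULL,
                                fusion = NULL) {
  if (length(h_list) != 3) {
    abort("Exactly three group tensors are required.",
          class = "reachgcn_invalid_argument")
  }
  fusion <- fusion %||% config$fusion
  single <- length(dim(h_list[[1]])) == 3
  h_list <- lapply(h_list, function(h) {
    if (length(dim(h)) == 3) array(h, c(1, dim(h))) else h
  })
  d_in <- dim(h_list[[1]])[2]
  if (config$shared_weights) {
    if (is.null(params)) params <- init_backbone_params(config, d_in = d_in)
    pooled <- lapply(seq_along(h_list), function(g) {
      x <- tb_from_array(h_list[[g]])
      s <- min(g, length(params$input_bn))
      sb <- stream_bn_fwd(x, params$input_bn, training = FALSE, streams = s)
      trunk_fwd(sb$out, params, config, graph, training = FALSE)$pooled
    })
    fc_w <- params$fc_w; fc_b <- params$fc_b
  } else {
    if (is.null(params)) {
      full <- init_backbone_params(config, d_in = d_in)
      params <- list(
        trunks = lapply(1:3, function(g) {
          init_backbone_params(config, d_in = d_in, seed = g,
                               n_streams = 1L)[c("input_bn", "blocks")]
        }),
        fc_w = full$fc_w, fc_b = full$fc_b
      )
    }
    pooled <- lapply(seq_along(h_list), function(g) {
      x <- tb_from_array(h_list[[g]])
      tp <- params$trunks[[g]]
      sb <- stream_bn_fwd(x, tp$input_bn, training = FALSE, streams = 1L)
      trunk_fwd(sb$out, tp, config, graph, training = FALSE)$pooled
    })
    fc_w <- params$fc_w; fc_b <- params$fc_b
  }
  feat <- if (fusion == "mean") {
    Reduce(`+`, pooled) / length(pooled)
  } else {
    do.call(rbind, pooled)
  }
  logits <- fc_w %*% feat + fc_b
  probs <- t(softmax_cols(logits))
  if (single) drop(probs) else probs
}

#' Ghost layer specification and functional forward pass
#'
#' The ghost layer passes its `M` intrinsic input channels through
#' unchanged and appends `N` cheaply computed channels (`N + M` equals
#' the block's output width; by default `M = N = c_out / 2`), in that
#' concatenation order.  If the input already has `M + N` channels (the
#' equal-input/output case), the first `M` are selected deterministically
#' (or a seeded random half with `random_select`).
#'
#' @param intrinsic_channels `M`, the pass-through width.
#' @param ghost_channels `N`, the cheaply generated width (default `M`).
#' @param cheap_op `"grouped1x1"` (one multiplier per channel; the
#'   default in the network), `"conv1x1"` or `"identity"`.
#' @return A `ghost_spec` list.
#' @export
ghost_spec <- function(intrinsic_channels, ghost_channels = intrinsic_channels,
                       cheap_op = c("grouped1x1", "conv1x1", "identity")) {
  cheap_op <- match.arg(cheap_op)
  structure(list(m = as.integer(intrinsic_channels),
                 n = as.integer(ghost_channels), cheap_op = cheap_op),
            class = "ghost_spec")
}

#' @rdname ghost_spec
#' @param h Input array `(C, T, V)` with `C = M` (or `C = M + N`, see
#'   above).
#' @param spec A `ghost_spec`.
#' @param weights Cheap-op weights: length-`N` vector (`grouped1x1`),
#'   `N x M` matrix (`conv1x1`) or ignored (`identity`).  Defaults to
#'   ones / identity-like.
#' @param random_select Use a seeded random half instead of the first
#'   `M` channels when the input is over-wide.
#' @param seed Seed for `random_select`.
#' @export
ghost_forward <- function(h, spec, weights = NULL, random_select = FALSE,
                          seed = 1L) {
  d <- dim(h)
  if (d[1] == spec$m + spec$n && spec$m == spec$n) {
    sel <- if (random_select) {
      set.seed(seed)
      sort(sample(d[1], spec$m))
    } else {
      seq_len(spec$m)
    }
    h <- h[sel, , , drop = FALSE]
    d <- dim(h)
  }
  if (d[1] != spec$m) {
    abort(sprintf("Ghost layer expects %d input channels, got %d.",
                  spec$m, d[1]),
          class = "reachgcn_shape_error")
  }
  x <- tb_new(matrix(h, d[1], d[2] * d[3]), d[1], d[2], d[3], 1L)
  if (spec$cheap_op == "grouped1x1") {
    w <- weights %||% rep(1, spec$n)
    y2 <- x$mat * w
  } else if (spec$cheap_op == "conv1x1") {
    w <- weights %||% diag(1, spec$n, spec$m)
    y2 <- w %*% x$mat
  } else {
    y2 <- x$mat
  }
  out <- rbind(x$mat, y2)
  array(out, c(spec$m + spec$n, d[2], d[3]))
}

#' Functional spatial graph convolution
#'
#' Computes `activation(A_hat %*% H %*% t(W))` independently per frame:
#' features propagate over the normalized self-loop adjacency, then the
#' channel transform `weights` maps `c_in` to `c_out` channels.
#'
#' @param h Input array `(C_in, T, V)`.
#' @param graph A [build_chain_graph()] result with `V` nodes.
#' @param weights A `c_out x c_in` matrix.
#' @param activation A vectorized function (default identity).
#' @return Array `(c_out, T, V)`.
#' @export
gcn_forward <- function(h, graph, weights, activation = identity) {
  d <- dim(h)
  if (d[3] != graph$num_nodes) {
    abort(sprintf("Input has %d nodes but graph has %d.", d[3],
                  graph$num_nodes),
          class = "reachgcn_shape_error")
  }
  x <- tb_new(matrix(h, d[1], d[2] * d[3]), d[1], d[2], d[3], 1L)
  s_op <- adjacency_operator(graph$normalized, d[2], 1L)
  y <- as.matrix((weights %*% x$mat) %*% s_op)
  array(activation(y), c(nrow(weights), d[2], d[3]))
}

#' Functional temporal convolution
#'
#' Channel-preserving filtering along the frame axis with an odd-length
#' filter bank, symmetric zero padding of `(kernel - 1) / 2`, and an
#' optional temporal stride (output length `ceiling(T / stride)`).
#'
#' @param h Input array `(C, T, V)`.
#' @param kernel Filter bank: a `C x C x K` array, or a length-`K`
#'   vector applied depthwise (each channel filtered by the same taps).
#' @param stride Temporal stride (positive integer).
#' @param bias Optional length-`C` bias.
#' @return Array `(C, ceiling(T / stride), V)`.
#' @export
tcn_forward <- function(h, kernel, stride = 1L, bias = NULL) {
  if (stride < 1) {
    abort("`stride` must be >= 1.", class = "reachgcn_invalid_argument")
  }
  d <- dim(h)
  if (is.vector(kernel)) {
    k <- length(kernel)
    w <- array(0, c(d[1], d[1], k))
    for (i in seq_len(k)) w[, , i] <- diag(kernel[i], d[1])
  } else {
    w <- kernel
    k <- dim(w)[3]
  }
  if (k %% 2 != 1) {
    abort("Kernel length must be odd.", class = "reachgcn_invalid_argument")
  }
  x <- tb_new(matrix(h, d[1], d[2] * d[3]), d[1], d[2], d[3], 1L)
  out <- tcn_fwd(x, w, bias %||% rep(0, dim(w)[1]), as.integer(stride))$out
  array(out$mat, c(out$c, out$t, out$v))
}

#' Functional forward pass of one block
#'
#' Pipeline GCN, BN, ReLU, Dropout, TCN, ghost; residual added before
#' the final ReLU (identity skip when shapes match, strided 1x1
#' projection otherwise).  Inference mode: BN uses its stored running
#' statistics and dropout is inactive.
#'
#' @param h Input array `(c_in, T, V)`.
#' @param spec A [block_spec()].
#' @param graph The group chain graph.
#' @param params Block parameters (from `init_block_params`-shaped
#'   lists); freshly initialized from `seed` if omitted.
#' @param seed Seed for fresh initialization.
#' @return Array `(c_out, ceiling(T / stride), V)`.
#' @export
block_forward <- function(h, spec, graph = build_chain_graph(4),
                          params = NULL, seed = 1L) {
  d <- dim(h)
  if (is.null(params)) {
    set.seed(seed)
    params <- init_block_params(spec)
  }
  x <- tb_new(matrix(h, d[1], d[2] * d[3]), d[1], d[2], d[3], 1L)
  s_op <- adjacency_operator(graph$normalized, d[2], 1L)
  out <- block_fwd(x, spec, params, s_op, training = FALSE)$out
  array(out$mat, c(out$c, out$t, out$v))
}
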