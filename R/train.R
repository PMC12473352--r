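# End-to-end training of the Ghost-ST-GCN classifier.

# recursive Adam step over nested parameter / gradient lists; running BN
# statistics are not trainable and are skipped
adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  if (is.list(p)) {
    if (is.null(m)) m <- vector("list", length(p))
    if (is.null(v)) v <- vector("list", length(p))
    names(m) <- names(p); names(v) <- names(p)
    keys <- if (is.null(names(g))) seq_along(g) else names(g)
    for (nm in keys) {
      if (is.null(g[[nm]]) || is.null(p[[nm]])) next
      r <- adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t,
                     beta1, beta2, eps, weight_decay)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  if (is.null(m)) m <- p * 0
  if (is.null(v)) v <- p * 0
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  p <- p - lr * (mh / (sqrt(vh) + eps) + weight_decay * p)
  list(p = p, m = m, v = v)
}

# stack the three group tensors of selected samples along the batch axis
stack_groups <- function(tensors, idx) {
  mats <- lapply(tensors, function(a) a[idx, , , , drop = FALSE])
  d <- dim(mats[[1]])
  out <- array(0, c(3 * d[1], d[2], d[3], d[4]))
  for (g in 1:3) out[(g - 1) * d[1] + seq_len(d[1]), , , ] <- mats[[g]]
  out
}

# forward + loss + gradients for one minibatch through the shared trunk
shared_step <- function(params, config, graph, tensors, y_idx, idx,
                        training = TRUE, class_weights = NULL) {
  nb <- length(idx)
  h <- stack_groups(tensors, idx)           # (3*nb, C, T, V)
  x <- tb_from_array(h)
  sb <- stream_bn_fwd(x, params$input_bn, training = training,
                      streams = 1:3)
  params$input_bn <- sb$bn
  tf <- trunk_fwd(sb$out, params, config, graph, training = training)
  params <- tf$params
  pooled <- tf$pooled                       # d x 3nb, group-major blocks
  cols <- function(g) (g - 1) * nb + seq_len(nb)
  feat <- if (config$fusion == "mean") {
    (pooled[, cols(1), drop = FALSE] + pooled[, cols(2), drop = FALSE] +
       pooled[, cols(3), drop = FALSE]) / 3
  } else {
    rbind(pooled[, cols(1), drop = FALSE], pooled[, cols(2), drop = FALSE],
          pooled[, cols(3), drop = FALSE])
  }
  logits <- params$fc_w %*% feat + params$fc_b
  probs <- softmax_cols(logits)
  yb <- y_idx[idx]
  w <- if (is.null(class_weights)) rep(1, nb) else class_weights[yb]
  loss <- -sum(w * log(pmax(probs[cbind(yb, seq_len(nb))], 1e-12))) / sum(w)
  pred <- max.col(t(probs))
  acc <- mean(pred == yb)
  if (!training) {
    return(list(loss = loss, acc = acc, probs = probs, params = params))
  }
  ymat <- matrix(0, nrow(probs), nb)
  ymat[cbind(yb, seq_len(nb))] <- 1
  dlogits <- (probs - ymat) * rep(w / sum(w), each = nrow(probs))
  gfc_w <- tcrossprod(dlogits, feat)
  gfc_b <- rowSums(dlogits)
  dfeat <- crossprod(params$fc_w, dlogits)
  d <- nrow(pooled)
  dpooled <- matrix(0, d, 3 * nb)
  if (config$fusion == "mean") {
    for (g in 1:3) dpooled[, cols(g)] <- dfeat / 3
  } else {
    for (g in 1:3) dpooled[, cols(g)] <- dfeat[(g - 1) * d + seq_len(d), ]
  }
  tbk <- trunk_bwd(dpooled, tf$cache, params, config)
  grads <- tbk$grads
  grads$input_bn <- stream_bn_bwd(tbk$dx, sb)$grads
  grads$fc_w <- gfc_w
  grads$fc_b <- gfc_b
  list(loss = loss, acc = acc, grads = grads, params = params)
}

#' Fit the Ghost-ST-GCN sit-and-reach classifier
#'
#' Trains the three-stream (shared-trunk) backbone on batched model
#' inputs with minibatch Adam and cross-entropy loss.  All randomness
#' (initialization, shuffling, dropout) derives from `seed`.
#'
#' @param x A `model_input` (see [clips_to_model_input()]) with three
#'   group tensors of shape `(N, 3, T, V)`.
#' @param y Clip labels: character or factor with values `"correct"` /
#'   `"wrong"`, length N.
#' @param config A [backbone_config()].
#' @param epochs Number of passes over the data.
#' @param batch_size Clips per minibatch (the protocol default is 8;
#'   larger batches are used for desk-scale experiments).
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled L2 coefficient.
#' @param seed RNG seed.
#' @param validation Optional list `list(x = model_input, y = labels)`
#'   evaluated after each epoch.
#' @param class_weights `NULL` for plain cross-entropy, `"balanced"`
#'   for inverse-frequency class weights (the recommended setting given
#'   the heavy correct:wrong imbalance of sit-and-reach recordings), or
#'   a length-2 numeric `(w_correct, w_wrong)`.
#' @param lr_schedule `"constant"` or `"cosine"` (cosine decay of the
#'   learning rate to zero over the run after warmup).
#' @param warmup_steps Linear learning-rate warmup over this many
#'   optimization steps (0 disables).
#' @param balance_batches Draw class-balanced minibatches (the minority
#'   class is oversampled with replacement); an alternative to
#'   `class_weights` for imbalanced data.  When enabled, epoch size
#'   stays at `n` but every batch is half correct / half wrong.
#' @param verbose Print per-epoch progress?
#' @return A fitted `ghost_stgcn` object with elements `params`,
#'   `config`, `graph`, `classes`, `history` (tibble), `groups`.
#' @export
fit_ghost_stgcn <- function(x, y, config = backbone_config(), epochs = 10L,
                            batch_size = 32L, lr = 1e-3, weight_decay = 0,
                            seed = 1L, validation = NULL,
                            class_weights = "balanced",
                            lr_schedule = c("constant", "cosine"),
                            warmup_steps = 0L, balance_batches = FALSE,
                            verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(inherits(x, "model_input"))
  classes <- c("correct", "wrong")
  y_idx <- match(as.character(y), classes)
  if (anyNA(y_idx)) {
    abort("Labels must be 'correct' or 'wrong'.",
          class = "reachgcn_invalid_argument")
  }
  n <- dim(x$tensors[[1]])[1]
  if (length(y_idx) != n) {
    abort("Length of `y` must match the batch dimension of `x`.",
          class = "reachgcn_shape_error")
  }
  graph <- build_chain_graph(dim(x$tensors[[1]])[4])
  if (identical(class_weights, "balanced")) {
    freq <- tabulate(y_idx, 2)
    class_weights <- sum(freq) / (2 * pmax(freq, 1))
  }
  set.seed(seed)
  params <- init_backbone_params(config, d_in = dim(x$tensors[[1]])[2],
                                 seed = seed)
  mstate <- NULL; vstate <- NULL
  step <- 0L
  total_steps <- epochs * ceiling(n / batch_size)
  lr_at <- function(t) {
    f <- if (warmup_steps > 0) min(1, t / warmup_steps) else 1
    if (lr_schedule == "cosine") {
      prog <- max(0, min(1, (t - warmup_steps) /
                           max(1, total_steps - warmup_steps)))
      f <- f * 0.5 * (1 + cos(pi * prog))
    }
    lr * f
  }
  history <- list()
  step_log <- numeric(0)
  for (ep in seq_len(epochs)) {
    perm <- if (balance_batches) {
      idx1 <- which(y_idx == 1L); idx2 <- which(y_idx == 2L)
      half <- ceiling(n / 2)
      sample(c(sample(idx1, half, replace = length(idx1) < half),
               sample(idx2, n - half, replace = length(idx2) < n - half)))
    } else {
      sample(n)
    }
    batches <- split(perm, ceiling(seq_along(perm) / batch_size))
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0
    for (b in batches) {
      st <- shared_step(params, config, graph, x$tensors, y_idx, b,
                        training = TRUE, class_weights = class_weights)
      params <- st$params
      step <- step + 1L
      up <- adam_step(params, st$grads, mstate, vstate, lr_at(step), step,
                      weight_decay = weight_decay)
      params <- up$p; mstate <- up$m; vstate <- up$v
      ep_loss <- ep_loss + st$loss * length(b)
      ep_acc <- ep_acc + st$acc * length(b)
      ep_n <- ep_n + length(b)
      step_log <- c(step_log, st$loss)
    }
    val_acc <- NA_real_; val_loss <- NA_real_
    if (!is.null(validation)) {
      ev <- evaluate_model(
        structure(list(params = params, config = config, graph = graph,
                       classes = classes), class = "ghost_stgcn"),
        validation$x, validation$y)
      val_acc <- ev$accuracy; val_loss <- ev$loss
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / ep_n, accuracy = ep_acc / ep_n,
      val_loss = val_loss, val_accuracy = val_acc
    )
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  acc %.3f  val_acc %s",
                      ep, ep_loss / ep_n, ep_acc / ep_n,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  }
  structure(
    list(params = params, config = config, graph = graph,
         classes = classes, history = dplyr::bind_rows(history),
         step_losses = step_log, seed = seed,
         groups = x$group_names),
    class = "ghost_stgcn"
  )
}

#' Predict pose correctness for new clips
#'
#' @param object A fitted `ghost_stgcn`.
#' @param newdata A `model_input`.
#' @param type `"class"` for hard labels, `"prob"` for a tibble of
#'   class probabilities.
#' @param batch_size Clips per forward pass.
#' @param ... Unused.
#' @return A character vector of labels, or a tibble with columns
#'   `clip_id`, `.pred_correct`, `.pred_wrong`.
#' @export
predict.ghost_stgcn <- function(object, newdata, type = c("class", "prob"),
                                batch_size = 64L, ...) {
  type <- match.arg(type)
  n <- dim(newdata$tensors[[1]])[1]
  y_dummy <- rep(1L, n)
  probs <- matrix(NA_real_, 2, n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    st <- shared_step(object$params, object$config, object$graph,
                      newdata$tensors, y_dummy, b, training = FALSE)
    probs[, b] <- st$probs
  }
  if (type == "class") {
    object$classes[max.col(t(probs))]
  } else {
    tibble::tibble(
      clip_id = newdata$clip_ids,
      .pred_correct = probs[1, ],
      .pred_wrong = probs[2, ]
    )
  }
}

#' Evaluate a fitted model on labeled data
#'
#' @param model A fitted `ghost_stgcn`.
#' @param x A `model_input`.
#' @param y True labels (`"correct"` / `"wrong"`).
#' @return A list with `accuracy`, `loss` and the confusion tibble.
#' @export
evaluate_model <- function(model, x, y) {
  y_idx <- match(as.character(y), model$classes)
  n <- dim(x$tensors[[1]])[1]
  loss_sum <- 0; correct <- 0
  preds <- integer(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / 64))) {
    st <- shared_step(model$params, model$config, model$graph, x$tensors,
                      y_idx, b, training = FALSE)
    loss_sum <- loss_sum + st$loss * length(b)
    correct <- correct + st$acc * length(b)
    preds[b] <- max.col(t(st$probs))
  }
  confusion <- tibble::tibble(
    truth = model$classes[y_idx],
    prediction = model$classes[preds]
  ) |>
    dplyr::count(.data$truth, .data$prediction)
  list(accuracy = correct / n, loss = loss_sum / n, confusion = confusion)
}

#' @export
print.ghost_stgcn <- function(x, ...) {
  cat("<ghost_stgcn>", length(x$config$plan), "blocks,",
      format(model_n_params(x), big.mark = ","), "parameters\n")
  cat("  plan:", paste(vapply(x$config$plan, function(s) {
    sprintf("%d,%d,%d", s$c_in, s$c_out, s$stride)
  }, character(1)), collapse = " | "), "\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs, final loss %.4f, train acc %.3f\n",
                last$epoch, last$loss, last$accuracy))
  }
  invisible(x)
}

model_n_params <- function(model) {
  count <- function(p) {
    if (is.list(p)) return(sum(vapply(p, count, numeric(1))))
    length(p)
  }
  trainable <- model$params
  for (i in seq_along(trainable$blocks)) {
    trainable$blocks[[i]]$bn_rmean <- NULL
    trainable$blocks[[i]]$bn_rvar <- NULL
  }
  for (s in seq_along(trainable$input_bn)) {
    trainable$input_bn[[s]]$rmean <- NULL
    trainable$input_bn[[s]]$rvar <- NULL
  }
  count(trainable)
}

#' Describe a model's block plan
#'
#' Prints the per-block plan as `Cin,Cout,stride` triples, one block
#' per line, matching the backbone notation.
#'
#' @param model A fitted `ghost_stgcn` or a [backbone_config()].
#' @return The plan as a character vector, invisibly.
#' @export
describe_model <- function(model) {
  config <- if (inherits(model, "ghost_stgcn")) model$config else model
  lines <- vapply(seq_along(config$plan), function(i) {
    s <- config$plan[[i]]
    sprintf("B%d: %d,%d,%d", i, s$c_in, s$c_out, s$stride)
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Save / load a model checkpoint as self-describing JSON
#'
#' The checkpoint echoes the backbone configuration and group names and
#' stores every weight at full precision.
#'
#' @param model A fitted `ghost_stgcn`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns a `ghost_stgcn`.
#' @export
save_checkpoint <- function(model, path) {
  enc <- function(p) {
    if (is.list(p)) return(lapply(p, enc))
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         data = as.vector(p))
  }
  plan <- lapply(model$config$plan, function(s) {
    list(c_in = s$c_in, c_out = s$c_out, stride = s$stride,
         use_ghost = s$use_ghost, use_residual = s$use_residual)
  })
  obj <- list(
    format = "reachgcn-checkpoint-1",
    config = list(plan = plan, kernel = model$config$kernel,
                  dropout = model$config$dropout,
                  n_classes = model$config$n_classes,
                  fusion = model$config$fusion,
                  shared_weights = model$config$shared_weights),
    classes = model$classes,
    groups = model$groups,
    num_nodes = model$graph$num_nodes,
    params = enc(model$params)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  # no simplification: homogeneous record lists must stay lists, never
  # collapse into data frames
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- function(p) {
    if (is.list(p) && !is.null(names(p)) &&
        setequal(names(p), c("dim", "data"))) {
      d <- as.integer(unlist(p$dim))
      x <- as.numeric(unlist(p$data))
      if (length(d) > 1) return(array(x, d))
      return(x)
    }
    if (is.list(p)) return(lapply(p, dec))
    p
  }
  plan <- lapply(obj$config$plan, function(r) {
    block_spec(r$c_in, r$c_out, r$stride, use_ghost = r$use_ghost,
               use_residual = r$use_residual)
  })
  config <- backbone_config(plan, kernel = obj$config$kernel,
                            dropout = obj$config$dropout,
                            n_classes = obj$config$n_classes,
                            fusion = obj$config$fusion,
                            shared_weights = obj$config$shared_weights)
  structure(
    list(params = dec(obj$params), config = config,
         graph = build_chain_graph(obj$num_nodes),
         classes = unlist(obj$classes),
         history = tibble::tibble(), step_losses = numeric(0),
         seed = NA_integer_, groups = unlist(obj$groups)),
    class = "ghost_stgcn"
  )
}
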