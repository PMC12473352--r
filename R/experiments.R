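# Evaluation protocol: stratified holdout split, repeated stratified
# k-fold cross-validation, ablation grid over depth x residual x ghost.

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Per class, `round(fraction * size)` clips (round-half-up) go to the
#' training set and the rest to testing; membership is randomized by
#' `seed`, the counts are seed-independent.  At the study scale of
#' 1014 correct and 186 wrong clips with an 8:2 ratio this yields
#' 811/203 and 149/37.
#'
#' @param labels Character/factor vector of clip labels, or a named
#'   integer vector of class sizes (then synthetic indices are used).
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed RNG seed for membership.
#' @return A `split_plan`: list with `assignments` (tibble `index`,
#'   `label`, `set`) and `counts` (tibble `label`, `train`, `test`).
#' @export
stratified_split <- function(labels, fraction = 0.8, seed = 1L) {
  if (is.numeric(labels) && !is.null(names(labels))) {
    if (any(labels == 0)) {
      abort("Every class must have positive size.",
            class = "reachgcn_invalid_argument")
    }
    labels <- rep(names(labels), times = labels)
  }
  labels <- as.character(labels)
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be in (0, 1).",
          class = "reachgcn_invalid_argument")
  }
  if (any(table(labels) == 0) || length(labels) == 0) {
    abort("Every class must be non-empty.",
          class = "reachgcn_invalid_argument")
  }
  set.seed(seed)
  set <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_train <- round_half_up(fraction * length(idx))
    train_idx <- sample(idx, n_train)
    set[train_idx] <- "train"
    set[setdiff(idx, train_idx)] <- "test"
  }
  assignments <- tibble::tibble(index = seq_along(labels), label = labels,
                                set = set)
  counts <- assignments |>
    dplyr::count(.data$label, .data$set) |>
    tidyr::pivot_wider(names_from = "set", values_from = "n",
                       values_fill = 0L)
  structure(list(assignments = assignments, counts = counts,
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> fraction", x$fraction, "\n")
  print(x$counts)
  invisible(x)
}

#' Repeated stratified k-fold cross-validation plan
#'
#' Builds `n_shuffles` independent stratified partitions of the clips
#' into `k` folds (every clip in exactly one test fold per shuffle),
#' for `k * n_shuffles` evaluations in total — 100 under the protocol
#' default of 5 folds and 20 shuffles.
#'
#' @param labels Clip labels (character/factor).
#' @param k Number of folds (default 5).
#' @param n_shuffles Number of random reshuffles (default 20).
#' @param seed Master seed; each shuffle derives its own.
#' @return A `cv_plan`: list with `folds` (tibble `shuffle`, `index`,
#'   `label`, `fold`), `k`, `n_shuffles`.
#' @export
make_cv_plan <- function(labels, k = 5L, n_shuffles = 20L, seed = 1L) {
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < k)) {
    abort(sprintf("Every class must have at least k = %d members.", k),
          class = "reachgcn_invalid_argument")
  }
  set.seed(seed)
  shuffle_seeds <- sample.int(.Machine$integer.max - 1L, n_shuffles)
  folds <- purrr::map(seq_len(n_shuffles), function(s) {
    set.seed(shuffle_seeds[s])
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    tibble::tibble(shuffle = s, index = seq_along(labels), label = labels,
                   fold = fold)
  })
  structure(list(folds = dplyr::bind_rows(folds), k = as.integer(k),
                 n_shuffles = as.integer(n_shuffles), seed = seed),
            class = "cv_plan")
}

#' Run cross-validation with a pluggable evaluator
#'
#' Executes every (shuffle, fold) cell of a [make_cv_plan()]: the
#' evaluator receives the train and test indices and returns the test
#' accuracy.  Any classifier can sit behind it — the Ghost-ST-GCN
#' trainer, the scripted angle rule, or a baseline.
#'
#' @param plan A `cv_plan`.
#' @param evaluator `function(train_idx, test_idx) -> accuracy in [0,1]`.
#' @return An `accuracy_stats` object: per-run accuracies plus mean,
#'   sd, min, max and the 95% normal CI `mean +/- 1.96 sd / sqrt(n)`.
#' @export
run_cv <- function(plan, evaluator) {
  stopifnot(inherits(plan, "cv_plan"))
  cells <- tidyr::expand_grid(shuffle = seq_len(plan$n_shuffles),
                              fold = seq_len(plan$k))
  accs <- purrr::pmap_dbl(cells, function(shuffle, fold) {
    sub <- plan$folds[plan$folds$shuffle == shuffle, ]
    test_idx <- sub$index[sub$fold == fold]
    train_idx <- sub$index[sub$fold != fold]
    evaluator(train_idx, test_idx)
  })
  accuracy_stats(dplyr::mutate(cells, accuracy = accs))
}

#' Summary statistics over per-run accuracies
#'
#' @param runs A tibble with an `accuracy` column (and any id columns).
#' @return An `accuracy_stats` object.
#' @export
accuracy_stats <- function(runs) {
  a <- runs$accuracy
  n <- length(a)
  mu <- mean(a)
  s <- if (n > 1) sd(a) else 0
  half <- 1.96 * s / sqrt(n)
  structure(
    list(runs = runs,
         summary = tibble::tibble(
           n_runs = n, mean = mu, sd = s, min = min(a), max = max(a),
           ci_lower = mu - half, ci_upper = mu + half)),
    class = "accuracy_stats"
  )
}

#' @export
print.accuracy_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<accuracy_stats> %d runs: mean %.4f (sd %.4f), range [%.4f, %.4f], 95%% CI [%.4f, %.4f]\n",
    s$n_runs, s$mean, s$sd, s$min, s$max, s$ci_lower, s$ci_upper))
  invisible(x)
}

#' Evaluator factories for [run_cv()]
#'
#' `rule_evaluator()` classifies with the scripted angle-threshold rule
#' (no training, so the train indices are ignored);
#' `stgcn_evaluator()` trains a fresh Ghost-ST-GCN on each training
#' fold and scores the test fold, optionally after affine test-set
#' augmentation.
#'
#' @param clips List of `skeleton_clip`s (rule evaluator).
#' @param labels True labels aligned with the clips / tensors.
#' @return A `function(train_idx, test_idx) -> accuracy`.
#' @export
rule_evaluator <- function(clips, labels) {
  preds <- vapply(clips, rule_classify, character(1))
  function(train_idx, test_idx) {
    mean(preds[test_idx] == labels[test_idx])
  }
}

#' @rdname rule_evaluator
#' @param x A batched `model_input` over all clips (stgcn evaluator).
#' @param config,epochs,batch_size,lr,seed Passed to
#'   [fit_ghost_stgcn()].
#' @param augment_test `function(model_input) -> model_input` applied
#'   to each test fold (e.g. an [affine_augment()] wrapper), or `NULL`.
#' @export
stgcn_evaluator <- function(x, labels, config = backbone_config(),
                            epochs = 5L, batch_size = 32L, lr = 1e-3,
                            seed = 1L, augment_test = NULL) {
  force(x); force(labels)
  function(train_idx, test_idx) {
    xt <- subset_model_input(x, train_idx)
    xe <- subset_model_input(x, test_idx)
    if (!is.null(augment_test)) xe <- augment_test(xe)
    fit <- fit_ghost_stgcn(xt, labels[train_idx], config, epochs = epochs,
                           batch_size = batch_size, lr = lr, seed = seed)
    evaluate_model(fit, xe, labels[test_idx])$accuracy
  }
}

#' Subset a batched model input along the clip axis
#'
#' @param x A `model_input`.
#' @param idx Clip indices to keep.
#' @return A `model_input` with `length(idx)` clips.
#' @export
subset_model_input <- function(x, idx) {
  structure(
    list(tensors = lapply(x$tensors,
                          function(a) a[idx, , , , drop = FALSE]),
         group_names = x$group_names,
         clip_ids = x$clip_ids[idx]),
    class = "model_input"
  )
}

#' Ablation grid over depth, residual and ghost variants
#'
#' Trains one model per grid cell — depths from {3, 6, 9, 12, 15}
#' crossed with residual on/off and ghost on/off — under identical
#' data, budget and seed, and reports holdout accuracy per cell.
#' Depths below 9 truncate the block plan's prefix; depths above 9
#' repeat the final (256, 256, 1) stage.
#'
#' @param x Batched `model_input`.
#' @param labels Clip labels.
#' @param depths Subset of `c(3, 6, 9, 12, 15)`.
#' @param residual,ghost Logical vectors of variants to cross.
#' @param split A [stratified_split()] over the clips; built at 0.8
#'   with `seed` if omitted.
#' @param epochs,batch_size,lr,seed Training budget, identical for all
#'   cells.
#' @param verbose Print one line per cell?
#' @param ... Further arguments passed to [fit_ghost_stgcn()] (e.g.
#'   `lr_schedule`, `warmup_steps`, `balance_batches`).
#' @return A tibble `depth`, `residual`, `ghost`, `accuracy`,
#'   `n_params`.
#' @export
run_ablation <- function(x, labels, depths = c(3L, 6L, 9L, 12L, 15L),
                         residual = c(TRUE, FALSE), ghost = c(TRUE, FALSE),
                         split = NULL, epochs = 5L, batch_size = 32L,
                         lr = 1e-3, seed = 1L, verbose = FALSE, ...) {
  if (!all(depths %in% c(3L, 6L, 9L, 12L, 15L))) {
    abort("`depths` must be a subset of {3, 6, 9, 12, 15}.",
          class = "reachgcn_invalid_argument")
  }
  if (is.null(split)) split <- stratified_split(labels, 0.8, seed)
  tr <- split$assignments$index[split$assignments$set == "train"]
  te <- split$assignments$index[split$assignments$set == "test"]
  grid <- tidyr::expand_grid(depth = depths, residual = residual,
                             ghost = ghost)
  res <- purrr::pmap(grid, function(depth, residual, ghost) {
    plan <- default_backbone_plan(depth, use_ghost = ghost,
                                  use_residual = residual)
    config <- backbone_config(plan)
    fit <- fit_ghost_stgcn(subset_model_input(x, tr), labels[tr], config,
                           epochs = epochs, batch_size = batch_size,
                           lr = lr, seed = seed, ...)
    acc <- evaluate_model(fit, subset_model_input(x, te),
                          labels[te])$accuracy
    if (verbose) {
      message(sprintf("depth %2d residual %-5s ghost %-5s -> acc %.3f",
                      depth, residual, ghost, acc))
    }
    tibble::tibble(depth = depth, residual = residual, ghost = ghost,
                   accuracy = acc, n_params = model_n_params(fit))
  })
  dplyr::bind_rows(res)
}
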