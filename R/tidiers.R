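# tidy()/glance()/autoplot() methods for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted Ghost-ST-GCN
#'
#' One row per backbone block: the (c_in, c_out, stride) plan, the
#' flags, and the block's parameter count.
#'
#' @param x A fitted `ghost_stgcn`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ghost_stgcn <- function(x, ...) {
  purrr::imap(x$config$plan, function(s, i) {
    tibble::tibble(block = i, c_in = s$c_in, c_out = s$c_out,
                   stride = s$stride, ghost = s$use_ghost,
                   residual = s$use_residual,
                   n_params = count_block_params(s, cheap_op = "grouped1x1",
                                                 include_bn = TRUE,
                                                 include_bias = TRUE))
  }) |>
    dplyr::bind_rows()
}

#' @rdname tidy.ghost_stgcn
#' @export
glance.ghost_stgcn <- function(x, ...) {
  last <- if (nrow(x$history) > 0) x$history[nrow(x$history), ] else
    tibble::tibble(epoch = 0L, loss = NA_real_, accuracy = NA_real_,
                   val_accuracy = NA_real_)
  tibble::tibble(
    n_blocks = length(x$config$plan),
    n_params = model_n_params(x),
    fusion = x$config$fusion,
    epochs = last$epoch,
    loss = last$loss,
    train_accuracy = last$accuracy,
    val_accuracy = last$val_accuracy
  )
}

#' Training-history curve of a fitted model
#'
#' @param object A fitted `ghost_stgcn`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ghost_stgcn <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("loss", "accuracy"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Ghost-ST-GCN training history") +
    ggplot2::theme_minimal()
}

#' Tidy cross-validation accuracy statistics
#'
#' `tidy()` returns the per-run accuracies; `glance()` the one-row
#' summary (mean, sd, min, max, 95% CI); `autoplot()` the accuracy
#' histogram across runs.
#'
#' @param x An `accuracy_stats` object (see [run_cv()]).
#' @param ... Unused.
#' @return A tibble (or ggplot for `autoplot`).
#' @export
tidy.accuracy_stats <- function(x, ...) x$runs

#' @rdname tidy.accuracy_stats
#' @export
glance.accuracy_stats <- function(x, ...) x$summary

#' @rdname tidy.accuracy_stats
#' @param object An `accuracy_stats` object.
#' @export
autoplot.accuracy_stats <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$summary$mean,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold accuracy", y = "runs",
                  title = sprintf("Cross-validation accuracy over %d runs",
                                  object$summary$n_runs)) +
    ggplot2::theme_minimal()
}

#' Plot a backbone complexity report
#'
#' Side-by-side no-ghost vs ghost FLOPs per block, annotated with the
#' lightweight percentage.
#'
#' @param object A `complexity_report` from [report_backbone()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.complexity_report <- function(object, ...) {
  per_block <- object[!is.na(object$block), ]
  long <- per_block |>
    tidyr::pivot_longer(c("flops_no_ghost", "flops_ghost"),
                        names_to = "variant", values_to = "flops") |>
    dplyr::mutate(variant = ifelse(.data$variant == "flops_no_ghost",
                                   "no ghost", "ghost"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$block),
                                     y = .data$flops / 1e6,
                                     fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "block", y = "MFLOPs", fill = NULL,
                  title = "Per-block FLOPs with and without the ghost layer") +
    ggplot2::theme_minimal()
}
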