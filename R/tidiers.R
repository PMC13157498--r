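# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x A `pa_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (loss components and validation
#'   AUC).
#' @method tidy pa_fit
#' @export
tidy.pa_fit <- function(x, ...) x$history

#' @rdname tidy.pa_fit
#' @method glance pa_fit
#' @export
glance.pa_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(phase = x$config$phase,
                 epochs = nrow(h),
                 best_epoch = x$best_epoch,
                 best_val_auc = if (nrow(h)) suppressWarnings(max(h$val_auc, na.rm = TRUE)) else NA_real_,
                 final_total = if (nrow(h)) h$total[nrow(h)] else NA_real_)
}

#' Tidy an FROC curve
#'
#' @param x A `pa_froc`.
#' @param ... Unused.
#' @return `tidy()` returns the (threshold, sensitivity, avg_fp) tibble;
#'   `glance()` a one-row summary with sensitivity at 0.25/0.5/1 average
#'   FP.
#' @method tidy pa_froc
#' @export
tidy.pa_froc <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.pa_froc
#' @method glance pa_froc
#' @export
glance.pa_froc <- function(x, ...) {
  tibble::tibble(n_images = attr(x, "n_images"),
                 n_gt = attr(x, "n_gt"),
                 sens_at_fp025 = sensitivity_at_fp(x, 0.25),
                 sens_at_fp05 = sensitivity_at_fp(x, 0.5),
                 sens_at_fp1 = sensitivity_at_fp(x, 1),
                 max_sensitivity = max(x$sensitivity),
                 max_avg_fp = max(x$avg_fp))
}

#' Plot an FROC curve
#'
#' @param object A `pa_froc`.
#' @param ... Unused.
#' @return A ggplot: sensitivity versus average false positives per image.
#' @method autoplot pa_froc
#' @export
autoplot.pa_froc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$avg_fp, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "average false positives per image", y = "sensitivity",
                  title = "FROC") +
    ggplot2::theme_minimal()
}

#' Plot a patch prediction map
#'
#' @param object A `pa_prediction_map`.
#' @param ... Unused.
#' @return A ggplot tile map of per-patch finding probabilities (grid row 1
#'   at the top, matching image orientation).
#' @method autoplot pa_prediction_map
#' @export
autoplot.pa_prediction_map <- function(object, ...) {
  m <- object$probs
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$prob <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "black", high = "yellow") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("'%s' (global prob %.2f)", object$class_name,
                                  object$global_prob),
                  fill = "P(finding)") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object A `pa_fit`.
#' @param ... Unused.
#' @return A ggplot of loss components and validation AUC per epoch.
#' @method autoplot pa_fit
#' @export
autoplot.pa_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch", names_to = "metric",
                           values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = sprintf("training history (%s)", object$config$phase)) +
    ggplot2::theme_minimal()
}
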