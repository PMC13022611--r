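# ggplot2 displays for pipeline results.

#' Plot cross-validated metrics
#'
#' Per-fold metric values (points) with across-fold mean and SD (bars), one
#' panel per task.
#'
#' @param object A `cv_report`.
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, metrics = c("accuracy", "f1", "mcc", "auc"),
                               ...) {
  long <- tidy(object) |> dplyr::filter(.data$metric %in% metrics)
  summ <- object$summary |> dplyr::filter(.data$metric %in% metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6, size = 1.6) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      color = "firebrick", linewidth = 0.7, size = 0.3) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Cross-validated section-level performance",
                  subtitle = "points: folds; bar: mean ± population SD") +
    ggplot2::theme_minimal()
}

#' ROC curves from section predictions
#'
#' Empirical ROC over all test sections pooled across folds, one curve per
#' task, using the continuous section score.
#'
#' @param predictions The `predictions` tibble of a `cv_report` (or a
#'   `cv_report` itself).
#' @return A ggplot object.
#' @export
plot_roc <- function(predictions) {
  if (inherits(predictions, "cv_report")) predictions <- predictions$predictions
  pts <- predictions |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$task) |>
    dplyr::group_modify(function(d, key) roc_points(d$score, d$true_label)) |>
    dplyr::ungroup()
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr, color = .data$task)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "Section-level ROC (pooled test folds)") +
    ggplot2::theme_minimal()
}

#' Empirical ROC points
#'
#' Sweeps every distinct score threshold and returns (FPR, TPR) pairs.
#'
#' @param scores Numeric scores.
#' @param y_true Binary truth.
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, y_true) {
  y <- as.integer(y_true)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tibble::tibble(
    threshold = ths,
    tpr = vapply(ths, function(t) mean(scores[y == 1] >= t), 0),
    fpr = vapply(ths, function(t) mean(scores[y == 0] >= t), 0)
  )
}

#' Confusion-matrix heatmaps per task
#'
#' Pooled test-section confusion counts across folds.
#'
#' @param report A `cv_report`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(report) {
  d <- report$folds |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(dplyr::across(c("tp", "fp", "tn", "fn"), sum),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("tp", "fp", "tn", "fn"), names_to = "cell") |>
    dplyr::mutate(
      truth = ifelse(.data$cell %in% c("tp", "fn"), "positive", "negative"),
      pred = ifelse(.data$cell %in% c("tp", "fp"), "positive", "negative"))
  ggplot2::ggplot(d, ggplot2::aes(.data$pred, .data$truth, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$value), color = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = "Pooled section-level confusion") +
    ggplot2::theme_minimal()
}

#' Grad-CAM overlay for one patch
#'
#' Shows the patch with the heatmap alpha-blended on top.
#'
#' @param patch `H x W x 3` array of 0-255 pixels.
#' @param cam Heatmap matrix from [grad_cam()] (same spatial size).
#' @param alpha Maximum overlay opacity.
#' @return A ggplot object.
#' @export
plot_grad_cam <- function(patch, cam, alpha = 0.6) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  d <- tibble::tibble(y = rep(seq_len(h), times = w),
                      x = rep(seq_len(w), each = h)) |> # column-major order
    dplyr::mutate(
      r = as.vector(patch[, , 1]) / 255, g = as.vector(patch[, , 2]) / 255,
      b = as.vector(patch[, , 3]) / 255, heat = as.vector(cam))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = grDevices::rgb(d$r, d$g, d$b)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$heat),
                         alpha = alpha * d$heat) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "Grad-CAM") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
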