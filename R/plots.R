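#' Plot per-class precision-recall curves
#'
#' @param object An `eval_report` from [evaluate_detections()].
#' @param ... Unused.
#' @return A ggplot: one PR curve per severity class, with the class AP
#'   in the legend.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.eval_report <- function(object, ...) {
  ap <- setNames(object$per_class_ap$ap, object$per_class_ap$class_id)
  curves <- dplyr::mutate(
    object$pr_curves,
    label = sprintf("class %d (AP %.3f)", .data$class_id,
                    ap[as.character(.data$class_id)]))
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$recall, .data$precision,
                               colour = .data$label)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = NULL,
                  title = sprintf("mAP@0.5 = %.3f", object$map50)) +
    ggplot2::theme_minimal()
}

#' Plot the micro-averaged F1-confidence curve
#'
#' @param report An `eval_report`.
#' @return A ggplot of F1 against confidence threshold.
#' @export
plot_f1_curve <- function(report) {
  ggplot2::ggplot(report$f1_curve,
                  ggplot2::aes(.data$confidence, .data$f1)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Confidence threshold", y = "F1 (all classes)") +
    ggplot2::theme_minimal()
}

#' Plot the detection confusion matrix
#'
#' @param report An `eval_report`.
#' @param normalize Divide each ground-truth row by its sum (default
#'   FALSE: raw counts).
#' @return A ggplot heat map; rows are ground-truth classes (plus
#'   background), columns detected classes.
#' @export
plot_confusion <- function(report, normalize = FALSE) {
  cm <- report$confusion
  if (normalize) {
    rs <- rowSums(cm)
    cm <- sweep(cm, 1, ifelse(rs > 0, rs, 1), "/")
  }
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(cm, rownames = "gt")),
    -"gt", names_to = "det", values_to = "count")
  lv <- c(as.character(1:9), "background")
  df$gt <- factor(df$gt, levels = rev(lv))
  df$det <- factor(df$det, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$det, .data$gt,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$count > 0,
                     format(round(.data$count, 2)), "")), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Detected class", y = "Ground-truth class",
                  fill = if (normalize) "fraction" else "count") +
    ggplot2::theme_minimal()
}

#' Plot a vegetation index map
#'
#' @param object An `index_map` from [vegetation_index()].
#' @param ... Unused.
#' @return A ggplot raster of the index values (masked pixels blank).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.index_map <- function(object, ...) {
  v <- object$values
  df <- tidyr::expand_grid(y = seq_len(nrow(v)), x = seq_len(ncol(v)))
  df$value <- as.vector(t(v))[(df$y - 1) * ncol(v) + df$x]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$name, x = NULL, y = NULL,
                  fill = object$name) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
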