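#' Tidy a registration result
#'
#' Returns the per-iteration optimizer trace (metric value, search radius,
#' acceptance flag).
#'
#' @param x A `registration_result` from [register_pair()] or
#'   [optimize_one_plus_one()].
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `metric`, `radius`,
#'   `accepted`.
#' @exportS3Method generics::tidy
#' @export
tidy.registration_result <- function(x, ...) x$trace

#' @rdname tidy.registration_result
#' @return For `glance()`: a one-row tibble with `theta`, `tx`, `ty`,
#'   `metric_value`, `iterations`, `converged`.
#' @exportS3Method generics::glance
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(theta = x$transform$theta, tx = x$transform$tx,
                 ty = x$transform$ty, metric_value = x$metric_value,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` from [evaluate_detections()].
#' @param ... Unused.
#' @return Per-class AP and match counts (tibble `class_id`, `ap`,
#'   `n_gt`, `tp`, `fp`, `fn`).
#' @exportS3Method generics::tidy
#' @export
tidy.eval_report <- function(x, ...) x$per_class_ap

#' @rdname tidy.eval_report
#' @return For `glance()`: a one-row tibble with `map50`, `map50_95`,
#'   `class_count`, `f1_max` and `f1_max_confidence` (peak of the
#'   micro-averaged F1-confidence curve).
#' @exportS3Method generics::glance
#' @export
glance.eval_report <- function(x, ...) {
  i <- which.max(x$f1_curve$f1)
  tibble::tibble(map50 = x$map50, map50_95 = x$map50_95,
                 class_count = x$class_count,
                 f1_max = x$f1_curve$f1[i],
                 f1_max_confidence = x$f1_curve$confidence[i])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
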