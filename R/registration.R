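#' Metric settings for intensity-based registration
#'
#' Controls the mutual-information similarity metric: number of histogram
#' bins per axis, the spread of the Gaussian spatial weighting, and whether
#' weighting is applied at all. The Gaussian weight
#' `w(x, y) = exp(-((x - x_c)^2 + (y - y_c)^2) / (2 sigma^2))` enters the
#' joint-histogram accumulation, focusing the metric on the image center
#' where plot structure is densest.
#'
#' @param bins Histogram bins per intensity axis (>= 2); default 64.
#' @param sigma Weighting spread in pixels; default `min(H, W) / 4` of the
#'   image being registered (resolved at evaluation time when `NULL`).
#' @param weighted Apply the Gaussian weighting (default `TRUE`).
#' @param center Optional `(x_c, y_c)` weighting center; defaults to the
#'   image center `((W - 1) / 2, (H - 1) / 2)`.
#' @return An object of class `metric_settings`.
#' @export
metric_settings <- function(bins = 64, sigma = NULL, weighted = TRUE,
                            center = NULL) {
  stopifnot(bins >= 2)
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(bins = as.integer(bins), sigma = sigma, weighted = weighted,
                 center = center),
            class = "metric_settings")
}

#' Optimizer settings for the (1+1)-evolution strategy
#'
#' Defaults follow the study-calibrated search constants: growth factor
#' 1.002, at most 500 iterations, initial radius 2e-4 and stopping radius
#' 1.5e-6. The radius lives in normalized parameter space; per-parameter
#' step scales (radians, pixels, pixels) are supplied by the caller, by
#' default `(1, diag, diag)` where `diag` is the image diagonal.
#'
#' @param growth_factor Radius multiplier on acceptance (> 1); the radius
#'   shrinks by the same factor on rejection.
#' @param max_iterations Iteration cap.
#' @param initial_radius Starting search radius (normalized units).
#' @param epsilon Radius below which the search stops (`converged = TRUE`).
#' @param seed Integer seed for the proposal RNG.
#' @param pyramid_levels Coarse-to-fine levels (factor 2 per level).
#' @param init_search_px,init_search_deg Capture range of the exhaustive
#'   initial scan run at the coarsest pyramid level before the evolution
#'   strategy: translations up to `init_search_px` full-resolution pixels
#'   (1-pixel steps at the coarse grid) and rotations up to
#'   `init_search_deg` degrees (1-degree steps). Set `init_search_px = 0`
#'   to disable the scan.
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(growth_factor = 1.002, max_iterations = 500,
                               initial_radius = 2e-4, epsilon = 1.5e-6,
                               seed = 1L, pyramid_levels = 3L,
                               init_search_px = 12, init_search_deg = 3) {
  stopifnot(growth_factor > 1, epsilon < initial_radius, max_iterations >= 1,
            pyramid_levels >= 1, init_search_px >= 0, init_search_deg >= 0)
  structure(list(growth_factor = growth_factor,
                 max_iterations = as.integer(max_iterations),
                 initial_radius = initial_radius, epsilon = epsilon,
                 seed = as.integer(seed),
                 pyramid_levels = as.integer(pyramid_levels),
                 init_search_px = init_search_px,
                 init_search_deg = init_search_deg),
            class = "optimizer_settings")
}

#' Read registration settings from a YAML or JSON config file
#'
#' The file may hold a `metric` and/or an `optimizer` section whose
#' fields mirror the [metric_settings()] and [optimizer_settings()]
#' arguments (`bins`, `sigma`, `weighted`; `growth_factor`,
#' `max_iterations`, `initial_radius`, `epsilon`, `seed`,
#' `pyramid_levels`, ...). Omitted fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `metric` and `optimizer`.
#' @export
read_settings <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  list(metric = do.call(metric_settings, as.list(cfg$metric)),
       optimizer = do.call(optimizer_settings, as.list(cfg$optimizer)))
}

#' Gaussian spatial weight map
#'
#' @param shape Integer `(height, width)`.
#' @param sigma Spread in pixels (> 0).
#' @param center Optional `(x_c, y_c)`; defaults to the image center
#'   `((W - 1) / 2, (H - 1) / 2)` in 0-based coordinates.
#' @return Numeric `height x width` matrix with values in `(0, 1]`.
#' @export
gaussian_weights <- function(shape, sigma, center = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  H <- shape[1]; W <- shape[2]
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)
  x <- (seq_len(W) - 1) - center[1]
  y <- (seq_len(H) - 1) - center[2]
  exp(-(outer(y^2, x^2, `+`)) / (2 * sigma^2))
}

#' Weighted joint intensity histogram
#'
#' Bins two equal-shape images into `bins` equal-width intensity bins over
#' `[0, 1]` (value 1.0 falls in the last bin); each valid pixel contributes
#' its spatial weight (1 when unweighted) to one joint cell. The table is
#' normalized to sum to 1; marginals are its row and column sums.
#'
#' @param ref,mov Numeric matrices (or [band_image()]s) with values in
#'   `[0, 1]`, identical shape.
#' @param bins Bins per axis.
#' @param valid Optional logical matrix; pixels flagged `FALSE` are
#'   excluded (e.g. resampling fell outside the source grid).
#' @param weights Optional numeric weight matrix (same shape).
#' @return An object of class `joint_histogram` with elements `joint`,
#'   `marginal_ref`, `marginal_mov`, `total_weight`.
#' @export
joint_histogram <- function(ref, mov, bins = 64, valid = NULL,
                            weights = NULL) {
  ref <- as_pixel_matrix(ref); mov <- as_pixel_matrix(mov)
  if (!identical(dim(ref), dim(mov))) {
    stop("ref and mov must have identical shape", call. = FALSE)
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(ref), ncol(ref))
  if (!any(valid)) stop("zero valid pixels", call. = FALSE)
  if (!is.null(weights) && !identical(dim(weights), dim(ref))) {
    stop("weights shape mismatch", call. = FALSE)
  }
  joint <- cpp_joint_hist(ref, mov, valid, as.integer(bins), weights)
  total <- sum(joint)
  if (total <= 0) stop("zero total weight in histogram", call. = FALSE)
  joint <- joint / total
  structure(list(joint = joint,
                 marginal_ref = rowSums(joint),
                 marginal_mov = colSums(joint),
                 total_weight = total),
            class = "joint_histogram")
}

#' Mutual information of a joint histogram (bits)
#'
#' `MI = sum_ij p_ij log2(p_ij / (p_i p_j))`, with zero-probability cells
#' contributing zero. Nonnegative; equals the marginal entropy when the two
#' images are identical.
#'
#' @param hist A [joint_histogram()] (normalized).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(hist) {
  if (!inherits(hist, "joint_histogram")) {
    stop("expected a joint_histogram", call. = FALSE)
  }
  p <- hist$joint
  if (abs(sum(p) - 1) > 1e-8) stop("histogram is not normalized",
                                   call. = FALSE)
  outer_pp <- outer(hist$marginal_ref, hist$marginal_mov)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer_pp[nz]))
}

# Resolve sigma / center defaults against an image shape.
resolve_metric <- function(settings, shape) {
  sigma <- settings$sigma %||% (min(shape) / 4)
  center <- settings$center %||% c((shape[2] - 1) / 2, (shape[1] - 1) / 2)
  list(bins = settings$bins, sigma = sigma, weighted = settings$weighted,
       center = center)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the registration similarity metric
#'
#' Resamples `mov` through `transform` onto `ref`'s grid, accumulates the
#' (optionally Gaussian-weighted) joint histogram over the valid region,
#' and returns the mutual information in bits.
#'
#' @param ref,mov Numeric pixel matrices (or [band_image()]s) in `[0, 1]`.
#' @param transform A [rigid_transform()] applied to `mov`.
#' @param settings A [metric_settings()].
#' @return Mutual information in bits.
#' @export
evaluate_metric <- function(ref, mov, transform,
                            settings = metric_settings()) {
  ref <- as_pixel_matrix(ref); mov <- as_pixel_matrix(mov)
  ms <- resolve_metric(settings, dim(ref))
  w <- if (ms$weighted) gaussian_weights(dim(ref), ms$sigma, ms$center)
  mi <- cpp_eval_mi(ref, mov, transform$theta, transform$tx, transform$ty,
                    transform$center[1], transform$center[2],
                    ms$bins, w)
  if (is.na(mi)) stop("empty valid region after transformation",
                      call. = FALSE)
  mi
}

#' (1+1)-evolution strategy over rigid-transform parameters
#'
#' Stochastic hill-climb on `(theta, tx, ty)`: each iteration proposes
#' `parent + radius * scales * N(0, 1)` (independent draws per parameter,
#' seeded RNG) and accepts it only if the objective strictly improves; the
#' radius grows by `growth_factor` on acceptance and shrinks by the same
#' factor on rejection. The search stops when the radius falls below
#' `epsilon` (`converged = TRUE`) or after `max_iterations`.
#'
#' @param objective Function mapping a [rigid_transform()] to a finite
#'   number (maximized).
#' @param settings An [optimizer_settings()].
#' @param initial Starting [rigid_transform()].
#' @param scales Length-3 numeric step scales for `(theta, tx, ty)`.
#' @return An object of class `registration_result`: `transform`,
#'   `metric_value`, `iterations`, `converged`, and a `trace` tibble with
#'   one row per iteration (`iteration`, `metric`, `radius`, `accepted`).
#' @export
optimize_one_plus_one <- function(objective, settings = optimizer_settings(),
                                  initial = transform_identity(),
                                  scales = c(1, 1, 1)) {
  p <- c(initial$theta, initial$tx, initial$ty)
  f <- objective(initial)
  if (!is.finite(f)) stop("objective not finite at the initial transform",
                          call. = FALSE)
  radius <- settings$initial_radius
  g <- settings$growth_factor
  tr_iter <- integer(0); tr_metric <- numeric(0)
  tr_radius <- numeric(0); tr_acc <- logical(0)
  it <- 0L
  while (it < settings$max_iterations && radius >= settings$epsilon) {
    it <- it + 1L
    cand <- p + radius * scales * rnorm(3)
    t_cand <- rigid_transform(cand[1], cand[2], cand[3],
                              center = initial$center)
    f_cand <- objective(t_cand)
    if (!is.finite(f_cand)) {
      stop("objective became non-finite during search (iteration ", it, ")",
           call. = FALSE)
    }
    if (f_cand > f) {
      p <- cand; f <- f_cand; radius <- radius * g
      tr_acc <- c(tr_acc, TRUE)
    } else {
      radius <- radius / g
      tr_acc <- c(tr_acc, FALSE)
    }
    tr_iter <- c(tr_iter, it); tr_metric <- c(tr_metric, f)
    tr_radius <- c(tr_radius, radius)
  }
  structure(
    list(transform = rigid_transform(p[1], p[2], p[3],
                                     center = initial$center),
         metric_value = f, iterations = it,
         converged = radius < settings$epsilon,
         trace = tibble::tibble(iteration = tr_iter, metric = tr_metric,
                                radius = tr_radius, accepted = tr_acc)),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> MI = %.4f bits after %d iterations (%s)\n",
    x$metric_value, x$iterations,
    if (x$converged) "converged" else "iteration cap"))
  print(x$transform)
  invisible(x)
}

# 2x2 block-mean pyramid reduction (odd trailing row/col dropped).
pyramid_reduce <- function(pixels) {
  H2 <- nrow(pixels) %/% 2; W2 <- ncol(pixels) %/% 2
  a <- pixels[seq_len(2 * H2), seq_len(2 * W2), drop = FALSE]
  (a[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
   a[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
   a[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
   a[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]) / 4
}

#' Register one moving band to a reference band
#'
#' Coarse-to-fine rigid registration maximizing Gaussian-weighted mutual
#' information with the (1+1)-evolution strategy. Each pyramid level
#' (factor 2) runs the optimizer on [evaluate_metric()], initialized from
#' the previous (coarser) level with translations doubled; the finest-level
#' result is reported. Step scales are `(1, diag, diag)` so the normalized
#' search radius corresponds to comparable angular and translational
#' perturbations.
#'
#' @param ref,mov Reference and moving images ([band_image()] or matrix).
#'   If shapes differ, `mov` is first bilinearly resized to `ref`'s shape.
#' @param metric A [metric_settings()].
#' @param optimizer An [optimizer_settings()].
#' @return A `registration_result` whose transform maps `mov` onto `ref`'s
#'   grid (use with [apply_transform()]).
#' @export
register_pair <- function(ref, mov, metric = metric_settings(),
                          optimizer = optimizer_settings()) {
  ref <- as_pixel_matrix(ref); mov <- as_pixel_matrix(mov)
  if (diff(range(ref)) == 0 || diff(range(mov)) == 0) {
    stop("no intensity structure: constant image cannot be registered",
         call. = FALSE)
  }
  if (!identical(dim(ref), dim(mov))) {
    mov <- resize_bilinear(mov, nrow(ref), ncol(ref))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(optimizer$seed)

  # build pyramids, coarsest last
  refs <- list(ref); movs <- list(mov)
  for (l in seq_len(optimizer$pyramid_levels - 1)) {
    if (min(dim(refs[[l]])) < 16) break
    refs[[l + 1]] <- pyramid_reduce(refs[[l]])
    movs[[l + 1]] <- pyramid_reduce(movs[[l]])
  }
  levels <- length(refs)
  theta <- 0; tx <- 0; ty <- 0
  result <- NULL
  for (l in rev(seq_len(levels))) {
    r <- refs[[l]]; m <- movs[[l]]
    center <- c((ncol(r) - 1) / 2, (nrow(r) - 1) / 2)
    diag_px <- sqrt(nrow(r)^2 + ncol(r)^2)
    init <- rigid_transform(theta, tx, ty, center = center)
    ms <- resolve_metric(metric, dim(r))
    w_level <- if (ms$weighted) gaussian_weights(dim(r), ms$sigma, ms$center)
    obj <- function(t) {
      mi <- cpp_eval_mi(r, m, t$theta, t$tx, t$ty, t$center[1], t$center[2],
                        ms$bins, w_level)
      if (is.na(mi)) stop("empty valid region after transformation",
                          call. = FALSE)
      mi
    }
    if (l == levels && optimizer$init_search_px > 0) {
      # exhaustive capture-range scan: the evolution strategy's printed
      # radius only supports local refinement, so seed it from the best
      # coarse integer shift / whole-degree rotation
      scale_l <- 2^(l - 1)
      shift_max <- ceiling(optimizer$init_search_px / scale_l)
      shifts <- -shift_max:shift_max
      thetas <- if (optimizer$init_search_deg > 0) {
        seq(-optimizer$init_search_deg, optimizer$init_search_deg,
            by = 1) * pi / 180
      } else 0
      best <- obj(init)
      for (th in thetas) for (sx in shifts) for (sy in shifts) {
        cand <- rigid_transform(theta + th, tx + sx, ty + sy,
                                center = center)
        f <- obj(cand)
        if (f > best) { best <- f; init <- cand }
      }
      theta <- init$theta; tx <- init$tx; ty <- init$ty
    } else if (optimizer$init_search_deg > 0) {
      # rotation does not shrink with the pyramid: refine the angle on a
      # local grid before the stochastic polish at this level
      best <- obj(init)
      for (th in seq(-0.5, 0.5, by = 0.125) * pi / 180) {
        if (th == 0) next
        cand <- rigid_transform(theta + th, tx, ty, center = center)
        f <- obj(cand)
        if (f > best) { best <- f; init <- cand }
      }
      theta <- init$theta
    }
    result <- optimize_one_plus_one(obj, settings = optimizer,
                                    initial = init,
                                    scales = c(1, diag_px, diag_px))
    theta <- result$transform$theta
    if (l > 1) { # translations double when moving to the finer level
      tx <- 2 * result$transform$tx
      ty <- 2 * result$transform$ty
    }
  }
  result
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Register every band of a capture to a reference band
#'
#' Fits a rigid transform from each non-reference band to the reference
#' band (green, band 2, by default) and resamples all bands onto the
#' reference grid. The panchromatic band 6, if present, is first bilinearly
#' resized to the reference shape and then registered like the others.
#' Bands that fail to converge are still resampled; convergence is
#' reported per band in the `registration` summary.
#'
#' @param capture A raw [multispectral_capture()] with bands 1-5 (band 6
#'   optional).
#' @param reference_band Band index used as the fixed image (default 2).
#' @param metric A [metric_settings()].
#' @param optimizer An [optimizer_settings()]; per-band RNG streams are
#'   derived from its seed.
#' @return An aligned `multispectral_capture` with per-band `transforms`
#'   and a `registration` tibble (band, theta, tx, ty, metric, iterations,
#'   converged).
#' @export
register_capture <- function(capture, reference_band = 2,
                             metric = metric_settings(),
                             optimizer = optimizer_settings()) {
  ref_key <- as.character(reference_band)
  if (!ref_key %in% names(capture$bands)) {
    stop("reference band ", reference_band, " absent from capture",
         call. = FALSE)
  }
  ref <- capture$bands[[ref_key]]$pixels
  shape <- dim(ref)
  center <- c((shape[2] - 1) / 2, (shape[1] - 1) / 2)
  out_bands <- list()
  transforms <- list()
  summary_rows <- list()
  for (key in names(capture$bands)) {
    b <- capture$bands[[key]]
    if (key == ref_key) {
      out_bands[[key]] <- b
      transforms[[key]] <- transform_identity(center)
      summary_rows[[key]] <- tibble::tibble(
        band = as.integer(key), theta = 0, tx = 0, ty = 0,
        metric = NA_real_, iterations = 0L, converged = TRUE)
      next
    }
    mov <- b$pixels
    if (!identical(dim(mov), shape)) mov <- resize_bilinear(mov, shape[1],
                                                            shape[2])
    band_opt <- optimizer
    band_opt$seed <- optimizer$seed + as.integer(key)
    fit <- register_pair(ref, mov, metric = metric, optimizer = band_opt)
    warped <- apply_transform(mov, fit$transform, output_shape = shape)
    out_bands[[key]] <- band_image(pmin(pmax(warped$pixels, 0), 1),
                                   as.integer(key),
                                   source_path = b$source_path)
    transforms[[key]] <- fit$transform
    summary_rows[[key]] <- tibble::tibble(
      band = as.integer(key), theta = fit$transform$theta,
      tx = fit$transform$tx, ty = fit$transform$ty,
      metric = fit$metric_value, iterations = fit$iterations,
      converged = fit$converged)
  }
  aligned <- multispectral_capture(capture$capture_id, out_bands,
                                   aligned = TRUE, transforms = transforms)
  aligned$registration <- dplyr::bind_rows(summary_rows)
  aligned
}
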