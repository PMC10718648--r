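#' Run the preprocessing pipeline over a directory of captures
#'
#' For every capture found in `input_dir` (files `<id>_<band>.tif`):
#' register all bands to the reference band, compose the requested band
#' order, apply the enhancement preset, optionally resize the composite
#' to a detector-ready square, and write the aligned bands, the composite
#' and a JSON transform sidecar under `output_dir`. Captures that fail
#' are recorded in the manifest and skipped, not fatal.
#'
#' @param input_dir Directory of raw band TIFFs.
#' @param output_dir Output directory (created if needed).
#' @param reference_band Registration reference band (default 2, green).
#' @param preset Enhancement preset (`"stretch"` or `"haze_gamma"`).
#' @param band_order Composite band order, default `c(3, 2, 1)`.
#' @param resize_to Side length of the square detector-input composite in
#'   pixels (default 640); `NULL` skips resizing.
#' @param metric A [metric_settings()].
#' @param optimizer An [optimizer_settings()]; its seed drives all
#'   registration randomness.
#' @return Invisibly, the run manifest: a tibble with one row per capture
#'   (`capture_id`, `status`, `message`, `mean_metric`, `all_converged`,
#'   `composite`). Also written as `manifest.json` in `output_dir`.
#' @export
run_preprocess <- function(input_dir, output_dir, reference_band = 2,
                           preset = "stretch", band_order = c(3, 2, 1),
                           resize_to = 640,
                           metric = metric_settings(),
                           optimizer = optimizer_settings()) {
  ids <- discover_captures(input_dir)
  if (length(ids) == 0) stop("no captures found in ", input_dir,
                             call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(ids, function(id) {
    tryCatch({
      cap <- assemble_capture(input_dir, id)
      aligned <- register_capture(cap, reference_band = reference_band,
                                  metric = metric, optimizer = optimizer)
      for (key in names(aligned$bands)) {
        write_band_tiff(aligned$bands[[key]]$pixels,
                        file.path(output_dir,
                                  paste0(id, "_aligned_", key, ".tif")))
      }
      tj <- lapply(aligned$transforms, function(t)
        list(theta = t$theta, tx = t$tx, ty = t$ty, center = t$center))
      jsonlite::write_json(tj,
                           file.path(output_dir,
                                     paste0(id, "_transforms.json")),
                           auto_unbox = TRUE, digits = NA)
      rgb <- compose_bands(aligned, order = band_order)
      rgb <- apply_preset(rgb, preset)
      if (!is.null(resize_to)) {
        rgb <- array(c(resize_bilinear(rgb[, , 1], resize_to, resize_to),
                       resize_bilinear(rgb[, , 2], resize_to, resize_to),
                       resize_bilinear(rgb[, , 3], resize_to, resize_to)),
                     dim = c(resize_to, resize_to, 3))
      }
      comp_path <- file.path(output_dir, paste0(id, "_composite.png"))
      write_rgb(rgb, comp_path)
      reg <- aligned$registration
      tibble::tibble(capture_id = id, status = "ok", message = "",
                     mean_metric = mean(reg$metric, na.rm = TRUE),
                     all_converged = all(reg$converged),
                     composite = comp_path)
    }, error = function(e) {
      tibble::tibble(capture_id = id, status = "failed",
                     message = conditionMessage(e),
                     mean_metric = NA_real_, all_converged = NA,
                     composite = NA_character_)
    })
  })
  manifest <- dplyr::bind_rows(records)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}

# Capture ids are the filename prefixes of `<id>_<band>.tif` files.
discover_captures <- function(input_dir) {
  if (!dir.exists(input_dir)) stop("no such directory: ", input_dir,
                                   call. = FALSE)
  f <- list.files(input_dir, pattern = "_[1-6]\\.tiff?$", ignore.case = TRUE)
  sort(unique(sub("_[1-6]\\.tiff?$", "", f, ignore.case = TRUE)))
}

#' Evaluate detection files against ground-truth files
#'
#' Reads matching annotation files from `gt_dir` and `pred_dir` (same
#' basenames; predictions carry a sixth confidence column), applies the
#' confidence filter and non-maximum suppression to the predictions, and
#' computes the full [evaluate_detections()] report. Prediction files
#' without a ground-truth counterpart are kept (their boxes can only be
#' false positives) with a warning.
#'
#' @param gt_dir,pred_dir Directories of annotation text files.
#' @param image_width,image_height Pixel frame used to denormalize boxes
#'   (default 640, the detector input size).
#' @param iou_threshold Match IoU (default 0.5).
#' @param conf_threshold Confidence filter applied to predictions
#'   (default 0.001).
#' @param nms_iou NMS overlap threshold (default 0.45).
#' @param output Optional path for a JSON report.
#' @return An `eval_report` (see [evaluate_detections()]).
#' @export
run_evaluate <- function(gt_dir, pred_dir, image_width = 640,
                         image_height = 640, iou_threshold = 0.5,
                         conf_threshold = 0.001, nms_iou = 0.45,
                         output = NULL) {
  gt_files <- list.files(gt_dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(gt_files) == 0) stop("no ground-truth files in ", gt_dir,
                                  call. = FALSE)
  gts <- dplyr::bind_rows(lapply(gt_files, function(p)
    read_boxes(p, image_width, image_height)))
  pred_files <- list.files(pred_dir, pattern = "\\.txt$", full.names = TRUE)
  dets <- if (length(pred_files) == 0) empty_boxes() else
    dplyr::bind_rows(lapply(pred_files, function(p)
      read_boxes(p, image_width, image_height, with_confidence = TRUE)))
  orphans <- setdiff(unique(dets$image_id), unique(gts$image_id))
  if (length(orphans)) {
    warning("predictions without ground truth (scored as false positives): ",
            paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (nrow(dets) > 0) {
    dets <- confidence_filter(dets, conf_threshold)
    dets <- nms(dets, iou_threshold = nms_iou)
  }
  report <- evaluate_detections(dets, gts, iou_threshold = iou_threshold)
  if (!is.null(output)) write_eval_report(report, output)
  report
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  payload <- list(
    map50 = report$map50,
    map50_95 = report$map50_95,
    class_count = report$class_count,
    per_class_ap = report$per_class_ap,
    f1_curve = report$f1_curve,
    confusion = report$confusion
  )
  jsonlite::write_json(payload, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Seeded train/validation/test split
#'
#' Shuffles the ids once and partitions them by the requested fractions
#' (70/10/20 by default). Counts are rounded so every id lands in exactly
#' one subset.
#'
#' @param ids Character or integer vector of item ids.
#' @param fractions Named fractions summing to 1.
#' @param seed Integer seed.
#' @return Named list of id vectors, one per subset.
#' @export
split_dataset <- function(ids, fractions = c(train = 0.7, val = 0.1,
                                             test = 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  shuffled <- sample(ids)
  n <- length(ids)
  counts <- diff(c(0, round(cumsum(fractions) * n)))
  ends <- cumsum(counts)
  starts <- c(1, head(ends, -1) + 1)
  out <- lapply(seq_along(fractions), function(i)
    if (counts[i] > 0) shuffled[starts[i]:ends[i]] else ids[0])
  names(out) <- names(fractions)
  out
}
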