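#' Single-band image
#'
#' Container for one spectral band: a numeric pixel matrix in `[0, 1]`
#' plus band metadata. Band indices follow the sensor layout: 1 blue,
#' 2 green, 3 red, 4 red edge, 5 near-infrared, 6 panchromatic.
#'
#' @param pixels Numeric matrix with values in `[0, 1]` (rows = y, cols = x).
#' @param band_index Integer in 1..6.
#' @param source_path Optional path the band was loaded from.
#' @return An object of class `band_image`.
#' @export
band_image <- function(pixels, band_index, source_path = NA_character_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  band_index <- as.integer(band_index)
  if (!band_index %in% 1:6) stop("band_index must be in 1..6", call. = FALSE)
  if (any(pixels < -1e-9 | pixels > 1 + 1e-9, na.rm = TRUE)) {
    stop("band pixels must lie in [0, 1]", call. = FALSE)
  }
  meta <- band_info[band_info$band_index == band_index, ]
  structure(
    list(pixels = pixels, band_index = band_index,
         center_nm = meta$center_nm, bandwidth_nm = meta$bandwidth_nm,
         source_path = source_path),
    class = "band_image"
  )
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("<band_image> band %d (%s, %g nm), %d x %d px\n",
              x$band_index,
              band_info$name[x$band_index], x$center_nm,
              ncol(x$pixels), nrow(x$pixels)))
  invisible(x)
}

#' Multi-spectral capture
#'
#' One camera shot: the set of per-band rasters, a flag saying whether the
#' bands have been resampled onto a common reference grid, and (once
#' registered) the fitted per-band rigid transforms.
#'
#' @param capture_id Character identifier.
#' @param bands Named list mapping band index (`"1"`..`"6"`) to
#'   [band_image()] objects.
#' @param aligned Logical; if `TRUE` all bands must share one shape and
#'   `transforms` must hold one entry per band.
#' @param transforms Optional named list of [rigid_transform()] per band.
#' @return An object of class `multispectral_capture`.
#' @export
multispectral_capture <- function(capture_id, bands, aligned = FALSE,
                                  transforms = NULL) {
  stopifnot(is.list(bands), length(bands) >= 1)
  names(bands) <- as.character(vapply(bands, function(b) b$band_index, 1L))
  if (aligned) {
    shapes <- vapply(bands, function(b) paste(dim(b$pixels), collapse = "x"), "")
    if (length(unique(shapes)) != 1) {
      stop("aligned capture requires identical band shapes", call. = FALSE)
    }
    if (is.null(transforms) || !all(names(bands) %in% names(transforms))) {
      stop("aligned capture requires one transform per band", call. = FALSE)
    }
  }
  structure(
    list(capture_id = capture_id, bands = bands, aligned = aligned,
         transforms = transforms),
    class = "multispectral_capture"
  )
}

#' @export
print.multispectral_capture <- function(x, ...) {
  cat(sprintf("<multispectral_capture> '%s': bands %s, %s\n",
              x$capture_id, paste(names(x$bands), collapse = ","),
              if (x$aligned) "aligned" else "raw"))
  invisible(x)
}

#' Load one band from a TIFF file
#'
#' Reads a single-channel 8- or 16-bit TIFF and normalizes integer codes to
#' `[0, 1]` by dividing by the type maximum (255 or 65535), so the maximum
#' code maps exactly to 1. The band index is parsed from the
#' `<capture>_<band>.tif` filename convention unless given explicitly.
#'
#' @param path Path to a single-band TIFF.
#' @param band_index Optional integer 1..6 overriding filename parsing.
#' @return A [band_image()].
#' @export
load_band <- function(path, band_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(band_index)) {
    m <- regmatches(basename(path),
                    regexec("_([0-9]+)\\.tiff?$", basename(path),
                            ignore.case = TRUE))[[1]]
    if (length(m) < 2) {
      stop("cannot parse band index from filename '", basename(path),
           "'; expected suffix _<band>.tif", call. = FALSE)
    }
    band_index <- as.integer(m[2])
  }
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (length(dim(img)) == 3 && dim(img)[3] > 1) {
    stop("multi-channel TIFF not supported for band input: ", path,
         call. = FALSE)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported TIFF bit depth: ", bits, call. = FALSE)
  }
  px <- unclass(img) / (2^bits - 1)
  attributes(px) <- list(dim = dim(img))
  band_image(px, band_index, source_path = path)
}

#' Assemble a capture from a directory of band TIFFs
#'
#' Looks for files named `<capture_id>_<band>.tif` (or `.tiff`). Bands 1-5
#' are required; the panchromatic band 6 is optional and may have a
#' different (higher) resolution.
#'
#' @param directory Directory containing the band files.
#' @param capture_id Capture identifier (filename prefix).
#' @return A raw (unaligned) [multispectral_capture()].
#' @export
assemble_capture <- function(directory, capture_id) {
  if (!dir.exists(directory)) stop("no such directory: ", directory,
                                   call. = FALSE)
  bands <- list()
  for (b in 1:6) {
    hits <- list.files(directory,
                       pattern = paste0("^", capture_id, "_", b,
                                        "\\.tiff?$"),
                       full.names = TRUE, ignore.case = TRUE)
    if (length(hits) >= 1) {
      bands[[as.character(b)]] <- load_band(hits[1], band_index = b)
    } else if (b <= 5) {
      stop("capture '", capture_id, "': band ", b, " is missing in ",
           directory, call. = FALSE)
    }
  }
  multispectral_capture(capture_id, bands, aligned = FALSE)
}

#' Write an 8-bit RGB image
#'
#' Writes a 3-channel array losslessly as an 8-bit PNG or TIFF (chosen by
#' file extension). Inputs on the unit scale (`max <= 1`) are first scaled
#' by 255; values are then clipped to `[0, 255]` and rounded half-up.
#'
#' @param image Numeric `H x W x 3` array in `[0, 1]` or `[0, 255]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, the integer array actually stored.
#' @export
write_rgb <- function(image, path) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("write_rgb expects an H x W x 3 array", call. = FALSE)
  }
  if (!all(is.finite(image))) stop("non-finite pixel values", call. = FALSE)
  if (max(image) <= 1 + 1e-12) image <- image * 255
  stored <- pmin(pmax(floor(image + 0.5), 0), 255)  # round half-up
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(stored / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    write_band_tiff_rgb(stored, path)
  } else {
    stop("unsupported extension '", ext, "' (use png/tif/tiff)",
         call. = FALSE)
  }
  invisible(stored)
}

# 8-bit RGB TIFF from integer codes; nudged so libtiff truncation lands
# on the intended code.
write_band_tiff_rgb <- function(stored, path) {
  tiff::writeTIFF(pmin((stored + 0.499) / 255, 1), where = path,
                  bits.per.sample = 8L)
}

#' Read bounding boxes from an annotation file
#'
#' Parses the plain-text detector annotation dialect: one box per line,
#' `class cx cy w h [confidence]` with geometry normalized to `[0, 1]` and
#' 0-based class indices on disk. In memory, severity classes are 1-based
#' (1 upright .. 9 flat) and boxes are 0-based half-open pixel rectangles,
#' so `area = (x_max - x_min) * (y_max - y_min)` exactly.
#'
#' @param path Annotation file path.
#' @param image_width,image_height Pixel dimensions used to denormalize.
#' @param with_confidence If `TRUE`, a sixth confidence column is required.
#' @param image_id Identifier stored in the `image_id` column; defaults to
#'   the file name without extension.
#' @return A tibble with columns `image_id`, `class_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence` (NA when absent).
#' @export
read_boxes <- function(path, image_width, image_height,
                       with_confidence = FALSE,
                       image_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_boxes(image_id))
  want <- if (with_confidence) 6L else 5L
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) != want) {
      stop("line ", i, " of ", path, ": expected ", want,
           " fields, found ", length(tok), call. = FALSE)
    }
    v <- as.numeric(tok)
    if (anyNA(v)) stop("line ", i, " of ", path, ": non-numeric field",
                       call. = FALSE)
    if (any(v[2:5] < -1e-9 | v[2:5] > 1 + 1e-9)) {
      stop("line ", i, " of ", path,
           ": normalized geometry outside [0, 1]", call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, rows)
  cls <- as.integer(m[, 1]) + 1L
  if (any(cls < 1 | cls > 9)) {
    stop("class index outside on-disk range 0..8 in ", path, call. = FALSE)
  }
  x_min <- pmax((m[, 2] - m[, 4] / 2) * image_width, 0)
  x_max <- pmin((m[, 2] + m[, 4] / 2) * image_width, image_width)
  y_min <- pmax((m[, 3] - m[, 5] / 2) * image_height, 0)
  y_max <- pmin((m[, 3] + m[, 5] / 2) * image_height, image_height)
  if (any(x_min >= x_max) || any(y_min >= y_max)) {
    stop("degenerate (zero-area) box in ", path, call. = FALSE)
  }
  tibble::tibble(
    image_id = image_id, class_id = cls,
    x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
    confidence = if (with_confidence) m[, 6] else NA_real_
  )
}

#' Write a single band as a quantized TIFF
#'
#' Stores unit-scale intensities as 8- or 16-bit codes rounded to the
#' nearest code (the quantization error is at most half a code step), so
#' a write/[load_band()] cycle reproduces the pixels to within
#' `0.5 / (2^bits - 1)`.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param path Output `.tif` path.
#' @param bits 8 or 16 (default).
#' @return Invisibly, `path`.
#' @export
write_band_tiff <- function(pixels, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  # libtiff truncates codes, so nudge the rounded code up by half a step
  q <- pmin((round(pixels * mx) + 0.499) / mx, 1)
  tiff::writeTIFF(q, where = path, bits.per.sample = as.integer(bits))
  invisible(path)
}

empty_boxes <- function(image_id = character(0)) {
  tibble::tibble(
    image_id = image_id[0], class_id = integer(0),
    x_min = numeric(0), y_min = numeric(0),
    x_max = numeric(0), y_max = numeric(0),
    confidence = numeric(0)
  )
}

#' Write bounding boxes to an annotation file
#'
#' Inverse of [read_boxes()]: pixel boxes are re-normalized to
#' center/size form and printed with six decimals, so a read/write
#' round-trip is exact to within half a quantization step
#' (`0.5e-6 * image_width` pixels).
#'
#' @param boxes Box tibble (see [read_boxes()]); one image at a time.
#' @param path Output file path.
#' @param image_width,image_height Pixel dimensions used to normalize.
#' @param with_confidence If `TRUE`, append the confidence column.
#' @return Invisibly, `path`.
#' @export
write_boxes <- function(boxes, path, image_width, image_height,
                        with_confidence = FALSE) {
  validate_boxes(boxes)
  if (nrow(boxes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cx <- (boxes$x_min + boxes$x_max) / 2 / image_width
  cy <- (boxes$y_min + boxes$y_max) / 2 / image_height
  w  <- (boxes$x_max - boxes$x_min) / image_width
  h  <- (boxes$y_max - boxes$y_min) / image_height
  fields <- sprintf("%d %.6f %.6f %.6f %.6f",
                    boxes$class_id - 1L, cx, cy, w, h)
  if (with_confidence) {
    if (anyNA(boxes$confidence)) {
      stop("with_confidence = TRUE but some boxes lack confidence",
           call. = FALSE)
    }
    fields <- sprintf("%s %.6f", fields, boxes$confidence)
  }
  writeLines(fields, path)
  invisible(path)
}

# Shared structural checks for box tibbles.
validate_boxes <- function(boxes, need_confidence = FALSE) {
  need <- c("image_id", "class_id", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(boxes))) {
    stop("box tibble must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"confidence" %in% names(boxes)) boxes$confidence <- NA_real_
  if (nrow(boxes) > 0) {
    if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max)) {
      stop("degenerate box: require x_min < x_max and y_min < y_max",
           call. = FALSE)
    }
    if (any(!boxes$class_id %in% 1:9)) {
      stop("class_id must be in 1..9", call. = FALSE)
    }
    if (need_confidence && anyNA(boxes$confidence)) {
      stop("operation requires a confidence for every box", call. = FALSE)
    }
  }
  invisible(boxes)
}
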