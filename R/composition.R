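#' Compose aligned bands into a 3-channel image
#'
#' Pure channel stacking (no value change): `order = c(3, 2, 1)` assigns
#' red/green/blue bands to the red/green/blue display channels (a
#' true-color "3-2-1" image); `c(4, 2, 1)` substitutes the red-edge band
#' for the red channel (the customized "4-2-1" composite).
#'
#' @param capture An aligned [multispectral_capture()].
#' @param order Length-3 integer band indices assigned to the (red, green,
#'   blue) channels.
#' @return Numeric `H x W x 3` array.
#' @export
compose_bands <- function(capture, order = c(3, 2, 1)) {
  if (!isTRUE(capture$aligned)) {
    stop("capture must be aligned before composition", call. = FALSE)
  }
  keys <- as.character(order)
  missing <- setdiff(keys, names(capture$bands))
  if (length(missing)) {
    stop("band(s) ", paste(missing, collapse = ", "),
         " absent from capture", call. = FALSE)
  }
  chans <- lapply(keys, function(k) capture$bands[[k]]$pixels)
  array(c(chans[[1]], chans[[2]], chans[[3]]),
        dim = c(dim(chans[[1]]), 3))
}

#' Vegetation index map
#'
#' Per-pixel evaluation of the standard reflectance-ratio indices over an
#' aligned capture (B = band 1, G = 2, R = 3, NIR = 5):
#' \itemize{
#'   \item NDVI = (NIR - R) / (NIR + R)
#'   \item VARI = (G - R) / (G + R - B)
#'   \item GARI = (NIR - (G - (B - R))) / (NIR + (G - (B - R)))
#'   \item SABI = (NIR - R) / (B + G)
#' }
#' Pixels whose denominator magnitude falls below `safe_epsilon` are
#' masked invalid (`NA` in `values`). `as_printed = TRUE` switches GARI's
#' denominator to the variant `NIR - (G + (B - R))` found in some
#' transcriptions of the formula.
#'
#' @param capture An aligned [multispectral_capture()].
#' @param name One of `"NDVI"`, `"VARI"`, `"GARI"`, `"SABI"`.
#' @param safe_epsilon Denominator magnitude below which a pixel is masked.
#' @param as_printed Use the non-standard GARI denominator (see above).
#' @return An object of class `index_map`: `name`, `values` (matrix,
#'   dimensionless, `NA` where masked), `valid_mask` (logical matrix).
#' @export
vegetation_index <- function(capture, name = c("NDVI", "VARI", "GARI",
                                               "SABI"),
                             safe_epsilon = 1e-9, as_printed = FALSE) {
  name <- match.arg(name)
  if (!isTRUE(capture$aligned)) {
    stop("capture must be aligned before index computation", call. = FALSE)
  }
  need <- switch(name, NDVI = c(3, 5), VARI = c(1, 2, 3),
                 GARI = c(1, 2, 3, 5), SABI = c(1, 2, 3, 5))
  missing <- setdiff(as.character(need), names(capture$bands))
  if (length(missing)) {
    stop(name, " requires band(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gb <- function(i) capture$bands[[as.character(i)]]$pixels
  if (name == "NDVI") {
    num <- gb(5) - gb(3); den <- gb(5) + gb(3)
  } else if (name == "VARI") {
    num <- gb(2) - gb(3); den <- gb(2) + gb(3) - gb(1)
  } else if (name == "GARI") {
    inner <- gb(2) - (gb(1) - gb(3))
    num <- gb(5) - inner
    den <- if (as_printed) gb(5) - (gb(2) + (gb(1) - gb(3)))
           else gb(5) + inner
  } else { # SABI
    num <- gb(5) - gb(3); den <- gb(1) + gb(2)
  }
  valid <- abs(den) >= safe_epsilon
  values <- num / den
  values[!valid] <- NA_real_
  structure(list(name = name, values = values, valid_mask = valid),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  cat(sprintf("<index_map> %s, %d x %d px, %.1f%% valid, range [%.3f, %.3f]\n",
              x$name, ncol(x$values), nrow(x$values),
              100 * mean(x$valid_mask),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Write and read an index map as a floating-point TIFF
#'
#' Index values (which may be negative or exceed 1, e.g. SABI) are
#' min-max scaled into `[0, 1]` for storage as a 32-bit float TIFF; the
#' affine scale and the validity mask are recorded in a JSON sidecar
#' (`<path>.json`) so `read_index()` restores the original values
#' exactly up to float-32 precision. Masked pixels are stored as 0.
#'
#' @param index A [vegetation_index()] result.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`.
#' @export
write_index <- function(index, path) {
  v <- index$values
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  span <- if (hi > lo) hi - lo else 1
  v <- (v - lo) / span
  v[!index$valid_mask] <- 0
  tiff::writeTIFF(v, where = path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(name = index$name, offset = lo, scale = span,
         invalid = which(!index$valid_mask)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @return For `read_index()`: the reconstructed `index_map`.
#' @export
read_index <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * meta$scale + meta$offset
  mask <- matrix(TRUE, nrow(v), ncol(v))
  if (length(meta$invalid)) {
    mask[meta$invalid] <- FALSE
    v[meta$invalid] <- NA_real_
  }
  structure(list(name = meta$name, values = v, valid_mask = mask),
            class = "index_map")
}
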