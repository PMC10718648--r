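#' Haze & gamma adjustment parameters
#'
#' Parameters of the haze-reduction + gamma preset. Per channel `c`, with
#' `I` the input intensities in `[0, 1]`:
#' \deqn{a_c = s \cdot percentile(I, q)}
#' \deqn{t_c = 1[I > a_c] (1 + \alpha_c (I - a_c)) - \beta_c}
#' \deqn{b_c = mean((I - a_c) t_c^{\gamma_c})}
#' \deqn{out = b_c t_c^{\gamma_c}}
#' `t_c` is clipped below at `floor` before the fractional power (with
#' `beta = 0.7`, raw `t_c` is frequently negative), and the output channel
#' is linearly rescaled so its maximum maps to 1 and clipped to `[0, 1]`.
#'
#' @param alpha Haze-intensity coefficient(s), default 0.2.
#' @param beta Curve-shape offset(s), default 0.7.
#' @param gamma Gamma exponent(s) (> 0), default 0.6.
#' @param dark_percentile Percentile (0-100) defining the dark level,
#'   default 1.
#' @param dark_scale Multiplier on the dark percentile, default 0.25.
#' @param floor Positive lower clip for `t_c`, default 1e-6.
#' @param rescale Rescale each output channel so its maximum maps to 1
#'   (default `TRUE`).
#' @return An object of class `haze_gamma_params`; scalars are recycled to
#'   the three channels.
#' @export
haze_gamma_params <- function(alpha = 0.2, beta = 0.7, gamma = 0.6,
                              dark_percentile = 1, dark_scale = 0.25,
                              floor = 1e-6, rescale = TRUE) {
  stopifnot(all(gamma > 0), dark_percentile >= 0, dark_percentile <= 100,
            floor > 0)
  structure(list(alpha = rep_len(alpha, 3), beta = rep_len(beta, 3),
                 gamma = rep_len(gamma, 3),
                 dark_percentile = dark_percentile, dark_scale = dark_scale,
                 floor = floor, rescale = rescale),
            class = "haze_gamma_params")
}

#' Haze & gamma adjustment preset
#'
#' Applies the haze-reduction + gamma chain of [haze_gamma_params()]
#' independently to each channel. Monotone within a channel: pixels that
#' were at least as bright as another stay so.
#'
#' @param rgb Numeric `H x W x 3` array with values in `[0, 1]`.
#' @param params A [haze_gamma_params()].
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
haze_gamma_adjust <- function(rgb, params = haze_gamma_params()) {
  check_rgb(rgb)
  if (any(rgb < -1e-12 | rgb > 1 + 1e-12)) {
    stop("haze_gamma_adjust expects values in [0, 1]", call. = FALSE)
  }
  out <- rgb
  for (c in 1:3) {
    ch <- rgb[, , c]
    a <- params$dark_scale *
      quantile(ch, params$dark_percentile / 100, names = FALSE, type = 7)
    t <- (ch > a) * (1 + params$alpha[c] * (ch - a)) - params$beta[c]
    t <- pmax(t, params$floor)
    tg <- t^params$gamma[c]
    b <- mean((ch - a) * tg)
    oc <- b * tg
    if (params$rescale) {
      m <- max(oc)
      if (m > 0) oc <- oc / m
    }
    out[, , c] <- pmin(pmax(oc, 0), 1)
  }
  out
}

#' Contrast limits of a band
#'
#' The per-band lower and upper stretch limits are simply the band's
#' minimum and maximum pixel values, computed separately for each band.
#'
#' @param pixels Numeric matrix (or vector) of intensities.
#' @return Numeric `(lower, upper)`.
#' @export
compute_limits <- function(pixels) {
  pixels <- if (inherits(pixels, "band_image")) pixels$pixels else pixels
  r <- range(pixels)
  if (r[1] >= r[2]) stop("degenerate contrast range: constant band",
                         call. = FALSE)
  c(lower = r[1], upper = r[2])
}

#' Contrast-limit stretching preset
#'
#' Per channel `c`: `out = (in - I_min,c) / (I_max,c - I_min,c) * 255`,
#' clipped to `[0, 255]` when explicit limits are narrower than the data.
#' Limits default to each channel's own min/max ([compute_limits()]), so
#' the channel minimum maps to 0 and the maximum to 255 exactly.
#'
#' @param rgb Numeric `H x W x 3` array.
#' @param limits Optional list of three `(lower, upper)` pairs (or a
#'   `2 x 3` matrix, one column per channel).
#' @return `H x W x 3` array in `[0, 255]`.
#' @export
stretch_contrast <- function(rgb, limits = NULL) {
  check_rgb(rgb)
  out <- rgb
  for (c in 1:3) {
    ch <- rgb[, , c]
    lim <- if (is.null(limits)) compute_limits(ch)
           else if (is.matrix(limits)) limits[, c]
           else limits[[c]]
    if (lim[1] >= lim[2]) {
      stop("invalid contrast limits: lower >= upper", call. = FALSE)
    }
    out[, , c] <- pmin(pmax((ch - lim[1]) / (lim[2] - lim[1]) * 255, 0), 255)
  }
  out
}

#' Apply a named enhancement preset
#'
#' Dispatches to [haze_gamma_adjust()] (`"haze_gamma"`, output in `[0, 1]`)
#' or [stretch_contrast()] (`"stretch"`, output in `[0, 255]`) with default
#' parameters.
#'
#' @param rgb Numeric `H x W x 3` array.
#' @param preset One of `"haze_gamma"`, `"stretch"`.
#' @return Enhanced `H x W x 3` array.
#' @export
apply_preset <- function(rgb, preset) {
  switch(preset,
    haze_gamma = haze_gamma_adjust(rgb),
    stretch = stretch_contrast(rgb),
    stop("unknown preset '", preset,
         "'; valid presets: haze_gamma, stretch", call. = FALSE)
  )
}

check_rgb <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("expected an H x W x 3 array", call. = FALSE)
  }
  invisible(rgb)
}
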