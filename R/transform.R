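#' Rigid 2-D transform
#'
#' A rotation by `theta` about `center` followed by a translation
#' `(tx, ty)`, in 0-based pixel coordinates (x right, y down). A point maps
#' as `p' = R(theta) (p - center) + center + (tx, ty)`.
#'
#' @param theta Rotation angle in radians (positive = x-axis towards y-axis,
#'   i.e. clockwise on screen with y pointing down).
#' @param tx,ty Translation in pixels.
#' @param center Length-2 numeric, rotation center `(x_c, y_c)` in pixels.
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' t <- rigid_transform(theta = pi / 2, tx = 1, ty = 0, center = c(0, 0))
#' transform_points(t, cbind(1, 0)) # rotates (1,0) to (0,1), shifts x by 1
rigid_transform <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(length(theta) == 1, length(tx) == 1, length(ty) == 1,
            length(center) == 2)
  structure(
    list(theta = as.numeric(theta), tx = as.numeric(tx), ty = as.numeric(ty),
         center = as.numeric(center)),
    class = "rigid_transform"
  )
}

#' @rdname rigid_transform
#' @export
transform_identity <- function(center = c(0, 0)) {
  rigid_transform(0, 0, 0, center = center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> theta = %.6g rad (%.4g deg), t = (%.6g, %.6g), center = (%.4g, %.4g)\n",
    x$theta, x$theta * 180 / pi, x$tx, x$ty, x$center[1], x$center[2]))
  invisible(x)
}

#' Map points through a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @param points Numeric matrix with columns `(x, y)`.
#' @return Matrix of mapped points, same shape as `points`.
#' @export
transform_points <- function(transform, points) {
  points <- rbind(points)
  ct <- cos(transform$theta); st <- sin(transform$theta)
  dx <- points[, 1] - transform$center[1]
  dy <- points[, 2] - transform$center[2]
  cbind(
    x = ct * dx - st * dy + transform$center[1] + transform$tx,
    y = st * dx + ct * dy + transform$center[2] + transform$ty
  )
}

#' Compose and invert rigid transforms
#'
#' `transform_compose(a, b)` is the transform mapping `p` to `a(b(p))`; the
#' result is expressed about `a`'s rotation center. `transform_inverse(t)`
#' satisfies `compose(t, inverse(t)) = identity` up to floating-point error.
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  # rotation angles add; translation follows from mapping a's center
  ca <- a$center
  t_new <- transform_points(a, transform_points(b, rbind(ca)))[1, ] - ca
  rigid_transform(a$theta + b$theta, t_new[1], t_new[2], center = ca)
}

#' @rdname transform_compose
#' @export
transform_inverse <- function(transform) {
  ct <- cos(-transform$theta); st <- sin(-transform$theta)
  tx <- transform$tx; ty <- transform$ty
  rigid_transform(
    -transform$theta,
    -(ct * tx - st * ty),
    -(st * tx + ct * ty),
    center = transform$center
  )
}

#' Resample an image through a rigid transform
#'
#' Inverse-mapping resampler with bilinear interpolation: output pixel `q`
#' takes the value of the input at `T^(-1)(q)`. Output pixels whose source
#' location falls outside the input grid are set to 0 and flagged invalid.
#'
#' @param pixels Numeric matrix of pixel intensities (rows = y, cols = x).
#' @param transform A [rigid_transform()].
#' @param output_shape Integer `(height, width)` of the output grid;
#'   defaults to the input shape.
#' @return List with `pixels` (numeric matrix) and `valid` (logical matrix).
#' @export
apply_transform <- function(pixels, transform, output_shape = dim(pixels)) {
  pixels <- as_pixel_matrix(pixels)
  if (!all(is.finite(c(transform$theta, transform$tx, transform$ty,
                       transform$center)))) {
    stop("non-finite rigid transform parameters", call. = FALSE)
  }
  res <- cpp_warp_rigid(pixels, transform$theta, transform$tx, transform$ty,
                        transform$center[1], transform$center[2],
                        as.integer(output_shape[1]),
                        as.integer(output_shape[2]))
  list(pixels = res$pixels, valid = res$valid)
}

#' Bilinear image resize
#'
#' Corner-aligned bilinear resampling onto a grid of the requested shape.
#'
#' @param pixels Numeric matrix.
#' @param out_h,out_w Output height and width in pixels.
#' @return Numeric matrix of shape `out_h` x `out_w`.
#' @export
resize_bilinear <- function(pixels, out_h, out_w) {
  pixels <- as_pixel_matrix(pixels)
  H <- nrow(pixels); W <- ncol(pixels)
  ys <- if (out_h == 1) 0 else (seq_len(out_h) - 1) * (H - 1) / (out_h - 1)
  xs <- if (out_w == 1) 0 else (seq_len(out_w) - 1) * (W - 1) / (out_w - 1)
  y0 <- pmin(floor(ys), max(H - 2, 0)); x0 <- pmin(floor(xs), max(W - 2, 0))
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  m00 <- pixels[y0 + 1, x0 + 1, drop = FALSE]
  m01 <- pixels[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- pixels[y1 + 1, x0 + 1, drop = FALSE]
  m11 <- pixels[y1 + 1, x1 + 1, drop = FALSE]
  outer(1 - fy, 1 - fx) * m00 + outer(1 - fy, fx) * m01 +
    outer(fy, 1 - fx) * m10 + outer(fy, fx) * m11
}

# Accept a band_image or bare matrix wherever raw pixels are needed.
as_pixel_matrix <- function(x) {
  if (inherits(x, "band_image")) x <- x$pixels
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric pixel matrix (or band_image)", call. = FALSE)
  }
  x
}
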