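#' Synthetic scene configuration
#'
#' Describes a simulated six-band capture of a trial field: a grid of
#' rectangular wheat plots on a soil background, each plot carrying a
#' lodging severity class 1..9 with a class-dependent lodged-area
#' fraction, band-dependent reflectance (high NIR / low red for upright
#' canopy, brighter visible bands over lodged patches), a known rigid
#' misalignment per band, and Gaussian sensor noise. Plot geometry is
#' given at native sensor resolution (spectral bands 1456 x 1088,
#' panchromatic 2464 x 2056) and scaled by `image_scale`; the default 0.25
#' gives a 364 x 272 working frame.
#'
#' @param rows,cols Plot-grid dimensions.
#' @param plot_size_px Plot `(width, height)` in native-resolution pixels.
#' @param gap_px Gap between plots, native pixels.
#' @param image_scale Fraction of native resolution to render at.
#' @param class_assignment `"random"`, or an integer vector/matrix of
#'   severity classes 1..9, one per plot (filled row by row).
#' @param band_offsets `"random"` (each non-reference band draws a uniform
#'   offset with `|t| <= max_shift_px` px and `|theta| <= max_rot_deg`
#'   degrees), or a named list of `c(theta, tx, ty)` per band index.
#'   Band 2, the registration reference, is always the identity.
#' @param max_shift_px,max_rot_deg Sampling ranges for random offsets, in
#'   working-resolution pixels / degrees.
#' @param noise_sd Gaussian sensor noise standard deviation (reflectance
#'   units).
#' @param include_pan Render the panchromatic band 6 (default TRUE).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(rows = 4, cols = 5, plot_size_px = c(220, 90),
                         gap_px = 40, image_scale = 0.25,
                         class_assignment = "random",
                         band_offsets = "random",
                         max_shift_px = 10, max_rot_deg = 2,
                         noise_sd = 0.01, include_pan = TRUE, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, noise_sd >= 0, image_scale > 0,
            image_scale <= 1)
  W <- round(NATIVE_SPECTRAL["width"] * image_scale)
  H <- round(NATIVE_SPECTRAL["height"] * image_scale)
  pw <- plot_size_px[1] * image_scale
  ph <- plot_size_px[2] * image_scale
  gap <- gap_px * image_scale
  if (cols * pw + (cols - 1) * gap > W || rows * ph + (rows - 1) * gap > H) {
    stop("plot grid does not fit inside the image", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, plot_size_px = plot_size_px,
                 gap_px = gap_px, image_scale = image_scale,
                 class_assignment = class_assignment,
                 band_offsets = band_offsets,
                 max_shift_px = max_shift_px, max_rot_deg = max_rot_deg,
                 noise_sd = noise_sd, include_pan = include_pan,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Lodged-area fraction by severity class: none at class 1, linear to 0.75
# at class 8; class 9 exceeds 0.75 (drawn per plot).
lodged_fraction_of_class <- function(class_id) {
  ifelse(class_id <= 8, 0.75 * (class_id - 1) / 8, NA_real_)
}

# Reflectance profiles per band (rows) and surface type (columns).
# Upright canopy: low visible / high NIR; lodged patches expose bright
# stems: brighter in the visible bands, darker in NIR and red edge.
SCENE_REFLECTANCE <- matrix(
  #      soil  canopy lodged
  c(0.18, 0.05, 0.12,   # 1 blue
    0.22, 0.12, 0.22,   # 2 green
    0.25, 0.06, 0.20,   # 3 red
    0.28, 0.40, 0.30,   # 4 red edge
    0.30, 0.55, 0.35,   # 5 NIR
    0.22, 0.10, 0.18),  # 6 panchromatic
  nrow = 6, byrow = TRUE,
  dimnames = list(NULL, c("soil", "canopy", "lodged"))
)

# Geometry of the plot grid at working resolution.
scene_geometry <- function(config) {
  s <- config$image_scale
  W <- as.numeric(round(NATIVE_SPECTRAL["width"] * s))
  H <- as.numeric(round(NATIVE_SPECTRAL["height"] * s))
  Wp <- as.numeric(round(NATIVE_PAN["width"] * s))
  Hp <- as.numeric(round(NATIVE_PAN["height"] * s))
  pw <- config$plot_size_px[1] * s
  ph <- config$plot_size_px[2] * s
  gap <- config$gap_px * s
  mx <- (W - (config$cols * pw + (config$cols - 1) * gap)) / 2
  my <- (H - (config$rows * ph + (config$rows - 1) * gap)) / 2
  list(W = W, H = H, Wp = Wp, Hp = Hp, pw = pw, ph = ph, gap = gap,
       mx = mx, my = my, pitch_x = pw + gap, pitch_y = ph + gap)
}

# Surface type (0 soil, 1 canopy, 2 lodged) at continuous scene
# coordinates. `frac` is the per-plot lodged fraction (rows x cols).
scene_region <- function(x, y, geom, config, frac) {
  ix <- floor((x - geom$mx) / geom$pitch_x)
  iy <- floor((y - geom$my) / geom$pitch_y)
  offx <- x - geom$mx - ix * geom$pitch_x
  offy <- y - geom$my - iy * geom$pitch_y
  inside <- ix >= 0 & ix < config$cols & iy >= 0 & iy < config$rows &
    offx < geom$pw & offy < geom$ph & offx >= 0 & offy >= 0
  region <- integer(length(x))
  idx <- which(inside)
  plot_lin <- iy[idx] * config$cols + ix[idx] + 1   # row-major plot index
  f <- frac[plot_lin]
  lodged <- offy[idx] < f * geom$ph
  region[idx] <- ifelse(lodged, 2L, 1L)
  region
}

#' Generate a synthetic six-band capture with ground truth
#'
#' Renders the scene described by a [scene_config()]: per-band rasters are
#' the analytic reflectance scene evaluated through each band's true rigid
#' transform (so truth recovery is exact up to noise), with a smooth
#' multiplicative texture shared across bands to give the registration
#' metric intensity structure, plus Gaussian sensor noise. Runs are fully
#' deterministic under the config seed.
#'
#' @param config A [scene_config()].
#' @param capture_id Identifier for the capture (default `"scene1"`).
#' @return List with `capture` (a raw [multispectral_capture()]) and
#'   `truth` (class `scene_truth`): `boxes` (one per plot, class =
#'   severity), `transforms` (true per-band [rigid_transform()]),
#'   `lodged_fraction` (rows x cols matrix), `classes` (rows x cols
#'   matrix), `image_width`, `image_height`.
#' @export
generate_capture <- function(config, capture_id = "scene1") {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  geom <- scene_geometry(config)
  n_plots <- config$rows * config$cols

  classes <- config$class_assignment
  if (identical(classes, "random")) {
    classes <- sample(1:9, n_plots, replace = TRUE)
  }
  classes <- matrix(as.integer(classes), config$rows, config$cols,
                    byrow = TRUE)
  if (any(!classes %in% 1:9)) stop("classes must be in 1..9", call. = FALSE)
  frac <- lodged_fraction_of_class(classes)
  frac[classes == 9] <- runif(sum(classes == 9), 0.76, 0.95)
  frac_rowmajor <- as.vector(t(frac))   # indexed row-major by scene_region

  # shared multiplicative texture (smooth, aperiodic-ish)
  phases <- runif(3, 0, 2 * pi)
  texture <- function(x, y) {
    1 + 0.12 * sin(2 * pi * x / (geom$W / 3.7) + phases[1]) *
        cos(2 * pi * y / (geom$H / 2.9) + phases[2]) +
      0.08 * cos(2 * pi * (x + y) / (geom$W / 5.3) + phases[3])
  }

  band_ids <- if (config$include_pan) 1:6 else 1:5
  transforms <- list()
  for (b in band_ids) {
    dims <- if (b == 6) c(geom$Hp, geom$Wp) else c(geom$H, geom$W)
    center <- c((dims[2] - 1) / 2, (dims[1] - 1) / 2)
    if (b == 2 || identical(config$band_offsets, "identity")) {
      transforms[[as.character(b)]] <- transform_identity(center)
    } else if (identical(config$band_offsets, "random")) {
      transforms[[as.character(b)]] <- rigid_transform(
        theta = runif(1, -config$max_rot_deg, config$max_rot_deg) * pi / 180,
        tx = runif(1, -config$max_shift_px, config$max_shift_px),
        ty = runif(1, -config$max_shift_px, config$max_shift_px),
        center = center)
    } else {
      par <- config$band_offsets[[as.character(b)]]
      if (is.null(par)) par <- c(0, 0, 0)
      transforms[[as.character(b)]] <- rigid_transform(par[1], par[2],
                                                       par[3],
                                                       center = center)
    }
  }

  bands <- list()
  for (b in band_ids) {
    dims <- if (b == 6) c(geom$Hp, geom$Wp) else c(geom$H, geom$W)
    qx <- matrix(rep(0:(dims[2] - 1), each = dims[1]), dims[1], dims[2])
    qy <- matrix(rep(0:(dims[1] - 1), times = dims[2]), dims[1], dims[2])
    inv <- transform_inverse(transforms[[as.character(b)]])
    p <- transform_points(inv, cbind(as.vector(qx), as.vector(qy)))
    if (b == 6) { # panchromatic grid maps onto the spectral scene frame
      p[, 1] <- p[, 1] * geom$W / geom$Wp
      p[, 2] <- p[, 2] * geom$H / geom$Hp
    }
    region <- scene_region(p[, 1], p[, 2], geom, config, frac_rowmajor)
    refl <- SCENE_REFLECTANCE[b, region + 1L]
    v <- refl * texture(p[, 1], p[, 2])
    v <- v + rnorm(length(v), sd = config$noise_sd)
    bands[[as.character(b)]] <- band_image(
      matrix(pmin(pmax(v, 0), 1), dims[1], dims[2]), b)
  }

  # one ground-truth box per plot, in the reference (band 1-5) grid
  grid <- expand.grid(col = 0:(config$cols - 1), row = 0:(config$rows - 1))
  boxes <- tibble::tibble(
    image_id = capture_id,
    class_id = as.integer(classes[cbind(grid$row + 1, grid$col + 1)]),
    x_min = geom$mx + grid$col * geom$pitch_x,
    y_min = geom$my + grid$row * geom$pitch_y,
    x_max = geom$mx + grid$col * geom$pitch_x + geom$pw,
    y_max = geom$my + grid$row * geom$pitch_y + geom$ph,
    confidence = NA_real_
  )
  truth <- structure(
    list(boxes = boxes, transforms = transforms,
         lodged_fraction = frac, classes = classes,
         image_width = geom$W, image_height = geom$H),
    class = "scene_truth")
  list(capture = multispectral_capture(capture_id, bands, aligned = FALSE),
       truth = truth)
}

#' Degrade ground truth into simulated detections
#'
#' Each truth box is independently dropped with probability `miss_rate`;
#' surviving boxes get independent uniform corner jitter up to
#' `jitter_px` and a confidence drawn uniformly from
#' `confidence_model$correct`. Spurious boxes (random geometry and class,
#' confidence from `confidence_model$spurious`) are added per image with a
#' Poisson count of mean `spurious_rate` times the image's truth-box
#' count. Deterministic under `seed`.
#'
#' @param truth A `scene_truth` (or any box tibble with `image_id`) plus
#'   image dimensions.
#' @param jitter_px Maximum absolute corner perturbation in pixels.
#' @param miss_rate,spurious_rate Rates in `[0, 1]`.
#' @param confidence_model List with `correct` and `spurious` uniform
#'   ranges `(lo, hi)`.
#' @param seed Integer seed.
#' @return Detection box tibble with confidences.
#' @export
generate_detections <- function(truth, jitter_px = 2, miss_rate = 0.1,
                                spurious_rate = 0.05,
                                confidence_model = list(
                                  correct = c(0.6, 1.0),
                                  spurious = c(0.05, 0.4)),
                                seed = 1L) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, spurious_rate >= 0,
            spurious_rate <= 1)
  boxes <- if (inherits(truth, "scene_truth")) truth$boxes else truth$boxes
  W <- truth$image_width; H <- truth$image_height
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  out <- list()
  for (img in unique(boxes$image_id)) {
    g <- boxes[boxes$image_id == img, , drop = FALSE]
    keep <- runif(nrow(g)) >= miss_rate
    d <- g[keep, , drop = FALSE]
    if (nrow(d) > 0) {
      d$x_min <- pmax(d$x_min + runif(nrow(d), -jitter_px, jitter_px), 0)
      d$y_min <- pmax(d$y_min + runif(nrow(d), -jitter_px, jitter_px), 0)
      d$x_max <- pmin(d$x_max + runif(nrow(d), -jitter_px, jitter_px), W)
      d$y_max <- pmin(d$y_max + runif(nrow(d), -jitter_px, jitter_px), H)
      bad <- d$x_min >= d$x_max | d$y_min >= d$y_max
      d <- d[!bad, , drop = FALSE]
      d$confidence <- runif(nrow(d), confidence_model$correct[1],
                            confidence_model$correct[2])
    }
    n_sp <- rpois(1, spurious_rate * nrow(g))
    if (n_sp > 0) {
      w <- runif(n_sp, 0.03, 0.15) * W
      h <- runif(n_sp, 0.03, 0.15) * H
      x0 <- runif(n_sp, 0, W - w)
      y0 <- runif(n_sp, 0, H - h)
      sp <- tibble::tibble(
        image_id = img,
        class_id = sample(1:9, n_sp, replace = TRUE),
        x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h,
        confidence = runif(n_sp, confidence_model$spurious[1],
                           confidence_model$spurious[2]))
      d <- dplyr::bind_rows(d, sp)
    }
    out[[img]] <- d
  }
  dplyr::bind_rows(out)
}

#' Write a synthetic capture and its truth to disk
#'
#' Produces a directory directly consumable by the pipeline: per-band
#' 16-bit TIFFs named `<capture>_<band>.tif`, the truth boxes as a
#' normalized annotation text file `<capture>.txt`, and the true per-band
#' transforms as `<capture>_transforms.json`.
#'
#' @param capture A [multispectral_capture()].
#' @param truth The matching `scene_truth`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(capture, truth, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create ", directory,
                                   call. = FALSE)
  paths <- character(0)
  for (key in names(capture$bands)) {
    p <- file.path(directory, paste0(capture$capture_id, "_", key, ".tif"))
    write_band_tiff(capture$bands[[key]]$pixels, p)
    paths <- c(paths, p)
  }
  boxp <- file.path(directory, paste0(capture$capture_id, ".txt"))
  write_boxes(truth$boxes, boxp, truth$image_width, truth$image_height)
  paths <- c(paths, boxp)
  tj <- lapply(truth$transforms, function(t)
    list(theta = t$theta, tx = t$tx, ty = t$ty, center = t$center))
  jp <- file.path(directory, paste0(capture$capture_id,
                                    "_transforms.json"))
  jsonlite::write_json(tj, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
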