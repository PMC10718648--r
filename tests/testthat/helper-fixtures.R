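# Programmatic fixtures shared across test files.

random_boxes <- function(n, width = 100, height = 100, classes = 1:3,
                         with_confidence = TRUE, image_id = "img1") {
  if (n == 0) return(lodgekit:::empty_boxes())
  x0 <- runif(n, 0, width * 0.8)
  y0 <- runif(n, 0, height * 0.8)
  tibble::tibble(
    image_id = image_id,
    class_id = sample(classes, n, replace = TRUE),
    x_min = x0, y_min = y0,
    x_max = x0 + runif(n, 2, width * 0.2),
    y_max = y0 + runif(n, 2, height * 0.2),
    confidence = if (with_confidence) runif(n) else NA_real_
  )
}

# A small multi-image detection scenario for metric oracle checks.
random_scenario <- function(n_images = 3, max_boxes = 8, classes = 1:3,
                            width = 60, height = 60) {
  gts <- dplyr::bind_rows(lapply(seq_len(n_images), function(i)
    random_boxes(sample(0:max_boxes, 1), width, height, classes,
                 with_confidence = FALSE,
                 image_id = paste0("img", i))))
  dets <- dplyr::bind_rows(lapply(seq_len(n_images), function(i) {
    g <- gts[gts$image_id == paste0("img", i), , drop = FALSE]
    # jittered copies of some truths plus pure noise boxes
    keep <- if (nrow(g)) g[runif(nrow(g)) < 0.7, , drop = FALSE] else g
    if (nrow(keep)) {
      keep$x_min <- pmax(keep$x_min + runif(nrow(keep), -4, 4), 0)
      keep$y_min <- pmax(keep$y_min + runif(nrow(keep), -4, 4), 0)
      keep$x_max <- keep$x_max + runif(nrow(keep), -4, 4)
      keep$y_max <- keep$y_max + runif(nrow(keep), -4, 4)
      bad <- keep$x_min >= keep$x_max | keep$y_min >= keep$y_max
      keep <- keep[!bad, , drop = FALSE]
      keep$confidence <- runif(nrow(keep), 0.3, 1)
    }
    noise <- random_boxes(sample(0:3, 1), width, height, classes,
                          image_id = paste0("img", i))
    dplyr::bind_rows(keep, noise)
  }))
  list(dets = dets, gts = gts)
}

# Tiny aligned capture with explicit band matrices (bands keyed 1,2,3,5).
tiny_capture <- function(B, G, R, NIR, RE = NULL) {
  bands <- list(
    "1" = band_image(B, 1), "2" = band_image(G, 2),
    "3" = band_image(R, 3), "5" = band_image(NIR, 5))
  if (!is.null(RE)) bands[["4"]] <- band_image(RE, 4)
  transforms <- lapply(bands, function(b) transform_identity())
  names(transforms) <- names(bands)
  multispectral_capture("tiny", bands, aligned = TRUE,
                        transforms = transforms)
}
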