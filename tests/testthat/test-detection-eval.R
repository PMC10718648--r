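box <- function(x1, y1, x2, y2) c(x1, y1, x2, y2)

test_that("IoU uses half-open pixel areas", {
  expect_equal(iou(box(0, 0, 10, 10), box(0, 0, 10, 10)), 1)
  expect_equal(iou(box(0, 0, 10, 10), box(20, 20, 30, 30)), 0)
  expect_equal(iou(box(0, 0, 10, 10), box(5, 0, 15, 10)), 1 / 3)
  # symmetry and the identity characterization
  set.seed(61)
  for (i in 1:20) {
    a <- c(sort(runif(2, 0, 50)), sort(runif(2, 0, 50)))[c(1, 3, 2, 4)]
    b <- c(sort(runif(2, 0, 50)), sort(runif(2, 0, 50)))[c(1, 3, 2, 4)]
    expect_equal(iou(a, b), iou(b, a))
    if (iou(a, b) == 1) expect_equal(a, b)
  }
  expect_error(iou(box(0, 0, 0, 10), box(0, 0, 1, 1)), "degenerate")
})

test_that("confidence filtering keeps order and respects the threshold", {
  set.seed(62)
  d <- random_boxes(3)
  d$confidence <- c(0.3, 0.6, 0.9)
  expect_equal(confidence_filter(d, 0), d)
  expect_equal(nrow(confidence_filter(d, 0.5)), 2)
  expect_equal(confidence_filter(d, 0.5)$confidence, c(0.6, 0.9))
  expect_equal(nrow(confidence_filter(d, 1.0)), 0)
  d$confidence[2] <- NA
  expect_error(confidence_filter(d, 0.5), "confidence")
})

test_that("NMS keeps the top box among duplicates and spares disjoint ones", {
  d <- tibble::tibble(image_id = "a", class_id = c(2L, 2L),
                      x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                      confidence = c(0.9, 0.8))
  expect_equal(nms(d)$confidence, 0.9)
  d2 <- d; d2$x_min <- c(0, 50); d2$x_max <- c(10, 60)
  expect_equal(nrow(nms(d2)), 2)
  # different classes are never suppressed when class-aware
  d3 <- d; d3$class_id <- c(2L, 5L)
  expect_equal(nrow(nms(d3)), 2)
  expect_equal(nrow(nms(d3, class_aware = FALSE)), 1)
})

test_that("NMS agrees with the exhaustive-pairwise oracle", {
  set.seed(63)
  for (i in 1:30) {
    d <- random_boxes(10, width = 40, height = 40, classes = 1:2)
    got <- nms(d, iou_threshold = 0.3)
    want <- oracle_nms(d, iou_threshold = 0.3)
    expect_equal(got, want)
  }
})

test_that("greedy matching follows the confidence-then-IoU protocol", {
  g <- tibble::tibble(image_id = "a", class_id = 1L, x_min = 0, y_min = 0,
                      x_max = 10, y_max = 10, confidence = NA_real_)
  d <- g; d$confidence <- 0.9
  m <- match_detections(d, g)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(m$pairs$iou, 1)
  m2 <- match_detections(d, g[0, ])
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 0))
  expect_error(match_detections(
    dplyr::mutate(d, class_id = 1:1),
    dplyr::mutate(g, class_id = 2L)), NA)  # single classes each are fine
  dd <- dplyr::bind_rows(d, dplyr::mutate(d, class_id = 3L))
  expect_error(match_detections(dd, g), "single class")
})

test_that("matching agrees with the naive-loop oracle on random scenes", {
  set.seed(64)
  for (i in 1:50) {
    g <- random_boxes(4, classes = 1, with_confidence = FALSE)
    d <- random_boxes(5, classes = 1)
    m <- match_detections(d, g, iou_threshold = 0.2)
    o <- oracle_match(d, g, iou_threshold = 0.2)
    expect_equal(m$tp, o$tp)
    expect_equal(m$fp, o$fp)
    expect_equal(m$fn, o$fn)
    expect_equal(m$det_matched, o$matched)
  }
})

test_that("precision/recall/F1 follow the defining ratios and conventions", {
  expect_equal(precision_recall_f1(8, 2, 0),
               tibble::tibble(precision = 0.8, recall = 1.0, f1 = 8 / 9))
  expect_equal(precision_recall_f1(0, 0, 5),
               tibble::tibble(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(5, 5, 15),
               tibble::tibble(precision = 0.5, recall = 0.25, f1 = 1 / 3))
  expect_error(precision_recall_f1(-1, 0, 0), "nonnegative")
})

test_that("average precision handles the canonical cases", {
  g <- tibble::tibble(image_id = "a", class_id = 1L,
                      x_min = c(0, 20, 40), y_min = 0,
                      x_max = c(10, 30, 50), y_max = 10,
                      confidence = NA_real_)
  # perfect detector
  d <- g; d$confidence <- c(0.9, 0.8, 0.7)
  expect_equal(average_precision(d, g, 1), 1.0)
  # no detections at all
  expect_equal(average_precision(d[0, ], g, 1), 0)
  # the (0.9 TP, 0.8 FP, 0.7 TP, 0.6 TP) sequence vs the rank oracle
  fp <- tibble::tibble(image_id = "a", class_id = 1L, x_min = 70,
                       y_min = 70, x_max = 80, y_max = 80,
                       confidence = 0.8)
  d2 <- dplyr::bind_rows(
    dplyr::mutate(g[1, ], confidence = 0.9), fp,
    dplyr::mutate(g[2, ], confidence = 0.7),
    dplyr::mutate(g[3, ], confidence = 0.6))
  expect_equal(average_precision(d2, g, 1), oracle_ap(d2, g, 1))
  expect_equal(average_precision(d2, g, 1), 1 / 3 + 3 / 4 * 2 / 3)
  # class without ground truth is undefined
  expect_true(is.na(average_precision(d2, g, 5)))
})

test_that("mAP composes per-class APs and excludes absent classes", {
  g1 <- tibble::tibble(image_id = "a", class_id = 1L, x_min = 0,
                       y_min = 0, x_max = 10, y_max = 10,
                       confidence = NA_real_)
  g2 <- dplyr::mutate(g1, class_id = 2L, x_min = 20, x_max = 30)
  gts <- dplyr::bind_rows(g1, g2)
  # class 1 perfect, class 2 entirely missed by a far-off detection
  dets <- dplyr::bind_rows(
    dplyr::mutate(g1, confidence = 0.9),
    dplyr::mutate(g2, confidence = 0.9, x_min = 50, x_max = 60))
  expect_equal(mean_ap(dets, gts), 0.5)
  expect_equal(mean_ap(dplyr::mutate(gts, confidence = 0.9), gts), 1.0)
  expect_error(mean_ap(dets, gts[0, ]), "ground-truth")
})

test_that("the IoU-threshold sweep penalizes loose boxes monotonically", {
  set.seed(65)
  gts <- random_boxes(8, width = 200, height = 200, classes = 1:3,
                      with_confidence = FALSE)
  # jittered detections: IoU with their truths well below 1
  dets <- gts
  dets$x_min <- dets$x_min + 1.5; dets$y_min <- dets$y_min + 1.5
  dets$confidence <- runif(8, 0.5, 1)
  expect_equal(length(seq(0.5, 0.95, by = 0.05)), 10)
  m_range <- map_range(dets, gts)
  m50 <- mean_ap(dets, gts, 0.5)
  expect_gte(m50, m_range)
  maps <- vapply(seq(0.5, 0.95, by = 0.05),
                 function(t) mean_ap(dets, gts, t), 1.0)
  expect_true(all(diff(maps) <= 1e-12))
  expect_equal(mean(maps), m_range)
  # identical detections are perfect at every threshold
  perfect <- dplyr::mutate(gts, confidence = 0.9)
  expect_equal(map_range(perfect, gts), 1.0)
})

test_that("AP is invariant to image and detection input order", {
  set.seed(66)
  sc <- random_scenario(n_images = 4, max_boxes = 6)
  base <- average_precision(sc$dets, sc$gts, 1, 0.3)
  perm <- sample(nrow(sc$dets))
  expect_equal(average_precision(sc$dets[perm, ], sc$gts, 1, 0.3), base)
  gperm <- sample(nrow(sc$gts))
  expect_equal(average_precision(sc$dets, sc$gts[gperm, ], 1, 0.3), base)
})

test_that("the confusion matrix conserves ground-truth counts", {
  set.seed(67)
  gts <- random_boxes(12, width = 300, height = 300, classes = 1:9,
                      with_confidence = FALSE)
  perfect <- dplyr::mutate(gts, confidence = 0.9)
  cm <- confusion_matrix(perfect, gts)
  expect_equal(sum(diag(cm[1:9, 1:9])), 12)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # zero detections: every ground truth falls in the background column
  cm0 <- confusion_matrix(perfect[0, ], gts)
  expect_equal(unname(cm0[1:9, 10]),
               unname(vapply(1:9, function(cl)
                 sum(gts$class_id == cl), 1L)))
  # row sums over class rows equal per-class ground-truth counts
  sc <- random_scenario(n_images = 3, max_boxes = 6, classes = 1:4)
  cmx <- confusion_matrix(sc$dets, sc$gts, iou_threshold = 0.3)
  for (cl in 1:9) {
    expect_equal(unname(sum(cmx[cl, ])), sum(sc$gts$class_id == cl))
  }
})

test_that("the full report ties the metric suite together", {
  set.seed(68)
  sc <- random_scenario(n_images = 3, max_boxes = 5, classes = 1:3)
  rep <- evaluate_detections(sc$dets, sc$gts, iou_threshold = 0.3)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$map50, mean_ap(sc$dets, sc$gts, 0.5))
  expect_equal(rep$map50_95, map_range(sc$dets, sc$gts))
  expect_equal(nrow(rep$per_class_ap), length(unique(sc$gts$class_id)))
  expect_true(all(rep$per_class_ap$ap >= 0 & rep$per_class_ap$ap <= 1,
                  na.rm = TRUE))
  expect_true(all(rep$f1_curve$f1 >= 0 & rep$f1_curve$f1 <= 1))
  # recall never increases as the threshold rises
  expect_true(all(diff(rep$f1_curve$recall) <= 1e-12))
  g <- glance(rep)
  expect_equal(g$map50, rep$map50)
  expect_equal(tidy(rep), rep$per_class_ap)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_f1_curve(rep), "ggplot")
  expect_s3_class(plot_confusion(rep), "ggplot")
})
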