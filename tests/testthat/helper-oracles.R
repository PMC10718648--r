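# Independent brute-force oracles: per-pixel / per-box loops written
# directly from the defining formulas, sharing no code with the package
# internals they check.

oracle_warp <- function(img, theta, tx, ty, center,
                        out_shape = dim(img)) {
  H <- out_shape[1]; W <- out_shape[2]
  Hs <- nrow(img); Ws <- ncol(img)
  out <- matrix(0, H, W); valid <- matrix(FALSE, H, W)
  for (row in seq_len(H)) for (col in seq_len(W)) {
    dx <- (col - 1) - center[1] - tx
    dy <- (row - 1) - center[2] - ty
    xs <- cos(-theta) * dx - sin(-theta) * dy + center[1]
    ys <- sin(-theta) * dx + cos(-theta) * dy + center[2]
    if (xs >= 0 && xs <= Ws - 1 && ys >= 0 && ys <= Hs - 1) {
      x0 <- min(floor(xs), Ws - 2); y0 <- min(floor(ys), Hs - 2)
      fx <- xs - x0; fy <- ys - y0
      out[row, col] <-
        (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] +
                    fx * img[y0 + 1, x0 + 2]) +
        fy * ((1 - fx) * img[y0 + 2, x0 + 1] + fx * img[y0 + 2, x0 + 2])
      valid[row, col] <- TRUE
    }
  }
  list(pixels = out, valid = valid)
}

oracle_bin <- function(v, bins) min(floor(v * bins), bins - 1)

oracle_joint_hist <- function(ref, mov, bins, valid = NULL,
                              weights = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(ref), ncol(ref))
  if (is.null(weights)) weights <- matrix(1, nrow(ref), ncol(ref))
  joint <- matrix(0, bins, bins)
  for (row in seq_len(nrow(ref))) for (col in seq_len(ncol(ref))) {
    if (!valid[row, col]) next
    i <- oracle_bin(ref[row, col], bins) + 1
    j <- oracle_bin(mov[row, col], bins) + 1
    joint[i, j] <- joint[i, j] + weights[row, col]
  }
  joint / sum(joint)
}

oracle_mi <- function(joint) {
  bins_i <- nrow(joint); bins_j <- ncol(joint)
  pi <- numeric(bins_i); pj <- numeric(bins_j)
  for (i in seq_len(bins_i)) for (j in seq_len(bins_j)) {
    pi[i] <- pi[i] + joint[i, j]
    pj[j] <- pj[j] + joint[i, j]
  }
  mi <- 0
  for (i in seq_len(bins_i)) for (j in seq_len(bins_j)) {
    if (joint[i, j] > 0) {
      mi <- mi + joint[i, j] * log2(joint[i, j] / (pi[i] * pj[j]))
    }
  }
  mi
}

oracle_entropy <- function(img, bins) {
  counts <- numeric(bins)
  for (v in as.vector(img)) {
    counts[oracle_bin(v, bins) + 1] <- counts[oracle_bin(v, bins) + 1] + 1
  }
  p <- counts / sum(counts)
  -sum(p[p > 0] * log2(p[p > 0]))
}

oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
           (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

box_row_vec <- function(df, i) {
  c(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i])
}

# Greedy NMS re-implemented from the rule statement; images independent.
oracle_nms <- function(d, iou_threshold = 0.45, class_aware = TRUE) {
  kept_all <- integer(0)
  for (img in unique(d$image_id)) {
    idx <- which(d$image_id == img)
    kept_all <- c(kept_all,
                  idx[oracle_nms_one(d[idx, , drop = FALSE],
                                     iou_threshold, class_aware)])
  }
  d[sort(kept_all), , drop = FALSE]
}

oracle_nms_one <- function(d, iou_threshold, class_aware) {
  remaining <- seq_len(nrow(d))
  kept <- integer(0)
  while (length(remaining) > 0) {
    confs <- d$confidence[remaining]
    top <- remaining[which.max(confs)]   # ties -> first (input order)
    kept <- c(kept, top)
    remaining <- setdiff(remaining, top)
    drop <- logical(length(remaining))
    for (idx in seq_along(remaining)) {
      j <- remaining[idx]
      if (class_aware && d$class_id[j] != d$class_id[top]) next
      if (oracle_iou(box_row_vec(d, top), box_row_vec(d, j)) >
          iou_threshold) {
        drop[idx] <- TRUE
      }
    }
    remaining <- remaining[!drop]
  }
  sort(kept)
}

# Greedy matching (one image, one class) re-implemented naively.
oracle_match <- function(dets, gts, iou_threshold = 0.5) {
  ord <- order(-dets$confidence)
  used <- rep(FALSE, nrow(gts))
  matched <- logical(nrow(dets))
  for (k in ord) {
    best_iou <- -1; best_j <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- oracle_iou(box_row_vec(dets, k), box_row_vec(gts, j))
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0 && best_iou >= iou_threshold) {
      used[best_j] <- TRUE
      matched[k] <- TRUE
    }
  }
  list(tp = sum(matched), fp = sum(!matched), fn = sum(!used),
       matched = matched)
}

# Rank-enumeration AP: re-run the greedy matching from scratch on the
# top-k detections for every k, then integrate the monotone envelope.
oracle_ap <- function(dets, gts, class_id, iou_threshold = 0.5) {
  d <- dets[dets$class_id == class_id, , drop = FALSE]
  g <- gts[gts$class_id == class_id, , drop = FALSE]
  if (nrow(g) == 0) return(NA_real_)
  if (nrow(d) == 0) return(0)
  ord <- order(-d$confidence)
  prec <- numeric(nrow(d)); rec <- numeric(nrow(d))
  for (k in seq_len(nrow(d))) {
    top <- d[ord[seq_len(k)], , drop = FALSE]
    tp <- 0
    for (img in unique(c(top$image_id, g$image_id))) {
      tp <- tp + oracle_match(top[top$image_id == img, , drop = FALSE],
                              g[g$image_id == img, , drop = FALSE],
                              iou_threshold)$tp
    }
    prec[k] <- tp / k
    rec[k] <- tp / nrow(g)
  }
  ap <- 0
  for (k in seq_len(nrow(d))) {
    env <- max(prec[k:nrow(d)])
    r_prev <- if (k == 1) 0 else rec[k - 1]
    ap <- ap + (rec[k] - r_prev) * env
  }
  ap
}

oracle_map <- function(dets, gts, iou_threshold = 0.5) {
  classes <- sort(unique(gts$class_id))
  mean(vapply(classes, function(cl)
    oracle_ap(dets, gts, cl, iou_threshold), 1.0))
}

# Linear-interpolation percentile implemented from the order-statistic
# definition (matches the type-7 convention).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= length(x)) return(x[length(x)])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Direct transcription of the haze/gamma chain, per-pixel loops.
oracle_haze_gamma <- function(rgb, alpha = 0.2, beta = 0.7, gamma = 0.6,
                              dark_percentile = 1, dark_scale = 0.25,
                              floor_clip = 1e-6) {
  out <- rgb
  for (c in 1:3) {
    ch <- rgb[, , c]
    a <- dark_scale * oracle_percentile(as.vector(ch), dark_percentile)
    tmat <- matrix(0, nrow(ch), ncol(ch))
    for (i in seq_len(nrow(ch))) for (j in seq_len(ncol(ch))) {
      ind <- if (ch[i, j] > a) 1 else 0
      tmat[i, j] <- max(ind * (1 + alpha * (ch[i, j] - a)) - beta,
                        floor_clip)
    }
    b <- 0
    for (i in seq_len(nrow(ch))) for (j in seq_len(ncol(ch))) {
      b <- b + (ch[i, j] - a) * tmat[i, j]^gamma
    }
    b <- b / length(ch)
    oc <- b * tmat^gamma
    m <- max(oc)
    if (m > 0) oc <- oc / m
    out[, , c] <- pmin(pmax(oc, 0), 1)
  }
  out
}

# Per-pixel vegetation-index loops straight from the formulas.
oracle_index <- function(B, G, R, NIR, name, eps = 1e-9,
                         as_printed = FALSE) {
  out <- matrix(NA_real_, nrow(B), ncol(B))
  for (i in seq_len(nrow(B))) for (j in seq_len(ncol(B))) {
    b <- B[i, j]; g <- G[i, j]; r <- R[i, j]; n <- NIR[i, j]
    if (name == "NDVI") { num <- n - r; den <- n + r }
    else if (name == "VARI") { num <- g - r; den <- g + r - b }
    else if (name == "GARI") {
      num <- n - (g - (b - r))
      den <- if (as_printed) n - (g + (b - r)) else n + (g - (b - r))
    } else { num <- n - r; den <- b + g }
    if (abs(den) >= eps) out[i, j] <- num / den
  }
  out
}
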