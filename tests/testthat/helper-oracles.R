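# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force and separate from the
# package's own code paths.

# Flood-fill connected components: returns a data frame of components
# (tight 0-based half-open boxes + pixel counts), sorted by (xmin, ymin).
flood_fill_components <- function(M, connectivity) {
  H <- nrow(M); W <- ncol(M)
  seen <- matrix(FALSE, H, W)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand_off <- expand.grid(dr = -1:1, dc = -1:1)
    expand_off <- expand_off[!(expand_off$dr == 0 & expand_off$dc == 0), ]
    lapply(seq_len(nrow(expand_off)),
           function(i) c(expand_off$dr[i], expand_off$dc[i]))
  }
  comps <- NULL
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (M[r0, c0] != 1 || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    px <- NULL
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      px <- rbind(px, p)
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            M[r, c] == 1 && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
    comps <- rbind(comps, data.frame(
      xmin = min(px[, 2]) - 1L, ymin = min(px[, 1]) - 1L,
      xmax = max(px[, 2]), ymax = max(px[, 1]),
      pixel_count = nrow(px)))
  }
  if (is.null(comps))
    return(data.frame(xmin = integer(0), ymin = integer(0),
                      xmax = integer(0), ymax = integer(0),
                      pixel_count = integer(0)))
  comps <- comps[order(comps$xmin, comps$ymin), , drop = FALSE]
  rownames(comps) <- NULL
  comps
}

# Direct 2D convolution with an explicitly constructed normalized
# Gaussian kernel and clamped (edge-replicated) indexing.
brute_gaussian_blur <- function(plane, sigma) {
  r <- ceiling(3 * sigma)
  ax <- -r:r
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(plane); W <- ncol(plane)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (dy in ax) for (dx in ax) {
      ii <- min(max(i + dy, 1), H); jj <- min(max(j + dx, 1), W)
      acc <- acc + k[dy + r + 1, dx + r + 1] * plane[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Per-pixel evaluation of the saliency definition from its parts:
# distance between the plane means and the brute-blurred LAB vector.
brute_saliency <- function(image, sigma) {
  lab <- to_lab(image)
  mu <- c(mean(lab$L), mean(lab$a), mean(lab$b))
  bl <- brute_gaussian_blur(lab$L, sigma)
  ba <- brute_gaussian_blur(lab$a, sigma)
  bb <- brute_gaussian_blur(lab$b, sigma)
  H <- nrow(bl); W <- ncol(bl)
  S <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    S[i, j] <- sqrt(sum((mu - c(bl[i, j], ba[i, j], bb[i, j]))^2))
  S
}

# Literal re-implementation of the merge loop with the same
# deterministic scan order, kept naive on purpose.
oracle_merge_phase <- function(dets, thr) {
  ord <- function(d) order((d$xmax - d$xmin) * (d$ymax - d$ymin),
                           d$xmin, d$ymin, d$confidence, d$label)
  pair_iou <- function(a, b) {
    iw <- max(0, min(a$xmax, b$xmax) - max(a$xmin, b$xmin))
    ih <- max(0, min(a$ymax, b$ymax) - max(a$ymin, b$ymin))
    inter <- iw * ih
    inter / ((a$xmax - a$xmin) * (a$ymax - a$ymin) +
               (b$xmax - b$xmin) * (b$ymax - b$ymin) - inter)
  }
  work <- dets[ord(dets), , drop = FALSE]
  hold <- dets[0, , drop = FALSE]
  while (nrow(work)) {
    b0 <- work[1, , drop = FALSE]
    work <- work[-1, , drop = FALSE]
    hit <- 0
    for (i in seq_len(nrow(work))) {
      if (work$label[i] == b0$label &&
          pair_iou(b0, work[i, , drop = FALSE]) > thr) { hit <- i; break }
    }
    if (hit == 0) {
      hold <- rbind(hold, b0)
    } else {
      bi <- work[hit, , drop = FALSE]
      w0 <- b0$confidence; w1 <- bi$confidence
      if (w0 + w1 == 0) { w0 <- 1; w1 <- 1 }
      av <- function(a, b) as.integer(round((w0 * a + w1 * b) / (w0 + w1)))
      work[hit, c("xmin", "ymin", "xmax", "ymax")] <-
        c(av(b0$xmin, bi$xmin), av(b0$ymin, bi$ymin),
          av(b0$xmax, bi$xmax), av(b0$ymax, bi$ymax))
      work$confidence[hit] <- 1 - (1 - b0$confidence) * (1 - bi$confidence)
      work <- work[ord(work), , drop = FALSE]
    }
  }
  rownames(hold) <- NULL
  hold
}

# Random detection sets for property tests.
random_detections <- function(n, labels = c("a", "b"), max_xy = 40) {
  x <- sample(0:max_xy, n, TRUE); y <- sample(0:max_xy, n, TRUE)
  w <- sample(4:20, n, TRUE); h <- sample(4:20, n, TRUE)
  detection(x, y, x + w, y + h, sample(labels, n, TRUE),
            round(stats::runif(n), 3))
}

# Canonical row order for comparing detection sets regardless of sort.
canon_dets <- function(d) {
  d <- d[order(d$xmin, d$ymin, d$xmax, d$ymax, d$label, d$confidence), ,
         drop = FALSE]
  rownames(d) <- NULL
  d
}

# A small scene with one dark ellipse on yellow background, plus its
# ground truth; convenience wrapper over the generator.
one_insect_scene <- function(seed = 5) {
  generate_scene(scene_params(n_insects = c(1, 1), seed = seed))
}

# External-detector fixture for fusion tests: the ground-truth boxes as
# confident detections plus n_fp injected false positives placed well
# away from every insect.
external_with_false_positives <- function(gts, n_fp, width = 320,
                                          height = 320) {
  ext <- data.frame(gts[, c("xmin", "ymin", "xmax", "ymax")],
                    label = gts$label, confidence = 0.9,
                    stringsAsFactors = FALSE)
  cx_gt <- (gts$xmin + gts$xmax) / 2; cy_gt <- (gts$ymin + gts$ymax) / 2
  for (k in seq_len(n_fp)) {
    repeat {
      cx <- stats::runif(1, 30, width - 30)
      cy <- stats::runif(1, 30, height - 30)
      if (!nrow(gts) ||
          min(sqrt((cx_gt - cx)^2 + (cy_gt - cy)^2)) > 45) break
    }
    ext <- rbind(ext, data.frame(
      xmin = round(cx - 12), ymin = round(cy - 12),
      xmax = round(cx + 12), ymax = round(cy + 12),
      label = "diamondback moth", confidence = 0.9,
      stringsAsFactors = FALSE))
  }
  list(dets = ext, n_gt = nrow(gts))
}
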