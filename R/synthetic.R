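#' Parameters for synthetic sticky-trap scenes
#'
#' Describes a simulated trap image: a near-uniform yellow background
#' with Gaussian pixel noise and a handful of small dark insects drawn
#' as filled rotated ellipses, each annotated with its tight bounding
#' box. Two classes are emulated with synthetic stand-in colours: the
#' target class `"diamondback moth"` (dark grey-brown) and `"others"`
#' (near black). An `adjacency_fraction` of the insects is deliberately
#' placed touching or nearly touching another insect of the same class,
#' which reproduces the known failure mode where closely packed insects
#' fuse into a single activation region.
#'
#' @param height,width Image size in pixels (default 320 x 320).
#' @param background Background RGB (default `c(230, 200, 40)`,
#'   sticky-trap yellow).
#' @param noise_sd Per-pixel Gaussian noise standard deviation
#'   (default 5).
#' @param n_insects Integer range `c(min, max)` of insects per scene
#'   (default `c(3, 8)`).
#' @param class_colours Named list of RGB stand-in colours per class.
#' @param class_probs Sampling probabilities per class (same order).
#' @param side_range Ellipse axis range in px (default `c(12, 36)`).
#' @param min_spacing Minimum center-to-center spacing between
#'   non-adjacent insects, px (default 60, comfortably more than one
#'   body length so saliency components stay separate).
#' @param adjacency_fraction Fraction of insects placed close to a
#'   partner (default 0).
#' @param colour_jitter_sd Per-insect colour jitter (default 5).
#' @param seed Integer seed; scenes are deterministic given the seed.
#' @return A named list of class `"scene_params"`.
#' @export
scene_params <- function(height = 320, width = 320,
                         background = c(230, 200, 40),
                         noise_sd = 5,
                         n_insects = c(3, 8),
                         class_colours = list(
                           "diamondback moth" = c(60, 50, 40),
                           "others" = c(20, 20, 20)),
                         class_probs = c(0.7, 0.3),
                         side_range = c(12, 36),
                         min_spacing = 60,
                         adjacency_fraction = 0,
                         colour_jitter_sd = 5,
                         seed = 1L) {
  p <- list(height = height, width = width, background = background,
            noise_sd = noise_sd, n_insects = n_insects,
            class_colours = class_colours, class_probs = class_probs,
            side_range = side_range, min_spacing = min_spacing,
            adjacency_fraction = adjacency_fraction,
            colour_jitter_sd = colour_jitter_sd, seed = as.integer(seed))
  stopifnot(p$height >= 32, p$width >= 32,
            all(p$background >= 0), all(p$background <= 255),
            p$noise_sd >= 0, all(p$n_insects >= 0),
            p$side_range[1] >= 4,
            p$adjacency_fraction >= 0, p$adjacency_fraction <= 1,
            length(p$class_probs) == length(p$class_colours))
  structure(p, class = "scene_params")
}

#' Generate one synthetic trap scene
#'
#' Draws the background, places insects subject to the spacing and
#' adjacency constraints of `params`, and returns the image with its
#' ground-truth annotation. Deterministic given `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @return A list with `image` (an `H x W x 3` array in `[0, 255]`) and
#'   `gts` (data frame `xmin`, `ymin`, `xmax`, `ymax`, `label`).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  local_seed(params$seed, {
    H <- params$height; W <- params$width
    n <- if (params$n_insects[1] == params$n_insects[2]) params$n_insects[1]
         else sample(seq(params$n_insects[1], params$n_insects[2]), 1L)
    img <- array(rep(params$background, each = H * W), c(H, W, 3L)) +
      stats::rnorm(H * W * 3L, sd = params$noise_sd)

    gts <- data.frame(xmin = integer(0), ymin = integer(0),
                      xmax = integer(0), ymax = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
    if (n == 0L) return(list(image = round(pmin(pmax(img, 0), 255)), gts = gts))

    margin <- params$side_range[2] / 2 + 4
    n_adj <- if (n >= 2L) round(params$adjacency_fraction * n) else 0L
    n_base <- n - n_adj

    centers <- matrix(numeric(0), 0L, 2L)
    sizes <- matrix(numeric(0), 0L, 2L)    # full axes (w, h)
    angles <- numeric(0)
    labels <- character(0)
    class_names <- names(params$class_colours)

    place <- function(test_ok) {
      for (try in seq_len(500L)) {
        cand <- c(stats::runif(1, margin, W - margin),
                  stats::runif(1, margin, H - margin))
        if (test_ok(cand)) return(cand)
      }
      stop("could not place insect after 500 retries; relax spacing or size")
    }

    for (i in seq_len(n_base)) {
      cand <- place(function(cc) {
        !nrow(centers) ||
          min(sqrt(rowSums(sweep(centers, 2L, cc)^2))) >= params$min_spacing
      })
      centers <- rbind(centers, cand)
      sizes <- rbind(sizes, stats::runif(2, params$side_range[1],
                                         params$side_range[2]))
      angles <- c(angles, stats::runif(1, 0, pi))
      labels <- c(labels, sample(class_names, 1L, prob = params$class_probs))
    }
    for (i in seq_len(n_adj)) {
      partner <- sample.int(n_base, 1L)
      psize <- sizes[partner, ]
      size <- stats::runif(2, params$side_range[1], params$side_range[2])
      placed <- FALSE
      for (try in seq_len(500L)) {
        d <- stats::runif(1, 0.45, 0.75) * (max(psize) / 2 + max(size) / 2)
        th <- stats::runif(1, 0, 2 * pi)
        cand <- centers[partner, ] + d * c(cos(th), sin(th))
        if (cand[1] < margin || cand[1] > W - margin ||
            cand[2] < margin || cand[2] > H - margin) next
        # keep full spacing to unrelated base insects; other companions
        # may crowd the same cluster but must not coincide
        base_others <- centers[setdiff(seq_len(n_base), partner), ,
                               drop = FALSE]
        if (nrow(base_others) &&
            min(sqrt(rowSums(sweep(base_others, 2L, cand)^2))) <
              params$min_spacing) next
        comp <- centers[-seq_len(n_base), , drop = FALSE]
        if (nrow(comp) &&
            min(sqrt(rowSums(sweep(comp, 2L, cand)^2))) < 8) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place adjacent insect after 500 retries")
      centers <- rbind(centers, cand)
      sizes <- rbind(sizes, size)
      angles <- c(angles, stats::runif(1, 0, pi))
      labels <- c(labels, labels[partner])   # close pairs share a class
    }

    for (i in seq_len(nrow(centers))) {
      colour <- params$class_colours[[labels[i]]] +
        stats::rnorm(3, sd = params$colour_jitter_sd)
      gt <- draw_ellipse(img, centers[i, ], sizes[i, ] / 2, angles[i],
                         colour, params$noise_sd)
      img <- gt$image
      gts <- rbind(gts, data.frame(xmin = gt$box[1], ymin = gt$box[2],
                                   xmax = gt$box[3], ymax = gt$box[4],
                                   label = labels[i],
                                   stringsAsFactors = FALSE))
    }
    list(image = round(pmin(pmax(img, 0), 255)), gts = gts)
  })
}

# Fill a rotated ellipse (semi-axes a, b) into the image; returns the
# updated image and the drawn pixels' tight bounding box (0-based,
# half-open).
draw_ellipse <- function(img, center, semi, angle, colour, noise_sd) {
  H <- dim(img)[1]; W <- dim(img)[2]
  R <- ceiling(max(semi)) + 1L
  cols <- max(1L, floor(center[1] - R)):min(W, ceiling(center[1] + R))
  rows <- max(1L, floor(center[2] - R)):min(H, ceiling(center[2] + R))
  X <- outer(rep(1, length(rows)), cols - 0.5) - center[1]  # pixel centers
  Y <- outer(rows - 0.5, rep(1, length(cols)))[, seq_along(cols)] - center[2]
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  inside <- (u / semi[1])^2 + (v / semi[2])^2 <= 1
  if (!any(inside)) stop("degenerate insect: no pixels covered")
  npix <- sum(inside)
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[inside] <- colour[ch] + stats::rnorm(npix, sd = noise_sd)
    img[rows, cols, ch] <- plane
  }
  hit_cols <- cols[colSums(inside) > 0]; hit_rows <- rows[rowSums(inside) > 0]
  list(image = img,
       box = c(min(hit_cols) - 1L, min(hit_rows) - 1L,
               max(hit_cols), max(hit_rows)))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` scenes as PNG files with PASCAL VOC XML annotations
#' and a manifest CSV. Per-image seeds are derived deterministically
#' from the master seed in `params`, so regenerating with the same seed
#' reproduces the files byte for byte.
#'
#' @param n_images Number of scenes to generate.
#' @param params A [scene_params()] object (its `seed` is the master
#'   seed).
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame (columns `image`, `annotation`,
#'   `n_insects`, `seed`), also written to `manifest.csv`.
#' @export
generate_dataset <- function(n_images, params, out_dir) {
  stopifnot(n_images >= 1, inherits(params, "scene_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  manifest <- data.frame(image = character(0), annotation = character(0),
                         n_insects = integer(0), seed = integer(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_images)) {
    seed_i <- scene_seed(params$seed, i)
    p_i <- params; p_i$seed <- seed_i
    scene <- generate_scene(p_i)
    img_name <- sprintf("scene_%04d.png", i)
    xml_name <- sprintf("scene_%04d.xml", i)
    write_image(scene$image, file.path(out_dir, img_name))
    write_voc(scene$gts, file.path(out_dir, xml_name),
              filename = img_name,
              width = params$width, height = params$height)
    manifest <- rbind(manifest, data.frame(
      image = img_name, annotation = xml_name,
      n_insects = nrow(scene$gts), seed = seed_i,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# Derived per-image seed, kept inside 32-bit integer range.
scene_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 7919) %% 2147483647)
}
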