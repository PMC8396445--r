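test_that("connected_components handles empty, full and the two-blob mask", {
  expect_equal(nrow(connected_components(matrix(0L, 6, 6))), 0L)

  full <- connected_components(matrix(1L, 10, 10))
  expect_equal(nrow(full), 1L)
  expect_equal(unlist(full[1, c("xmin", "ymin", "xmax", "ymax")],
                      use.names = FALSE), c(0L, 0L, 10L, 10L))
  expect_equal(full$pixel_count, 100L)

  # pixels at rows/cols (1,1),(1,2) and (7,7) in 0-based (row, col) terms
  M <- matrix(0L, 9, 9)
  M[2, 2] <- 1L; M[2, 3] <- 1L; M[8, 8] <- 1L
  regs <- connected_components(M, 8)
  expect_equal(nrow(regs), 2L)
  expect_equal(unlist(regs[1, c("xmin", "ymin", "xmax", "ymax")],
                      use.names = FALSE), c(1L, 1L, 3L, 2L))
  expect_equal(unlist(regs[2, c("xmin", "ymin", "xmax", "ymax")],
                      use.names = FALSE), c(7L, 7L, 8L, 8L))
})

test_that("connected_components agrees with the flood-fill oracle and conserves pixels", {
  set.seed(19)
  for (rep in 1:25) {
    M <- matrix(rbinom(32 * 32, 1, 0.35), 32, 32)
    for (conn in c(4, 8)) {
      got <- connected_components(M, conn)
      want <- flood_fill_components(M, conn)
      expect_equal(got[, c("xmin", "ymin", "xmax", "ymax", "pixel_count")],
                   want, ignore_attr = TRUE)
      expect_equal(sum(got$pixel_count), sum(M))
      # centroid lies inside its box
      if (nrow(got)) {
        expect_true(all(got$xc >= got$xmin & got$xc <= got$xmax))
        expect_true(all(got$yc >= got$ymin & got$yc <= got$ymax))
      }
    }
  }
})

test_that("area_filter keeps areas >= beta and is monotone in beta", {
  regs <- data.frame(xmin = c(0, 10, 20), ymin = 0,
                     xmax = c(2, 15, 30), ymax = c(2, 6, 10),
                     pixel_count = c(4, 30, 100), xc = 1, yc = 1)
  expect_equal(nrow(area_filter(regs, 0)), 3L)              # no-op
  surv <- area_filter(regs, 30)
  expect_equal(box_area(surv), c(30, 100))                  # equality survives
  expect_equal(nrow(area_filter(regs[0, ], 10)), 0L)

  set.seed(4)
  S <- normalize_saliency(matrix(runif(900), 30, 30))
  regs2 <- connected_components(threshold_mask(S, 0.5))
  betas <- sort(runif(5, 0, 40))
  counts <- vapply(betas, function(b) nrow(area_filter(regs2, b)), integer(1))
  expect_true(all(diff(counts) <= 0))                       # never grows
})

test_that("iogt measures intersection over ground-truth area", {
  expect_equal(iogt(box(0, 0, 20, 20), box(5, 5, 10, 10)), 1.0)  # contained
  expect_equal(iogt(box(0, 0, 5, 5), box(10, 10, 20, 20)), 0.0)  # disjoint
  expect_equal(iogt(box(0, 0, 10, 5), box(0, 0, 10, 10)), 0.5)
})

test_that("label_region_fg_bg applies the strict-below-threshold rule", {
  region <- data.frame(xmin = 0, ymin = 0, xmax = 20, ymax = 20)
  gt_in <- data.frame(xmin = 5, ymin = 5, xmax = 10, ymax = 10, label = "m")
  expect_equal(label_region_fg_bg(region, gt_in, 0.5), "foreground")
  expect_equal(label_region_fg_bg(region, NULL, 0.5), "background")
  expect_equal(label_region_fg_bg(region, gt_in[0, ], 0.5), "background")
  # max iogt 0.49 < 0.5 -> background (boundary is strict)
  gt_part <- data.frame(xmin = c(-15, 13), ymin = c(0, 0),
                        xmax = c(30, 120), ymax = c(5, 10),
                        label = c("m", "m"))
  vals <- iogt(region[c(1, 1), ], gt_part)
  expect_true(all(vals < 0.5))
  expect_equal(label_region_fg_bg(region, gt_part, 0.5), "background")
})

test_that("tuneup_boxes center, clip and drop correctly", {
  b <- tuneup_boxes(c(50, 50), list(c(20, 20)), c(100, 100))
  expect_equal(unlist(b[1, c("xmin", "ymin", "xmax", "ymax")],
                      use.names = FALSE), c(40L, 40L, 60L, 60L))

  clipped <- tuneup_boxes(c(2, 2), list(c(20, 20)), c(100, 100))
  expect_equal(unlist(clipped[1, c("xmin", "ymin", "xmax", "ymax")],
                      use.names = FALSE), c(0L, 0L, 12L, 12L))

  expect_equal(nrow(tuneup_boxes(c(50, 50), list(), c(100, 100))), 0L)
  expect_error(tuneup_boxes(c(150, 50), list(c(10, 10)), c(100, 100)),
               "outside")
  expect_error(tuneup_boxes(c(50, 50), list(c(1, 10)), c(100, 100)), ">= 2")
})

test_that("generate_proposals runs the full first stage", {
  cfg <- pest_config()
  # uniform image: no saliency, no proposals
  expect_equal(nrow(generate_proposals(uniform_image(64, 64, c(230, 200, 40)),
                                       classifier = constant_classifier("fg"),
                                       config = cfg)), 0L)

  sc <- one_insect_scene(seed = 5)
  props <- generate_proposals(sc$image,
                              classifier = constant_classifier("insect"),
                              config = cfg)
  # one foreground region: its own box plus k tune-up boxes, one anchor
  expect_equal(nrow(props), 1L + length(cfg$scales))
  expect_equal(length(unique(props$anchor_x)), 1L)
  expect_equal(props$scale_index, 0:3)
  # all boxes inside the image
  expect_true(all(props$xmin >= 0 & props$ymin >= 0 &
                    props$xmax <= 320 & props$ymax <= 320))

  # a closed gate yields nothing
  expect_equal(nrow(generate_proposals(
    sc$image, classifier = constant_classifier("background"),
    config = cfg)), 0L)

  # training mode gates on iogt against the annotation
  props_tr <- generate_proposals(sc$image, gts = sc$gts, config = cfg)
  expect_equal(nrow(props_tr), 1L + length(cfg$scales))
  props_none <- generate_proposals(sc$image, gts = sc$gts[0, ], config = cfg)
  expect_equal(nrow(props_none), 0L)

  expect_error(generate_proposals(sc$image, config = cfg), "exactly one")
})
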