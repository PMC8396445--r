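test_that("iou matches area arithmetic", {
  expect_equal(iou(box(0, 0, 10, 10), box(0, 0, 10, 10)), 1.0)
  expect_equal(iou(box(0, 0, 10, 10), box(20, 20, 30, 30)), 0.0)
  expect_equal(iou(box(0, 0, 10, 10), box(5, 0, 15, 10)), 1 / 3)
})

test_that("crop_with_padding pads out-of-image pixels with white", {
  sc <- one_insect_scene()
  img <- sc$image

  inside <- crop_with_padding(img, box(10, 20, 30, 35))
  expect_equal(dim(inside), c(15L, 20L, 3L))
  expect_equal(inside, img[21:35, 11:30, , drop = FALSE])

  # box hanging off the top-left corner: outside quadrants are white
  b <- box(-5, -5, 5, 5)
  patch <- crop_with_padding(img, b)
  expect_equal(dim(patch), c(10L, 10L, 3L))
  expect_true(all(patch[1:5, , ] == 255))     # rows above the image
  expect_true(all(patch[, 1:5, ] == 255))     # cols left of the image
  expect_equal(patch[6:10, 6:10, ], img[1:5, 1:5, , drop = FALSE])

  # full-image box is the identity
  H <- dim(img)[1]; W <- dim(img)[2]
  expect_equal(crop_with_padding(img, box(0, 0, W, H)), img,
               ignore_attr = TRUE)

  expect_error(crop_with_padding(img, box(400, 400, 420, 420)),
               "outside")
})

test_that("make_c2_labels applies the max-iou >= threshold rule", {
  img <- uniform_image(100, 100, c(230, 200, 40))
  gts <- data.frame(xmin = c(10, 40), ymin = c(10, 10),
                    xmax = c(30, 60), ymax = c(30, 30),
                    label = c("diamondback moth", "others"))

  props <- data.frame(xmin = c(10, 70, 12), ymin = c(10, 70, 10),
                      xmax = c(30, 90, 38), ymax = c(30, 90, 30),
                      anchor_x = 0, anchor_y = 0, scale_index = 0)
  ex <- make_c2_labels(props, gts, img, iou_threshold = 0.5, patch_side = 32)
  expect_equal(vapply(ex, `[[`, "", "label"),
               c("diamondback moth", "background", "diamondback moth"))
  # every patch resized to the classifier input side
  expect_true(all(vapply(ex, function(e) all(dim(e$patch) == c(32, 32, 3)),
                         logical(1))))

  # labels attach per proposal: permuting proposals permutes labels
  ex_rev <- make_c2_labels(props[3:1, ], gts, img, 0.5, 32)
  expect_equal(vapply(ex_rev, `[[`, "", "label"),
               rev(vapply(ex, `[[`, "", "label")))

  # a proposal overlapping two classes takes the class of the higher iou
  props2 <- data.frame(xmin = 14, ymin = 10, xmax = 34, ymax = 30,
                      anchor_x = 0, anchor_y = 0, scale_index = 0)
  i1 <- iou(props2, gts[1, ]); i2 <- iou(props2, gts[2, ])
  expect_true(i1 >= 0.5 && i1 > i2)
  expect_equal(make_c2_labels(props2, gts, img, 0.5, 32)[[1]]$label,
               "diamondback moth")
})

test_that("oracle classifier predicts by central mean colour", {
  clf <- synthetic_category_classifier()
  moth_patch <- uniform_image(20, 20, c(60, 50, 40))
  oth_patch <- uniform_image(20, 20, c(20, 20, 20))
  bg_patch <- uniform_image(20, 20, c(230, 200, 40))
  expect_equal(predict_patch(clf, moth_patch),
               list(label = "diamondback moth", confidence = 1.0))
  expect_equal(predict_patch(clf, oth_patch),
               list(label = "others", confidence = 1.0))
  expect_equal(predict_patch(clf, bg_patch),
               list(label = "background", confidence = 1.0))

  # a patch straddling an insect edge, mean between the rule boxes
  straddle <- uniform_image(20, 20, c(230, 200, 40))
  for (ch in 1:3) straddle[, 1:10, ch] <- c(60, 50, 40)[ch]  # half moth
  m <- (c(60, 50, 40) + c(230, 200, 40)) / 2
  expect_true(m[1] > 140)               # outside both rule boxes
  expect_equal(predict_patch(clf, straddle)$label, "background")

  expect_error(oracle_classifier(list(
    a = list(lo = c(0, 0, 0), hi = c(100, 100, 100)),
    b = list(lo = c(50, 50, 50), hi = c(150, 150, 150)))), "overlapping")
})
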