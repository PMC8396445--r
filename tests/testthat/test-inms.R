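test_that("nms keeps the confident box and respects the overlap graph", {
  one <- detection(0, 0, 10, 10, "m", 0.7)
  expect_equal(nms(one, 0.5), one)

  two <- rbind(detection(0, 0, 10, 10, "m", 0.9),
               detection(0, 0, 10, 10, "m", 0.7))
  out <- nms(two, 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$confidence, 0.9)

  # A-B overlap, B-C overlap, A-C disjoint: greedy keeps A then C
  A <- detection(0, 0, 10, 10, "m", 0.9)
  B <- detection(0, 4, 10, 14, "m", 0.8)     # iou(A,B) = 0.6/1.4 > 0.5? no:
  # use boxes engineered for iou = 0.6 with each neighbour
  A <- detection(0, 0, 10, 20, "m", 0.9)
  B <- detection(0, 5, 10, 25, "m", 0.8)     # inter 150, union 250 -> 0.6
  C <- detection(0, 10, 10, 30, "m", 0.7)    # iou(B,C)=0.6, iou(A,C)=0.25
  expect_equal(iou(A, B), 0.6)
  expect_equal(iou(B, C), 0.6)
  expect_lt(iou(A, C), 0.5)
  out <- nms(rbind(A, B, C), 0.5)
  expect_equal(canon_dets(out), canon_dets(rbind(A, C)))
  expect_error(nms(rbind(A, B), 1), "iou_threshold")
})

test_that("merge_detections averages coordinates and noisy-ORs confidence", {
  d <- detection(0, 0, 10, 10, "m", 0.5)
  same <- merge_detections(d, detection(0, 0, 10, 10, "m", 0.5))
  expect_equal(unlist(same[1, 1:4], use.names = FALSE), c(0L, 0L, 10L, 10L))
  expect_equal(same$confidence, 0.75)

  # c0 = 1 absorbs
  expect_equal(merge_detections(detection(0, 0, 10, 10, "m", 1),
                                detection(2, 2, 8, 8, "m", 0.3))$confidence, 1)

  side <- merge_detections(detection(0, 0, 10, 10, "m", 0.5),
                           detection(10, 0, 20, 10, "m", 0.5))
  expect_equal(unlist(side[1, 1:4], use.names = FALSE), c(5L, 0L, 15L, 10L))
  expect_equal(side$confidence, 0.75)

  expect_error(merge_detections(detection(0, 0, 10, 10, "m", 0.5),
                                detection(0, 0, 10, 10, "x", 0.5)),
               "different labels")
})

test_that("inms merges weak duplicates past gamma and resolves the error-suppression scenario", {
  solo <- detection(0, 0, 10, 10, "m", 0.8)
  expect_equal(inms(solo, gamma = 0.5), solo)
  expect_equal(nrow(inms(empty_dets <- solo[0, ], gamma = 0.5)), 0L)

  # two same-class boxes, iou 0.8: merged confidence 0.75 survives
  # gamma = 0.6 where each alone would not
  dup <- rbind(detection(0, 0, 10, 10, "m", 0.5),
               detection(0, 1, 10, 11, "m", 0.5))
  expect_gt(iou(dup[1, ], dup[2, ]), 0.5)
  out <- inms(dup, 0.5, 0.3, gamma = 0.6)
  expect_equal(nrow(out), 1L)
  expect_equal(out$confidence, 0.75)

  # error-suppression: a small wrong-class box with the highest raw
  # confidence sits inside the correct box; merging the correct-class
  # duplicate lifts it to 0.84, and conventional NMS then removes the
  # wrong-class box
  dets <- rbind(detection(2, 2, 10, 10, "wrong", 0.8),
                detection(0, 0, 10, 10, "right", 0.6),
                detection(0, 0, 10, 9, "right", 0.6))
  expect_gt(iou(dets[2, ], dets[3, ]), 0.5)
  out <- inms(dets, 0.5, 0.5, 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$label, "right")
  expect_equal(out$confidence, 1 - 0.4 * 0.4)
})

test_that("inms invariants hold on random instances", {
  set.seed(123)
  for (rep in 1:60) {
    d <- random_detections(sample(1:8, 1))
    out <- inms(d, 0.5, 0.3, 0.2)
    expect_lte(nrow(out), nrow(d))
    expect_true(all(out$confidence >= 0.2))
    expect_true(all(out$label %in% d$label))      # no new classes
    # permutation invariance
    perm <- d[sample(nrow(d)), , drop = FALSE]
    expect_equal(canon_dets(inms(perm, 0.5, 0.3, 0.2)), canon_dets(out))
  }
})

test_that("inms reduces to nms-then-gamma when nothing can merge", {
  set.seed(55)
  for (rep in 1:40) {
    d <- random_detections(sample(1:8, 1))
    # knock out mergeable pairs: keep only detections pairwise below the
    # merge threshold within a class
    keep <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
      if (i < j && keep[i] && keep[j] && d$label[i] == d$label[j] &&
          iou(d[i, ], d[j, ]) > 0.5) keep[j] <- FALSE
    }
    d <- d[keep, , drop = FALSE]
    ref <- nms(d, 0.3)
    ref <- ref[ref$confidence >= 0.2, , drop = FALSE]
    expect_equal(canon_dets(inms(d, 0.5, 0.3, 0.2)), canon_dets(ref))
  }
})

test_that("the merge phase is idempotent and matches the scan-order oracle", {
  set.seed(321)
  for (rep in 1:100) {
    d <- random_detections(sample(1:8, 1))
    m1 <- stickypest:::inms_merge_phase(d, 0.5)
    expect_equal(canon_dets(stickypest:::inms_merge_phase(m1, 0.5)),
                 canon_dets(m1))
    expect_equal(canon_dets(m1), canon_dets(oracle_merge_phase(d, 0.5)))
  }
})
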