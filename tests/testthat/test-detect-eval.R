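mkbox <- function(x1, y1, x2, y2) c(x1, y1, x2, y2)

det_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(confidence = r[[1]], x_min = r[[2]], y_min = r[[3]],
               x_max = r[[4]], y_max = r[[5]])
  }))
}

# integer pixel-grid IoU oracle
pixel_iou_oracle <- function(a, b, grid = 30) {
  px <- expand.grid(x = seq_len(grid) - 0.5, y = seq_len(grid) - 0.5)
  ina <- px$x > a[1] & px$x < a[3] & px$y > a[2] & px$y < a[4]
  inb <- px$x > b[1] & px$x < b[3] & px$y > b[2] & px$y < b[4]
  sum(ina & inb) / sum(ina | inb)
}

test_that("IoU matches the pixel-grid counting oracle", {
  expect_equal(box_iou(mkbox(0, 0, 2, 2), mkbox(0, 0, 2, 2)), 1)
  expect_equal(box_iou(mkbox(0, 0, 2, 2), mkbox(5, 5, 7, 7)), 0)
  expect_equal(box_iou(mkbox(0, 0, 2, 2), mkbox(1, 1, 3, 3)), 1 / 7)
  expect_equal(box_iou(mkbox(0, 0, 2, 2), mkbox(1, 1, 3, 3)),
               pixel_iou_oracle(mkbox(0, 0, 2, 2), mkbox(1, 1, 3, 3)))
  expect_error(box_iou(mkbox(0, 0, 0, 2), mkbox(1, 1, 3, 3)), "degenerate")
})

test_that("greedy matching follows the single-match rule", {
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  one <- det_df(list(0.9, 0, 0, 10, 10))
  m <- match_detections(one, gt)
  expect_equal(sum(m$tp), 1)

  two <- det_df(list(0.9, 0, 0, 10, 10), list(0.8, 1, 1, 10, 10))
  m2 <- match_detections(two, gt)
  expect_equal(m2$tp, c(TRUE, FALSE))  # second hit on same GT is FP
  expect_equal(sum(m2$gt_matched), 1)
})

test_that("greedy matching equals the enumeration oracle on crafted cases", {
  set.seed(20)
  for (rep in 1:25) {
    ng <- sample(1:3, 1)
    nd <- sample(1:5, 1)
    gt <- do.call(rbind, lapply(seq_len(ng), function(i) {
      x <- stats::runif(1, 0, 20); y <- stats::runif(1, 0, 20)
      data.frame(x_min = x, y_min = y, x_max = x + stats::runif(1, 3, 8),
                 y_max = y + stats::runif(1, 3, 8))
    }))
    det <- do.call(rbind, lapply(seq_len(nd), function(i) {
      base <- gt[sample(ng, 1), ]
      jit <- stats::rnorm(2, sd = 1.5)
      data.frame(confidence = stats::runif(1),
                 x_min = base$x_min + jit[1], y_min = base$y_min + jit[2],
                 x_max = base$x_max + jit[1], y_max = base$y_max + jit[2])
    }))
    m <- match_detections(det, gt)
    expect_equal(m$tp, brute_force_tp(det, gt))
  }
})

test_that("average precision reproduces the hand-built PR curve", {
  # TP, FP, TP over 2 ground truths at confidences 0.9 / 0.8 / 0.7:
  # precision envelope over recall {0.5, 1.0} integrates to 5/6
  pr <- average_precision(c(TRUE, FALSE, TRUE), n_ground_truth = 2)
  expect_equal(pr$ap, 5 / 6)
  expect_true(all(diff(pr$recall) >= 0))
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))

  expect_equal(average_precision(c(TRUE, TRUE), 2)$ap, 1)   # perfect detector
  expect_equal(average_precision(logical(0), 2)$ap, 0)      # no detections
})

test_that("appending a low-confidence false positive never raises AP", {
  set.seed(4)
  for (rep in 1:20) {
    flags <- stats::runif(8) > 0.5
    ngt <- sum(flags) + sample(0:3, 1)
    if (ngt == 0) ngt <- 1
    ap0 <- average_precision(flags, ngt)$ap
    ap1 <- average_precision(c(flags, FALSE), ngt)$ap
    expect_lte(ap1, ap0 + 1e-12)
  }
})

test_that("all-point AP tracks 11-point AP on random small cases", {
  set.seed(9)
  for (rep in 1:20) {
    flags <- stats::runif(12) > 0.4
    ngt <- max(1, sum(flags))
    a <- average_precision(flags, ngt)$ap
    b <- average_precision(flags, ngt, interpolation = "11point")$ap
    expect_lt(abs(a - b), 0.05 + 1e-12)
  }
})

test_that("dataset evaluation aggregates per class and over images", {
  gt <- data.frame(image = c("a", "a", "b"),
                   class = c("benign", "malignant", "benign"),
                   x_min = c(0, 20, 5), y_min = c(0, 20, 5),
                   x_max = c(10, 30, 15), y_max = c(10, 30, 15))
  det <- data.frame(image = c("a", "a", "b"),
                    class = c("benign", "malignant", "benign"),
                    confidence = c(0.9, 0.8, 0.7),
                    x_min = c(0, 20, 5), y_min = c(0, 20, 5),
                    x_max = c(10, 30, 15), y_max = c(10, 30, 15))
  ev <- evaluate_detections(det, gt)
  expect_equal(ev$map, 1)
  expect_equal(ev$per_class$precision, c(1, 1))
  expect_equal(ev$per_class$recall, c(1, 1))
  # duplicating every detection leaves recall unchanged
  ev2 <- evaluate_detections(rbind(det, det), gt)
  expect_equal(ev2$per_class$recall, ev$per_class$recall)
  # a detection class absent from ground truth is dropped with a warning
  det_extra <- rbind(det, data.frame(image = "a", class = "cyst",
                                     confidence = 0.5, x_min = 0, y_min = 0,
                                     x_max = 5, y_max = 5))
  expect_warning(evaluate_detections(det_extra, gt), "cyst")
})
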