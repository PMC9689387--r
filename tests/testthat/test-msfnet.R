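test_that("backbone emits C2..C5 at strides 4/8/16/32", {
  model <- build_msfnet(msf_config(input_size = 64L,
                                   widths = c(8L, 16L, 32L, 64L)), seed = 0)
  img <- matrix(stats::runif(64 * 64), 64, 64)
  maps <- backbone_forward(model, img)
  expect_equal(dim(maps$C2)[1:3], c(16L, 16L, 8L))
  expect_equal(dim(maps$C3)[1:3], c(8L, 8L, 16L))
  expect_equal(dim(maps$C4)[1:3], c(4L, 4L, 32L))
  expect_equal(dim(maps$C5)[1:3], c(2L, 2L, 64L))
  # determinism: identical inputs give identical outputs
  expect_identical(maps, backbone_forward(model, img))
  expect_error(graph_forward(model$graph, matrix(0, 32, 32)), "expects")
})

test_that("FPN fusion follows the lateral + top-down recursion", {
  # identity laterals on 1-channel toy maps: C5 = 1, C4 = 2 everywhere
  lat_id <- list(w = array(1, c(1, 1, 1, 1)))
  c_maps <- list(C2 = array(0, c(8, 8, 1)), C3 = array(0, c(4, 4, 1)),
                 C4 = array(2, c(2, 2, 1)), C5 = array(1, c(1, 1, 1)))
  p <- fpn_fuse(c_maps, list(lat2 = lat_id, lat3 = lat_id,
                             lat4 = lat_id, lat5 = lat_id))
  expect_true(all(p$P5 == 1))
  expect_true(all(p$P4 == 3))           # 2 + upsampled 1
  expect_true(all(p$P3 == 3))           # 0 + upsampled 3
  expect_equal(dim(p$P2)[1:2], c(8L, 8L))
  # all-zero inputs give all-zero pyramid
  z <- lapply(c_maps, function(m) m * 0)
  pz <- fpn_fuse(z, list(lat2 = lat_id, lat3 = lat_id,
                         lat4 = lat_id, lat5 = lat_id))
  expect_true(all(vapply(pz, function(m) all(m == 0), logical(1))))
  # linear in its inputs when biases are zero
  p2 <- fpn_fuse(lapply(c_maps, function(m) 3 * m),
                 list(lat2 = lat_id, lat3 = lat_id,
                      lat4 = lat_id, lat5 = lat_id))
  expect_equal(p2$P3, 3 * p$P3)
  expect_error(fpn_fuse(c_maps, list(lat2 = lat_id, lat3 = lat_id,
                                     lat4 = list(w = array(1, c(1, 1, 3, 1))),
                                     lat5 = lat_id)), "channels")
})

test_that("saliency masking follows min-max normalisation with ties passing through", {
  s <- saliency_apply(matrix(c(0, 2, 1, 3), 2, 2))
  expect_equal(s$mask, matrix(c(0, 2 / 3, 1 / 3, 1), 2, 2))
  expect_equal(s$masked, matrix(c(0, 2, 1, 3), 2, 2) * s$mask)
  # constant map: degenerate range gives an all-ones mask
  s2 <- saliency_apply(matrix(5, 3, 3))
  expect_true(all(s2$mask == 1))
  expect_equal(s2$masked, matrix(5, 3, 3))
  # masked magnitude never exceeds the input
  set.seed(8)
  f <- array(stats::rnorm(36), c(3, 3, 4))
  s3 <- saliency_apply(f)
  expect_true(all(abs(s3$masked) <= abs(f) + 1e-12))
  expect_true(all(s3$mask >= 0 & s3$mask <= 1))
})

test_that("head decoding turns cell logits into centred boxes", {
  anchors <- list(p3 = cbind(w = c(10, 20, 30), h = c(10, 20, 30)))
  strides <- c(p3 = 8L)
  s <- 12L  # 96 px / stride 8
  m <- array(-20, c(s, s, 21))
  # all strongly negative logits: nothing detected
  expect_equal(nrow(decode_head(list(p3 = m), anchors, strides, 0.25, 96)), 0)
  # one confident cell at the image centre (cell 6,6 with 0.5 offsets)
  m[6, 6, 5] <- 10    # anchor 1 objectness
  m[6, 6, 6] <- 10    # benign class
  m[6, 6, 1] <- 0     # sigmoid 0.5 offsets
  m[6, 6, 2] <- 0
  m[6, 6, 3] <- 0     # box = anchor size
  m[6, 6, 4] <- 0
  det <- decode_head(list(p3 = m), anchors, strides, 0.25, 96)
  expect_equal(nrow(det), 1)
  expect_equal(det$class, "benign")
  expect_equal((det$x_min + det$x_max) / 2, (6 - 1 + 0.5) * 8)
  expect_equal(det$x_max - det$x_min, 10)
  expect_error(decode_head(list(p3 = m), list(), strides, 0.25, 96),
               "anchors")
})

test_that("NMS suppresses duplicated boxes", {
  det <- data.frame(class = c("benign", "benign"),
                    confidence = c(0.9, 0.8),
                    x_min = c(10, 10), y_min = c(10, 10),
                    x_max = c(30, 30), y_max = c(30, 30))
  kept <- nms_boxes(det)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)
  # different classes are not suppressed against each other
  det$class[2] <- "malignant"
  expect_equal(nrow(nms_boxes(det)), 2)
})

test_that("anchors cluster box sizes and split by area across levels", {
  set.seed(14)
  boxes <- data.frame(x_min = 0, y_min = 0,
                      x_max = c(stats::runif(30, 8, 16), stats::runif(30, 30, 45)),
                      y_max = c(stats::runif(30, 8, 16), stats::runif(30, 30, 45)))
  a <- anchors_from_boxes(boxes, levels = c("p3", "p4"), k = 3, seed = 0)
  expect_equal(names(a), c("p3", "p4"))
  expect_equal(dim(a$p3), c(3L, 2L))
  expect_lt(max(a$p3[, 1] * a$p3[, 2]), min(a$p4[, 1] * a$p4[, 2]))
})

test_that("zero learning rate leaves weights unchanged; same seed reproduces", {
  ds <- tiny_dataset(n = 4, seed = 42)
  model <- build_msfnet(msf_config(), seed = 0)
  cfg0 <- train_config(batch = 4, subdivision = 1, learning_rate = 0)
  m0 <- train_tiny(ds, steps = 2, config = cfg0, model = model, seed = 0)
  expect_equal(m0$graph$nodes$stem_conv$w, model$graph$nodes$stem_conv$w)
  expect_equal(m0$graph$nodes$head_p3$w, model$graph$nodes$head_p3$w)

  cfg <- train_config(batch = 4, subdivision = 2)
  m1 <- train_tiny(ds, steps = 3, config = cfg, seed = 7)
  m2 <- train_tiny(ds, steps = 3, config = cfg, seed = 7)
  expect_identical(m1$graph$nodes$head_p3$w, m2$graph$nodes$head_p3$w)
  expect_identical(m1$history, m2$history)
  expect_error(train_tiny(list(), steps = 1), "no annotated images")
})

test_that("model containers round-trip and reproduce detections", {
  ds <- tiny_dataset(n = 4, seed = 42)
  model <- train_tiny(ds, steps = 2,
                      config = train_config(batch = 4, subdivision = 1),
                      seed = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_msf_model(model, path)
  back <- read_msf_model(path)
  d1 <- detect(model, ds[[1]]$image, conf_threshold = 0.01)
  d2 <- detect(back, ds[[1]]$image, conf_threshold = 0.01)
  expect_equal(d1, d2, tolerance = 1e-12)
})
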