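#' Configuration of the multi-scale saliency fusion network
#'
#' A four-stage residual backbone (strides 4/8/16/32 for C2..C5 after a
#' stride-2 stem), feature-pyramid top-down fusion to a common channel
#' count, a spatial saliency mask per head level, and a grid detection head
#' with 3 anchors per level. Defaults are desk-scale: 96 x 96 single-channel
#' input and narrow stages.
#'
#' @param input_size square input side (pixels); must be divisible by 32.
#' @param widths channel widths of stages 2..5.
#' @param stem_width channels of the stride-2 stem.
#' @param blocks residual blocks per stage.
#' @param fpn_channels common pyramid channel count `d`.
#' @param head_levels pyramid levels carrying detection heads (subset of
#'   `"p2".."p5"`).
#' @param classes class names (detection outputs).
#' @param anchors_per_level anchors per head level.
#' @param saliency apply the spatial sum-mask before each head.
#' @param channel_gate also apply the per-channel global-average gate
#'   (off by default; the spatial mask alone is the standard configuration).
#' @return An object of class `msf_config`.
#' @export
msf_config <- function(input_size = 96L, widths = c(8L, 16L, 32L, 64L),
                       stem_width = 8L, blocks = 1L, fpn_channels = 24L,
                       head_levels = c("p3", "p4"),
                       classes = c("benign", "malignant"),
                       anchors_per_level = 3L, saliency = TRUE,
                       channel_gate = FALSE) {
  stopifnot(input_size %% 32 == 0, length(widths) == 4L, blocks >= 1L,
            all(head_levels %in% c("p2", "p3", "p4", "p5")))
  structure(list(input_size = as.integer(input_size),
                 widths = as.integer(widths),
                 stem_width = as.integer(stem_width),
                 blocks = as.integer(blocks),
                 fpn_channels = as.integer(fpn_channels),
                 head_levels = head_levels, classes = classes,
                 anchors_per_level = as.integer(anchors_per_level),
                 saliency = isTRUE(saliency),
                 channel_gate = isTRUE(channel_gate)),
            class = "msf_config")
}

he_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

fresh_bn <- function(id, input, c) {
  nd <- node_batchnorm(id, input, gamma = rep(1, c), beta = rep(0, c),
                       mu = rep(0, c), sigma = rep(1, c))
  nd$var_run <- rep(1, c)
  nd
}

level_stride <- c(p2 = 4L, p3 = 8L, p4 = 16L, p5 = 32L)

#' Build an untrained multi-scale saliency fusion model
#'
#' Weights are He-initialised from `seed`; anchors default to lesion-scale
#' priors and are normally replaced by [anchors_from_boxes()] before
#' training.
#'
#' @param config an [msf_config()].
#' @param seed RNG seed for the weight initialisation.
#' @return An object of class `msf_model`: `graph` ([layer_graph()]),
#'   `config`, `anchors` (named list of `A x 2` matrices, pixel w/h per
#'   head level), `strides`.
#' @export
build_msfnet <- function(config = msf_config(), seed = 0L) {
  stopifnot(inherits(config, "msf_config"))
  with_local_seed(seed, {
    nodes <- list()
    push <- function(nd) nodes[[length(nodes) + 1L]] <<- nd
    push(node_input("in", c(config$input_size, config$input_size, 1L)))
    push(node_conv2d("stem_conv", "in", he_conv(3, 3, 1, config$stem_width),
                     stride = 2L, pad = 1L))
    push(fresh_bn("stem_bn", "stem_conv", config$stem_width))
    push(node_relu("stem_relu", "stem_bn"))
    prev <- "stem_relu"; prev_c <- config$stem_width
    stage_out <- character(4)
    for (k in 1:4) {
      wk <- config$widths[k]
      push(node_conv2d(sprintf("s%d_down", k), prev, he_conv(3, 3, prev_c, wk),
                       stride = 2L, pad = 1L))
      push(fresh_bn(sprintf("s%d_down_bn", k), sprintf("s%d_down", k), wk))
      push(node_relu(sprintf("s%d_in", k), sprintf("s%d_down_bn", k)))
      blk_in <- sprintf("s%d_in", k)
      for (b in seq_len(config$blocks)) {
        c1 <- sprintf("s%d_b%d_c1", k, b)
        push(node_conv2d(c1, blk_in, he_conv(3, 3, wk, wk), stride = 1L, pad = 1L))
        push(fresh_bn(paste0(c1, "_bn"), c1, wk))
        push(node_relu(paste0(c1, "_relu"), paste0(c1, "_bn")))
        c2 <- sprintf("s%d_b%d_c2", k, b)
        push(node_conv2d(c2, paste0(c1, "_relu"), he_conv(3, 3, wk, wk),
                         stride = 1L, pad = 1L))
        push(fresh_bn(paste0(c2, "_bn"), c2, wk))
        push(node_add(sprintf("s%d_b%d_add", k, b),
                      c(paste0(c2, "_bn"), blk_in)))
        push(node_relu(sprintf("s%d_b%d_out", k, b), sprintf("s%d_b%d_add", k, b)))
        blk_in <- sprintf("s%d_b%d_out", k, b)
      }
      stage_out[k] <- blk_in
      prev <- blk_in; prev_c <- wk
    }
    d <- config$fpn_channels
    # lateral 1x1 reductions C2..C5 -> d channels
    for (k in 1:4) {
      push(node_conv2d(sprintf("lat%d", k + 1), stage_out[k],
                       he_conv(1, 1, config$widths[k], d)))
    }
    # top-down fusion: p5 = lat5; pk = latk + up2(p(k+1))
    fuse <- c(p5 = "lat5")
    for (lv in c(4, 3, 2)) {
      up_id <- sprintf("up%d", lv)
      push(node_upsample(up_id, fuse[[paste0("p", lv + 1)]], factor = 2L))
      push(node_add(sprintf("p%d_fuse", lv), c(sprintf("lat%d", lv), up_id)))
      fuse[[paste0("p", lv)]] <- sprintf("p%d_fuse", lv)
    }
    # 3x3 smoothing + BN + ReLU gives the pyramid outputs P2..P5
    for (lv in 2:5) {
      cid <- sprintf("p%d_conv", lv)
      push(node_conv2d(cid, fuse[[paste0("p", lv)]], he_conv(3, 3, d, d),
                       stride = 1L, pad = 1L))
      push(fresh_bn(paste0(cid, "_bn"), cid, d))
      push(node_relu(sprintf("p%d", lv), paste0(cid, "_bn")))
    }
    nc <- length(config$classes)
    ch <- config$anchors_per_level * (5L + nc)
    outs <- character(0)
    for (lv_id in config$head_levels) {
      src <- lv_id
      if (config$saliency) {
        sal <- paste0("sal_", lv_id)
        push(node_saliency(sal, lv_id, channel_gate = config$channel_gate))
        src <- sal
      }
      hid <- paste0("head_", lv_id)
      push(node_conv2d(hid, src, he_conv(1, 1, d, ch)))
      outs <- c(outs, hid)
    }
    graph <- layer_graph(nodes, outputs = outs)
    base <- config$input_size / 12
    anchors <- lapply(config$head_levels, function(lv) {
      scl <- level_stride[[lv]] / 8
      cbind(w = base * scl * c(1.6, 2.4, 3.2),
            h = base * scl * c(1.6, 2.4, 3.2))
    })
    names(anchors) <- config$head_levels
    structure(list(graph = graph, config = config, anchors = anchors,
                   strides = level_stride[config$head_levels]),
              class = "msf_model")
  })
}

#' @export
print.msf_model <- function(x, ...) {
  cat(sprintf("msf_model: %dx%d input, stages %s, FPN d=%d, heads %s\n",
              x$config$input_size, x$config$input_size,
              paste(x$config$widths, collapse = "/"),
              x$config$fpn_channels,
              paste(x$config$head_levels, collapse = ",")))
  invisible(x)
}

#' Backbone feature maps C2..C5
#'
#' Runs the residual backbone and returns the four per-stage feature maps
#' at strides 4, 8, 16 and 32.
#'
#' @param model an [build_msfnet()] model.
#' @param image input image matching the configured size.
#' @return Named list `C2`, `C3`, `C4`, `C5` of `(h, w, c, n)` arrays.
#' @export
backbone_forward <- function(model, image) {
  stopifnot(inherits(model, "msf_model"))
  vals <- graph_forward(model$graph, image, all_nodes = TRUE)
  b <- model$config$blocks
  ids <- vapply(1:4, function(k) sprintf("s%d_b%d_out", k, b), character(1))
  out <- vals[ids]
  names(out) <- paste0("C", 2:5)
  out
}

#' Feature pyramid top-down fusion
#'
#' Given backbone maps at strides 4/8/16/32 and lateral 1x1 weights mapping
#' each to a common channel count, computes
#' `P5 = lat5(C5)` and `Pk = latk(Ck) + upsample2(P(k+1))` for k = 4, 3, 2.
#'
#' @param c_maps named list `C2`..`C5` of feature arrays.
#' @param lateral named list `lat2`..`lat5`, each `list(w, b)` with a
#'   `(1, 1, in_c, d)` weight array.
#' @return Named list `P2`..`P5`, all with `d` channels.
#' @export
fpn_fuse <- function(c_maps, lateral) {
  stopifnot(all(paste0("C", 2:5) %in% names(c_maps)),
            all(paste0("lat", 2:5) %in% names(lateral)))
  lat_out <- lapply(2:5, function(k) {
    l <- lateral[[paste0("lat", k)]]
    cm <- as_t4(c_maps[[paste0("C", k)]])
    if (dim(cm)[3] != dim(l$w)[3]) {
      stop(sprintf("lateral lat%d expects %d channels, C%d has %d",
                   k, dim(l$w)[3], k, dim(cm)[3]), call. = FALSE)
    }
    b <- if (is.null(l$b)) numeric(dim(l$w)[4]) else l$b
    conv2d_forward(cm, l$w, b)
  })
  names(lat_out) <- paste0("P", 2:5)
  p <- list(P5 = lat_out$P5)
  for (k in c(4, 3, 2)) {
    p[[paste0("P", k)]] <- lat_out[[paste0("P", k)]] +
      upsample_nearest(p[[paste0("P", k + 1)]], 2L)
  }
  p[paste0("P", 2:5)]
}

#' Spatial saliency mask of a feature map
#'
#' Sums the feature map over channels, min-max normalises the result to
#' `[0, 1]` (a uniform map yields an all-ones mask, i.e. pass-through), and
#' multiplies the mask back onto every channel.
#'
#' @param feature `(h, w)` matrix or `(h, w, c)` array.
#' @param channel_gate also scale channels by their global-average gate.
#' @return List `mask` (`h x w` matrix in `[0,1]`) and `masked` (same shape
#'   as `feature`).
#' @export
saliency_apply <- function(feature, channel_gate = FALSE) {
  x <- as_t4(feature)
  y <- apply_saliency_t4(x, channel_gate)
  m <- attr(y, "mask")[, , 1, 1]
  masked <- array(y, dim(y)[1:3])
  if (length(dim(feature)) == 2L) masked <- masked[, , 1]
  list(mask = m, masked = masked)
}

sigmoid_stable <- function(x) 1 / (1 + exp(-x))

decode_level <- function(logits, anchors, stride, conf_threshold,
                         image_size, classes) {
  d <- dim(logits)
  s_h <- d[1]; s_w <- d[2]
  a_n <- nrow(anchors)
  nc <- length(classes)
  per <- 5L + nc
  stopifnot(d[3] == a_n * per)
  rows <- list()
  for (a in seq_len(a_n)) {
    off <- (a - 1L) * per
    tx <- logits[, , off + 1L]; ty <- logits[, , off + 2L]
    tw <- logits[, , off + 3L]; th <- logits[, , off + 4L]
    obj <- sigmoid_stable(logits[, , off + 5L])
    cls <- array(sigmoid_stable(logits[, , off + 5L + seq_len(nc)]),
                 c(s_h, s_w, nc))
    best_c <- apply(cls, c(1, 2), which.max)
    best_p <- apply(cls, c(1, 2), max)
    conf <- obj * best_p
    hit <- which(conf >= conf_threshold, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1]; j <- hit[r, 2]
      bx <- (j - 1 + sigmoid_stable(tx[i, j])) * stride
      by <- (i - 1 + sigmoid_stable(ty[i, j])) * stride
      bw <- anchors[a, 1] * exp(min(tw[i, j], 8))
      bh <- anchors[a, 2] * exp(min(th[i, j], 8))
      x1 <- max(0, bx - bw / 2); y1 <- max(0, by - bh / 2)
      x2 <- min(image_size, bx + bw / 2); y2 <- min(image_size, by + bh / 2)
      if (x2 <= x1 || y2 <= y1) next
      rows[[length(rows) + 1L]] <- data.frame(
        class = classes[best_c[i, j]], confidence = conf[i, j],
        x_min = x1, y_min = y1, x_max = x2, y_max = y2)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(class = character(0), confidence = numeric(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Greedy non-maximum suppression
#'
#' @param det detections data.frame (`class`, `confidence`, box columns).
#' @param iou_threshold suppression threshold.
#' @return The surviving subset, sorted by descending confidence.
#' @export
nms_boxes <- function(det, iou_threshold = 0.5) {
  if (nrow(det) == 0) return(det)
  keep <- list()
  for (cl in unique(det$class)) {
    d <- det[det$class == cl, , drop = FALSE]
    d <- d[order(d$confidence, decreasing = TRUE), , drop = FALSE]
    taken <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      if (taken[i]) next
      keep[[length(keep) + 1L]] <- d[i, ]
      if (i < nrow(d)) {
        bi <- as.numeric(d[i, c("x_min", "y_min", "x_max", "y_max")])
        for (j in (i + 1):nrow(d)) {
          if (taken[j]) next
          bj <- as.numeric(d[j, c("x_min", "y_min", "x_max", "y_max")])
          if (box_iou(bi, bj) >= iou_threshold) taken[j] <- TRUE
        }
      }
    }
  }
  out <- do.call(rbind, keep)
  out[order(out$confidence, decreasing = TRUE), , drop = FALSE]
}

#' Decode grid-head logits into detections
#'
#' YOLO-style decoding: per cell and anchor, sigmoid center offsets,
#' exponential size terms on the anchor priors, sigmoid objectness and
#' class scores (confidence = objectness x best class score), confidence
#' filtering and greedy per-class NMS at IoU 0.5.
#'
#' @param head_maps named list of logit arrays `(s, s, anchors*(5+nc))`,
#'   one per head level.
#' @param anchors named list of `A x 2` pixel anchor matrices, same names.
#' @param strides named integer vector of level strides.
#' @param conf_threshold confidence cut.
#' @param image_size square image side (pixels).
#' @param classes class names.
#' @param nms_iou NMS threshold.
#' @return Detections data.frame (`class`, `confidence`, `x_min`, `y_min`,
#'   `x_max`, `y_max`).
#' @export
decode_head <- function(head_maps, anchors, strides, conf_threshold = 0.25,
                        image_size, classes = c("benign", "malignant"),
                        nms_iou = 0.5) {
  if (length(anchors) == 0 || any(vapply(anchors, nrow, 1L) == 0)) {
    stop("anchors must be non-empty", call. = FALSE)
  }
  det <- list()
  for (lv in names(head_maps)) {
    m <- head_maps[[lv]]
    if (length(dim(m)) == 4L) m <- array(m, dim(m)[1:3])
    det[[lv]] <- decode_level(m, anchors[[lv]], strides[[lv]],
                              conf_threshold, image_size, classes)
  }
  det <- do.call(rbind, det)
  rownames(det) <- NULL
  if (nrow(det) == 0) return(det)
  nms_boxes(det, nms_iou)
}

#' Run the detector on one image
#'
#' @param model a trained [build_msfnet()] model.
#' @param image `(h, w)` grayscale matrix in `[0, 1]`.
#' @param conf_threshold confidence cut.
#' @return Detections data.frame as in [decode_head()].
#' @export
detect <- function(model, image, conf_threshold = 0.25) {
  stopifnot(inherits(model, "msf_model"))
  heads <- graph_forward(model$graph, image)
  names(heads) <- sub("^head_", "", names(heads))
  decode_head(heads, model$anchors, model$strides, conf_threshold,
              model$config$input_size, model$config$classes)
}

#' Anchor priors by k-means over box sizes
#'
#' Clusters the training boxes' widths/heights (k per head level, pooled
#' k-means, clusters sorted by area and split across levels smallest to
#' largest).
#'
#' @param boxes data.frame with `x_min`, `y_min`, `x_max`, `y_max`.
#' @param levels head level names (low to high stride).
#' @param k anchors per level.
#' @param seed RNG seed for k-means.
#' @return Named list of `k x 2` anchor matrices.
#' @export
anchors_from_boxes <- function(boxes, levels = c("p3", "p4"), k = 3L,
                               seed = 0L) {
  wh <- cbind(w = boxes$x_max - boxes$x_min, h = boxes$y_max - boxes$y_min)
  ktot <- k * length(levels)
  with_local_seed(seed, {
    cent <- if (nrow(wh) <= ktot) {
      wh[rep(seq_len(nrow(wh)), length.out = ktot), , drop = FALSE]
    } else {
      stats::kmeans(wh, centers = ktot, nstart = 5, iter.max = 50)$centers
    }
    cent <- cent[order(cent[, 1] * cent[, 2]), , drop = FALSE]
    out <- lapply(seq_along(levels), function(i) {
      m <- cent[(i - 1) * k + seq_len(k), , drop = FALSE]
      colnames(m) <- c("w", "h")
      m
    })
    names(out) <- levels
    out
  })
}

#' Save or load a detection model (JSON container)
#'
#' Stores the layer graph, anchors, strides and configuration in a single
#' plain-text JSON file.
#'
#' @param model an `msf_model`.
#' @param path file path (`.json`).
#' @return `read_msf_model()` returns the `msf_model`.
#' @export
write_msf_model <- function(model, path) {
  stopifnot(inherits(model, "msf_model"))
  anch <- lapply(model$anchors, function(a) {
    list(w = as.numeric(a[, 1]), h = as.numeric(a[, 2]))
  })
  jsonlite::write_json(
    c(list(format = "spikelesion-model", version = 1L),
      serialize_graph(model$graph),
      list(anchors = anch, strides = as.list(model$strides),
           config = unclass(model$config))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_msf_model
#' @export
read_msf_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "spikelesion-model")) {
    stop("not a spikelesion model container: ", path, call. = FALSE)
  }
  graph <- layer_graph(deserialize_nodes(doc$nodes),
                       outputs = as.character(unlist(doc$outputs)))
  anchors <- lapply(doc$anchors, function(a) {
    cbind(w = as.numeric(unlist(a$w)), h = as.numeric(unlist(a$h)))
  })
  cfgl <- doc$config
  config <- msf_config(
    input_size = as.integer(cfgl$input_size),
    widths = as.integer(unlist(cfgl$widths)),
    stem_width = as.integer(cfgl$stem_width),
    blocks = as.integer(cfgl$blocks),
    fpn_channels = as.integer(cfgl$fpn_channels),
    head_levels = as.character(unlist(cfgl$head_levels)),
    classes = as.character(unlist(cfgl$classes)),
    anchors_per_level = as.integer(cfgl$anchors_per_level),
    saliency = isTRUE(cfgl$saliency),
    channel_gate = isTRUE(cfgl$channel_gate))
  strides <- vapply(doc$strides, as.integer, integer(1))
  structure(list(graph = graph, config = config, anchors = anchors,
                 strides = strides),
            class = "msf_model")
}
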