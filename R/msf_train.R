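# Desk-scale training of the detection network: training-mode graph
# forward/backward (batch-statistics batch norm, cached im2col columns),
# a single-stage detection loss (sigmoid box offsets, objectness with an
# IoU ignore band, per-class logistic terms), and SGD with momentum and
# weight decay.

#' Training hyperparameters
#'
#' Defaults are the experiment settings used throughout the package:
#' batch 64 split into 8 subdivisions (so each gradient accumulation chunk
#' holds 8 images), momentum 0.9, weight decay 0.0005, learning rate 0.001
#' and an objectness ignore threshold of 0.5 (predicted boxes overlapping a
#' ground truth above this IoU receive no no-object penalty).
#'
#' @param batch images per optimizer step.
#' @param subdivision gradient-accumulation chunks per step.
#' @param momentum SGD momentum.
#' @param decay L2 weight decay on convolution weights.
#' @param learning_rate SGD learning rate.
#' @param ignore_threshold objectness ignore IoU.
#' @param lambda_box weight of the box-regression terms.
#' @param lambda_obj weight of the positive-objectness term (cells holding a
#'   target are rare, roughly one per hundred grid cells, so their term is
#'   upweighted against the no-object background).
#' @param lambda_noobj weight of the no-object background term.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch = 64L, subdivision = 8L, momentum = 0.9,
                         decay = 0.0005, learning_rate = 0.001,
                         ignore_threshold = 0.5, lambda_box = 5,
                         lambda_obj = 20, lambda_noobj = 0.5) {
  stopifnot(batch >= 1L, subdivision >= 1L, batch %% subdivision == 0,
            momentum >= 0, decay >= 0, learning_rate >= 0,
            ignore_threshold > 0, lambda_box > 0, lambda_obj > 0,
            lambda_noobj > 0)
  structure(list(batch = as.integer(batch),
                 subdivision = as.integer(subdivision),
                 momentum = momentum, decay = decay,
                 learning_rate = learning_rate,
                 ignore_threshold = ignore_threshold,
                 lambda_box = lambda_box, lambda_obj = lambda_obj,
                 lambda_noobj = lambda_noobj),
            class = "train_config")
}

forward_train <- function(graph, x) {
  vals <- list(); caches <- list()
  for (nd in graph$nodes) {
    id <- nd$id
    if (nd$kind == "input") {
      vals[[id]] <- as_t4(x)
    } else if (nd$kind == "conv2d") {
      y <- conv2d_forward(vals[[nd$inputs[1]]], nd$w, nd$b, nd$stride,
                          nd$pad, keep_cols = TRUE)
      caches[[id]] <- list(cols = attr(y, "cols"), ix = attr(y, "ix"))
      attr(y, "cols") <- NULL
      vals[[id]] <- y
    } else if (nd$kind == "batchnorm") {
      r <- bn_forward(vals[[nd$inputs[1]]], nd$gamma, nd$beta,
                      mu = NULL, sigma2 = NULL, training = TRUE)
      caches[[id]] <- r[c("xhat", "inv", "mu", "sigma2")]
      vals[[id]] <- r$y
    } else if (nd$kind == "relu") {
      vals[[id]] <- pmax(vals[[nd$inputs[1]]], 0)
    } else if (nd$kind == "add") {
      vals[[id]] <- Reduce(`+`, vals[nd$inputs])
    } else if (nd$kind == "upsample") {
      vals[[id]] <- upsample_nearest(vals[[nd$inputs[1]]], nd$factor)
    } else if (nd$kind == "saliency") {
      xin <- vals[[nd$inputs[1]]]
      m <- saliency_mask_t4(xin)
      y <- apply_saliency_t4(xin, channel_gate = FALSE)
      caches[[id]] <- list(mask = m, x = xin)
      attr(y, "mask") <- NULL
      vals[[id]] <- y
    } else {
      stop("unsupported node kind in training: ", nd$kind, call. = FALSE)
    }
  }
  list(vals = vals, caches = caches)
}

backward_train <- function(graph, fw, dout) {
  vals <- fw$vals; caches <- fw$caches
  d <- list()
  for (id in names(dout)) d[[id]] <- dout[[id]]
  grads <- list()
  for (nd in rev(graph$nodes)) {
    id <- nd$id
    dy <- d[[id]]
    if (is.null(dy)) next
    if (nd$kind == "conv2d") {
      ca <- caches[[id]]
      g <- conv2d_backward(dy, vals[[nd$inputs[1]]], nd$w, ca$ix, ca$cols)
      grads[[id]] <- list(w = g$dw, b = g$db)
      tgt <- nd$inputs[1]
      d[[tgt]] <- if (is.null(d[[tgt]])) g$dx else d[[tgt]] + g$dx
    } else if (nd$kind == "batchnorm") {
      g <- bn_backward(dy, caches[[id]], nd$gamma)
      grads[[id]] <- list(gamma = g$dgamma, beta = g$dbeta)
      tgt <- nd$inputs[1]
      d[[tgt]] <- if (is.null(d[[tgt]])) g$dx else d[[tgt]] + g$dx
    } else if (nd$kind == "relu") {
      dx <- dy * (vals[[id]] > 0)
      tgt <- nd$inputs[1]
      d[[tgt]] <- if (is.null(d[[tgt]])) dx else d[[tgt]] + dx
    } else if (nd$kind == "add") {
      for (tgt in nd$inputs) {
        d[[tgt]] <- if (is.null(d[[tgt]])) dy else d[[tgt]] + dy
      }
    } else if (nd$kind == "upsample") {
      dx <- upsample_nearest_backward(dy, nd$factor)
      tgt <- nd$inputs[1]
      d[[tgt]] <- if (is.null(d[[tgt]])) dx else d[[tgt]] + dx
    } else if (nd$kind == "saliency") {
      ca <- caches[[id]]
      xin <- ca$x
      dd <- dim(xin)
      dx <- array(0, dd)
      for (b in seq_len(dd[4])) {
        mb <- ca$mask[, , 1, b]
        xd_sum <- matrix(0, dd[1], dd[2])
        for (ch in seq_len(dd[3])) {
          dx[, , ch, b] <- dy[, , ch, b] * mb
          xd_sum <- xd_sum + xin[, , ch, b] * dy[, , ch, b]
        }
        # mask gradient through the channel sum (range treated constant)
        s <- apply(xin[, , , b, drop = FALSE], c(1, 2), sum)
        rng <- max(s) - min(s)
        if (rng > 0) {
          for (ch in seq_len(dd[3])) {
            dx[, , ch, b] <- dx[, , ch, b] + xd_sum / rng
          }
        }
      }
      tgt <- nd$inputs[1]
      d[[tgt]] <- if (is.null(d[[tgt]])) dx else d[[tgt]] + dx
    }
    # input node: nothing to propagate to
  }
  grads
}

# shape-only IoU of anchor priors vs a box (both centred)
shape_iou <- function(aw, ah, bw, bh) {
  inter <- pmin(aw, bw) * pmin(ah, bh)
  inter / (aw * ah + bw * bh - inter)
}

# Detection loss and head-logit gradients for one minibatch.
detection_loss <- function(heads, boxes_list, model, cfg) {
  levels <- model$config$head_levels
  classes <- model$config$classes
  nc <- length(classes)
  per <- 5L + nc
  n <- dim(heads[[1]])[4]
  img <- model$config$input_size
  grads <- lapply(heads, function(h) array(0, dim(h)))
  loss <- 0
  # flatten anchors for global best-anchor assignment
  all_anch <- do.call(rbind, lapply(levels, function(lv) {
    cbind(model$anchors[[lv]], lv = match(lv, levels),
          a = seq_len(nrow(model$anchors[[lv]])))
  }))
  for (b in seq_len(n)) {
    boxes <- boxes_list[[b]]
    pos <- list()
    if (nrow(boxes) > 0) {
      for (gi in seq_len(nrow(boxes))) {
        bw <- boxes$x_max[gi] - boxes$x_min[gi]
        bh <- boxes$y_max[gi] - boxes$y_min[gi]
        sc <- shape_iou(all_anch[, 1], all_anch[, 2], bw, bh)
        best <- which.max(sc)
        lv <- levels[all_anch[best, "lv"]]
        a <- all_anch[best, "a"]
        stride <- model$strides[[lv]]
        cx <- (boxes$x_min[gi] + boxes$x_max[gi]) / 2
        cy <- (boxes$y_min[gi] + boxes$y_max[gi]) / 2
        s_grid <- dim(heads[[paste0("head_", lv)]])[1]
        col <- min(s_grid, max(1L, floor(cx / stride) + 1L))
        row <- min(s_grid, max(1L, floor(cy / stride) + 1L))
        pos[[length(pos) + 1L]] <- list(
          lv = lv, a = a, row = row, col = col,
          tx = cx / stride - (col - 1L), ty = cy / stride - (row - 1L),
          tw = log(bw / model$anchors[[lv]][a, 1]),
          th = log(bh / model$anchors[[lv]][a, 2]),
          cls = match(boxes$class[gi], classes))
      }
    }
    for (lv in levels) {
      hid <- paste0("head_", lv)
      h <- heads[[hid]][, , , b, drop = FALSE]
      s_grid <- dim(h)[1]
      stride <- model$strides[[lv]]
      anch <- model$anchors[[lv]]
      g <- array(0, dim(h)[1:3])
      for (a in seq_len(nrow(anch))) {
        off <- (a - 1L) * per
        obj_logit <- h[, , off + 5L, 1]
        p_obj <- sigmoid_stable(obj_logit)
        # no-object everywhere, minus the IoU ignore band
        ignore <- matrix(FALSE, s_grid, s_grid)
        if (nrow(boxes) > 0) {
          sx <- sigmoid_stable(h[, , off + 1L, 1])
          sy <- sigmoid_stable(h[, , off + 2L, 1])
          pw <- anch[a, 1] * exp(pmin(h[, , off + 3L, 1], 8))
          ph <- anch[a, 2] * exp(pmin(h[, , off + 4L, 1], 8))
          bx <- (matrix(rep(seq_len(s_grid), each = s_grid), s_grid) - 1 + sx) * stride
          by <- (matrix(seq_len(s_grid), s_grid, s_grid) - 1 + sy) * stride
          px1 <- bx - pw / 2; px2 <- bx + pw / 2
          py1 <- by - ph / 2; py2 <- by + ph / 2
          best_iou <- matrix(0, s_grid, s_grid)
          for (gi in seq_len(nrow(boxes))) {
            iw <- pmin(px2, boxes$x_max[gi]) - pmax(px1, boxes$x_min[gi])
            ih <- pmin(py2, boxes$y_max[gi]) - pmax(py1, boxes$y_min[gi])
            inter <- pmax(iw, 0) * pmax(ih, 0)
            uni <- (px2 - px1) * (py2 - py1) +
              (boxes$x_max[gi] - boxes$x_min[gi]) *
              (boxes$y_max[gi] - boxes$y_min[gi]) - inter
            best_iou <- pmax(best_iou, inter / uni)
          }
          ignore <- best_iou > cfg$ignore_threshold
        }
        dobj <- cfg$lambda_noobj * p_obj
        dobj[ignore] <- 0
        loss <- loss +
          cfg$lambda_noobj * sum(-log(pmax(1 - p_obj[!ignore], 1e-12)))
        g[, , off + 5L] <- g[, , off + 5L] + dobj
      }
      grads[[hid]][, , , b] <- g
    }
    # positive cells overwrite the no-object gradient
    for (p in pos) {
      hid <- paste0("head_", p$lv)
      off <- (p$a - 1L) * per
      h <- heads[[hid]]
      lx <- h[p$row, p$col, off + 1L, b]; ly <- h[p$row, p$col, off + 2L, b]
      lw <- h[p$row, p$col, off + 3L, b]; lh <- h[p$row, p$col, off + 4L, b]
      lo <- h[p$row, p$col, off + 5L, b]
      sx <- sigmoid_stable(lx); sy <- sigmoid_stable(ly)
      po <- sigmoid_stable(lo)
      grads[[hid]][p$row, p$col, off + 1L, b] <-
        cfg$lambda_box * 2 * (sx - p$tx) * sx * (1 - sx)
      grads[[hid]][p$row, p$col, off + 2L, b] <-
        cfg$lambda_box * 2 * (sy - p$ty) * sy * (1 - sy)
      grads[[hid]][p$row, p$col, off + 3L, b] <-
        cfg$lambda_box * 2 * (lw - p$tw)
      grads[[hid]][p$row, p$col, off + 4L, b] <-
        cfg$lambda_box * 2 * (lh - p$th)
      grads[[hid]][p$row, p$col, off + 5L, b] <- cfg$lambda_obj * (po - 1)
      loss <- loss + cfg$lambda_box * ((sx - p$tx)^2 + (sy - p$ty)^2 +
                                         (lw - p$tw)^2 + (lh - p$th)^2) -
        cfg$lambda_obj * log(pmax(po, 1e-12))
      for (ci in seq_len(nc)) {
        lc <- h[p$row, p$col, off + 5L + ci, b]
        pc <- sigmoid_stable(lc)
        yc <- as.numeric(ci == p$cls)
        grads[[hid]][p$row, p$col, off + 5L + ci, b] <- pc - yc
        loss <- loss - (yc * log(pmax(pc, 1e-12)) +
                          (1 - yc) * log(pmax(1 - pc, 1e-12)))
      }
    }
  }
  for (hid in names(grads)) grads[[hid]] <- grads[[hid]] / n
  list(loss = loss / n, grads = grads)
}

trainable_params <- function(graph) {
  out <- list()
  for (nd in graph$nodes) {
    if (nd$kind %in% c("conv2d", "linear")) {
      out[[nd$id]] <- c("w", "b")
    } else if (nd$kind == "batchnorm") {
      out[[nd$id]] <- c("gamma", "beta")
    }
  }
  out
}

#' Train the detection network on a small synthetic dataset
#'
#' SGD with momentum and weight decay on the full graph (backbone, FPN,
#' saliency, heads). Each step draws `batch` images (with replacement when
#' the dataset is smaller), processes them in `subdivision` accumulation
#' chunks, and applies one update. Batch-norm running statistics are
#' updated with an exponential moving average (rate 0.1). Deterministic
#' given `seed`.
#'
#' @param dataset list of `annotated_image` objects; images without boxes
#'   are excluded.
#' @param steps number of optimizer steps.
#' @param config a [train_config()].
#' @param model optional pre-built [build_msfnet()] model; by default one
#'   is built to match the dataset's image size, with anchors fit to the
#'   dataset's boxes.
#' @param seed RNG seed controlling initialisation and batch sampling.
#' @return The trained `msf_model`, with a `history` element (per-step
#'   loss).
#' @export
train_tiny <- function(dataset, steps = 200L, config = train_config(),
                       model = NULL, seed = 0L) {
  stopifnot(inherits(config, "train_config"), steps >= 0L)
  dataset <- Filter(function(ai) nrow(ai$boxes) > 0, dataset)
  if (length(dataset) == 0) stop("dataset has no annotated images", call. = FALSE)
  size <- nrow(dataset[[1]]$image)
  if (is.null(model)) {
    model <- build_msfnet(msf_config(input_size = size), seed = seed)
    all_boxes <- do.call(rbind, lapply(dataset, `[[`, "boxes"))
    model$anchors <- anchors_from_boxes(all_boxes,
                                        levels = model$config$head_levels,
                                        seed = seed)
  }
  graph <- model$graph
  ptab <- trainable_params(graph)
  vel <- lapply(names(ptab), function(id) {
    lapply(ptab[[id]], function(f) array(0, dim(graph$nodes[[id]][[f]]) %||%
                                           length(graph$nodes[[id]][[f]])))
  })
  names(vel) <- names(ptab)
  for (id in names(ptab)) names(vel[[id]]) <- ptab[[id]]
  chunk <- config$batch %/% config$subdivision
  history <- numeric(steps)
  with_local_seed(seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(length(dataset), config$batch,
                        replace = length(dataset) < config$batch)
      acc <- NULL; step_loss <- 0
      for (sub in seq_len(config$subdivision)) {
        take <- idx[(sub - 1L) * chunk + seq_len(chunk)]
        x <- array(0, c(size, size, 1L, chunk))
        for (q in seq_along(take)) x[, , 1L, q] <- dataset[[take[q]]]$image
        fw <- forward_train(graph, x)
        heads <- fw$vals[graph$outputs]
        dl <- detection_loss(heads, lapply(dataset[take], `[[`, "boxes"),
                             model, config)
        step_loss <- step_loss + dl$loss / config$subdivision
        g <- backward_train(graph, fw, dl$grads)
        # EMA update of batch-norm running statistics
        for (nd in graph$nodes) {
          if (nd$kind == "batchnorm") {
            ca <- fw$caches[[nd$id]]
            graph$nodes[[nd$id]]$mu <- 0.9 * nd$mu + 0.1 * ca$mu
            vr <- graph$nodes[[nd$id]]$var_run
            if (is.null(vr)) vr <- nd$sigma^2
            vr <- 0.9 * vr + 0.1 * ca$sigma2
            graph$nodes[[nd$id]]$var_run <- vr
            graph$nodes[[nd$id]]$sigma <- sqrt(vr + 1e-5)
          }
        }
        if (is.null(acc)) {
          acc <- g
        } else {
          for (id in names(g)) {
            for (f in names(g[[id]])) {
              acc[[id]][[f]] <- acc[[id]][[f]] + g[[id]][[f]]
            }
          }
        }
      }
      for (id in names(acc)) {
        nd <- graph$nodes[[id]]
        for (f in names(acc[[id]])) {
          gr <- acc[[id]][[f]] / config$subdivision
          if (f == "w") gr <- gr + config$decay * nd[[f]]
          vel[[id]][[f]] <- config$momentum * vel[[id]][[f]] -
            config$learning_rate * gr
          nd[[f]] <- nd[[f]] + vel[[id]][[f]]
        }
        graph$nodes[[id]] <- nd
      }
      history[step] <- step_loss
    }
  })
  model$graph <- graph
  model$history <- history
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-phase training recipe for the tiny detector
#'
#' Runs [train_tiny()] in two phases: the configured learning rate for
#' `steps[1]` steps, then a polish phase at one tenth of it for `steps[2]`
#' steps. The polish phase sharpens the confidence margins, which matters
#' for stable spiking conversion (near-tied objectness scores flip under
#' rate quantisation). Deterministic given `seed`.
#'
#' @param dataset list of `annotated_image` objects.
#' @param steps integer vector `c(main, polish)`.
#' @param config a [train_config()].
#' @param seed RNG seed.
#' @return The trained `msf_model` (with the concatenated loss `history`).
#' @export
train_detector <- function(dataset, steps = c(500L, 200L),
                           config = train_config(batch = 16L,
                                                 subdivision = 2L,
                                                 lambda_obj = 10,
                                                 lambda_noobj = 1),
                           seed = 0L) {
  stopifnot(length(steps) == 2L)
  model <- train_tiny(dataset, steps = steps[1], config = config,
                      seed = seed)
  h1 <- model$history
  cfg2 <- config
  cfg2$learning_rate <- config$learning_rate / 10
  model <- train_tiny(dataset, steps = steps[2], config = cfg2,
                      model = model, seed = seed + 1L)
  model$history <- c(h1, model$history)
  model
}
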