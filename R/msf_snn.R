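# Spiking execution of the detection network: conversion wrapper, spiking
# inference, and the ANN-vs-SNN agreement audit used to validate a
# conversion end to end.

#' Convert a trained detection model to a spiking network
#'
#' Folds batch normalization, calibrates activation scales on the supplied
#' images and rate-codes every ReLU ([convert_to_snn()]); the saliency
#' masks and detection heads run in full precision on the decoded rates.
#'
#' @param model a trained [build_msfnet()] model.
#' @param calibration list of grayscale image matrices (or a
#'   `(h, w, 1, n)` array) used to measure activation ranges.
#' @param cfg a [rate_code_config()]; `timesteps` is the default simulation
#'   length. Detection conversion calibrates with the exact activation
#'   maximum (`norm_percentile = 1`): the strongest activations sit on the
#'   lesions themselves, and clipping them would selectively distort the
#'   objectness evidence the head relies on.
#' @return An object of class `msf_snn`.
#' @export
convert_msf <- function(model, calibration,
                        cfg = rate_code_config(timesteps = 512L,
                                               norm_percentile = 1)) {
  stopifnot(inherits(model, "msf_model"))
  if (is.list(calibration)) {
    size <- model$config$input_size
    x <- array(0, c(size, size, 1L, length(calibration)))
    for (i in seq_along(calibration)) x[, , 1L, i] <- calibration[[i]]
    calibration <- x
  }
  snn <- convert_to_snn(model$graph, cfg, calibration)
  structure(list(snn = snn, anchors = model$anchors,
                 strides = model$strides, config = model$config),
            class = "msf_snn")
}

#' @export
print.msf_snn <- function(x, ...) {
  cat(sprintf("msf_snn: rate-coded detector, default T = %d\n",
              x$snn$cfg$timesteps))
  invisible(x)
}

#' Run the spiking detector on one image
#'
#' @param msnn an [convert_msf()] result.
#' @param image `(h, w)` grayscale matrix in `[0, 1]`.
#' @param conf_threshold confidence cut.
#' @param timesteps simulation length `T` (default from the conversion
#'   config).
#' @return List `detections` (data.frame as in [decode_head()]) and `sim`
#'   (the [simulate_rates()] record, usable for energy accounting).
#' @export
detect_spiking <- function(msnn, image, conf_threshold = 0.25,
                           timesteps = NULL) {
  stopifnot(inherits(msnn, "msf_snn"))
  sim <- simulate_rates(msnn$snn, image, timesteps)
  heads <- sim$outputs
  names(heads) <- sub("^head_", "", names(heads))
  det <- decode_head(heads, msnn$anchors, msnn$strides, conf_threshold,
                     msnn$config$input_size, msnn$config$classes)
  list(detections = det, sim = sim)
}

#' Detections over a whole dataset
#'
#' @param model a trained [build_msfnet()] model.
#' @param dataset list of `annotated_image` objects.
#' @param conf_threshold confidence cut.
#' @return data.frame with an `image` column (image names) plus the
#'   [decode_head()] columns.
#' @export
detect_dataset <- function(model, dataset, conf_threshold = 0.25) {
  rows <- lapply(dataset, function(ai) {
    det <- detect(model, ai$image, conf_threshold)
    if (nrow(det) == 0) return(NULL)
    cbind(image = ai$name, det)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image = character(0), class = character(0),
                      confidence = numeric(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Ground-truth table of a dataset
#'
#' @param dataset list of `annotated_image` objects.
#' @return data.frame `image`, `class`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
dataset_ground_truth <- function(dataset) {
  rows <- lapply(dataset, function(ai) {
    if (nrow(ai$boxes) == 0) return(NULL)
    cbind(image = ai$name, ai$boxes)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement between conventional and spiking detections
#'
#' For each image, the conventional (ANN) and spiking (SNN) detectors are
#' run and their outputs compared: an image agrees when both produce the
#' same number of detections and a greedy confidence-ordered matching
#' pairs every ANN detection with an SNN detection of identical class and
#' box IoU at least `iou_min`. Images where both detectors produce nothing
#' agree trivially.
#'
#' @param model trained [build_msfnet()] model.
#' @param msnn its [convert_msf()] conversion.
#' @param dataset list of `annotated_image` objects.
#' @param conf_threshold confidence cut for both detectors.
#' @param timesteps simulation length `T`.
#' @param iou_min box IoU required for a pair to count as matching.
#' @return List: `fraction_agree`, `mean_iou` (over matched pairs),
#'   `per_image` data.frame (`image`, `n_ann`, `n_snn`, `agree`).
#' @export
detection_agreement <- function(model, msnn, dataset, conf_threshold = 0.25,
                                timesteps = NULL, iou_min = 0.7) {
  rows <- list(); ious <- numeric(0)
  for (ai in dataset) {
    ann <- detect(model, ai$image, conf_threshold)
    snn <- detect_spiking(msnn, ai$image, conf_threshold, timesteps)$detections
    agree <- nrow(ann) == nrow(snn)
    if (agree && nrow(ann) > 0) {
      used <- logical(nrow(snn))
      for (i in order(ann$confidence, decreasing = TRUE)) {
        bi <- as.numeric(ann[i, c("x_min", "y_min", "x_max", "y_max")])
        best <- 0; bj <- 0L
        for (j in seq_len(nrow(snn))) {
          if (used[j] || snn$class[j] != ann$class[i]) next
          ov <- box_iou(bi, as.numeric(snn[j, c("x_min", "y_min",
                                                "x_max", "y_max")]))
          if (ov > best) { best <- ov; bj <- j }
        }
        if (bj > 0L && best >= iou_min) {
          used[bj] <- TRUE
          ious <- c(ious, best)
        } else {
          agree <- FALSE
          break
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      image = ai$name, n_ann = nrow(ann), n_snn = nrow(snn), agree = agree)
  }
  per_image <- do.call(rbind, rows)
  list(fraction_agree = mean(per_image$agree),
       mean_iou = if (length(ious) > 0) mean(ious) else NA_real_,
       per_image = per_image)
}
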