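# Synthetic two-class (benign/malignant) lesion images. Ultrasound-like
# images carry multiplicative speckle with hypointense (dark) lesions;
# mammogram-like images carry additive Gaussian texture with hyperintense
# masses. Benign lesions have smooth, near-elliptical margins; malignant
# lesions have strongly irregular, spiculated margins. Bounding boxes are
# exact by construction (tight box of the rendered lesion mask).
#
# Conventions: images are H x W matrices in [0, 1] quantised to 8 bits,
# rows = y (top to bottom), columns = x. Boxes are 0-based, half-open
# [x_min, x_max) x [y_min, y_max) in pixels.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

empty_boxes <- function() {
  data.frame(class = character(0), x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0))
}

smooth_field <- function(h, w, waves = 3L, amp = 1) {
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(rep(seq_len(w) / w, each = h), h, w)
  f <- matrix(0, h, w)
  for (k in seq_len(waves)) {
    fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + stats::runif(1, 0.5, 1) *
      cos(2 * pi * (fx * xx + ph[1])) * cos(2 * pi * (fy * yy + ph[2]))
  }
  amp * f / waves
}

# Radial boundary profile: base radius modulated by low-order harmonics
# (benign) or high-order spiculation (malignant).
lesion_boundary <- function(r0, irregularity, harmonics) {
  a <- stats::rnorm(length(harmonics)) * irregularity / sqrt(length(harmonics))
  ph <- stats::runif(length(harmonics), 0, 2 * pi)
  aspect <- stats::runif(1, 0.75, 1.3)
  rot <- stats::runif(1, 0, pi)
  function(theta) {
    ell <- 1 / sqrt((cos(theta - rot) / aspect)^2 + (sin(theta - rot) * aspect)^2)
    mod <- rep(0, length(theta))
    for (k in seq_along(harmonics)) {
      mod <- mod + a[k] * cos(harmonics[k] * theta + ph[k])
    }
    pmax(0.25, ell * (1 + mod)) * r0
  }
}

render_lesion_mask <- function(h, w, cx, cy, radius_fn, edge = 1.5) {
  yy <- matrix(seq_len(h) - 0.5, h, w)
  xx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  dx <- xx - cx; dy <- yy - cy
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  r <- radius_fn(theta)
  mask <- d <= r
  soft <- pmin(pmax((r - d) / edge + 0.5, 0), 1)
  dim(soft) <- dim(d)
  list(mask = mask, soft = soft)
}

tight_box <- function(mask) {
  rows <- which(apply(mask, 1, any))
  cols <- which(apply(mask, 2, any))
  # 0-based half-open: pixel i (1-based) covers [i-1, i)
  c(x_min = min(cols) - 1, y_min = min(rows) - 1,
    x_max = max(cols), y_max = max(rows))
}

class_profile <- function(class) {
  if (class == "benign") {
    list(irregularity = 0.05, harmonics = 2:3)
  } else {
    list(irregularity = 0.32, harmonics = 2:8)
  }
}

render_annotated_image <- function(class, modality, size, n_lesions,
                                   contrast) {
  h <- size; w <- size
  boxes <- empty_boxes()
  soft_total <- matrix(0, h, w)
  placed <- 0L
  attempts <- 0L
  while (placed < n_lesions) {
    attempts <- attempts + 1L
    if (attempts > 60L) {
      stop("could not place a lesion inside the image after 60 attempts",
           call. = FALSE)
    }
    prof <- class_profile(class)
    r0 <- stats::runif(1, 0.11, 0.18) * size
    rmax <- r0 * (1 + 3 * prof$irregularity) * 1.35
    if (rmax > size / 2 - 2) next
    cx <- stats::runif(1, rmax + 1, w - rmax - 1)
    cy <- stats::runif(1, rmax + 1, h - rmax - 1)
    rfn <- lesion_boundary(r0, prof$irregularity, prof$harmonics)
    lm <- render_lesion_mask(h, w, cx, cy, rfn)
    if (!any(lm$mask)) next
    bx <- tight_box(lm$mask)
    if (bx["x_max"] > w || bx["y_max"] > h || bx["x_min"] < 0 || bx["y_min"] < 0) next
    if (nrow(boxes) > 0) {
      clash <- any(vapply(seq_len(nrow(boxes)), function(j) {
        b <- boxes[j, ]
        !(bx["x_max"] <= b$x_min || b$x_max <= bx["x_min"] ||
            bx["y_max"] <= b$y_min || b$y_max <= bx["y_min"])
      }, logical(1)))
      if (clash) next
    }
    boxes <- rbind(boxes, data.frame(class = class, x_min = bx[["x_min"]],
                                     y_min = bx[["y_min"]],
                                     x_max = bx[["x_max"]],
                                     y_max = bx[["y_max"]]))
    soft_total <- pmax(soft_total, lm$soft)
    placed <- placed + 1L
  }
  if (modality == "ultrasound") {
    bg <- 0.55 + smooth_field(h, w, amp = 0.10)
    img <- bg * (1 - contrast * soft_total)
    speckle <- matrix(stats::rgamma(h * w, shape = 14, rate = 14), h, w)
    img <- img * speckle
  } else {
    bg <- 0.32 + smooth_field(h, w, amp = 0.06)
    img <- bg + contrast * soft_total
    img <- img + matrix(stats::rnorm(h * w, sd = 0.035), h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255  # 8-bit quantisation
  list(image = img, boxes = boxes)
}

#' Generate a labelled synthetic lesion dataset
#'
#' Produces reproducible grayscale images with one or more boxed lesions.
#' The class mix defaults to the benign/malignant proportions of the breast
#' ultrasound study data (437 benign : 210 malignant); when
#' `sum(class_mix) == n_images` the per-class counts equal the mix exactly,
#' otherwise they are allocated proportionally (largest remainder).
#' `n_normal` appends lesion-free images with empty box lists (excluded
#' from detection training/evaluation by convention).
#'
#' @param n_images number of lesion images.
#' @param class_mix named integer vector `c(benign = ..., malignant = ...)`
#'   interpreted as proportions.
#' @param modality `"ultrasound"` or `"mammogram"`.
#' @param size image side in pixels (square; 96 is the desk default, 500
#'   matches the source imagery scale).
#' @param lesions_per_image lesions per image (1 keeps the task easy).
#' @param contrast lesion/background intensity contrast in `[0, 1]`.
#' @param n_normal number of additional lesion-free images.
#' @param seed RNG seed; identical seeds give bitwise-identical datasets.
#' @return List of `annotated_image` objects: `image` (H x W matrix in
#'   `[0,1]`, 8-bit quantised), `boxes` (data.frame `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max`; 0-based half-open pixels), `modality`,
#'   `name`, `seed`.
#' @export
generate_dataset <- function(n_images,
                             class_mix = c(benign = 437, malignant = 210),
                             modality = c("ultrasound", "mammogram"),
                             size = 96L, lesions_per_image = 1L,
                             contrast = 0.55, n_normal = 0L, seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(n_images >= 1L, size >= 32L, lesions_per_image >= 1L)
  cls <- names(class_mix)
  stopifnot(!is.null(cls), all(cls %in% c("benign", "malignant")))
  if (sum(class_mix) == n_images) {
    counts <- class_mix
  } else {
    raw <- class_mix / sum(class_mix) * n_images
    counts <- floor(raw)
    rem <- n_images - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
  }
  labels <- rep(cls, times = counts)
  with_local_seed(seed, {
    labels <- sample(labels)
    out <- vector("list", n_images + n_normal)
    for (i in seq_len(n_images)) {
      r <- render_annotated_image(labels[i], modality, size,
                                  lesions_per_image, contrast)
      out[[i]] <- structure(
        list(image = r$image, boxes = r$boxes, modality = modality,
             name = sprintf("%s_%04d", modality, i), seed = seed),
        class = "annotated_image")
    }
    for (i in seq_len(n_normal)) {
      r <- render_annotated_image("benign", modality, size, 0L, contrast)
      out[[n_images + i]] <- structure(
        list(image = r$image, boxes = empty_boxes(), modality = modality,
             name = sprintf("%s_normal_%04d", modality, i), seed = seed),
        class = "annotated_image")
    }
    out
  })
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("annotated_image '%s': %dx%d %s, %d box(es)\n", x$name,
              nrow(x$image), ncol(x$image), x$modality, nrow(x$boxes)))
  invisible(x)
}

#' Rotate an image and its boxes by 90 degrees clockwise
#'
#' For an `H x W` image, a 0-based half-open box `(x1, y1, x2, y2)` maps to
#' `(H - y2, x1, H - y1, x2)` in the rotated `W x H` image. Four successive
#' rotations restore the original; box areas are preserved.
#'
#' @param image `H x W` matrix.
#' @param boxes data.frame with `x_min`, `y_min`, `x_max`, `y_max` (and any
#'   other columns, carried through).
#' @return List `image` (rotated matrix), `boxes` (rotated data.frame).
#' @export
rotate90_augment <- function(image, boxes) {
  h <- nrow(image)
  rot <- t(image)[, h:1, drop = FALSE]  # clockwise
  out <- boxes
  if (nrow(boxes) > 0) {
    out$x_min <- h - boxes$y_max
    out$y_min <- boxes$x_min
    out$x_max <- h - boxes$y_min
    out$y_max <- boxes$x_max
  }
  list(image = rot, boxes = out)
}

#' Double the malignant images of a dataset by 90-degree rotation
#'
#' Appends one clockwise-rotated copy of every image whose boxes are all
#' malignant, exactly doubling that class's image count.
#'
#' @param dataset list of `annotated_image` objects.
#' @return The augmented dataset (original images first).
#' @export
augment_malignant <- function(dataset) {
  extra <- list()
  for (ai in dataset) {
    if (nrow(ai$boxes) > 0 && all(ai$boxes$class == "malignant")) {
      r <- rotate90_augment(ai$image, ai$boxes)
      rot <- ai
      rot$image <- r$image
      rot$boxes <- r$boxes
      rot$name <- paste0(ai$name, "_rot90")
      extra[[length(extra) + 1L]] <- rot
    }
  }
  c(dataset, extra)
}

#' Breast-ultrasound study composition
#'
#' Image counts per class of the breast ultrasound collection the
#' generator's defaults emulate: 133 normal, 437 benign and 210 malignant
#' images (780 in total). The benign:malignant ratio is the generator's
#' default class mix, and the malignant class is the one doubled by the
#' 90-degree rotation augmentation.
#'
#' @return Named integer vector with elements `normal`, `benign`,
#'   `malignant`.
#' @export
ultrasound_study_counts <- function() {
  c(normal = 133L, benign = 437L, malignant = 210L)
}
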