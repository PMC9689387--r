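# Annotation dialects. Internally boxes are 0-based half-open pixels.
# The VOC XML dialect follows the LabelImg convention: 1-based, inclusive
# xmin/ymin/xmax/ymax, so a half-open box (x1,y1,x2,y2) exports as
# (x1+1, y1+1, x2, y2) and round-trips exactly for integer boxes. The YOLO
# text dialect stores "class_index cx cy w h" normalised to the image size
# with six decimals (round-trip error below half a pixel at any size the
# package uses).

default_classes <- c("benign", "malignant")

#' Write and read PASCAL-VOC XML annotations
#'
#' @param boxes data.frame `class`, `x_min`, `y_min`, `x_max`, `y_max`
#'   (0-based half-open pixels).
#' @param path output/input XML file.
#' @param filename image file name recorded in the annotation.
#' @param width,height image size in pixels.
#' @return `read_voc_xml()` returns a list `boxes` (internal convention),
#'   `filename`, `width`, `height`.
#' @export
write_voc_xml <- function(boxes, path, filename, width, height) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(width))
  xml2::xml_add_child(size, "height", as.character(height))
  xml2::xml_add_child(size, "depth", "1")
  for (j in seq_len(nrow(boxes))) {
    b <- boxes[j, ]
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$class)
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", "0")
    xml2::xml_add_child(obj, "difficult", "0")
    bnd <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bnd, "xmin", as.character(b$x_min + 1))
    xml2::xml_add_child(bnd, "ymin", as.character(b$y_min + 1))
    xml2::xml_add_child(bnd, "xmax", as.character(b$x_max))
    xml2::xml_add_child(bnd, "ymax", as.character(b$y_max))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_voc_xml
#' @export
read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed VOC XML '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  objs <- xml2::xml_find_all(doc, ".//object")
  num <- function(node, tag) {
    v <- xml2::xml_text(xml2::xml_find_first(node, tag))
    as.numeric(v)
  }
  boxes <- if (length(objs) == 0) empty_boxes() else do.call(rbind, lapply(objs, function(o) {
    data.frame(
      class = xml2::xml_text(xml2::xml_find_first(o, "name")),
      x_min = num(o, "bndbox/xmin") - 1,
      y_min = num(o, "bndbox/ymin") - 1,
      x_max = num(o, "bndbox/xmax"),
      y_max = num(o, "bndbox/ymax"))
  }))
  list(boxes = boxes,
       filename = xml2::xml_text(xml2::xml_find_first(doc, "filename")),
       width = as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "size/width"))),
       height = as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "size/height"))))
}

#' Write and read YOLO text annotations
#'
#' @inheritParams write_voc_xml
#' @param classes class-name vector defining the 0-based class indices.
#' @return `read_yolo_txt()` returns a boxes data.frame in the internal
#'   convention.
#' @export
write_yolo_txt <- function(boxes, path, width, height,
                           classes = default_classes) {
  lines <- character(nrow(boxes))
  for (j in seq_len(nrow(boxes))) {
    b <- boxes[j, ]
    ci <- match(b$class, classes) - 1L
    if (is.na(ci)) stop("unknown class: ", b$class, call. = FALSE)
    lines[j] <- sprintf("%d %.6f %.6f %.6f %.6f", ci,
                        (b$x_min + b$x_max) / 2 / width,
                        (b$y_min + b$y_max) / 2 / height,
                        (b$x_max - b$x_min) / width,
                        (b$y_max - b$y_min) / height)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_txt
#' @export
read_yolo_txt <- function(path, width, height, classes = default_classes) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_boxes())
  rows <- lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) != 5L || anyNA(suppressWarnings(as.numeric(f)))) {
      stop(sprintf("malformed YOLO annotation at %s line %d", path, k),
           call. = FALSE)
    }
    v <- as.numeric(f)
    ci <- as.integer(v[1]) + 1L
    if (ci < 1L || ci > length(classes)) {
      stop(sprintf("class index out of range at %s line %d", path, k),
           call. = FALSE)
    }
    data.frame(class = classes[ci],
               x_min = (v[2] - v[4] / 2) * width,
               y_min = (v[3] - v[5] / 2) * height,
               x_max = (v[2] + v[4] / 2) * width,
               y_max = (v[3] + v[5] / 2) * height)
  })
  do.call(rbind, rows)
}

#' Write a dataset to disk (images + annotations + manifest)
#'
#' Writes one grayscale PNG per image, its annotation in the chosen
#' dialect, and a `manifest.csv` (`name`, `image`, `annotation`,
#' `modality`, `n_benign`, `n_malignant`).
#'
#' @param dataset list of `annotated_image` objects from
#'   [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param dialect `"voc"` (XML) or `"yolo"` (txt).
#' @param classes class names defining YOLO indices.
#' @return Invisibly, the manifest data.frame.
#' @export
write_dataset <- function(dataset, dir, dialect = c("voc", "yolo"),
                          classes = default_classes) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(ai) {
    img_file <- file.path(dir, paste0(ai$name, ".png"))
    png::writePNG(ai$image, img_file)
    ann_file <- file.path(dir, paste0(
      ai$name, if (dialect == "voc") ".xml" else ".txt"))
    if (dialect == "voc") {
      write_voc_xml(ai$boxes, ann_file, basename(img_file),
                    ncol(ai$image), nrow(ai$image))
    } else {
      write_yolo_txt(ai$boxes, ann_file, ncol(ai$image), nrow(ai$image),
                     classes)
    }
    data.frame(name = ai$name, image = basename(img_file),
               annotation = basename(ann_file), modality = ai$modality,
               n_benign = sum(ai$boxes$class == "benign"),
               n_malignant = sum(ai$boxes$class == "malignant"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param dialect annotation dialect used when writing.
#' @param classes class names defining YOLO indices.
#' @return List of `annotated_image` objects.
#' @export
read_dataset <- function(dir, dialect = c("voc", "yolo"),
                         classes = default_classes) {
  dialect <- match.arg(dialect)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    img <- png::readPNG(file.path(dir, m$image))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    boxes <- if (dialect == "voc") {
      read_voc_xml(file.path(dir, m$annotation))$boxes
    } else {
      read_yolo_txt(file.path(dir, m$annotation), ncol(img), nrow(img),
                    classes)
    }
    structure(list(image = img, boxes = boxes, modality = m$modality,
                   name = m$name, seed = NA_integer_),
              class = "annotated_image")
  })
}
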