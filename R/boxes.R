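# Axis-aligned box utilities. Pixel coordinates, origin top-left; normalised
# YOLO labels are (class, cx, cy, w, h) in [0, 1].

# IoU between rows of a (n x 4) and rows of b (m x 4); returns n x m matrix.
box_iou_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0 || m == 0) return(out)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  for (j in seq_len(m)) {
    iw <- pmax(0, pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1]))
    ih <- pmax(0, pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2]))
    inter <- iw * ih
    out[, j] <- inter / (area_a + area_b[j] - inter)
  }
  out
}

# Greedy non-maximum suppression; returns indices of survivors.
nms_indices <- function(boxes, scores, iou_threshold) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) == 0) break
    ious <- box_iou_matrix(boxes[ord, , drop = FALSE],
                           boxes[i, , drop = FALSE])[, 1]
    ord <- ord[ious < iou_threshold]
  }
  keep
}

# Normalised (cx, cy, w, h) -> pixel (x1, y1, x2, y2) for a W x H canvas.
yolo_to_xyxy <- function(boxes, width, height) {
  cbind(x1 = (boxes$cx - boxes$w / 2) * width,
        y1 = (boxes$cy - boxes$h / 2) * height,
        x2 = (boxes$cx + boxes$w / 2) * width,
        y2 = (boxes$cy + boxes$h / 2) * height)
}

xyxy_to_yolo <- function(xyxy, width, height) {
  data.frame(cx = (xyxy[, 1] + xyxy[, 3]) / 2 / width,
             cy = (xyxy[, 2] + xyxy[, 4]) / 2 / height,
             w = (xyxy[, 3] - xyxy[, 1]) / width,
             h = (xyxy[, 4] - xyxy[, 2]) / height)
}

#' Read YOLO-format labels
#'
#' One line per box: `class cx cy w h`, whitespace separated, coordinates
#' normalised to `[0, 1]`. A missing or empty file yields zero boxes.
#'
#' @param path Label file path.
#' @return `data.frame` with columns `class`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path) {
  empty <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  if (!file.exists(path) || file.size(path) == 0) return(empty)
  m <- utils::read.table(path, col.names = c("class", "cx", "cy", "w", "h"))
  m$class <- as.integer(m$class)
  m
}

#' Write YOLO-format labels
#'
#' @param boxes `data.frame` with columns `class`, `cx`, `cy`, `w`, `h`
#'   (normalised coordinates).
#' @param path Output file path.
#' @export
write_yolo_labels <- function(boxes, path) {
  if (nrow(boxes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class, boxes$cx,
                   boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write detections as YOLO text with confidence
#'
#' One line per detection: `class cx cy w h confidence`, coordinates
#' normalised by the image size.
#'
#' @param detections `data.frame` with `class`, `confidence` and pixel
#'   corners `x1, y1, x2, y2`.
#' @param path File path.
#' @param width,height Image size in pixels used for normalisation.
#' @return `write_detections` the path, invisibly; `read_detections` a
#'   `data.frame` with `class`, `confidence` and pixel corners.
#' @export
write_detections <- function(detections, path, width, height) {
  if (nrow(detections) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  y <- xyxy_to_yolo(as.matrix(detections[, c("x1", "y1", "x2", "y2")]),
                    width, height)
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f %.6f", detections$class,
                     y$cx, y$cy, y$w, y$h, detections$confidence), path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, width, height) {
  empty <- data.frame(class = integer(0), confidence = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0))
  if (!file.exists(path) || file.size(path) == 0) return(empty)
  m <- utils::read.table(path, col.names = c("class", "cx", "cy", "w", "h",
                                             "confidence"))
  px <- yolo_to_xyxy(m, width, height)
  cbind(data.frame(class = as.integer(m$class), confidence = m$confidence),
        as.data.frame(px))
}
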