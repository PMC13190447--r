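#' Detection quality and face visibility
#'
#' Head detection is scored by intersection-over-union against annotated
#' ground-truth boxes with a lenient success threshold of 0.3 (face and
#' head crops rarely align perfectly), summarised as precision, recall and
#' F1. Facial occlusion — from the ball, arms, or the head turning away —
#' is quantified per frame as the visible face area: the part of the face
#' box not covered by any annotated occluder box, normalised per camera by
#' the maximum observed area to give a visibility ratio in [0, 1].
#'
#' Boxes are continuous \code{c(x, y, w, h)} with a top-left pixel origin
#' and area \code{w * h} (no +1 convention).
#'
#' @name detection
#' @keywords internal
NULL

.box_ok <- function(b) {
  is.numeric(b) && length(b) == 4L && !anyNA(b) && b[3] >= 0 && b[4] >= 0
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as \code{c(x, y, w, h)} in pixels.
#' @return ratio in [0, 1]; 0 when the union has zero area.
#' @export
iou <- function(a, b) {
  stopifnot(.box_ok(a), .box_ok(b))
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  uni <- a[3] * a[4] + b[3] * b[4] - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Match detections to ground truth in one frame
#'
#' Greedy one-to-one matching in descending IoU order: pairs with IoU at or
#' above \code{threshold} become true positives, unmatched detections false
#' positives, unmatched ground-truth boxes false negatives. With at most
#' one ground-truth box per frame (single participant) greedy matching is
#' optimal.
#'
#' @param ground_truth,detections lists of boxes \code{c(x, y, w, h)}.
#' @param threshold IoU success threshold (default 0.3).
#' @return list with \code{tp}, \code{fp}, \code{fn}.
#' @export
match_detections <- function(ground_truth, detections, threshold = 0.3) {
  ng <- length(ground_truth); nd <- length(detections)
  if (ng == 0L || nd == 0L) {
    return(list(tp = 0L, fp = nd, fn = ng))
  }
  M <- outer(seq_len(ng), seq_len(nd),
             Vectorize(function(i, j) iou(ground_truth[[i]],
                                          detections[[j]])))
  M <- matrix(M, ng, nd)
  used_g <- logical(ng); used_d <- logical(nd); tp <- 0L
  repeat {
    M[used_g, ] <- -1; M[, used_d] <- -1
    best <- which.max(M)
    if (M[best] < threshold) break
    i <- (best - 1L) %% ng + 1L
    j <- (best - 1L) %/% ng + 1L
    used_g[i] <- TRUE; used_d[j] <- TRUE
    tp <- tp + 1L
  }
  list(tp = tp, fp = nd - tp, fn = ng - tp)
}

#' Precision, recall and F1 from detection counts
#'
#' \code{precision = TP/(TP+FP)}, \code{recall = TP/(TP+FN)},
#' \code{f1 = 2 PR/(P+R)}; each is defined as 0 when its denominator is 0
#' (reported via message).
#'
#' @param counts list with \code{tp}, \code{fp}, \code{fn}, or the three
#'   counts given separately.
#' @param fp,fn counts when \code{counts} is the TP count.
#' @return named numeric vector \code{c(precision, recall, f1)}.
#' @export
detection_metrics <- function(counts, fp = NULL, fn = NULL) {
  if (is.list(counts)) {
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  } else {
    tp <- counts
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    message("no detections: precision defined as 0"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    message("no ground truth: recall defined as 0"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' F1 score from precision and recall
#'
#' @param precision,recall values in [0, 1].
#' @return harmonic mean, 0 when both are 0.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

# exact area of the union of axis-aligned rectangles (coordinate
# compression; no double counting)
.union_area <- function(boxes) {
  boxes <- Filter(function(b) b[3] > 0 && b[4] > 0, boxes)
  if (!length(boxes)) return(0)
  xs <- sort(unique(unlist(lapply(boxes, function(b) c(b[1], b[1] + b[3])))))
  ys <- sort(unique(unlist(lapply(boxes, function(b) c(b[2], b[2] + b[4])))))
  area <- 0
  for (i in seq_len(length(xs) - 1L)) {
    for (j in seq_len(length(ys) - 1L)) {
      cx <- (xs[i] + xs[i + 1]) / 2; cy <- (ys[j] + ys[j + 1]) / 2
      covered <- any(vapply(boxes, function(b) {
        cx > b[1] && cx < b[1] + b[3] && cy > b[2] && cy < b[2] + b[4]
      }, TRUE))
      if (covered) {
        area <- area + (xs[i + 1] - xs[i]) * (ys[j + 1] - ys[j])
      }
    }
  }
  area
}

#' Visible face area in one frame
#'
#' Face-box area minus the area of the face's intersection with the union
#' of the occluder boxes (computed exactly, so overlapping occluders are
#' not double-counted). Frames without a face box yield NA and are
#' excluded from visibility analyses.
#'
#' @param face face box \code{c(x, y, w, h)} or NULL.
#' @param occluders list of occluder boxes (possibly empty).
#' @return area in squared pixels, in [0, area(face)]; NA if no face box.
#' @export
visible_face_area <- function(face, occluders = list()) {
  if (is.null(face)) return(NA_real_)
  stopifnot(.box_ok(face))
  fa <- face[3] * face[4]
  if (!length(occluders)) return(fa)
  clipped <- lapply(occluders, function(b) {
    x0 <- max(face[1], b[1]); y0 <- max(face[2], b[2])
    x1 <- min(face[1] + face[3], b[1] + b[3])
    y1 <- min(face[2] + face[4], b[2] + b[4])
    c(x0, y0, max(0, x1 - x0), max(0, y1 - y0))
  })
  max(0, fa - .union_area(clipped))
}

#' Visibility ratios normalised per camera
#'
#' Each frame's visible face area divided by the maximum observed visible
#' area for the same camera over the whole supplied dataset (the maximal
#' frame maps to exactly 1). Set \code{per_camera = FALSE} to normalise by
#' the global maximum instead.
#'
#' @param frames data.frame with columns \code{camera} and \code{area}
#'   (visible face area; NA allowed), or a numeric vector of areas.
#' @param per_camera normalise within camera (default TRUE).
#' @return numeric vector of ratios in [0, 1] (NA propagated).
#' @export
visibility_ratio_series <- function(frames, per_camera = TRUE) {
  if (is.numeric(frames)) {
    frames <- data.frame(camera = "all", area = frames)
    per_camera <- FALSE
  }
  stopifnot(all(c("camera", "area") %in% names(frames)))
  out <- rep(NA_real_, nrow(frames))
  groups <- if (per_camera) split(seq_len(nrow(frames)), frames$camera)
            else list(seq_len(nrow(frames)))
  for (idx in groups) {
    a <- frames$area[idx]
    if (all(is.na(a))) {
      stop("camera '", frames$camera[idx[1]], "' has no face boxes: ",
           "cannot normalise visibility", call. = FALSE)
    }
    mx <- max(a, na.rm = TRUE)
    if (mx <= 0) stop("all visible areas are zero for camera '",
                      frames$camera[idx[1]], "'", call. = FALSE)
    out[idx] <- a / mx
  }
  out
}

#' Interpolate ground-truth boxes across occluded frames
#'
#' Optional annotation helper: linear interpolation of box corners across
#' frames where the box is missing (interior gaps only).
#'
#' @param boxes list of boxes (\code{c(x,y,w,h)} or NULL) per frame.
#' @return list with gaps filled.
#' @export
interpolate_boxes <- function(boxes) {
  have <- !vapply(boxes, is.null, TRUE)
  if (all(have)) return(boxes)
  if (!have[1] || !have[length(boxes)]) {
    stop("cannot extrapolate boxes at sequence boundaries", call. = FALSE)
  }
  M <- matrix(NA_real_, length(boxes), 4)
  M[have, ] <- do.call(rbind, boxes[have])
  for (k in 1:4) {
    M[, k] <- stats::approx(which(have), M[have, k],
                            xout = seq_along(boxes))$y
  }
  lapply(seq_along(boxes), function(i) M[i, ])
}

#' Read and write per-trial boxes JSON
#'
#' Schema: \code{{"camera":"F","image_size":[1280,720],"frames":[{"frame":0,
#' "face":[x,y,w,h],"occluders":[[...]],"detections":[[...]],
#' "ground_truth":[[...]]}]}}.
#'
#' @param path file path.
#' @return \code{read_boxes_json}: list with \code{camera},
#'   \code{image_size} and \code{frames} (each with \code{frame},
#'   \code{face} or NULL, and lists \code{occluders}, \code{detections},
#'   \code{ground_truth}).
#' @export
read_boxes_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  frames <- lapply(j$frames, function(f) {
    list(frame = f$frame,
         face = if (is.null(f$face)) NULL else as.numeric(unlist(f$face)),
         occluders = lapply(f$occluders, function(b) as.numeric(unlist(b))),
         detections = lapply(f$detections, function(b) as.numeric(unlist(b))),
         ground_truth = lapply(f$ground_truth,
                               function(b) as.numeric(unlist(b))))
  })
  list(camera = j$camera, image_size = as.numeric(unlist(j$image_size)),
       frames = frames)
}

#' @rdname read_boxes_json
#' @param x box set as returned by \code{read_boxes_json}.
#' @export
write_boxes_json <- function(x, path) {
  jsonlite::write_json(
    list(camera = x$camera, image_size = x$image_size,
         frames = lapply(x$frames, function(f) {
           list(frame = f$frame, face = f$face, occluders = f$occluders,
                detections = f$detections, ground_truth = f$ground_truth)
         })),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
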