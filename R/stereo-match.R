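# Bounding-box stereo correspondence and corner-based measurement.  In the
# rectified frame, a true correspondence has its box centers on (nearly)
# the same row, so candidates are scored by overlap divided by the angle of
# the center-connecting line from the horizontal:
#
#   mscore(box1, box2) = 0            if theta > theta_thresh,
#                                        iou < iou_thresh, or classes differ
#                      = iou / theta  otherwise
#
# with theta = |arctan((y2 - y1) / (x2 - x1))| in degrees between the box
# centers.  theta -> 0 is the ideal rectified case, so the ratio is
# evaluated as iou / max(theta, eps) with a small angle floor eps that caps
# the score while preserving its ordering.

#' Stereo-matching configuration
#'
#' @param thetaThresh maximum center-line angle from horizontal, degrees
#' @param iouThresh minimum box overlap (IoU) for a valid match
#' @param eps angle floor, degrees, guarding the `iou / theta` score at
#'   `theta = 0`
#' @param requireClassEquality reject matches whose predicted classes differ
#' @return a `MatchConfig` list
#' @export
matchConfig <- function(thetaThresh = 5, iouThresh = 0.05, eps = 0.1,
                        requireClassEquality = TRUE) {
  stopifnot(thetaThresh > 0, eps > 0, iouThresh >= 0, iouThresh <= 1)
  structure(list(thetaThresh = thetaThresh, iouThresh = iouThresh,
                 eps = eps, requireClassEquality = requireClassEquality),
            class = "MatchConfig")
}

#' Stereo matching score for a box pair
#'
#' @param boxLeft,boxRight boxes `c(x1, y1, x2, y2)` in rectified pixel
#'   coordinates
#' @param classLeft,classRight predicted class labels
#' @param config a [matchConfig()]
#' @return list with `score` (0 under any gate, else `iou / max(theta,
#'   eps)`), `theta` (degrees) and `iou`
#' @export
matchScore <- function(boxLeft, boxRight, classLeft = NA, classRight = NA,
                       config = matchConfig()) {
  cxl <- (boxLeft[1] + boxLeft[3]) / 2;  cyl <- (boxLeft[2] + boxLeft[4]) / 2
  cxr <- (boxRight[1] + boxRight[3]) / 2; cyr <- (boxRight[2] + boxRight[4]) / 2
  dx <- cxr - cxl; dy <- cyr - cyl
  theta <- if (dx == 0) {
    if (dy == 0) 0 else 90  # coincident centers lie on the epipolar line
  } else abs(atan(dy / dx)) * 180 / pi
  iou <- boxIoU(boxLeft, boxRight)
  gated <- theta > config$thetaThresh || iou < config$iouThresh ||
    (config$requireClassEquality &&
       (is.na(classLeft) || is.na(classRight) || classLeft != classRight))
  score <- if (gated) 0 else iou / max(theta, config$eps)
  list(score = score, theta = theta, iou = iou)
}

#' Match detections across a rectified stereo pair
#'
#' Scores every left/right detection pair of one synchronized frame with
#' [matchScore()] and accepts matches greedily by descending score with
#' one-to-one use of each detection; zero-score pairs are never matched.
#' Ties are broken deterministically by lower left index, then lower right
#' index.  Box coordinates must already be rectified (see
#' [rectifyDetections()]).
#'
#' @param left,right detections data.frames from one synchronized frame
#'   pair, boxes in rectified coordinates
#' @param config a [matchConfig()]
#' @return list with `matches` (data.frame: left, right row indices, score,
#'   theta, iou) and the `unmatchedLeft` / `unmatchedRight` row indices
#'   (monocular detections)
#' @export
matchDetections <- function(left, right, config = matchConfig()) {
  nl <- nrow(left); nr <- nrow(right)
  empty <- data.frame(left = integer(), right = integer(),
                      score = numeric(), theta = numeric(), iou = numeric())
  if (nl == 0 || nr == 0)
    return(list(matches = empty, unmatchedLeft = seq_len(nl),
                unmatchedRight = seq_len(nr)))
  cand <- expand.grid(left = seq_len(nl), right = seq_len(nr))
  sc <- t(vapply(seq_len(nrow(cand)), function(k) {
    i <- cand$left[k]; j <- cand$right[k]
    s <- matchScore(as.numeric(left[i, c("x1", "y1", "x2", "y2")]),
                    as.numeric(right[j, c("x1", "y1", "x2", "y2")]),
                    left$class[i], right$class[j], config)
    c(s$score, s$theta, s$iou)
  }, numeric(3)))
  cand$score <- sc[, 1]; cand$theta <- sc[, 2]; cand$iou <- sc[, 3]
  cand <- cand[cand$score > 0, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$left, cand$right), , drop = FALSE]
  usedL <- logical(nl); usedR <- logical(nr)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$left[k]; j <- cand$right[k]
    if (!usedL[i] && !usedR[j]) {
      keep[k] <- TRUE
      usedL[i] <- TRUE; usedR[j] <- TRUE
    }
  }
  matches <- cand[keep, , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatchedLeft = which(!usedL), unmatchedRight = which(!usedR))
}

#' Rectify detection boxes
#'
#' Transforms each box's four corners through undistortion and
#' rectification and re-forms the box as the axis-aligned hull of the
#' transformed corners.  Matching and measurement operate on these
#' rectified boxes.
#'
#' @param detections detections data.frame (single camera)
#' @param rect a [RectifiedRig-class]
#' @param camera `"left"` or `"right"`
#' @return the detections with rectified box coordinates
#' @export
rectifyDetections <- function(detections, rect, camera = c("left", "right")) {
  camera <- match.arg(camera)
  if (!nrow(detections)) return(detections)
  corners <- rbind(
    cbind(detections$x1, detections$y1), cbind(detections$x2, detections$y1),
    cbind(detections$x1, detections$y2), cbind(detections$x2, detections$y2))
  rc <- rectifyPixels(rect, corners, camera)
  n <- nrow(detections)
  xs <- matrix(rc[, 1], n, 4); ys <- matrix(rc[, 2], n, 4)
  detections$x1 <- apply(xs, 1, min); detections$x2 <- apply(xs, 1, max)
  detections$y1 <- apply(ys, 1, min); detections$y2 <- apply(ys, 1, max)
  detections
}

#' Measure a matched box pair
#'
#' Triangulates the four corner correspondences of a matched rectified box
#' pair (top-left to top-left, etc.).  The animal's width is the mean 3D
#' length of the top and bottom box edges, its height the mean 3D length of
#' the left and right edges, and its distance the Euclidean norm of the
#' triangulated box-center point.
#'
#' @param boxLeft,boxRight rectified boxes `c(x1, y1, x2, y2)`
#' @param rect a [RectifiedRig-class]
#' @return list with `distance`, `width`, `height` (mm), `corners`
#'   (4 x 3 triangulated corner coordinates, rows TL, TR, BL, BR) and
#'   `rejected` (NULL, or a reason string when measurement is impossible)
#' @export
measureMatch <- function(boxLeft, boxRight, rect) {
  if (boxLeft[3] <= boxLeft[1] || boxLeft[4] <= boxLeft[2] ||
      boxRight[3] <= boxRight[1] || boxRight[4] <= boxRight[2])
    return(list(distance = NA_real_, width = NA_real_, height = NA_real_,
                corners = NULL, rejected = "degenerate zero-area box"))
  cl <- rbind(c(boxLeft[1], boxLeft[2]), c(boxLeft[3], boxLeft[2]),
              c(boxLeft[1], boxLeft[4]), c(boxLeft[3], boxLeft[4]),
              c((boxLeft[1] + boxLeft[3]) / 2, (boxLeft[2] + boxLeft[4]) / 2))
  cr <- rbind(c(boxRight[1], boxRight[2]), c(boxRight[3], boxRight[2]),
              c(boxRight[1], boxRight[4]), c(boxRight[3], boxRight[4]),
              c((boxRight[1] + boxRight[3]) / 2,
                (boxRight[2] + boxRight[4]) / 2))
  if (any(cl[, 1] - cr[, 1] <= 0))
    return(list(distance = NA_real_, width = NA_real_, height = NA_real_,
                corners = NULL,
                rejected = "non-positive corner disparity"))
  X <- suppressWarnings(triangulate(rect, cl, cr, rectified = TRUE))
  d3 <- function(a, b) sqrt(sum((a - b)^2))
  list(distance = sqrt(sum(X[5, ]^2)),
       width = (d3(X[1, ], X[2, ]) + d3(X[3, ], X[4, ])) / 2,
       height = (d3(X[1, ], X[3, ]) + d3(X[2, ], X[4, ])) / 2,
       corners = X[1:4, , drop = FALSE], rejected = NULL)
}

#' Match and measure a full detection stream
#'
#' Runs [rectifyDetections()], [matchDetections()] and [measureMatch()]
#' frame by frame over a two-camera detection table.
#'
#' @param detections detections data.frame with a `camera` column
#'   (`"left"` / `"right"`), raw pixel coordinates
#' @param rect a [RectifiedRig-class]
#' @param config a [matchConfig()]
#' @param streamId stream identifier for the output rows
#' @return data.frame of measurements: stream_id, frame, species,
#'   distance_mm, width_mm, height_mm, mscore, theta_deg, iou (rejected
#'   pairs are dropped with a message)
#' @export
measureStream <- function(detections, rect, config = matchConfig(),
                          streamId = "stream") {
  out <- list(); nrej <- 0L
  for (fr in sort(unique(detections$frame))) {
    L <- rectifyDetections(
      detections[detections$frame == fr & detections$camera == "left", ,
                 drop = FALSE], rect, "left")
    R <- rectifyDetections(
      detections[detections$frame == fr & detections$camera == "right", ,
                 drop = FALSE], rect, "right")
    mm <- matchDetections(L, R, config)
    for (k in seq_len(nrow(mm$matches))) {
      i <- mm$matches$left[k]; j <- mm$matches$right[k]
      meas <- measureMatch(as.numeric(L[i, c("x1", "y1", "x2", "y2")]),
                           as.numeric(R[j, c("x1", "y1", "x2", "y2")]), rect)
      if (!is.null(meas$rejected)) { nrej <- nrej + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        stream_id = streamId, frame = fr, species = L$class[i],
        distance_mm = meas$distance, width_mm = meas$width,
        height_mm = meas$height, mscore = mm$matches$score[k],
        theta_deg = mm$matches$theta[k], iou = mm$matches$iou[k])
    }
  }
  if (nrej > 0) message(nrej, " matched pair(s) rejected during measurement")
  if (length(out)) do.call(rbind, out) else
    data.frame(stream_id = character(), frame = integer(),
               species = character(), distance_mm = numeric(),
               width_mm = numeric(), height_mm = numeric(),
               mscore = numeric(), theta_deg = numeric(), iou = numeric())
}
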