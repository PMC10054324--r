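# Detector-agnostic post-processing and evaluation.  Detections are plain
# data.frames with columns frame, camera, x1, y1, x2, y2, class, confidence
# (boxes as upper-left / bottom-right pixel corners, x1 < x2, y1 < y2).

#' Intersection over union of bounding boxes
#'
#' @param a,b boxes as length-4 vectors `c(x1, y1, x2, y2)` or n x 4
#'   matrices (recycled row-wise against each other)
#' @return IoU values in `[0, 1]`: 0 for disjoint boxes, 1 iff identical
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
boxIoU <- function(a, b) {
  a <- matrix(as.numeric(t(a)), ncol = 4, byrow = TRUE)
  b <- matrix(as.numeric(t(b)), ncol = 4, byrow = TRUE)
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (areaA + areaB - inter)
}

# IoU matrix between two box sets (n x 4, m x 4) -> n x m.
iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  outer(seq_len(n), seq_len(m), function(i, j)
    boxIoU(A[i, , drop = FALSE], B[j, , drop = FALSE]))
}

#' Class-agnostic non-maximum suppression
#'
#' Greedy suppression over the detections of one frame/camera: detections
#' are visited in decreasing confidence and any remaining detection whose
#' IoU with an already-kept box is strictly greater than `iouThreshold` is
#' discarded regardless of its class.
#'
#' @param detections data.frame with box columns and `confidence`
#' @param iouThreshold suppression threshold; overlaps exactly at the
#'   threshold are kept
#' @return the retained subset of `detections`
#' @export
nmsFilter <- function(detections, iouThreshold = 0.6) {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  ord <- order(-detections$confidence)
  boxes <- as.matrix(detections[ord, c("x1", "y1", "x2", "y2")])
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < n) {
      later <- which(alive & seq_len(n) > i)
      if (length(later)) {
        ious <- boxIoU(matrix(boxes[i, ], length(later), 4, byrow = TRUE),
                       boxes[later, , drop = FALSE])
        alive[later[ious > iouThreshold]] <- FALSE
      }
    }
  }
  detections[sort(ord[keep]), , drop = FALSE]
}

#' Confidence filter and per-frame post-processing
#'
#' Applies a minimum-confidence filter followed by class-agnostic NMS
#' within each (frame, camera) group.
#'
#' @param detections detections data.frame
#' @param minConfidence minimum confidence retained
#' @param iouThreshold NMS threshold, see [nmsFilter()]
#' @return the filtered detections data.frame
#' @export
postprocessDetections <- function(detections, minConfidence = 0.25,
                                  iouThreshold = 0.6) {
  det <- detections[detections$confidence >= minConfidence, , drop = FALSE]
  if (!nrow(det)) return(det)
  parts <- split(det, list(det$frame, det$camera), drop = TRUE)
  out <- do.call(rbind, lapply(parts, nmsFilter, iouThreshold = iouThreshold))
  out <- out[order(out$frame, out$camera, -out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Greedy one-to-one matching of detections (descending confidence) against
# ground truth within each frame/camera group.  Returns, per detection, the
# index of the matched GT row (NA if none).  When classAware, only
# same-class pairs are considered.
match_detections_to_truth <- function(truth, det, iouMin, classAware = TRUE) {
  gtMatched <- rep(FALSE, nrow(truth))
  detMatch <- rep(NA_integer_, nrow(det))
  if (!nrow(det) || !nrow(truth)) return(list(detMatch = detMatch,
                                              gtMatched = gtMatched))
  ord <- order(-det$confidence)
  groups <- split(seq_len(nrow(truth)), paste(truth$frame, truth$camera))
  dkey <- paste(det$frame, det$camera)
  for (i in ord) {
    cand <- groups[[dkey[i]]]
    if (is.null(cand)) next
    cand <- cand[!gtMatched[cand]]
    if (classAware) cand <- cand[truth$class[cand] == det$class[i]]
    if (!length(cand)) next
    ious <- boxIoU(matrix(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                          length(cand), 4, byrow = TRUE),
                   as.matrix(truth[cand, c("x1", "y1", "x2", "y2")]))
    best <- which.max(ious)
    if (ious[best] >= iouMin) {
      detMatch[i] <- cand[best]
      gtMatched[cand[best]] <- TRUE
    }
  }
  list(detMatch = detMatch, gtMatched = gtMatched)
}

# Average precision by all-point (continuous) interpolation from ranked
# TP/FP flags.
average_precision <- function(tp, nGT) {
  if (nGT == 0) return(NA_real_)
  if (!length(tp)) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / nGT
  precision <- ctp / (ctp + cfp)
  # precision envelope, monotone non-increasing from the right
  penv <- rev(cummax(rev(precision)))
  r0 <- c(0, recall[-length(recall)])
  sum((recall - r0) * penv)
}

#' Evaluate detections against ground truth
#'
#' Computes the field-standard object-detection evaluation: per class,
#' detections are ranked by confidence and matched greedily one-to-one to
#' same-class ground-truth boxes of the same frame and camera at IoU >=
#' `iouMin`; matched detections are true positives, the rest false
#' positives, and unmatched ground truth are false negatives.  Reported
#' are the per-class average precision (all-point interpolation) and their
#' mean (mAP), precision/recall/F1 per class over a confidence grid with
#' the best mean F1 and its confidence, and a confusion matrix with a
#' background class (see [EvaluationResult-class] for its layout).
#' Misclassifications are surfaced by a second, class-agnostic matching
#' pass over the leftovers, which fills the off-diagonal cells.
#'
#' @param truth ground-truth data.frame: frame, camera, x1, y1, x2, y2,
#'   class
#' @param detections detections data.frame: frame, camera, x1, y1, x2, y2,
#'   class, confidence
#' @param iouMin IoU acceptance threshold (default 0.5, i.e. mAP@0.5)
#' @param confidenceGrid thresholds for the precision/recall/F1 curves
#' @param matrixConfidence confidence threshold at which the confusion
#'   matrix is tallied
#' @param classes class vocabulary; defaults to the classes present in the
#'   ground truth
#' @return an [EvaluationResult-class]
#' @export
evaluateDetections <- function(truth, detections, iouMin = 0.5,
                               confidenceGrid = seq(0, 1, by = 0.005),
                               matrixConfidence = 0.25, classes = NULL) {
  if (!"camera" %in% names(truth)) truth$camera <- "left"
  if (!"camera" %in% names(detections)) detections$camera <- "left"
  if (is.null(classes)) classes <- sort(unique(truth$class))
  if (!all(detections$class %in% classes))
    stop("detections contain class labels outside the vocabulary: ",
         paste(setdiff(detections$class, classes), collapse = ", "))
  truth <- as.data.frame(truth); detections <- as.data.frame(detections)

  # ranked TP flags per class -> AP
  ap <- vapply(classes, function(cl) {
    gt <- truth[truth$class == cl, , drop = FALSE]
    dt <- detections[detections$class == cl, , drop = FALSE]
    dt <- dt[order(-dt$confidence), , drop = FALSE]
    m <- match_detections_to_truth(gt, dt, iouMin)
    average_precision(!is.na(m$detMatch), nrow(gt))
  }, numeric(1))
  names(ap) <- classes
  map <- mean(ap, na.rm = TRUE)

  # PR/F1 curves over the confidence grid: matching is monotone in the
  # threshold, so match once on all detections and threshold the flags.
  curves <- do.call(rbind, lapply(classes, function(cl) {
    gt <- truth[truth$class == cl, , drop = FALSE]
    dt <- detections[detections$class == cl, , drop = FALSE]
    dt <- dt[order(-dt$confidence), , drop = FALSE]
    m <- match_detections_to_truth(gt, dt, iouMin)
    tp_flag <- !is.na(m$detMatch)
    vals <- t(vapply(confidenceGrid, function(th) {
      sel <- dt$confidence >= th
      tp <- sum(tp_flag & sel); fp <- sum(!tp_flag & sel)
      fn <- nrow(gt) - tp
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rec <- if (nrow(gt) > 0) tp / nrow(gt) else NA_real_
      f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else 0
      c(tp, fp, fn, prec, rec, f1)
    }, numeric(6)))
    data.frame(confidence = confidenceGrid, class = cl, tp = vals[, 1],
               fp = vals[, 2], fn = vals[, 3], precision = vals[, 4],
               recall = vals[, 5], f1 = vals[, 6])
  }))
  gtClasses <- classes[classes %in% truth$class]
  withGT <- curves[curves$class %in% gtClasses, , drop = FALSE]
  meanF1 <- tapply(withGT$f1, withGT$confidence, mean)
  bestIdx <- which.max(meanF1)
  bestF1 <- as.numeric(meanF1[bestIdx])
  bestConf <- as.numeric(names(meanF1)[bestIdx])

  # confusion matrix with background class at matrixConfidence
  det <- detections[detections$confidence >= matrixConfidence, , drop = FALSE]
  labs <- c(classes, "background")
  conf <- matrix(0L, length(labs), length(labs), dimnames = list(
    truth = labs, predicted = labs))
  m1 <- match_detections_to_truth(truth, det, iouMin, classAware = TRUE)
  for (i in which(!is.na(m1$detMatch)))
    conf[truth$class[m1$detMatch[i]], det$class[i]] <-
      conf[truth$class[m1$detMatch[i]], det$class[i]] + 1L
  restT <- truth[!m1$gtMatched, , drop = FALSE]
  restD <- det[is.na(m1$detMatch), , drop = FALSE]
  m2 <- match_detections_to_truth(restT, restD, iouMin, classAware = FALSE)
  for (i in which(!is.na(m2$detMatch)))
    conf[restT$class[m2$detMatch[i]], restD$class[i]] <-
      conf[restT$class[m2$detMatch[i]], restD$class[i]] + 1L
  fn_cls <- restT$class[!m2$gtMatched]
  for (cl in fn_cls) conf[cl, "background"] <- conf[cl, "background"] + 1L
  fp_cls <- restD$class[is.na(m2$detMatch)]
  for (cl in fp_cls) conf["background", cl] <- conf["background", cl] + 1L

  rn <- sweep(conf, 1, pmax(rowSums(conf), 1), "/")
  cn <- sweep(conf, 2, pmax(colSums(conf), 1), "/")
  new("EvaluationResult", confusion = conf, confusionRowNorm = rn,
      confusionColNorm = cn, curves = curves, ap = ap, map = map,
      bestF1 = bestF1, bestConfidence = bestConf, iouMin = iouMin)
}

#' Read and write detection tables
#'
#' Detections CSV columns: stream_id, frame, camera, x1, y1, x2, y2, class,
#' confidence (header mandatory, one row per detection).
#'
#' @param path file path
#' @return `readDetections()` a detections data.frame
#' @export
readDetections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "camera", "x1", "y1", "x2", "y2", "class", "confidence")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detections file lacks columns: ",
                         paste(miss, collapse = ", "))
  d
}

#' @rdname readDetections
#' @param detections data.frame to write
#' @param streamId stream identifier added when absent
#' @export
writeDetections <- function(detections, path, streamId = "stream") {
  if (!"stream_id" %in% names(detections))
    detections <- cbind(stream_id = streamId, detections)
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' Read YOLO-format detections
#'
#' Reads per-image YOLO text files (`class cx cy w h [confidence]`, all box
#' fields normalized to the image size) and converts them to corner-pixel
#' detections.
#'
#' @param path YOLO text file for one image
#' @param imageSize image width, height in pixels
#' @param classes class vocabulary mapping the integer class ids
#' @param frame,camera values for the emitted rows
#' @return detections data.frame
#' @export
readYoloDetections <- function(path, imageSize, classes = defaultClasses(),
                               frame = 1L, camera = "left") {
  raw <- utils::read.table(path, header = FALSE,
                           col.names = c("cls", "cx", "cy", "w", "h",
                                         "confidence")[1:6],
                           fill = TRUE)
  if (all(is.na(raw$confidence))) raw$confidence <- 1
  data.frame(frame = frame, camera = camera,
             x1 = (raw$cx - raw$w / 2) * imageSize[1],
             y1 = (raw$cy - raw$h / 2) * imageSize[2],
             x2 = (raw$cx + raw$w / 2) * imageSize[1],
             y2 = (raw$cy + raw$h / 2) * imageSize[2],
             class = classes[raw$cls + 1L],
             confidence = raw$confidence)
}
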