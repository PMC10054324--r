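#' @import methods
NULL

#' Camera intrinsics with lens distortion
#'
#' Intrinsic parameters of a single pinhole camera extended by the usual
#' five-coefficient polynomial lens-distortion model (radial k1, k2, k3 and
#' tangential p1, p2).  Pixel coordinates have their origin at the top-left
#' image corner, x to the right and y downwards, with continuous coordinates
#' at pixel centers.
#'
#' @slot fx,fy focal lengths in pixels (> 0)
#' @slot cx,cy principal point in pixels
#' @slot dist named numeric of length 5: k1, k2, p1, p2, k3 (dimensionless,
#'   applied to normalized image coordinates)
#' @slot imageSize integer width, height in pixels
#'
#' @seealso [cameraIntrinsics()], [projectPoints()], [undistortPoints()]
#' @export
setClass("CameraIntrinsics",
  representation(
    fx = "numeric", fy = "numeric",
    cx = "numeric", cy = "numeric",
    dist = "numeric",
    imageSize = "integer"
  )
)

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  if (length(object@fx) != 1 || !is.finite(object@fx) || object@fx <= 0)
    msg <- c(msg, "fx must be a single positive finite number")
  if (length(object@fy) != 1 || !is.finite(object@fy) || object@fy <= 0)
    msg <- c(msg, "fy must be a single positive finite number")
  if (length(object@cx) != 1 || !is.finite(object@cx))
    msg <- c(msg, "cx must be finite")
  if (length(object@cy) != 1 || !is.finite(object@cy))
    msg <- c(msg, "cy must be finite")
  if (length(object@dist) != 5 || any(!is.finite(object@dist)))
    msg <- c(msg, "dist must be 5 finite coefficients (k1, k2, p1, p2, k3)")
  if (length(object@imageSize) != 2 || any(object@imageSize < 1))
    msg <- c(msg, "imageSize must be two positive integers (width, height)")
  if (length(msg)) msg else TRUE
})

#' Construct camera intrinsics
#'
#' @param fx,fy focal lengths in pixels
#' @param cx,cy principal point in pixels; defaults to the image center
#' @param dist distortion coefficients, recycled/zero-padded to length 5 in
#'   the order k1, k2, p1, p2, k3
#' @param imageSize image width and height in pixels
#' @return a [CameraIntrinsics-class] object
#' @examples
#' cam <- cameraIntrinsics(1400, 1400, imageSize = c(1280, 1024))
#' @export
cameraIntrinsics <- function(fx, fy = fx, cx = imageSize[1] / 2,
                             cy = imageSize[2] / 2, dist = numeric(5),
                             imageSize = c(1280L, 1024L)) {
  d <- numeric(5)
  d[seq_along(dist)] <- dist
  names(d) <- c("k1", "k2", "p1", "p2", "k3")
  new("CameraIntrinsics", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy), dist = d,
      imageSize = as.integer(imageSize))
}

#' Calibrated stereo rig
#'
#' Two cameras plus the pose of the right camera in the left-camera frame.
#' All 3D quantities are expressed in millimetres in the left-camera frame
#' (z forward, x right, y down).  `rotation` is the orientation of the right
#' camera (its camera-to-left-frame rotation) and `translation` the position
#' of the right camera center, so a left-frame point `X` has right-camera
#' coordinates `t(rotation) %*% (X - translation)`.
#'
#' @slot left,right [CameraIntrinsics-class] of the two cameras
#' @slot rotation 3x3 orthonormal rotation, determinant +1
#' @slot translation length-3 numeric, millimetres; the baseline is its norm
#'
#' @seealso [stereoRig()], [makeRig()], [rectify()]
#' @export
setClass("StereoRig",
  representation(
    left = "CameraIntrinsics", right = "CameraIntrinsics",
    rotation = "matrix", translation = "numeric"
  )
)

setValidity("StereoRig", function(object) {
  msg <- character()
  R <- object@rotation
  if (!is.numeric(R) || !all(dim(R) == c(3, 3))) {
    msg <- c(msg, "rotation must be a 3x3 numeric matrix")
  } else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msg <- c(msg, "rotation must be orthonormal (tolerance 1e-9)")
    if (abs(det(R) - 1) > 1e-9)
      msg <- c(msg, "rotation must have determinant +1")
  }
  if (length(object@translation) != 3 || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be a finite 3-vector")
  else if (sqrt(sum(object@translation^2)) <= 0)
    msg <- c(msg, "baseline (norm of translation) must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a stereo rig
#'
#' @param left,right [CameraIntrinsics-class] objects
#' @param rotation 3x3 rotation of the right camera w.r.t. the left
#' @param translation position of the right camera center in the left frame,
#'   millimetres
#' @return a [StereoRig-class] object
#' @export
stereoRig <- function(left, right, rotation = diag(3),
                      translation = c(120, 0, 0)) {
  new("StereoRig", left = left, right = right,
      rotation = rotation, translation = as.numeric(translation))
}

#' Epipolar-rectified stereo rig
#'
#' A virtual pair of row-aligned pinhole cameras derived from a calibrated
#' [StereoRig-class].  A 3D point projected through both rectified cameras
#' lands on the same row, so stereo correspondence search reduces to a
#' horizontal (epipolar) line and depth follows from the column disparity as
#' `z = focal * baseline / disparity`.
#'
#' @slot rig the source [StereoRig-class]
#' @slot Rl,Rr 3x3 rectifying rotations applied to left/right camera-frame
#'   rays
#' @slot focal common rectified focal length, pixels
#' @slot cx,cy common rectified principal point, pixels
#' @slot baseline rectified baseline, millimetres
#'
#' @seealso [rectify()], [rectifyPixels()], [triangulate()]
#' @export
setClass("RectifiedRig",
  representation(
    rig = "StereoRig",
    Rl = "matrix", Rr = "matrix",
    focal = "numeric", cx = "numeric", cy = "numeric",
    baseline = "numeric"
  )
)

#' Checkerboard calibration-target specification
#'
#' The physical calibration target: a checkerboard of `squaresX` by
#' `squaresY` squares of side `squareMm`.  Its detectable inner-corner grid
#' has `(squaresX - 1) x (squaresY - 1)` points.
#'
#' @slot squaresX,squaresY number of squares along each side (>= 2)
#' @slot squareMm square side length, millimetres (> 0)
#' @seealso [boardSpec()], [projectCheckerboard()], [boardErrors()]
#' @export
setClass("BoardSpec",
  representation(squaresX = "integer", squaresY = "integer",
                 squareMm = "numeric")
)

setValidity("BoardSpec", function(object) {
  msg <- character()
  if (object@squaresX < 2 || object@squaresY < 2)
    msg <- c(msg, "need at least 2 squares per side")
  if (!is.finite(object@squareMm) || object@squareMm <= 0)
    msg <- c(msg, "squareMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a checkerboard specification
#'
#' Defaults describe a 9 x 8 board with 50 mm squares (8 x 7 inner corners).
#'
#' @param squaresX,squaresY squares along each side
#' @param squareMm square side, millimetres
#' @return a [BoardSpec-class] object
#' @export
boardSpec <- function(squaresX = 9, squaresY = 8, squareMm = 50) {
  new("BoardSpec", squaresX = as.integer(squaresX),
      squaresY = as.integer(squaresY), squareMm = as.numeric(squareMm))
}

#' Detection-evaluation result
#'
#' Output container of [evaluateDetections()]: a confusion matrix with an
#' extra background class, per-class precision/recall/F1 curves over a
#' confidence grid, per-class average precision at the chosen IoU threshold
#' and their mean (mAP).
#'
#' Confusion-matrix layout: rows are true classes, columns predicted classes.
#' A ground-truth box left unmatched at the matrix confidence threshold
#' counts in its class row under the `background` column (a miss); a
#' detection matching no ground truth counts in the `background` row under
#' its predicted column (a false positive).  Row sums over the true-class
#' rows therefore equal the per-class ground-truth instance counts, and the
#' background-row sum is the total number of false positives.
#'
#' @slot confusion raw-count confusion matrix, (N+1) x (N+1)
#' @slot confusionRowNorm row-normalized view (rows sum to 1 where defined)
#' @slot confusionColNorm column-normalized view
#' @slot curves data.frame: confidence, class, tp, fp, fn, precision,
#'   recall, f1
#' @slot ap named per-class average precision
#' @slot map mean average precision over the evaluated classes
#' @slot bestF1 maximum mean F1 over the confidence grid
#' @slot bestConfidence confidence at which `bestF1` is attained
#' @slot iouMin IoU acceptance threshold used for matching
#' @export
setClass("EvaluationResult",
  representation(
    confusion = "matrix",
    confusionRowNorm = "matrix",
    confusionColNorm = "matrix",
    curves = "data.frame",
    ap = "numeric",
    map = "numeric",
    bestF1 = "numeric",
    bestConfidence = "numeric",
    iouMin = "numeric"
  )
)

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics: f = (%.2f, %.2f) px, c = (%.2f, %.2f) px, %d x %d image\n",
              object@fx, object@fy, object@cx, object@cy,
              object@imageSize[1], object@imageSize[2]))
  cat("  distortion:", paste(sprintf("%s=%.4g", names(object@dist), object@dist),
                             collapse = ", "), "\n")
})

setMethod("show", "StereoRig", function(object) {
  cat(sprintf("StereoRig: baseline %.2f mm\n", baseline(object)))
  cat("left  "); show(object@left)
  cat("right "); show(object@right)
})

setMethod("show", "RectifiedRig", function(object) {
  cat(sprintf("RectifiedRig: focal %.2f px, baseline %.2f mm, principal (%.2f, %.2f)\n",
              object@focal, object@baseline, object@cx, object@cy))
})

setMethod("show", "BoardSpec", function(object) {
  cat(sprintf("BoardSpec: %d x %d squares of %.1f mm (%d x %d inner corners)\n",
              object@squaresX, object@squaresY, object@squareMm,
              object@squaresX - 1L, object@squaresY - 1L))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult: mAP@%.2f = %.4f over %d classes; best mean F1 = %.4f at confidence %.3f\n",
              object@iouMin, object@map, length(object@ap),
              object@bestF1, object@bestConfidence))
})

#' Baseline of a stereo rig
#'
#' @param rig a [StereoRig-class] or [RectifiedRig-class]
#' @return baseline in millimetres
#' @export
baseline <- function(rig) {
  if (is(rig, "RectifiedRig")) return(rig@baseline)
  sqrt(sum(rig@translation^2))
}

#' Accessors for evaluation results
#'
#' @param x an [EvaluationResult-class]
#' @param normalize `"none"`, `"row"` or `"column"` view of the confusion
#'   matrix
#' @return `confusionMatrix()` the requested matrix; `meanAP()` the scalar
#'   mAP; `apByClass()` the named per-class AP vector; `prCurves()` the
#'   threshold-indexed precision/recall/F1 table.
#' @export
confusionMatrix <- function(x, normalize = c("none", "row", "column")) {
  normalize <- match.arg(normalize)
  switch(normalize, none = x@confusion, row = x@confusionRowNorm,
         column = x@confusionColNorm)
}

#' @rdname confusionMatrix
#' @export
meanAP <- function(x) x@map

#' @rdname confusionMatrix
#' @export
apByClass <- function(x) x@ap

#' @rdname confusionMatrix
#' @export
prCurves <- function(x) x@curves
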