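# Metric backbone: pinhole + distortion projection, undistortion, epipolar
# rectification, triangulation and reprojection error.  All 3D coordinates
# are millimetres in the left-camera frame (z forward, x right, y down);
# pixel origin is the top-left corner with continuous coordinates at pixel
# centers.

as_points3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = FALSE)
  if (ncol(x) != 3) stop("3D points must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

as_points2 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  if (ncol(x) != 2) stop("pixel coordinates must be an n x 2 matrix")
  storage.mode(x) <- "double"
  x
}

# Apply the radial/tangential distortion polynomial to normalized image
# coordinates (n x 2).
distort_normalized <- function(cam, xy) {
  k <- cam@dist
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + k[["k1"]] * r2 + k[["k2"]] * r2^2 + k[["k3"]] * r2^3
  xd <- x * radial + 2 * k[["p1"]] * x * y + k[["p2"]] * (r2 + 2 * x^2)
  yd <- y * radial + k[["p1"]] * (r2 + 2 * y^2) + 2 * k[["p2"]] * x * y
  cbind(xd, yd, deparse.level = 0)
}

#' Project 3D points through a camera
#'
#' Forward model: transform points into the camera frame (pose given by the
#' camera's orientation `R` and center `center` in the world/left frame),
#' perspective-divide, apply the distortion polynomial and map to pixels.
#' With all distortion coefficients zero this is the pure pinhole projection
#' `(fx * x/z + cx, fy * y/z + cy)`.
#'
#' @param cam a [CameraIntrinsics-class]
#' @param points n x 3 matrix (or length-3 vector) of 3D points, mm
#' @param R 3x3 camera orientation in the world frame (camera-to-world)
#' @param center camera center in the world frame, mm
#' @return n x 2 matrix of distorted pixel coordinates
#' @details Points at or behind the optical center (`z <= 0` in the camera
#'   frame) are not projectable and raise an error.
#' @examples
#' cam <- cameraIntrinsics(1400, imageSize = c(1280, 1024))
#' projectPoints(cam, c(0, 0, 1500))   # principal point
#' @export
projectPoints <- function(cam, points, R = diag(3), center = c(0, 0, 0)) {
  P <- as_points3(points)
  Pc <- sweep(P, 2, as.numeric(center)) %*% R  # == t(R) %*% (P - center) rowwise
  if (any(Pc[, 3] <= 0))
    stop("point at or behind the optical center is not projectable")
  xy <- Pc[, 1:2, drop = FALSE] / Pc[, 3]
  d <- distort_normalized(cam, xy)
  cbind(cam@fx * d[, 1] + cam@cx, cam@fy * d[, 2] + cam@cy,
        deparse.level = 0)
}

#' Undistort pixel coordinates
#'
#' Inverts the distortion polynomial by fixed-point iteration on normalized
#' coordinates (at most `maxIter` iterations, convergence tolerance `tol` in
#' normalized units).  Returns ideal-pinhole pixel coordinates: re-applying
#' the distortion model recovers the input.
#'
#' @param cam a [CameraIntrinsics-class]
#' @param pixels n x 2 matrix of observed (distorted) pixel coordinates
#' @param maxIter iteration budget
#' @param tol convergence tolerance, normalized units
#' @return n x 2 matrix of undistorted pixel coordinates
#' @export
undistortPoints <- function(cam, pixels, maxIter = 20L, tol = 1e-8) {
  px <- as_points2(pixels)
  if (any(!is.finite(px))) stop("pixel coordinates must be finite")
  xd <- (px[, 1] - cam@cx) / cam@fx
  yd <- (px[, 2] - cam@cy) / cam@fy
  k <- cam@dist
  x <- xd; y <- yd
  if (any(k != 0)) {
    converged <- FALSE
    for (i in seq_len(maxIter)) {
      r2 <- x^2 + y^2
      radial <- 1 + k[["k1"]] * r2 + k[["k2"]] * r2^2 + k[["k3"]] * r2^3
      dx <- 2 * k[["p1"]] * x * y + k[["p2"]] * (r2 + 2 * x^2)
      dy <- k[["p1"]] * (r2 + 2 * y^2) + 2 * k[["p2"]] * x * y
      xn <- (xd - dx) / radial
      yn <- (yd - dy) / radial
      if (max(abs(xn - x), abs(yn - y)) < tol) {
        x <- xn; y <- yn; converged <- TRUE
        break
      }
      x <- xn; y <- yn
    }
    if (!converged)
      stop("undistortion did not converge: pixel outside the distortion model")
  }
  cbind(cam@fx * x + cam@cx, cam@fy * y + cam@cy, deparse.level = 0)
}

#' Rectify a stereo rig
#'
#' Computes the pair of virtual row-aligned cameras for a calibrated rig
#' (Bouguet-style): the new x-axis is the baseline direction, both cameras
#' share one rectifying orientation, a common focal length (mean of the four
#' input focals) and a common principal point (mean of the two).  After
#' rectification a 3D point projects to equal rows in both views and the
#' correspondence search is a horizontal epipolar line.
#'
#' @param rig a [StereoRig-class]
#' @param ... unused
#' @return a [RectifiedRig-class]
#' @export
setGeneric("rectify", function(rig, ...) standardGeneric("rectify"))

#' @rdname rectify
#' @export
setMethod("rectify", "StereoRig", function(rig, ...) {
  t <- rig@translation
  B <- sqrt(sum(t^2))
  if (B <= .Machine$double.eps)
    stop("degenerate rig: zero baseline")
  e1 <- t / B
  e2 <- crossprod_3(c(0, 0, 1), e1)
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-12)  # baseline (anti)parallel to z: no valid horizontal axis
    stop("degenerate rig: baseline along the optical axis")
  e2 <- e2 / n2
  e3 <- crossprod_3(e1, e2)
  Rrect <- rbind(e1, e2, e3, deparse.level = 0)
  focal <- mean(c(rig@left@fx, rig@left@fy, rig@right@fx, rig@right@fy))
  new("RectifiedRig", rig = rig,
      Rl = Rrect, Rr = Rrect %*% rig@rotation,
      focal = focal,
      cx = mean(c(rig@left@cx, rig@right@cx)),
      cy = mean(c(rig@left@cy, rig@right@cy)),
      baseline = B)
})

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Map raw pixels into the rectified frame
#'
#' Undistorts raw pixel observations, rotates the corresponding viewing rays
#' by the camera's rectifying rotation and reprojects with the rectified
#' intrinsics.
#'
#' @param rect a [RectifiedRig-class]
#' @param pixels n x 2 raw pixel coordinates
#' @param camera `"left"` or `"right"`
#' @return n x 2 rectified pixel coordinates
#' @export
rectifyPixels <- function(rect, pixels, camera = c("left", "right")) {
  camera <- match.arg(camera)
  cam <- if (camera == "left") rect@rig@left else rect@rig@right
  Rr <- if (camera == "left") rect@Rl else rect@Rr
  und <- undistortPoints(cam, pixels)
  rays <- cbind((und[, 1] - cam@cx) / cam@fx,
                (und[, 2] - cam@cy) / cam@fy, 1)
  rot <- rays %*% t(Rr)
  cbind(rect@focal * rot[, 1] / rot[, 3] + rect@cx,
        rect@focal * rot[, 2] / rot[, 3] + rect@cy,
        deparse.level = 0)
}

#' Triangulate stereo correspondences
#'
#' Recovers 3D points (mm, left-camera frame) from corresponding pixel
#' observations in the two views.  Raw pixels (default) are first
#' undistorted and rectified; already-rectified coordinates can be passed
#' with `rectified = TRUE`.  In the rectified frame depth follows the
#' disparity relation `z = focal * baseline / (col_left - col_right)`.
#'
#' Rows of a correspondence should agree up to noise; a row disagreement
#' beyond `epipolarTol` pixels triggers a warning and the rows are averaged.
#' Non-positive disparity means a point at infinity or a matching error and
#' raises an error.
#'
#' @param rect a [RectifiedRig-class]
#' @param left,right n x 2 pixel coordinates of the correspondences
#' @param rectified are the inputs already rectified coordinates?
#' @param epipolarTol row-disagreement tolerance before warning, pixels
#' @return n x 3 matrix of 3D points, mm, left-camera frame
#' @export
triangulate <- function(rect, left, right, rectified = FALSE,
                        epipolarTol = 2.0) {
  L <- as_points2(left); R <- as_points2(right)
  if (nrow(L) != nrow(R)) stop("left/right correspondence counts differ")
  if (!rectified) {
    L <- rectifyPixels(rect, L, "left")
    R <- rectifyPixels(rect, R, "right")
  }
  disp <- L[, 1] - R[, 1]
  if (any(disp <= 0))
    stop("non-positive disparity: point at infinity or matching error")
  drow <- abs(L[, 2] - R[, 2])
  if (any(drow > epipolarTol))
    warning(sprintf("%d correspondence(s) exceed the epipolar row tolerance (%.2f px); rows averaged",
                    sum(drow > epipolarTol), epipolarTol))
  v <- (L[, 2] + R[, 2]) / 2
  z <- rect@focal * rect@baseline / disp
  x <- (L[, 1] - rect@cx) * z / rect@focal
  y <- (v - rect@cy) * z / rect@focal
  Xr <- cbind(x, y, z, deparse.level = 0)
  Xr %*% rect@Rl  # rows X_l = t(Rl) %*% X_rect
}

#' Mean reprojection error
#'
#' Mean Euclidean pixel distance between the model projections of known 3D
#' points and their observed pixel positions, pooled over whichever cameras
#' observations are supplied for.
#'
#' @param rig a [StereoRig-class]
#' @param points3d n x 3 matrix of 3D points, mm, left-camera frame
#' @param left,right n x 2 observed pixel coordinates (either may be NULL)
#' @return mean reprojection error in pixels (>= 0)
#' @export
reprojectionError <- function(rig, points3d, left = NULL, right = NULL) {
  P <- as_points3(points3d)
  errs <- numeric()
  if (!is.null(left)) {
    obs <- as_points2(left)
    if (nrow(obs) != nrow(P)) stop("point/observation lengths differ")
    proj <- projectPoints(rig@left, P)
    errs <- c(errs, sqrt(rowSums((proj - obs)^2)))
  }
  if (!is.null(right)) {
    obs <- as_points2(right)
    if (nrow(obs) != nrow(P)) stop("point/observation lengths differ")
    proj <- projectPoints(rig@right, P, R = rig@rotation,
                          center = rig@translation)
    errs <- c(errs, sqrt(rowSums((proj - obs)^2)))
  }
  if (!length(errs)) stop("no observations supplied")
  mean(errs)
}

#' Read and write stereo calibration files
#'
#' Calibration files are YAML (or JSON, a YAML subset) with a `left` and a
#' `right` camera block (3x3 `camera_matrix` row-major, 5-coefficient
#' `distortion` in the order k1, k2, p1, p2, k3, `image_size`) and the
#' inter-camera `rotation` (3x3 row-major or Rodrigues 3-vector) and
#' `translation` (mm).  The reader validates all rig invariants; the writer
#' round-trips decimal representations exactly.
#'
#' @param path file path
#' @return `readCalibration()` a [StereoRig-class]
#' @export
readCalibration <- function(path) {
  y <- yaml::read_yaml(path)
  cam <- function(b) {
    K <- matrix(as.numeric(unlist(b$camera_matrix)), 3, 3, byrow = TRUE)
    cameraIntrinsics(fx = K[1, 1], fy = K[2, 2], cx = K[1, 3], cy = K[2, 3],
                     dist = as.numeric(unlist(b$distortion)),
                     imageSize = as.integer(unlist(b$image_size)))
  }
  rot <- as.numeric(unlist(y$rotation))
  R <- if (length(rot) == 9) matrix(rot, 3, 3, byrow = TRUE)
       else rodrigues(rot)
  stereoRig(cam(y$left), cam(y$right), rotation = R,
            translation = as.numeric(unlist(y$translation)))
}

#' @rdname readCalibration
#' @param rig a [StereoRig-class] to serialize
#' @export
writeCalibration <- function(rig, path) {
  cam <- function(c) list(
    camera_matrix = lapply(seq_len(3), function(i)
      as.list(c(matrix(c(c@fx, 0, c@cx, 0, c@fy, c@cy, 0, 0, 1),
                       3, 3, byrow = TRUE)[i, ]))),
    distortion = as.list(unname(c@dist)),
    image_size = as.list(as.integer(c@imageSize)))
  y <- list(left = cam(rig@left), right = cam(rig@right),
            rotation = lapply(seq_len(3), function(i)
              as.list(rig@rotation[i, ])),
            translation = as.list(rig@translation))
  yaml::write_yaml(y, path, precision = 17)
  invisible(path)
}

# Rodrigues rotation vector -> matrix.
rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Euler angles (degrees) -> rotation matrix, applied as Rz(roll) Ry(yaw) Rx(pitch).
euler_rotation <- function(pitch = 0, yaw = 0, roll = 0) {
  d <- pi / 180
  cx <- cos(pitch * d); sx <- sin(pitch * d)
  cy <- cos(yaw * d);   sy <- sin(yaw * d)
  cz <- cos(roll * d);  sz <- sin(roll * d)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
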