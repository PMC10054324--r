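# Independent oracles used to cross-check the implementation paths.

# Two-ray least-squares triangulation: intersect the left and right viewing
# rays (undistorted, expressed in the left-camera frame) by minimizing the
# summed squared distance of a 3D point to both rays.  Independent of the
# rectification-based triangulation path.
lsq_triangulate <- function(rig, pxL, pxR) {
  uL <- undistortPoints(rig@left, pxL)
  uR <- undistortPoints(rig@right, pxR)
  out <- matrix(NA_real_, nrow(uL), 3)
  for (i in seq_len(nrow(uL))) {
    dL <- c((uL[i, 1] - rig@left@cx) / rig@left@fx,
            (uL[i, 2] - rig@left@cy) / rig@left@fy, 1)
    dR <- rig@rotation %*% c((uR[i, 1] - rig@right@cx) / rig@right@fx,
                             (uR[i, 2] - rig@right@cy) / rig@right@fy, 1)
    # point X minimizing sum of squared distances to lines (o_k, d_k):
    # sum_k (I - d d^T / |d|^2) X = sum_k (I - d d^T / |d|^2) o_k
    A <- matrix(0, 3, 3); b <- numeric(3)
    for (ray in list(list(o = c(0, 0, 0), d = dL),
                     list(o = rig@translation, d = c(dR)))) {
      P <- diag(3) - tcrossprod(ray$d) / sum(ray$d^2)
      A <- A + P; b <- b + P %*% ray$o
    }
    out[i, ] <- solve(A, b)
  }
  out
}

# Set-based non-maximum suppression oracle: repeatedly select the global
# highest-confidence survivor and delete everything it overlaps.
nms_oracle <- function(det, thr) {
  remaining <- seq_len(nrow(det))
  kept <- integer()
  while (length(remaining)) {
    i <- remaining[which.max(det$confidence[remaining])]
    kept <- c(kept, i)
    ious <- boxIoU(matrix(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                          length(remaining), 4, byrow = TRUE),
                   as.matrix(det[remaining, c("x1", "y1", "x2", "y2")]))
    remaining <- remaining[!(ious > thr) & remaining != i]
  }
  det[sort(kept), , drop = FALSE]
}

# All-threshold average-precision oracle: walk every prefix of the ranked
# TP flags, build the raw PR set, and integrate the upper precision
# envelope over recall.
ap_oracle <- function(tp, nGT) {
  if (nGT == 0) return(NA_real_)
  if (!length(tp)) return(0)
  pr <- t(vapply(seq_along(tp), function(k) {
    ntp <- sum(tp[1:k])
    c(r = ntp / nGT, p = ntp / k)
  }, numeric(2)))
  rs <- sort(unique(pr[, "r"]))
  ap <- 0; prev <- 0
  for (r in rs) {
    penv <- max(pr[pr[, "r"] >= r, "p"])  # best precision at recall >= r
    ap <- ap + (r - prev) * penv
    prev <- r
  }
  ap
}

# Exhaustive maximum-score-sum assignment over a score matrix (zero scores
# unusable), by recursion over the left side.  Returns the best total and
# one optimal match set.
assignment_oracle <- function(S) {
  nl <- nrow(S); nr <- ncol(S)
  best <- list(total = 0, pairs = matrix(integer(), 0, 2))
  rec <- function(i, usedR, total, pairs) {
    if (i > nl) {
      if (total > best$total)
        best <<- list(total = total, pairs = pairs)
      return()
    }
    if (total + sum(apply(S[i:nl, , drop = FALSE], 1, max)) < best$total)
      return()
    rec(i + 1, usedR, total, pairs)  # leave i unmatched
    for (j in seq_len(nr)) {
      if (!usedR[j] && S[i, j] > 0) {
        u <- usedR; u[j] <- TRUE
        rec(i + 1, u, total + S[i, j], rbind(pairs, c(i, j)))
      }
    }
  }
  if (nl > 0 && nr > 0) rec(1, logical(nr), 0, matrix(integer(), 0, 2))
  best
}

# Score matrix for a left/right detection pair set under a MatchConfig.
score_matrix <- function(L, R, config) {
  S <- matrix(0, nrow(L), nrow(R))
  for (i in seq_len(nrow(L))) for (j in seq_len(nrow(R)))
    S[i, j] <- matchScore(as.numeric(L[i, c("x1", "y1", "x2", "y2")]),
                          as.numeric(R[j, c("x1", "y1", "x2", "y2")]),
                          L$class[i], R$class[j], config)$score
  S
}

# Checkerboard corner table for one posed board, tagged with an image id.
board_corners <- function(rig, boardR = diag(3), boardT = c(0, 0, 1200),
                          noiseSd = 0, seed = NULL, image_id = 1L) {
  cb <- projectCheckerboard(rig, boardR, boardT, noiseSd = noiseSd,
                            seed = seed)
  cb$image_id <- image_id
  cb
}

# Rotation about x (pitch) then y (yaw), degrees; used to pose boards.
euler_rig_rot <- function(pitch = 0, yaw = 0) {
  p <- pitch * pi / 180; y <- yaw * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(p), -sin(p), 0, sin(p), cos(p)), 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(y), 0, sin(y), 0, 1, 0, -sin(y), 0, cos(y)), 3,
               byrow = TRUE)
  Ry %*% Rx
}

# Default synthetic test rigs.
rig_default <- function(...) makeRig(...)
rig_yawed <- function() makeRig(yawDeg = 2, pitchDeg = 0.5)
rig_distorted <- function() makeRig(distortion = c(-0.1, 0.02, 5e-4, -5e-4, 0.001))

random_points <- function(n, zmin = 300, zmax = 5000) {
  cbind(stats::runif(n, -300, 300), stats::runif(n, -250, 250),
        stats::runif(n, zmin, zmax))
}

# A one-fish crossing scene used by several tests.
crossing_scene <- function(rig = makeRig(), z = 1500, lengthMm = 300,
                           heightMm = 100, frames = 5:45, nFrames = 50,
                           jitterSd = 0, dropout = 0, fpRate = 0, seed = 1,
                           species = "Gadus morhua") {
  x <- 0.25 * z * c(-1, 1)  # stays inside the field of view
  cfg <- sceneConfig(rig, targets = list(
    sceneTarget(species, lengthMm, heightMm = heightMm,
                waypoints = rbind(c(x[1], 0, z), c(x[2], 0, z)),
                frames = frames)),
    jitterSd = jitterSd, dropout = dropout, fpRate = fpRate,
    nFrames = nFrames, seed = seed)
  list(config = cfg, scene = simulateFishScene(cfg))
}
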