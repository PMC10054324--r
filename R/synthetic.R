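# Synthetic fixtures: virtual calibrated rigs, projected checkerboards and
# moving fish/jellyfish scenes with noisy detections and renderable frames.
# Defaults emulate the stationary observatory setup this package targets:
# a 120 mm baseline monochrome stereo pair recording 1280 x 1024 at 20 fps,
# calibrated with a 9 x 8 / 50 mm checkerboard at 0.5-2.0 m.

#' Default species vocabulary
#'
#' The ten marine object categories used throughout the package:
#' four jellyfish-type and six fish-type classes.
#'
#' @return character vector of class labels
#' @export
defaultClasses <- function() {
  c("Ctenophora", "Aurelia aurita", "Cyanea capillata", "Gadus morhua",
    "Fish unspecified", "Clupeidae", "Jellyfish unspecified", "Salmonidae",
    "Scomber scombrus", "Pleuronectoidei")
}

#' Build a virtual calibrated stereo rig
#'
#' Constructs a [StereoRig-class] with the right camera translated along +x
#' by `baselineMm` and optionally misaligned by small Euler angles.
#'
#' @param baselineMm stereo baseline, millimetres
#' @param focalPx focal length of both cameras, pixels
#' @param imageSize image width, height in pixels
#' @param distortion 5 distortion coefficients (k1, k2, p1, p2, k3), both
#'   cameras
#' @param pitchDeg,yawDeg,rollDeg right-camera misalignment, degrees
#' @return a [StereoRig-class]
#' @examples
#' rig <- makeRig()           # 120 mm baseline, f = 1400 px
#' baseline(rig)
#' @export
makeRig <- function(baselineMm = 120, focalPx = 1400,
                    imageSize = c(1280, 1024), distortion = numeric(5),
                    pitchDeg = 0, yawDeg = 0, rollDeg = 0) {
  if (baselineMm <= 0) stop("baseline must be > 0")
  cam <- cameraIntrinsics(focalPx, focalPx, dist = distortion,
                          imageSize = imageSize)
  stereoRig(cam, cam,
            rotation = euler_rotation(pitchDeg, yawDeg, rollDeg),
            translation = c(baselineMm, 0, 0))
}

#' Project a checkerboard into both cameras
#'
#' Places a checkerboard target (inner-corner grid
#' `(squaresX-1) x (squaresY-1)`) at a given pose and projects its inner
#' corners through both cameras of the rig, optionally adding i.i.d.
#' Gaussian pixel noise.  Corners falling outside an image (or behind a
#' camera) are marked unobserved.
#'
#' @param rig a [StereoRig-class]
#' @param boardR 3x3 board orientation in the left-camera frame
#' @param boardT board-center position in the left-camera frame, mm
#' @param spec a [BoardSpec-class]
#' @param noiseSd corner-noise standard deviation per coordinate, pixels
#' @param seed optional integer seed for the noise
#' @return data.frame: camera, grid_i (column index along horizontal lines),
#'   grid_j (row index), px, py, observed
#' @export
projectCheckerboard <- function(rig, boardR = diag(3),
                                boardT = c(0, 0, 1500),
                                spec = boardSpec(), noiseSd = 0,
                                seed = NULL) {
  ni <- spec@squaresX - 1L   # corners per horizontal line
  nj <- spec@squaresY - 1L   # number of horizontal lines
  g <- expand.grid(grid_i = seq_len(ni) - 1L, grid_j = seq_len(nj) - 1L)
  local <- cbind((g$grid_i - (ni - 1) / 2) * spec@squareMm,
                 (g$grid_j - (nj - 1) / 2) * spec@squareMm,
                 0)
  world <- local %*% t(boardR)
  world <- sweep(world, 2, as.numeric(boardT), "+")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  project_cam <- function(camera) {
    cam <- if (camera == "left") rig@left else rig@right
    R <- if (camera == "left") diag(3) else rig@rotation
    ctr <- if (camera == "left") c(0, 0, 0) else rig@translation
    zc <- (sweep(world, 2, ctr) %*% R)[, 3]
    px <- matrix(NA_real_, nrow(world), 2)
    ok <- zc > 0
    if (!any(ok)) stop("board entirely behind the ", camera, " camera")
    px[ok, ] <- projectPoints(cam, world[ok, , drop = FALSE], R, ctr)
    if (noiseSd > 0)
      px[ok, ] <- px[ok, ] + matrix(stats::rnorm(2 * sum(ok), 0, noiseSd),
                                    ncol = 2)
    inside <- ok & px[, 1] >= 0 & px[, 1] <= cam@imageSize[1] &
      px[, 2] >= 0 & px[, 2] <= cam@imageSize[2]
    data.frame(camera = camera, grid_i = g$grid_i, grid_j = g$grid_j,
               px = px[, 1], py = px[, 2], observed = inside)
  }
  rbind(project_cam("left"), project_cam("right"))
}

#' Scene configuration for the synthetic generator
#'
#' @param rig a [StereoRig-class]
#' @param targets list of targets from [sceneTarget()]
#' @param jitterSd box-corner jitter standard deviation, pixels
#' @param dropout per-detection dropout probability
#' @param fpRate expected false positives per frame per camera
#' @param confusion probability a detection's label is swapped for another
#'   class
#' @param fps frame rate, frames per second
#' @param nFrames number of frames simulated
#' @param classes class vocabulary used for labels and false positives
#' @param seed integer seed controlling all randomness of the scene
#' @return a `SceneConfig` list
#' @export
sceneConfig <- function(rig = makeRig(), targets = list(), jitterSd = 0.5,
                        dropout = 0.05, fpRate = 0.02, confusion = 0,
                        fps = 20, nFrames = 50, classes = defaultClasses(),
                        seed = 1L) {
  stopifnot(dropout >= 0, dropout <= 1, confusion >= 0, confusion <= 1,
            fpRate >= 0, fps > 0, nFrames >= 1,
            all(rig@left@imageSize >= 64))
  structure(list(rig = rig, targets = targets, jitterSd = jitterSd,
                 dropout = dropout, fpRate = fpRate, confusion = confusion,
                 fps = fps, nFrames = as.integer(nFrames), classes = classes,
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

#' Define a moving target
#'
#' A target is a 3D ellipsoid (length along x, height along y, width along
#' z) following a piecewise-linear trajectory through `waypoints` over its
#' visible frame span.
#'
#' @param species class label
#' @param lengthMm,heightMm,widthMm true target dimensions, mm
#' @param waypoints k x 3 matrix of 3D waypoints, mm, left-camera frame
#' @param frames integer vector of frame indices the target exists in
#' @return a target description list
#' @export
sceneTarget <- function(species, lengthMm, heightMm = lengthMm / 3,
                        widthMm = heightMm, waypoints, frames) {
  stopifnot(lengthMm > 0, heightMm > 0, widthMm > 0)
  waypoints <- as_points3(waypoints)
  list(species = species, lengthMm = lengthMm, heightMm = heightMm,
       widthMm = widthMm, waypoints = waypoints,
       frames = as.integer(frames))
}

# 26 extremal surface samples of a unit ball: all sign combinations of
# {-1,0,1}^3 minus the origin, normalized.  Scaled by the semi-axes these
# include the six axis extremes exactly, so the projected axis-aligned hull
# is a tight bounding box for fronto-parallel targets.
ellipsoid_dirs <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  d / sqrt(rowSums(d^2))
}

target_center <- function(target, frame) {
  f <- target$frames
  if (length(f) == 1 || nrow(target$waypoints) == 1)
    return(target$waypoints[1, ])
  s <- (frame - f[1]) / (f[length(f)] - f[1])  # 0..1 along the trajectory
  k <- nrow(target$waypoints)
  seg <- s * (k - 1)
  i <- min(floor(seg), k - 2)
  w <- seg - i
  (1 - w) * target$waypoints[i + 1, ] + w * target$waypoints[i + 2, ]
}

#' Simulate a stereo fish scene
#'
#' Generates per-frame per-camera ground-truth boxes (the image-axis-aligned
#' hull of 26 projected ellipsoid surface points per target) and a noisy
#' detection stream: corner jitter, detection dropout, uniformly placed
#' false positives with labels drawn from the class vocabulary, and optional
#' class confusion.  True-positive confidences are drawn from Beta(8, 2)
#' and false-positive confidences from Beta(2, 5).
#'
#' @param config a [sceneConfig()]
#' @return list with elements `truth` (frame, camera, track, species,
#'   x1, y1, x2, y2, dist_mm), `detections` (frame, camera, x1, y1, x2, y2,
#'   class, confidence, track, is_fp) and `targets` (track, species,
#'   length_mm, height_mm)
#' @export
simulateFishScene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  rig <- config$rig
  dirs <- ellipsoid_dirs()
  w <- rig@left@imageSize[1]; h <- rig@left@imageSize[2]
  truth <- list()
  for (ti in seq_along(config$targets)) {
    tg <- config$targets[[ti]]
    semi <- c(tg$lengthMm, tg$heightMm, tg$widthMm) / 2
    for (fr in tg$frames) {
      ctr <- target_center(tg, fr)
      pts <- sweep(dirs %*% diag(semi), 2, ctr, "+")
      for (camera in c("left", "right")) {
        R <- if (camera == "left") diag(3) else rig@rotation
        cc <- if (camera == "left") c(0, 0, 0) else rig@translation
        pc <- sweep(pts, 2, cc) %*% R
        if (any(pc[, 3] <= 0)) next
        cam <- if (camera == "left") rig@left else rig@right
        px <- projectPoints(cam, pts, R, cc)
        b <- c(min(px[, 1]), min(px[, 2]), max(px[, 1]), max(px[, 2]))
        b <- c(max(b[1], 0), max(b[2], 0), min(b[3], w), min(b[4], h))
        if (b[3] <= b[1] || b[4] <= b[2]) next
        truth[[length(truth) + 1L]] <- data.frame(
          frame = fr, camera = camera, track = ti, species = tg$species,
          x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
          dist_mm = sqrt(sum(ctr^2)))
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(), camera = character(), track = integer(),
               species = character(), x1 = numeric(), y1 = numeric(),
               x2 = numeric(), y2 = numeric(), dist_mm = numeric())
  if (length(config$targets) && !all(seq_along(config$targets) %in% truth$track))
    message("some targets were never visible and produced no detections")

  det <- truth
  if (nrow(det)) {
    keep <- stats::runif(nrow(det)) >= config$dropout
    det <- det[keep, , drop = FALSE]
  }
  if (nrow(det)) {
    if (config$jitterSd > 0) {
      jit <- matrix(stats::rnorm(4 * nrow(det), 0, config$jitterSd), ncol = 4)
      det$x1 <- det$x1 + jit[, 1]; det$y1 <- det$y1 + jit[, 2]
      det$x2 <- det$x2 + jit[, 3]; det$y2 <- det$y2 + jit[, 4]
      bad <- det$x1 >= det$x2 | det$y1 >= det$y2
      det <- det[!bad, , drop = FALSE]
    }
    det$class <- det$species
    if (config$confusion > 0 && nrow(det)) {
      swap <- stats::runif(nrow(det)) < config$confusion
      if (any(swap)) {
        det$class[swap] <- vapply(det$class[swap], function(cl) {
          pool <- setdiff(config$classes, cl)
          pool[sample.int(length(pool), 1L)]
        }, character(1))
      }
    }
    det$confidence <- stats::rbeta(nrow(det), 8, 2)
    det$is_fp <- FALSE
  } else {
    det <- data.frame(frame = integer(), camera = character(),
                      track = integer(), species = character(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), dist_mm = numeric(),
                      class = character(), confidence = numeric(),
                      is_fp = logical())
  }
  # uniformly placed false positives
  fp <- list()
  for (fr in seq_len(config$nFrames)) {
    for (camera in c("left", "right")) {
      nfp <- stats::rpois(1, config$fpRate)
      if (nfp == 0) next
      for (i in seq_len(nfp)) {
        bw <- stats::runif(1, 0.03, 0.2) * w
        bh <- stats::runif(1, 0.03, 0.2) * h
        x1 <- stats::runif(1, 0, w - bw); y1 <- stats::runif(1, 0, h - bh)
        fp[[length(fp) + 1L]] <- data.frame(
          frame = fr, camera = camera, track = NA_integer_,
          species = NA_character_, x1 = x1, y1 = y1, x2 = x1 + bw,
          y2 = y1 + bh, dist_mm = NA_real_,
          class = config$classes[sample.int(length(config$classes), 1L)],
          confidence = stats::rbeta(1, 2, 5), is_fp = TRUE)
      }
    }
  }
  if (length(fp)) det <- rbind(det, do.call(rbind, fp))
  det <- det[order(det$frame, det$camera, -det$confidence), ]
  rownames(det) <- NULL
  targets <- if (length(config$targets)) data.frame(
    track = seq_along(config$targets),
    species = vapply(config$targets, `[[`, character(1), "species"),
    length_mm = vapply(config$targets, `[[`, numeric(1), "lengthMm"),
    height_mm = vapply(config$targets, `[[`, numeric(1), "heightMm"))
  else data.frame(track = integer(), species = character(),
                  length_mm = numeric(), height_mm = numeric())
  list(truth = truth,
       detections = det[, c("frame", "camera", "x1", "y1", "x2", "y2",
                            "class", "confidence", "track", "is_fp")],
       targets = targets)
}

#' Render monochrome frames for a scene
#'
#' Draws each visible ground-truth target as a filled ellipse inscribed in
#' its box over a static background with additive Gaussian pixel noise.
#' Intended as input for the activity-detection stage; deterministic given
#' `seed`.
#'
#' @param scene output of [simulateFishScene()]
#' @param config the [sceneConfig()] the scene was generated from
#' @param camera `"left"` or `"right"`
#' @param bgLevel background intensity in `[0, 1]`
#' @param noiseSd background pixel-noise standard deviation
#' @param fgLevel target intensity
#' @param seed integer seed for the pixel noise
#' @return list of height x width intensity matrices, one per frame
#' @export
renderFrames <- function(scene, config, camera = "left", bgLevel = 0.3,
                         noiseSd = 0.02, fgLevel = 0.85, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  w <- config$rig@left@imageSize[1]; h <- config$rig@left@imageSize[2]
  tr <- scene$truth[scene$truth$camera == camera, , drop = FALSE]
  lapply(seq_len(config$nFrames), function(fr) {
    m <- matrix(bgLevel + stats::rnorm(w * h, 0, noiseSd), h, w)
    boxes <- tr[tr$frame == fr, , drop = FALSE]
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      cx <- (b$x1 + b$x2) / 2; cy <- (b$y1 + b$y2) / 2
      rx <- max((b$x2 - b$x1) / 2, 1); ry <- max((b$y2 - b$y1) / 2, 1)
      xs <- max(1, floor(b$x1)):min(w, ceiling(b$x2))
      ys <- max(1, floor(b$y1)):min(h, ceiling(b$y2))
      ell <- outer(ys - 0.5 - cy, xs - 0.5 - cx,
                   function(dy, dx) (dx / rx)^2 + (dy / ry)^2 <= 1)
      sub <- m[ys, xs, drop = FALSE]
      sub[ell] <- fgLevel
      m[ys, xs] <- sub
    }
    pmin(pmax(m, 0), 1)
  })
}

#' Write rendered frames as PNG files
#'
#' @param frames list of intensity matrices from [renderFrames()]
#' @param dir output directory (created if needed); files are zero-padded
#'   `frame_000001.png` etc.
#' @return invisibly, the file paths written
#' @export
writeFrames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame_%06d.png", i))
    png::writePNG(frames[[i]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of frames
#'
#' @param dir directory of PNG frames, read in lexicographic order
#' @return list of grayscale intensity matrices
#' @export
readFrames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible()
}
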