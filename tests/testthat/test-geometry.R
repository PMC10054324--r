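# Camera model, rectification, triangulation and reprojection error.

test_that("pinhole projection: axis symmetry and the pinhole identity", {
  cam <- cameraIntrinsics(1400, 1400, dist = numeric(5),
                          imageSize = c(1280, 1024))
  for (z in c(100, 1500, 4000))
    expect_equal(as.numeric(projectPoints(cam, c(0, 0, z))),
                 c(cam@cx, cam@cy))
  set.seed(11)
  P <- random_points(50)
  px <- projectPoints(cam, P)
  expect_equal(px[, 1], cam@fx * P[, 1] / P[, 3] + cam@cx, tolerance = 1e-12)
  expect_equal(px[, 2], cam@fy * P[, 2] / P[, 3] + cam@cy, tolerance = 1e-12)
  expect_error(projectPoints(cam, c(0, 0, -5)), "behind")
  expect_error(projectPoints(cam, c(10, 10, 0)), "behind")
})

test_that("radial distortion matches a directly coded polynomial", {
  cam <- cameraIntrinsics(1400, 1400, dist = c(-0.1, 0, 0, 0, 0),
                          imageSize = c(1280, 1024))
  P <- c(200, -150, 1200)
  px <- projectPoints(cam, P)
  # independent evaluation: normalized coords, r^2, radial factor
  xn <- P[1] / P[3]; yn <- P[2] / P[3]
  r2 <- xn^2 + yn^2
  f <- 1 - 0.1 * r2
  expect_equal(as.numeric(px),
               c(1400 * xn * f + cam@cx, 1400 * yn * f + cam@cy),
               tolerance = 1e-12)
})

test_that("undistortion inverts the distortion model", {
  cam0 <- cameraIntrinsics(1400, imageSize = c(1280, 1024))
  px <- cbind(c(100, 640, 1200), c(50, 512, 1000))
  expect_equal(undistortPoints(cam0, px), px)  # zero distortion: identity

  cam <- rig_distorted()@left
  # principal point is a fixed point for any coefficients
  pp <- cbind(cam@cx, cam@cy)
  expect_equal(undistortPoints(cam, pp), pp)
  # undistort(project(P)) equals the pinhole projection of P
  set.seed(4)
  P <- random_points(200)
  pin <- cbind(cam@fx * P[, 1] / P[, 3] + cam@cx,
               cam@fy * P[, 2] / P[, 3] + cam@cy)
  und <- undistortPoints(cam, projectPoints(cam, P))
  expect_lt(max(abs(und - pin)), 1e-6)
})

test_that("rectification row-aligns both views", {
  # axis-aligned rig: rectifying rotations are the identity
  rect0 <- rectify(makeRig())
  expect_equal(rect0@Rl, diag(3), tolerance = 1e-12)
  expect_equal(rect0@Rr, diag(3), tolerance = 1e-12)
  expect_equal(rect0@baseline, 120)

  # misaligned rig: rows agree to 1e-6 px on random points
  rig <- rig_yawed()
  rect <- rectify(rig)
  set.seed(21)
  P <- random_points(100)
  L <- rectifyPixels(rect, projectPoints(rig@left, P), "left")
  R <- rectifyPixels(rect,
                     projectPoints(rig@right, P, rig@rotation,
                                   rig@translation), "right")
  expect_lt(max(abs(L[, 2] - R[, 2])), 1e-6)
  expect_true(all(L[, 1] - R[, 1] > 0))  # positive disparity for z > 0

  badRig <- makeRig()
  badRig@translation <- c(0, 0, 0)
  expect_error(validObject(badRig), "baseline")
})

test_that("triangulation recovers known points and scales as f*B/d", {
  rig <- makeRig(focalPx = 1400, baselineMm = 120)
  rect <- rectify(rig)
  # on-axis point at 1500 mm, forward-projected then inverted
  P <- matrix(c(0, 0, 1500), 1)
  L <- projectPoints(rig@left, P)
  R <- projectPoints(rig@right, P, rig@rotation, rig@translation)
  expect_lt(abs(triangulate(rect, L, R)[3] - 1500), 1e-6)
  # doubling disparity at fixed row halves depth
  d <- 1400 * 120 / 1500
  z1 <- triangulate(rect, cbind(640, 512), cbind(640 - d, 512),
                    rectified = TRUE)[3]
  z2 <- triangulate(rect, cbind(640, 512), cbind(640 - 2 * d, 512),
                    rectified = TRUE)[3]
  expect_equal(z1 / z2, 2, tolerance = 1e-12)
  # error cases
  expect_error(triangulate(rect, cbind(600, 512), cbind(650, 512),
                           rectified = TRUE), "disparity")
  expect_warning(triangulate(rect, cbind(650, 512), cbind(600, 517),
                             rectified = TRUE), "epipolar")
})

test_that("triangulated checkerboard corners one square apart are 50 mm apart", {
  rig <- makeRig()
  rect <- rectify(rig)
  cb <- projectCheckerboard(rig, boardR = euler_rig_rot(10, 5),
                            boardT = c(40, -30, 1200))
  L <- cb[cb$camera == "left", ]; R <- cb[cb$camera == "right", ]
  X <- triangulate(rect, cbind(L$px, L$py), cbind(R$px, R$py))
  a <- which(L$grid_i == 2 & L$grid_j == 3)
  b <- which(L$grid_i == 3 & L$grid_j == 3)
  expect_equal(sqrt(sum((X[a, ] - X[b, ])^2)), 50, tolerance = 1e-9)
})

test_that("reprojection error: exact, offset and Rayleigh-mean cases", {
  rig <- makeRig()
  set.seed(31)
  P <- random_points(100)
  L <- projectPoints(rig@left, P)
  R <- projectPoints(rig@right, P, rig@rotation, rig@translation)
  expect_equal(reprojectionError(rig, P, L, R), 0)
  # single point offset by (3, 4) px -> error 5
  expect_equal(reprojectionError(rig, P[1, , drop = FALSE],
                                 L[1, , drop = FALSE] + c(3, 4)), 5)
  # isotropic Gaussian noise sigma = 1: mean error ~ sigma * sqrt(pi/2)
  set.seed(32)
  Pn <- random_points(5000)
  Ln <- projectPoints(rig@left, Pn)
  Ln2 <- Ln + matrix(rnorm(2 * nrow(Ln)), ncol = 2)
  expect_equal(reprojectionError(rig, Pn, Ln2), sqrt(pi / 2),
               tolerance = 0.03)
  expect_error(reprojectionError(rig, P), "no observations")
})

test_that("triangulation agrees with a two-ray least-squares oracle", {
  set.seed(41)
  for (rig in list(rig_default(), rig_yawed(), rig_distorted())) {
    rect <- rectify(rig)
    P <- random_points(50)
    L <- projectPoints(rig@left, P)
    R <- projectPoints(rig@right, P, rig@rotation, rig@translation)
    X <- triangulate(rect, L, R)
    expect_lt(max(abs(X - lsq_triangulate(rig, L, R))), 1e-6)
  }
})

test_that("triangulated coordinates scale with the rig and scene", {
  set.seed(43)
  P <- random_points(30)
  s <- 2.5
  rigA <- makeRig(baselineMm = 120); rigB <- makeRig(baselineMm = 120 * s)
  LA <- projectPoints(rigA@left, P)
  RA <- projectPoints(rigA@right, P, rigA@rotation, rigA@translation)
  LB <- projectPoints(rigB@left, P * s)
  RB <- projectPoints(rigB@right, P * s, rigB@rotation, rigB@translation)
  XA <- triangulate(rectify(rigA), LA, RA)
  XB <- triangulate(rectify(rigB), LB, RB)
  expect_equal(XB, XA * s, tolerance = 1e-9)
})

test_that("calibration files round-trip through YAML", {
  rig <- makeRig(distortion = c(-0.12, 0.034, 1e-4, -2e-4, 0.002),
                 yawDeg = 1.5)
  path <- tempfile(fileext = ".yaml")
  writeCalibration(rig, path)
  rig2 <- readCalibration(path)
  expect_equal(rig2@left@fx, rig@left@fx)
  expect_equal(rig2@left@dist, rig@left@dist)
  expect_equal(rig2@rotation, rig@rotation, tolerance = 1e-15)
  expect_equal(rig2@translation, rig@translation)
  expect_equal(rig2@right@imageSize, rig@right@imageSize)
})
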