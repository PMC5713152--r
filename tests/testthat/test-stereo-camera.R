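# Pinhole projection, stereo composition, DLT calibration, triangulation.

test_that("optical-axis points project to the principal point", {
  intr <- camera_intrinsics(600, 600, 320, 240)
  for (z in c(10, 500, 3000)) {
    p <- project_point(intr, camera_pose(), c(0, 0, z))
    expect_equal(c(p$mu, p$gamma), c(320, 240))
  }
  p <- project_point(intr, camera_pose(), c(100, 0, 600))
  expect_equal(c(p$mu, p$gamma), c(420, 240))
})

test_that("projection equals the homogeneous 3x4 matrix product", {
  set.seed(11)
  intr <- camera_intrinsics(runif(1, 400, 900), runif(1, 400, 900),
                            runif(1, 300, 340), runif(1, 220, 260))
  for (i in 1:20) {
    pose <- camera_pose(random_rotation(), c(runif(2, -100, 100), runif(1, 0, 200)))
    p <- random_world_points(1)
    # independent oracle: c [mu gamma 1]' = M1 M2 Xw
    M1 <- rbind(c(intr$ax, 0, intr$mu0, 0), c(0, intr$ay, intr$gamma0, 0),
                c(0, 0, 1, 0))
    M2 <- rbind(cbind(pose$R, pose$T), c(0, 0, 0, 1))
    h <- M1 %*% M2 %*% c(p, 1)
    got <- project_point(intr, pose, p)
    expect_equal(c(got$mu, got$gamma), c(h[1] / h[3], h[2] / h[3]),
                 tolerance = 1e-12)
    expect_equal(got$depth, h[3], tolerance = 1e-12) # scale c equals depth
  }
})

test_that("projection rejects points behind the camera", {
  intr <- camera_intrinsics(600, 600, 320, 240)
  expect_error(project_point(intr, camera_pose(), c(0, 0, -5)),
               "behind camera")
})

test_that("compose_stereo returns identity for equal poses and satisfies the point-transport contract", {
  pose <- random_pose()
  rel <- compose_stereo(pose, pose)
  expect_equal(rel$R_rel, diag(3), tolerance = 1e-12)
  expect_equal(rel$T_rel, c(0, 0, 0), tolerance = 1e-9)

  # translation-only rigs: right camera 200 mm to the right of the left
  pl <- camera_pose(diag(3), c(5, -3, 10))
  pr <- camera_pose(diag(3), c(5, -3, 10) + c(-200, 0, 0))
  rel <- compose_stereo(pl, pr)
  expect_equal(rel$R_rel, diag(3))
  expect_equal(rel$T_rel, c(-200, 0, 0))

  set.seed(21)
  for (i in 1:100) {
    pl <- random_pose()
    pr <- random_pose()
    rel <- compose_stereo(pl, pr)
    x <- as.numeric(random_world_points(1))
    lhs <- pr$R %*% x + pr$T
    rhs <- rel$R_rel %*% (pl$R %*% x + pl$T) + rel$T_rel
    expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-9)
  }
})

test_that("compose_stereo rejects non-orthogonal rotations", {
  bad <- list(R = matrix(runif(9), 3, 3), T = c(0, 0, 0))
  expect_error(compose_stereo(bad, list(R = diag(3), T = c(0, 0, 0))),
               "orthonormal")
})

test_that("calibration recovers the generating camera from noiseless correspondences", {
  set.seed(31)
  intr <- camera_intrinsics(650, 620, 318, 242)
  pose <- camera_pose(rotation_matrix(0.08, -0.15, 0.2), c(40, -25, 1200))
  X <- random_world_points(30, depth = c(200, 900))
  X[, 3] <- X[, 3] + runif(30, 0, 400) # non-coplanar
  px <- project_point(intr, pose, X)
  cal <- calibrate_from_correspondences(X, cbind(px$mu, px$gamma))
  expect_lt(cal$rms, 1e-6)
  expect_equal(cal$intrinsics$ax, intr$ax, tolerance = 1e-6)
  expect_equal(cal$intrinsics$ay, intr$ay, tolerance = 1e-6)
  expect_equal(cal$intrinsics$mu0, intr$mu0, tolerance = 1e-6)
  expect_equal(cal$pose$R, pose$R, tolerance = 1e-6)
  expect_equal(cal$pose$T, pose$T, tolerance = 1e-4)
  expect_equal(cal$pose$R %*% t(cal$pose$R), diag(3), tolerance = 1e-9)
})

test_that("planar single-pose correspondences signal rank deficiency", {
  set.seed(32)
  intr <- camera_intrinsics(650, 620, 318, 242)
  pose <- camera_pose(diag(3), c(0, 0, 1000))
  X <- cbind(runif(20, -200, 200), runif(20, -200, 200), 0)
  px <- project_point(intr, pose, X)
  expect_error(calibrate_from_correspondences(X, cbind(px$mu, px$gamma)),
               "rank deficiency")
})

test_that("calibration from a noisy 11x8 board stays near the noise level", {
  # 88 corner points, 1% pixel noise relative to the pixel scale
  set.seed(33)
  intr <- camera_intrinsics(800, 800, 320, 240)
  pose <- camera_pose(rotation_matrix(0.05, 0.1, -0.07), c(10, 5, 1500))
  board <- as.matrix(expand.grid(x = (0:10) * 30, y = (0:7) * 30))
  X <- cbind(board, runif(88, 0, 250)) # corners at varying depth
  px <- project_point(intr, pose, X)
  noise <- 0.5
  U <- cbind(px$mu + rnorm(88, 0, noise), px$gamma + rnorm(88, 0, noise))
  cal <- calibrate_from_correspondences(X, U)
  expect_lt(cal$rms, 2 * noise)
})

test_that("triangulation inverts the projection on a rectified rig", {
  rig <- rectified_rig(ax = 600, ay = 600, mu0 = 320, gamma0 = 240,
                       baseline = 200)
  # closed form: zc = ax * baseline / d
  wp <- triangulate(rig, c(320, 240), 100)
  expect_equal(wp$zw, 600 * 200 / 100)

  set.seed(41)
  for (i in 1:20) {
    p <- as.numeric(random_world_points(1))
    pl <- project_point(rig$left$intrinsics, rig$left$pose, p)
    pr <- project_point(rig$right$intrinsics, rig$right$pose, p)
    d <- pl$mu - pr$mu
    got <- triangulate(rig, c(pl$mu, pl$gamma), d)
    expect_equal(c(got$xw, got$yw, got$zw), p, tolerance = 1e-6)
  }
  expect_error(triangulate(rig, c(320, 240), 0), "disparity")
})

test_that("a stereo rig round-trips through its JSON file", {
  rig <- rectified_rig(baseline = 200)
  path <- tempfile(fileext = ".json")
  write_rig(rig, path)
  back <- read_rig(path)
  expect_equal(back$baseline, rig$baseline)
  expect_equal(back$left$intrinsics, rig$left$intrinsics)
  expect_equal(back$R_rel, rig$R_rel)
  expect_equal(back$T_rel, rig$T_rel)
})
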