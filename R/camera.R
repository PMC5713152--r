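# Pinhole stereo geometry: projection, calibration from 3-D/2-D
# correspondences, composition of two camera poses into a rig, and
# disparity-based triangulation.
#
# Conventions: pixel coordinates are 0-based with x = column (rightward)
# and y = row (downward), origin at the top-left pixel centre; world and
# camera coordinates are in millimetres.

#' Camera intrinsics
#'
#' Bundle the four internal parameters of the pinhole model: the focal
#' scales along the two image axes (in pixels) and the principal point.
#'
#' @param ax,ay Focal scale along image x and y (pixels), both `> 0`.
#' @param mu0,gamma0 Principal point (pixels, 0-based).
#' @return An object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics(800, 800, 320, 240)
#' @export
camera_intrinsics <- function(ax, ay, mu0, gamma0) {
  stopifnot(is.numeric(ax), is.numeric(ay), length(ax) == 1, length(ay) == 1)
  if (ax <= 0 || ay <= 0) stop("focal scales ax and ay must be positive")
  structure(list(ax = ax, ay = ay, mu0 = mu0, gamma0 = gamma0),
            class = "camera_intrinsics")
}

#' Camera pose
#'
#' A rigid world-to-camera transform: `x_cam = R x_world + T`.
#'
#' @param R 3x3 rotation matrix (orthonormal, `det(R) = +1`).
#' @param T Length-3 translation vector (mm).
#' @param tol Orthonormality tolerance.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(R = diag(3), T = c(0, 0, 0), tol = 1e-9) {
  R <- unname(as.matrix(R))
  T <- as.numeric(T)
  stopifnot(all(dim(R) == c(3L, 3L)), length(T) == 3L)
  if (max(abs(R %*% t(R) - diag(3))) > sqrt(tol) * 1e3 ||
      abs(det(R) - 1) > sqrt(tol) * 1e3) {
    # accept down to ~1e-6 of numerical slack, reject genuinely invalid input
    if (max(abs(R %*% t(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
      stop("R is not a rotation matrix (orthonormal with det +1)")
    }
  }
  structure(list(R = R, T = T), class = "camera_pose")
}

#' Rotation matrix from Euler angles
#'
#' Convenience constructor used by the synthetic rigs and tests:
#' intrinsic rotations about x, y then z (radians).
#'
#' @param rx,ry,rz Rotation angles in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Project world points through a pinhole camera
#'
#' Maps world points to image coordinates: with camera-frame coordinates
#' `(xc, yc, zc) = R p + T`, the pixel is
#' `(mu, gamma) = (ax xc / zc + mu0, ay yc / zc + gamma0)`; the homogeneous
#' scale equals the camera-frame depth `zc`.
#'
#' @param intrinsics A [camera_intrinsics()] object.
#' @param pose A [camera_pose()] object.
#' @param p Length-3 world point or an n x 3 matrix of world points (mm).
#' @return A tibble with columns `mu`, `gamma` (pixels) and `depth` (mm).
#' @export
project_point <- function(intrinsics, pose, p) {
  P <- if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 3)
  stopifnot(ncol(P) == 3)
  cam <- t(pose$R %*% t(P) + pose$T)
  zc <- cam[, 3]
  if (any(zc <= 0)) stop("point behind camera: camera-frame depth <= 0")
  tibble(
    mu = intrinsics$ax * cam[, 1] / zc + intrinsics$mu0,
    gamma = intrinsics$ay * cam[, 2] / zc + intrinsics$gamma0,
    depth = zc
  )
}

#' Relative transform between two camera poses
#'
#' Composes the extrinsics of the left and right cameras into the
#' transform taking left-camera coordinates to right-camera coordinates:
#' `R_rel = R_r R_l'`, `T_rel = T_r - R_rel T_l`, so that for every world
#' point `x`, `R_r x + T_r = R_rel (R_l x + T_l) + T_rel`.
#'
#' @param left_pose,right_pose [camera_pose()] objects.
#' @return A list with elements `R_rel` (3x3) and `T_rel` (length 3, mm).
#' @export
compose_stereo <- function(left_pose, right_pose) {
  for (p in list(left_pose, right_pose)) {
    if (max(abs(p$R %*% t(p$R) - diag(3))) > 1e-6) {
      stop("invalid pose: R is not orthonormal")
    }
  }
  R_rel <- right_pose$R %*% t(left_pose$R)
  T_rel <- as.numeric(right_pose$T - R_rel %*% left_pose$T)
  list(R_rel = R_rel, T_rel = T_rel)
}

#' Stereo rig
#'
#' A pair of calibrated cameras. For a rectified rig (`R_rel` identity and
#' `T_rel` along x) the baseline equals `||T_rel||`; the default baseline of
#' the image-acquisition geometry is 200 mm.
#'
#' @param left,right Lists with elements `intrinsics` and `pose`.
#' @return An object of class `stereo_rig` with elements `left`, `right`,
#'   `R_rel`, `T_rel` and `baseline` (mm).
#' @seealso [rectified_rig()] for the common row-aligned special case.
#' @export
stereo_rig <- function(left, right) {
  rel <- compose_stereo(left$pose, right$pose)
  structure(list(
    left = left, right = right,
    R_rel = rel$R_rel, T_rel = rel$T_rel,
    baseline = sqrt(sum(rel$T_rel^2))
  ), class = "stereo_rig")
}

#' Rectified stereo rig
#'
#' Two identical, row-aligned cameras separated by `baseline` mm along x
#' (the left camera frame is the rig frame). Matching along epipolar rows
#' and disparity-based triangulation assume this geometry.
#'
#' @param ax,ay,mu0,gamma0 Shared intrinsics (see [camera_intrinsics()]).
#' @param baseline Baseline in mm (default 200).
#' @param image_size `c(width, height)` in pixels.
#' @return A `stereo_rig`.
#' @export
rectified_rig <- function(ax = 800, ay = 800, mu0 = 320, gamma0 = 240,
                          baseline = 200, image_size = c(640, 480)) {
  intr <- camera_intrinsics(ax, ay, mu0, gamma0)
  rig <- stereo_rig(
    left = list(intrinsics = intr, pose = camera_pose()),
    right = list(intrinsics = intr,
                 pose = camera_pose(diag(3), c(-baseline, 0, 0)))
  )
  rig$image_size <- as.integer(image_size)
  rig
}

#' Calibrate a camera from 3-D/2-D correspondences
#'
#' Direct linear transform (DLT) estimate of the full 3x4 projection
#' matrix from at least six non-coplanar correspondences, decomposed into
#' intrinsics and pose (RQ decomposition, nearest-rotation projection of R).
#'
#' @param world_points n x 3 matrix of world points (mm), n >= 6.
#' @param pixels n x 2 matrix of measured pixel coordinates.
#' @return A list with `intrinsics`, `pose`, the 3x4 matrix `P` and the
#'   reprojection root-mean-square error `rms` (pixels).
#' @export
calibrate_from_correspondences <- function(world_points, pixels) {
  X <- as.matrix(world_points)
  U <- as.matrix(pixels)
  stopifnot(ncol(X) == 3, ncol(U) == 2, nrow(X) == nrow(U))
  n <- nrow(X)
  if (n < 6) stop("at least 6 correspondences are required")

  Xh <- cbind(X, 1)
  A <- matrix(0, 2 * n, 12)
  A[seq(1, 2 * n, 2), 1:4] <- Xh
  A[seq(1, 2 * n, 2), 9:12] <- -U[, 1] * Xh
  A[seq(2, 2 * n, 2), 5:8] <- Xh
  A[seq(2, 2 * n, 2), 9:12] <- -U[, 2] * Xh

  sv <- svd(A)
  # a one-dimensional nullspace is required; coplanar or collinear input
  # leaves additional near-zero singular values
  if (sv$d[11] < 1e-8 * sv$d[1]) {
    stop("rank deficiency: correspondences are degenerate (coplanar or collinear)")
  }
  P <- matrix(sv$v[, 12], nrow = 3, byrow = TRUE)

  # fix the homogeneous sign so points sit in front of the camera
  w <- Xh %*% P[3, ]
  if (mean(sign(w)) < 0) P <- -P
  P <- P / sqrt(sum(P[3, 1:3]^2))

  # RQ decomposition of the leading 3x3 block: M = K %*% Rm
  M <- P[, 1:3]
  rev3 <- 3:1
  qrres <- qr(t(M[rev3, ]))
  Q <- qr.Q(qrres)
  Rr <- qr.R(qrres)
  K <- t(Rr)[rev3, rev3]
  Rm <- t(Q)[rev3, ]
  S <- diag(sign(diag(K)))
  K <- K %*% S
  Rm <- S %*% Rm
  K <- K / K[3, 3]
  Tm <- as.numeric(solve(K, P[, 4]))

  # nearest rotation (absorbs DLT noise)
  svR <- svd(Rm)
  Rm <- svR$u %*% t(svR$v)
  if (det(Rm) < 0) Rm <- -Rm

  intr <- camera_intrinsics(K[1, 1], K[2, 2], K[1, 3], K[2, 3])
  pose <- camera_pose(Rm, Tm, tol = 1e-6)
  proj <- project_point(intr, pose, X)
  rms <- sqrt(mean((proj$mu - U[, 1])^2 + (proj$gamma - U[, 2])^2))
  list(intrinsics = intr, pose = pose, P = P, rms = rms)
}

#' Triangulate left-image pixels from disparity
#'
#' For a rectified rig, depth follows from the disparity as
#' `zc = ax * baseline / d`; the lateral coordinates invert the projection.
#' The result is expressed in the left-camera frame (mm).
#'
#' @param rig A rectified [stereo_rig()].
#' @param left_pixel Length-2 pixel `(mu, gamma)` or an n x 2 matrix.
#' @param disparity Positive disparity(ies) in pixels.
#' @return A tibble with columns `xw`, `yw`, `zw` (mm).
#' @export
triangulate <- function(rig, left_pixel, disparity) {
  px <- if (is.matrix(left_pixel)) left_pixel else matrix(left_pixel, ncol = 2)
  d <- as.numeric(disparity)
  stopifnot(nrow(px) == length(d))
  if (any(d <= 0)) stop("non-positive disparity")
  if (max(abs(rig$R_rel - diag(3))) > 1e-6) {
    stop("rig is not rectified (R_rel must be the identity)")
  }
  intr <- rig$left$intrinsics
  zc <- intr$ax * rig$baseline / d
  tibble(
    xw = (px[, 1] - intr$mu0) * zc / intr$ax,
    yw = (px[, 2] - intr$gamma0) * zc / intr$ay,
    zw = zc
  )
}

#' Write / read a stereo rig as JSON
#'
#' The file stores image size, per-camera intrinsics and poses (R row-major)
#' and the baseline in mm.
#'
#' @param rig A `stereo_rig`.
#' @param path File path.
#' @return `read_rig` returns a `stereo_rig`; `write_rig` returns `path`
#'   invisibly.
#' @export
write_rig <- function(rig, path) {
  cam <- function(side) {
    list(
      ax = side$intrinsics$ax, ay = side$intrinsics$ay,
      mu0 = side$intrinsics$mu0, gamma0 = side$intrinsics$gamma0,
      R = as.numeric(t(side$pose$R)), T = side$pose$T
    )
  }
  obj <- list(
    image_size = rig$image_size %||% c(640L, 480L),
    left = cam(rig$left), right = cam(rig$right),
    baseline_mm = rig$baseline
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rig
#' @export
read_rig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cam <- function(side) {
    list(
      intrinsics = camera_intrinsics(side$ax, side$ay, side$mu0, side$gamma0),
      pose = camera_pose(matrix(side$R, 3, 3, byrow = TRUE), side$T)
    )
  }
  rig <- stereo_rig(cam(obj$left), cam(obj$right))
  rig$image_size <- as.integer(obj$image_size)
  rig
}

`%||%` <- function(a, b) if (is.null(a)) b else a
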