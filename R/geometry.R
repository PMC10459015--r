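# Lie-group parameterizations, pinhole projection and pixel warping.
#
# Conventions used throughout the package:
#   * twists are length-6 vectors, rotation part first (omega, 3) then
#     translation (3);
#   * camera frame: x right, y down, z forward; image coordinates are
#     0-based with u = column, v = row and pixel centers at integers;
#   * all lengths are meters.

.SMALL_ANGLE <- 1e-8

#' Skew-symmetric (cross-product) matrix
#'
#' @param w numeric length-3 vector.
#' @return 3x3 matrix `S` with `S %*% x == cross(w, x)`.
#' @keywords internal
skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' se(3) twist
#'
#' Bundles the rotation (`omega`, radians) and translation parts of an
#' se(3) element into the ordering used by every operation in this package:
#' rotation first, translation last.
#'
#' @param omega numeric length-3 rotation part (radians).
#' @param tvec numeric length-3 translation part (meters).
#' @return numeric length-6 twist vector of class `twist6`.
#' @examples
#' xi <- twist6(c(0, 0, 0), c(1, 2, 3))
#' se3_exp(xi)$trans
#' @export
twist6 <- function(omega = c(0, 0, 0), tvec = c(0, 0, 0)) {
  stopifnot(length(omega) == 3, length(tvec) == 3,
            all(is.finite(omega)), all(is.finite(tvec)))
  structure(c(as.numeric(omega), as.numeric(tvec)), class = "twist6")
}

#' Rigid 3D transform
#'
#' @param rot 3x3 rotation matrix (orthonormal, det +1).
#' @param trans numeric length-3 translation.
#' @param check validate orthonormality within 1e-9 (default TRUE).
#' @return list with elements `rot` and `trans`, class `rigid3`.
#' @export
rigid3 <- function(rot = diag(3), trans = c(0, 0, 0), check = TRUE) {
  rot <- matrix(as.numeric(rot), 3, 3)
  trans <- as.numeric(trans)
  if (check) {
    if (max(abs(crossprod(rot) - diag(3))) > 1e-9 || abs(det(rot) - 1) > 1e-9)
      stop("rigid3: rotation is not orthonormal with unit determinant")
  }
  structure(list(rot = rot, trans = trans), class = "rigid3")
}

#' Pinhole stereo camera intrinsics
#'
#' @param f focal length in pixels (unit aspect ratio assumed).
#' @param cu,cv principal point (pixels, 0-based image coordinates).
#' @param baseline stereo baseline in meters.
#' @param width,height optional image size in pixels.
#' @return list of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(f, cu, cv, baseline, width = NA, height = NA) {
  stopifnot(f > 0, baseline > 0)
  structure(list(f = f, cu = cu, cv = cv, baseline = baseline,
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' Projection matrix K and its inverse
#' @param K `camera_intrinsics`.
#' @return 3x3 matrix.
#' @export
intrinsics_matrix <- function(K) {
  matrix(c(K$f, 0, 0, 0, K$f, 0, K$cu, K$cv, 1), 3, 3)
}

#' @rdname intrinsics_matrix
#' @export
intrinsics_matrix_inv <- function(K) {
  matrix(c(1 / K$f, 0, 0, 0, 1 / K$f, 0, -K$cu / K$f, -K$cv / K$f, 1), 3, 3)
}

#' Exponential map of se(3)
#'
#' Closed-form (Rodrigues) exponential: `R = exp(skew(omega))` and
#' `t = V %*% tvec`. Below a rotation angle of 1e-8 rad the coefficients
#' switch to their Taylor limits.
#'
#' @param xi length-6 twist (rotation first).
#' @return `rigid3` transform.
#' @export
se3_exp <- function(xi) {
  xi <- as.numeric(xi)
  stopifnot(length(xi) == 6, all(is.finite(xi)))
  w <- xi[1:3]
  v <- xi[4:6]
  th <- sqrt(sum(w^2))
  S <- skew3(w)
  S2 <- S %*% S
  if (th < .SMALL_ANGLE) {
    a <- 1
    b <- 0.5
    c <- 1 / 6
  } else {
    a <- sin(th) / th
    b <- (1 - cos(th)) / th^2
    c <- (th - sin(th)) / th^3
  }
  R <- diag(3) + a * S + b * S2
  V <- diag(3) + b * S + c * S2
  rigid3(R, as.numeric(V %*% v), check = FALSE)
}

#' Logarithm map of SE(3)
#'
#' Inverse of [se3_exp()] for rotation angles strictly below pi.
#'
#' @param T `rigid3` transform with rotation angle < pi.
#' @return length-6 twist.
#' @export
se3_log <- function(T) {
  R <- T$rot
  tr <- (sum(diag(R)) - 1) / 2
  tr <- min(1, max(-1, tr))
  th <- acos(tr)
  if (th > pi - 1e-6)
    stop("se3_log: rotation angle at or near pi is ill-conditioned")
  if (th < .SMALL_ANGLE) {
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
    b <- 0.5
    c <- 1 / 6
  } else {
    w <- th / (2 * sin(th)) *
      c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    b <- (1 - cos(th)) / th^2
    c <- (th - sin(th)) / th^3
  }
  S <- skew3(w)
  S2 <- S %*% S
  V <- diag(3) + b * S + c * S2
  v <- solve(V, T$trans)
  twist6(w, as.numeric(v))
}

#' Compose two rigid transforms
#' @param A,B `rigid3` transforms.
#' @return `rigid3` equal to `A` followed-by-applied-to `B` (i.e. `A %*% B`
#'   as homogeneous matrices).
#' @export
rigid3_compose <- function(A, B) {
  rigid3(A$rot %*% B$rot, as.numeric(A$rot %*% B$trans + A$trans),
         check = FALSE)
}

#' Inverse of a rigid transform
#' @param T `rigid3`.
#' @return `rigid3` inverse.
#' @export
rigid3_inverse <- function(T) {
  Rt <- t(T$rot)
  rigid3(Rt, as.numeric(-Rt %*% T$trans), check = FALSE)
}

#' Inverse-compositional twist update
#'
#' Applies the inverse of an incremental twist to a current estimate:
#' `log(exp(xi) %*% exp(-dxi))`.
#'
#' @param xi current twist.
#' @param dxi incremental twist to be inverted and composed.
#' @return updated twist.
#' @export
ic_update <- function(xi, dxi) {
  se3_log(rigid3_compose(se3_exp(xi), se3_exp(-as.numeric(dxi))))
}

#' Back-project pixels to 3D
#'
#' `z * K^-1 %*% c(u, v, 1)`, returned homogenized (4th coordinate 1).
#'
#' @param p numeric length-2 pixel or m x 2 matrix of pixels (u, v).
#' @param z depth(s) in meters, positive.
#' @param K `camera_intrinsics`.
#' @return 4-vector for a single pixel, otherwise an m x 4 matrix.
#' @export
backproject <- function(p, z, K) {
  single <- is.null(dim(p))
  P <- if (single) matrix(p, 1, 2) else p
  if (any(z <= 0)) stop("backproject: depth must be positive")
  x <- z * (P[, 1] - K$cu) / K$f
  y <- z * (P[, 2] - K$cv) / K$f
  out <- cbind(x, y, z, 1, deparse.level = 0)
  if (single) out[1, ] else out
}

#' Project 3D points to the image plane
#'
#' Normalized homogeneous projection `K %*% x` with division by depth.
#'
#' @param x length-3 point or m x 3 matrix (camera frame).
#' @param K `camera_intrinsics`.
#' @return length-2 pixel or m x 2 matrix (u, v).
#' @export
project <- function(x, K) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1, 3) else x
  if (any(X[, 3] <= 0)) stop("project: point has non-positive depth")
  u <- K$f * X[, 1] / X[, 3] + K$cu
  v <- K$f * X[, 2] / X[, 3] + K$cv
  out <- cbind(u, v, deparse.level = 0)
  if (single) out[1, ] else out
}

#' Warp pixels through a rigid motion
#'
#' The direct-alignment warp: back-project at the reference depth, apply
#' `se3_exp(xi)`, re-project. Vectorized over pixels.
#'
#' @param p length-2 pixel or m x 2 matrix (u, v).
#' @param xi length-6 twist.
#' @param z depth(s), meters.
#' @param K `camera_intrinsics`.
#' @return list with `uv` (warped pixels, m x 2 or length-2), `z` (warped
#'   depths) and `valid` (logical, positive warped depth).
#' @export
warp_pixels <- function(p, xi, z, K) {
  single <- is.null(dim(p))
  P <- if (single) matrix(p, 1, 2) else p
  T <- se3_exp(xi)
  X <- backproject(P, z, K)[, 1:3, drop = FALSE]
  Xw <- X %*% t(T$rot)
  Xw[, 1] <- Xw[, 1] + T$trans[1]
  Xw[, 2] <- Xw[, 2] + T$trans[2]
  Xw[, 3] <- Xw[, 3] + T$trans[3]
  valid <- Xw[, 3] > 0
  uv <- matrix(NA_real_, nrow(P), 2)
  if (any(valid)) uv[valid, ] <- project(Xw[valid, , drop = FALSE], K)
  if (single) list(uv = uv[1, ], z = Xw[1, 3], valid = valid[1])
  else list(uv = uv, z = Xw[, 3], valid = valid)
}

#' Warp a single pixel
#'
#' Scalar convenience wrapper around [warp_pixels()]; errors if the warped
#' point falls behind the camera.
#'
#' @inheritParams warp_pixels
#' @return length-2 warped pixel (may fall outside the image domain).
#' @export
warp_pixel <- function(p, xi, z, K) {
  w <- warp_pixels(p, xi, z, K)
  if (!w$valid) stop("warp_pixel: warped point behind the camera")
  w$uv
}

#' Wrap an angle to (-pi, pi]
#' @param theta angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Planar pose
#'
#' @param x,y position (meters, easting/northing-like).
#' @param theta heading in radians, normalized to (-pi, pi].
#' @return numeric length-3 vector (x, y, theta).
#' @export
pose2 <- function(x = 0, y = 0, theta = 0) {
  c(x, y, wrap_angle(theta))
}

#' 2D rotation matrix and its derivatives
#' @param theta angle, radians.
#' @return 2x2 matrix.
#' @export
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' @rdname rot2
#' @export
drot2 <- function(theta) {
  matrix(c(-sin(theta), cos(theta), -cos(theta), -sin(theta)), 2, 2)
}

#' Reduce an se(3) twist to a planar motion triple
#'
#' Extracts the translation along the camera x (lateral) and z (forward)
#' axes and the heading change about the camera y (down) axis, giving the
#' se(2) motion used by the pose graph. The heading is taken with atan2
#' from the x-z block of the rotation matrix so that a positive yaw turns
#' the forward axis towards +x.
#'
#' @param xi length-6 twist.
#' @return length-3 planar motion (t_lateral, t_forward, theta_yaw).
#' @export
se3_to_se2_motion <- function(xi) {
  T <- se3_exp(xi)
  theta <- atan2(T$rot[1, 3], T$rot[3, 3])
  pose2(T$trans[1], T$trans[3], theta)
}
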