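# Direct (photometric) frame-to-frame egomotion.
#
# Inverse-compositional alignment: the 6-dof Jacobian of the photometric
# error is linearized once on the reference frame, each iteration solves a
# weighted Gauss-Newton step against residuals sampled from the input frame,
# and the incremental twist is composed inversely. Robustness to occlusions,
# exposure changes and disparity faults comes from Tukey-biweight IRLS with
# a MAD residual scale.
#
# Images are numeric matrices indexed [row, col] = [v + 1, u + 1] with
# intensities in [0, 255]; pixel coordinates are 0-based.

#' Image gradients by central differences
#'
#' Borders are replicated before differencing, so border gradients are
#' one-sided half-differences.
#'
#' @param img numeric matrix.
#' @return list with matrices `gu` (along columns/u) and `gv` (along rows/v).
#' @export
image_gradients <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  left <- img[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- img[, c(2:w, w), drop = FALSE]
  up <- img[c(1, seq_len(h - 1)), , drop = FALSE]
  down <- img[c(2:h, h), , drop = FALSE]
  list(gu = (right - left) / 2, gv = (down - up) / 2)
}

#' Bundle an intensity image with its gradients and depth
#'
#' @param intensity numeric matrix, grayscale in [0, 255].
#' @param disparity integer-valued disparity matrix (0 = invalid), same size.
#' @param K `camera_intrinsics`.
#' @return list of class `vo_frame` with `intensity`, `grad_u`, `grad_v`,
#'   `disparity`, `depth`.
#' @export
make_frame <- function(intensity, disparity, K) {
  if (!all(dim(intensity) == dim(disparity)))
    stop("make_frame: intensity and disparity dimensions differ")
  g <- image_gradients(intensity)
  structure(list(intensity = intensity, grad_u = g$gu, grad_v = g$gv,
                 disparity = disparity,
                 depth = depth_from_disparity(disparity, K)),
            class = "vo_frame")
}

#' Select high-gradient pixels with valid depth
#'
#' Pixels with zero disparity are discarded first (they back-project to
#' infinity), the remainder are ranked by gradient magnitude in descending
#' order with raster (row-major) order as the deterministic tie-break, and
#' the first `floor(N * percent / 100)` are kept, where N is the total
#' number of image pixels. The count is capped at the number of usable
#' pixels.
#'
#' @param frame `vo_frame`.
#' @param percent percentage of the full image to select, in (0, 100].
#' @return list of class `pixel_selection`: `pixels` (m x 2, 0-based u, v),
#'   `depths`, `grads` (m x 2), `ref_intensity`, `index` (1-based linear
#'   index into the image matrix).
#' @export
select_pixels <- function(frame, percent) {
  stopifnot(percent > 0, percent <= 100)
  h <- nrow(frame$intensity)
  w <- ncol(frame$intensity)
  gmag2 <- frame$grad_u^2 + frame$grad_v^2
  usable <- which(frame$disparity > 0 & gmag2 > 0)
  if (length(usable) == 0)
    stop("select_pixels: no usable pixels (degenerate frame)")
  n_target <- min(floor(h * w * percent / 100), length(usable))
  # 0-based coordinates from the 1-based column-major linear index
  v <- (usable - 1) %% h
  u <- (usable - 1) %/% h
  raster <- v * w + u
  ord <- order(-gmag2[usable], raster)[seq_len(n_target)]
  keep <- usable[ord]
  structure(list(
    pixels = cbind(u = u[ord], v = v[ord]),
    depths = frame$depth[keep],
    grads = cbind(gu = frame$grad_u[keep], gv = frame$grad_v[keep]),
    ref_intensity = frame$intensity[keep],
    index = keep
  ), class = "pixel_selection")
}

#' Precompute the inverse-compositional Jacobian and Hessian
#'
#' One row per selected pixel: the photometric derivative with respect to
#' the six twist parameters (rotation first) at the identity warp, built
#' from the reference gradients and the back-projected point. Computed once
#' per reference frame; no input-frame quantity enters.
#'
#' @param ref reference `vo_frame`.
#' @param sel `pixel_selection` built from `ref`.
#' @param K `camera_intrinsics`.
#' @return list of class `ic_system` with `jacobian` (m x 6) and
#'   `hessian` (6 x 6 Gauss-Newton approximation).
#' @export
build_ic_system <- function(ref, sel, K) {
  z <- sel$depths
  f <- K$f
  x <- z * (sel$pixels[, 1] - K$cu) / f
  y <- z * (sel$pixels[, 2] - K$cv) / f
  gu <- sel$grads[, 1]
  gv <- sel$grads[, 2]
  z2 <- z^2
  J <- cbind(
    -(gu * f * x * y + gv * (f * y^2 + f * z2)) / z2,
    (gu * (f * x^2 + f * z2) + gv * f * x * y) / z2,
    (-gu * f * y + gv * f * x) / z,
    gu * f / z,
    gv * f / z,
    -(gu * f * x + gv * f * y) / z2
  )
  colnames(J) <- c("wx", "wy", "wz", "tx", "ty", "tz")
  structure(list(jacobian = J, hessian = crossprod(J)), class = "ic_system")
}

#' Bilinear interpolation at sub-pixel coordinates
#'
#' @param img numeric matrix.
#' @param uv m x 2 matrix of 0-based (u, v) coordinates, assumed inside
#'   the image domain.
#' @return numeric vector of sampled intensities.
#' @export
bilinear_sample <- function(img, uv) {
  h <- nrow(img)
  w <- ncol(img)
  u <- uv[, 1]
  v <- uv[, 2]
  u0 <- pmin(pmax(floor(u), 0), w - 2)
  v0 <- pmin(pmax(floor(v), 0), h - 2)
  du <- u - u0
  dv <- v - v0
  i00 <- img[cbind(v0 + 1, u0 + 1)]
  i01 <- img[cbind(v0 + 1, u0 + 2)]
  i10 <- img[cbind(v0 + 2, u0 + 1)]
  i11 <- img[cbind(v0 + 2, u0 + 2)]
  (1 - dv) * ((1 - du) * i00 + du * i01) + dv * ((1 - du) * i10 + du * i11)
}

#' Photometric residuals at a candidate warp
#'
#' Each residual is the bilinearly interpolated input intensity at the
#' warped pixel location minus the reference intensity. Pixels warping
#' outside the input domain or behind the camera are masked invalid.
#'
#' @param ref,input `vo_frame`s sharing calibration.
#' @param sel `pixel_selection` from the reference.
#' @param xi length-6 twist.
#' @param K `camera_intrinsics`.
#' @return list with `residuals` (NA where invalid), `valid` (logical) and
#'   `valid_fraction`; a warning is raised when more than half of the
#'   selected pixels are invalid (low overlap).
#' @export
photometric_residuals <- function(ref, input, sel, xi, K) {
  h <- nrow(input$intensity)
  w <- ncol(input$intensity)
  wp <- warp_pixels(sel$pixels, xi, sel$depths, K)
  ok <- wp$valid
  ok[ok] <- wp$uv[ok, 1] >= 0 & wp$uv[ok, 1] <= w - 1 &
    wp$uv[ok, 2] >= 0 & wp$uv[ok, 2] <= h - 1
  r <- rep(NA_real_, nrow(sel$pixels))
  if (any(ok))
    r[ok] <- bilinear_sample(input$intensity, wp$uv[ok, , drop = FALSE]) -
      sel$ref_intensity[ok]
  frac <- mean(ok)
  if (frac < 0.5)
    warning("photometric_residuals: more than 50% of pixels invalid (low overlap)")
  list(residuals = r, valid = ok, valid_fraction = frac)
}

#' Robust estimation settings
#'
#' @param c Tukey biweight constant (default 4.6851, 95% asymptotic
#'   efficiency under Gaussian noise).
#' @param k MAD consistency constant for the residual scale (default
#'   1.4826).
#' @param max_iters maximum Gauss-Newton iterations (default 100).
#' @param step_tol terminate when the incremental twist norm falls below
#'   this (default 1e-6).
#' @param cost_tol terminate on relative weighted-cost change below this
#'   (default 1e-8).
#' @param robust use Tukey IRLS weights; all weights are 1 when FALSE.
#' @return list of class `robust_config`.
#' @export
robust_config <- function(c = 4.6851, k = 1.4826, max_iters = 100,
                          step_tol = 1e-6, cost_tol = 1e-8, robust = TRUE) {
  stopifnot(c > 0, k > 0, max_iters >= 1)
  structure(list(c = c, k = k, max_iters = max_iters, step_tol = step_tol,
                 cost_tol = cost_tol, robust = robust),
            class = "robust_config")
}

#' Tukey biweight IRLS weights with MAD scale
#'
#' The residual scale is `s = k * median(|r|)`; weights are
#' `(1 - (r / (s c))^2)^2` inside the cutoff `|r / s| <= c` and zero
#' outside. When the scale is exactly zero (all residuals zero) every
#' weight is 1.
#'
#' @param r numeric residual vector (non-empty; NAs receive weight 0).
#' @param cfg `robust_config`.
#' @return numeric weight vector of the same length.
#' @export
robust_weights <- function(r, cfg = robust_config()) {
  stopifnot(length(r) > 0)
  w <- numeric(length(r))
  ok <- !is.na(r)
  s <- cfg$k * stats::median(abs(r[ok]))
  if (s == 0) {
    w[ok] <- 1
    return(w)
  }
  u <- r[ok] / s
  wi <- (1 - (u / cfg$c)^2)^2
  wi[abs(u) > cfg$c] <- 0
  w[ok] <- wi
  w
}

#' Frame-to-frame egomotion by robust inverse-compositional alignment
#'
#' Minimizes the weighted photometric error over the selected pixel set.
#' The Jacobian and Hessian come from the reference frame only; each
#' iteration recomputes residuals on the input frame, IRLS weights, the
#' weighted Gauss-Newton step and the inverse-compositional twist update,
#' until the step norm or the relative cost change falls below tolerance.
#'
#' @param ref,input `vo_frame`s.
#' @param K `camera_intrinsics`.
#' @param cfg `robust_config`.
#' @param percent pixel-selection percentage (default 25, matching a
#'   240 x 320 budget of 19,200 pixels).
#' @param xi_init optional warm-start twist (default zero; at 10 fps the
#'   inter-frame motion is small).
#' @param trace if TRUE, prints per-iteration cost, step norm and scale.
#' @return list of class `vo_result`: `xi`, `iterations`, `final_cost`
#'   (weighted SSD), `converged`, `valid_pixel_fraction`.
#' @export
estimate_egomotion <- function(ref, input, K, cfg = robust_config(),
                               percent = 25, xi_init = NULL, trace = FALSE) {
  sel <- select_pixels(ref, percent)
  sys <- build_ic_system(ref, sel, K)
  J <- sys$jacobian
  xi <- if (is.null(xi_init)) rep(0, 6) else as.numeric(xi_init)
  cost_prev <- Inf
  converged <- FALSE
  iters <- 0
  frac <- 1
  cost <- NA_real_
  for (iter in seq_len(cfg$max_iters)) {
    iters <- iter
    res <- suppressWarnings(photometric_residuals(ref, input, sel, xi, K))
    frac <- res$valid_fraction
    if (frac == 0) stop("estimate_egomotion: no valid pixels after warping")
    scale <- cfg$k * stats::median(abs(res$residuals), na.rm = TRUE)
    w <- if (cfg$robust) robust_weights(res$residuals, cfg)
         else as.numeric(res$valid)
    r0 <- ifelse(res$valid, res$residuals, 0)
    cost <- sum(w * r0^2)
    Hw <- crossprod(J, w * J)
    bw <- crossprod(J, w * r0)
    dxi <- tryCatch(solve(Hw, bw),
                    error = function(e)
                      stop("estimate_egomotion: singular weighted Hessian (degenerate texture)"))
    dxi <- as.numeric(dxi)
    xi <- as.numeric(ic_update(xi, dxi))
    step <- sqrt(sum(dxi^2))
    if (trace)
      message(sprintf("iter %3d  cost %.6g  |dxi| %.3g  scale %.3g",
                      iter, cost, step, scale))
    if (step < cfg$step_tol ||
        (is.finite(cost_prev) &&
         abs(cost_prev - cost) <= cfg$cost_tol * max(cost_prev, 1e-12))) {
      converged <- TRUE
      break
    }
    cost_prev <- cost
  }
  structure(list(xi = xi, iterations = iters, final_cost = cost,
                 converged = converged, valid_pixel_fraction = frac),
            class = "vo_result")
}

#' Convert an estimated warp twist to a planar odometry motion
#'
#' The alignment twist maps reference-frame coordinates into the input
#' frame; the physical camera motion is its inverse. Its translation along
#' the camera x (right) and z (forward) axes becomes the planar (x, y)
#' motion, and the heading increment is the negated yaw (the camera y axis
#' points down, so a counter-clockwise map heading is a negative yaw).
#'
#' @param xi length-6 alignment twist.
#' @return length-3 planar motion (dx lateral, dy forward, dtheta), meters
#'   and radians, suitable for [odometry_edges()].
#' @export
vo_to_odometry <- function(xi) {
  M <- rigid3_inverse(se3_exp(xi))
  yaw <- atan2(M$rot[1, 3], M$rot[3, 3])
  pose2(M$trans[1], M$trans[3], -yaw)
}
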