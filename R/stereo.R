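# Disparity validation and depth recovery.
#
# Disparity maps are integer-valued matrices over the image domain with 0
# marking an invalid (unusable) pixel; no sub-pixel refinement is applied
# anywhere. Stereo matching itself is an external component: maps are read
# from files or produced by the synthetic renderer.

#' Validate a disparity map
#' @param d numeric matrix, entries >= 0 and integer-valued.
#' @return the map, invisibly.
#' @keywords internal
check_disparity <- function(d) {
  if (!is.matrix(d)) stop("disparity must be a matrix")
  if (any(d < 0)) stop("disparity entries must be >= 0")
  if (max(abs(d - round(d))) > 0) stop("disparity entries must be integers")
  invisible(d)
}

#' Left-right disparity consistency filter
#'
#' Keeps the left-to-right disparity wherever it agrees with the
#' right-to-left disparity within `delta` pixels and invalidates (sets to
#' zero) every other pixel. Occluded regions, which stereo matchers with
#' smoothness constraints fill with arbitrary values, fail the check and
#' are dropped.
#'
#' @param d_lr,d_rl disparity matrices of equal dimension.
#' @param delta non-negative consistency threshold in pixels (default 1).
#' @return filtered disparity matrix.
#' @export
lr_consistency_filter <- function(d_lr, d_rl, delta = 1) {
  if (!all(dim(d_lr) == dim(d_rl)))
    stop("lr_consistency_filter: disparity maps differ in dimension")
  check_disparity(d_lr)
  check_disparity(d_rl)
  out <- d_lr
  out[abs(d_lr - d_rl) > delta] <- 0
  out
}

#' Depth from disparity
#'
#' Triangulation `z = f * b / D` at valid (positive) disparities; invalid
#' pixels are carried as `NA` so that no downstream stage can use them.
#'
#' @param d disparity matrix (pixels; 0 = invalid).
#' @param K `camera_intrinsics` with focal length in pixels and baseline in
#'   meters.
#' @return matrix of depths in meters, `NA` where disparity is zero.
#' @export
depth_from_disparity <- function(d, K) {
  check_disparity(d)
  z <- matrix(NA_real_, nrow(d), ncol(d))
  ok <- d > 0
  z[ok] <- K$f * K$baseline / d[ok]
  z
}
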