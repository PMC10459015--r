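# Seeded synthetic generators: world, GPS, stem detections and rendered
# stereo pairs.
#
# Defaults mimic the field deployment the pipeline targets: a ~1115 m
# smooth walking path sampled at 10 poses per second at ~1 m/s, ~140 tree
# stems over the surrounding stand, consumer-grade GPS noise (sigma = 5 m),
# optional 5% outliers uniform in [0, 200] m, and an intermittent mode of
# 12 fixes (first, last, one per 100 m interval). Every generator is a
# pure function of (spec, seed); the global RNG state is restored on exit.

# Evaluate `code` under `seed` without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic world specification
#'
#' @param seed RNG seed; identical specs produce bit-identical worlds.
#' @param path_length_m total trajectory length (default 1115).
#' @param frame_rate_hz camera/odometry rate (default 10).
#' @param speed_mps walking speed (default 1).
#' @param max_curvature maximum path curvature in 1/m (default 0.03, a
#'   minimum turning radius of ~33 m).
#' @param n_harmonics number of random low-frequency curvature harmonics.
#' @param stem_count number of stems placed in the stand (default 140).
#' @param stem_margin_m stand half-width around the path within which
#'   stems are placed (default 12).
#' @param stem_min_spacing_m minimum stem spacing (default 4, a hard-core
#'   spacing typical of a sparse pine stand and comfortably above twice
#'   the clustering radius).
#' @param stem_clearance_m minimum stem distance from the path (default 1).
#' @param fov_rad horizontal field of view for stem visibility (default
#'   pi/2).
#' @param max_range_m maximum stem detection range (default 12).
#' @param obs_sigma0,obs_sigma_range range-dependent detection noise
#'   `sigma(d) = sigma0 + sigma_range d` (defaults 0.1 m and 0.05).
#' @param origin UTM-like coordinates of the path start.
#' @return list of class `world_spec`.
#' @export
world_spec <- function(seed = 1, path_length_m = 1115, frame_rate_hz = 10,
                       speed_mps = 1, max_curvature = 0.03, n_harmonics = 3,
                       stem_count = 140, stem_margin_m = 12,
                       stem_min_spacing_m = 4, stem_clearance_m = 1,
                       fov_rad = pi / 2, max_range_m = 12,
                       obs_sigma0 = 0.1, obs_sigma_range = 0.05,
                       origin = c(100000, 200000)) {
  stopifnot(path_length_m > 0, frame_rate_hz > 0, speed_mps > 0,
            max_curvature >= 0, stem_count >= 0)
  structure(as.list(environment()), class = "world_spec")
}

#' Simulate a smooth trajectory, stems and exact odometry edges
#'
#' The path has constant speed and a smooth random curvature profile
#' (bounded by `max_curvature`); stems are placed uniformly over the stand
#' corridor with a minimum spacing and clearance from the path. The
#' emitted odometry edges are the exact relative motions between
#' consecutive poses (noise, if wanted, is added separately with
#' [perturb_odometry()]), so chaining them with [build_graph()] reproduces
#' the trajectory in the frame of its first pose.
#'
#' @param spec `world_spec`.
#' @return list of class `synthetic_world`: `trajectory` (n x 3 UTM
#'   poses), `stems` (S x 2), `edges` (`odometry_edges` with exact
#'   motions), `spec`.
#' @export
simulate_world <- function(spec = world_spec()) {
  ds <- spec$speed_mps / spec$frame_rate_hz
  n <- floor(spec$path_length_m / ds) + 1
  with_seed(spec$seed, {
    s <- (seq_len(n) - 1) * ds
    kappa <- numeric(n)
    if (spec$max_curvature > 0 && spec$n_harmonics > 0) {
      for (j in seq_len(spec$n_harmonics)) {
        amp <- stats::runif(1, 0.5, 1) / j
        phase <- stats::runif(1, 0, 2 * pi)
        kappa <- kappa + amp * sin(2 * pi * j * s / spec$path_length_m + phase)
      }
      kappa <- kappa / max(abs(kappa)) * spec$max_curvature
    }
    theta0 <- stats::runif(1, -pi, pi)
    theta <- wrap_angle(theta0 + c(0, cumsum(kappa[-n] * ds)))
    fx <- -sin(theta)
    fy <- cos(theta)
    x <- spec$origin[1] + c(0, cumsum(fx[-n] * ds))
    y <- spec$origin[2] + c(0, cumsum(fy[-n] * ds))
    trajectory <- cbind(x, y, theta, deparse.level = 0)
    # exact relative motions: translation in the frame of pose i
    dxy <- cbind(diff(x), diff(y))
    ii <- seq_len(n - 1)
    motions <- cbind(cos(theta[ii]) * dxy[, 1] + sin(theta[ii]) * dxy[, 2],
                     -sin(theta[ii]) * dxy[, 1] + cos(theta[ii]) * dxy[, 2],
                     wrap_angle(theta[-1] - theta[ii]))
    stems <- matrix(numeric(0), 0, 2)
    if (spec$stem_count > 0) {
      lo <- c(min(x), min(y)) - spec$stem_margin_m
      hi <- c(max(x), max(y)) + spec$stem_margin_m
      placed <- 0
      attempts <- 0
      stems <- matrix(0, spec$stem_count, 2)
      while (placed < spec$stem_count && attempts < 200 * spec$stem_count) {
        attempts <- attempts + 1
        cand <- stats::runif(2, lo, hi)
        d_path <- min(sqrt((x - cand[1])^2 + (y - cand[2])^2))
        if (d_path < spec$stem_clearance_m || d_path > spec$stem_margin_m)
          next
        if (placed > 0) {
          d_stem <- min(sqrt((stems[seq_len(placed), 1] - cand[1])^2 +
                             (stems[seq_len(placed), 2] - cand[2])^2))
          if (d_stem < spec$stem_min_spacing_m) next
        }
        placed <- placed + 1
        stems[placed, ] <- cand
      }
      stems <- stems[seq_len(placed), , drop = FALSE]
    }
    structure(list(trajectory = trajectory, stems = stems,
                   edges = odometry_edges(motions), spec = spec),
              class = "synthetic_world")
  })
}

#' Add noise to odometry edges
#'
#' Independent zero-mean Gaussian perturbations per edge, used to emulate
#' visual-odometry drift; the edge information matrices are reset to match
#' the perturbation scale.
#'
#' @param edges `odometry_edges`.
#' @param sigma_t,sigma_theta per-edge noise standard deviations (m, rad).
#' @param seed RNG seed.
#' @return perturbed `odometry_edges`.
#' @export
perturb_odometry <- function(edges, sigma_t, sigma_theta, seed = 1) {
  m <- edges$n_edges
  with_seed(seed, {
    noisy <- edges$motions +
      cbind(stats::rnorm(m, 0, sigma_t), stats::rnorm(m, 0, sigma_t),
            stats::rnorm(m, 0, sigma_theta))
    odometry_edges(noisy, sigma_t = sigma_t, sigma_theta = sigma_theta)
  })
}

#' GPS noise specification
#'
#' @param sigma_m per-axis Gaussian noise standard deviation (default 5).
#' @param outlier_fraction fraction of fixes additionally perturbed by
#'   uniform radial noise (default 0).
#' @param outlier_range_m magnitude range of outlier perturbations
#'   (default c(0, 200)).
#' @param mode `"dense"` (one fix per pose) or `"intermittent"` (first,
#'   last, and one random fix per `interval_m` along the path).
#' @param interval_m spacing of intermittent fixes (default 100).
#' @param seed RNG seed.
#' @return list of class `gps_noise_spec`.
#' @export
gps_noise_spec <- function(sigma_m = 5, outlier_fraction = 0,
                           outlier_range_m = c(0, 200),
                           mode = c("dense", "intermittent"),
                           interval_m = 100, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(sigma_m >= 0, outlier_fraction >= 0, outlier_fraction <= 1)
  structure(list(sigma_m = sigma_m, outlier_fraction = outlier_fraction,
                 outlier_range_m = outlier_range_m, mode = mode,
                 interval_m = interval_m, seed = seed),
            class = "gps_noise_spec")
}

#' Simulate a GPS track over a trajectory
#'
#' Dense mode emits one fix per pose with i.i.d. per-axis Gaussian noise;
#' outlier mode additionally displaces a random fraction of fixes by a
#' uniform radial perturbation; intermittent mode keeps the first fix, the
#' last fix, and one randomly chosen fix per path interval.
#'
#' @param trajectory n x 3 pose matrix (UTM).
#' @param spec `gps_noise_spec`.
#' @param info_sigma sigma used for the information matrices (defaults to
#'   `spec$sigma_m`, or 1 when that is zero).
#' @return `gps_observations` with `pose_index` giving the
#'   pose-fix correspondences.
#' @export
simulate_gps_track <- function(trajectory, spec = gps_noise_spec(),
                               info_sigma = NULL) {
  n <- nrow(trajectory)
  if (is.null(info_sigma))
    info_sigma <- if (spec$sigma_m > 0) spec$sigma_m else 1
  with_seed(spec$seed, {
    idx <- if (spec$mode == "dense") {
      seq_len(n)
    } else {
      ds <- sqrt(diff(trajectory[, 1])^2 + diff(trajectory[, 2])^2)
      s <- c(0, cumsum(ds))
      L <- s[n]
      k <- max(0, floor(L / spec$interval_m) - 1)
      picks <- integer(k)
      for (j in seq_len(k)) {
        pool <- which(s >= j * spec$interval_m & s < (j + 1) * spec$interval_m)
        picks[j] <- pool[sample.int(length(pool), 1)]
      }
      sort(unique(c(1, picks, n)))
    }
    K <- length(idx)
    coords <- trajectory[idx, 1:2, drop = FALSE] +
      matrix(stats::rnorm(2 * K, 0, spec$sigma_m), K, 2)
    if (spec$outlier_fraction > 0) {
      n_out <- round(spec$outlier_fraction * K)
      if (n_out > 0) {
        out <- sample.int(K, n_out)
        mag <- stats::runif(n_out, spec$outlier_range_m[1],
                            spec$outlier_range_m[2])
        ang <- stats::runif(n_out, 0, 2 * pi)
        coords[out, ] <- coords[out, ] + cbind(mag * cos(ang), mag * sin(ang))
      }
    }
    gps_track(coords, idx, sigma = info_sigma)
  })
}

#' Simulate per-frame stem detections
#'
#' For every pose, stems within the field of view and detection range are
#' emitted as camera-frame offsets (lateral, forward) with zero-mean
#' Gaussian noise whose standard deviation grows with range
#' (`sigma0 + sigma_range * d`); the observation information matrices are
#' set from the same sigma. Observations whose noisy forward component is
#' not positive are dropped.
#'
#' @param trajectory n x 3 pose matrix.
#' @param stems S x 2 stem positions.
#' @param spec `world_spec` (fov, range, noise model).
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param noiseless emit exact offsets when TRUE.
#' @return `stem_observations` with an extra element `truth_id` giving the
#'   generating stem of each observation.
#' @export
simulate_stem_observations <- function(trajectory, stems, spec,
                                       seed = spec$seed, noiseless = FALSE) {
  n <- nrow(trajectory)
  S <- nrow(stems)
  pose_index <- integer(0)
  truth_id <- integer(0)
  lat <- numeric(0)
  fwd <- numeric(0)
  dist <- numeric(0)
  cth <- cos(trajectory[, 3])
  sth <- sin(trajectory[, 3])
  for (s in seq_len(S)) {
    dx <- stems[s, 1] - trajectory[, 1]
    dy <- stems[s, 2] - trajectory[, 2]
    # camera frame: R(theta)^T (m - t)
    zx <- cth * dx + sth * dy
    zy <- -sth * dx + cth * dy
    d <- sqrt(zx^2 + zy^2)
    vis <- which(zy > 0 & d <= spec$max_range_m &
                 abs(atan2(zx, zy)) <= spec$fov_rad / 2)
    if (length(vis) == 0) next
    pose_index <- c(pose_index, vis)
    truth_id <- c(truth_id, rep.int(s, length(vis)))
    lat <- c(lat, zx[vis])
    fwd <- c(fwd, zy[vis])
    dist <- c(dist, d[vis])
  }
  sig <- spec$obs_sigma0 + spec$obs_sigma_range * dist
  if (!noiseless) {
    m <- length(lat)
    with_seed(seed + 11L, {
      lat <- lat + stats::rnorm(m, 0, sig)
      fwd <- fwd + stats::rnorm(m, 0, sig)
    })
  }
  keep <- fwd > 0.05
  info <- array(0, c(sum(keep), 2, 2))
  info[, 1, 1] <- 1 / sig[keep]^2
  info[, 2, 2] <- 1 / sig[keep]^2
  obs <- stem_observations(pose_index[keep],
                           cbind(lat[keep], fwd[keep]), info = info)
  obs$truth_id <- truth_id[keep]
  obs
}

#' Textured slanted-plane scene for stereo rendering
#'
#' A single plane `n . x = d` carrying a smooth random albedo defined by
#' bilinear interpolation of a coarse grid in world (x, y); both rendered
#' views sample the same continuous albedo, so the pair is photometrically
#' consistent up to interpolation.
#'
#' @param K `camera_intrinsics` with image `width`/`height`.
#' @param depth_m depth of the plane along the optical axis at the
#'   principal point (default 3).
#' @param slant (nx, ny) components of the (unnormalized) plane normal;
#'   (0, 0) is fronto-parallel.
#' @param texture_period_px approximate projected texture wavelength in
#'   pixels (default 14).
#' @param contrast peak-to-peak intensity range (default 180).
#' @param margin_m extra world extent of the albedo grid beyond the
#'   reference footprint, to cover camera motion (default 1).
#' @param seed RNG seed.
#' @return list of class `plane_scene`.
#' @export
plane_scene <- function(K, depth_m = 3, slant = c(0, 0),
                        texture_period_px = 14, contrast = 180,
                        margin_m = 1, seed = 1) {
  stopifnot(is.finite(K$width), is.finite(K$height))
  nvec <- c(slant[1], slant[2], 1)
  d <- depth_m  # plane passes through (0, 0, depth_m) on the optical axis
  spacing <- texture_period_px * depth_m / K$f
  half_x <- depth_m * (K$width / K$f)
  half_y <- depth_m * (K$height / K$f)
  x0 <- -half_x - margin_m
  y0 <- -half_y - margin_m
  nx <- ceiling((2 * (half_x + margin_m)) / spacing) + 3
  ny <- ceiling((2 * (half_y + margin_m)) / spacing) + 3
  grid <- with_seed(seed, matrix(stats::runif(nx * ny), ny, nx))
  structure(list(n = nvec, d = d, grid = grid, x0 = x0, y0 = y0,
                 spacing = spacing, contrast = contrast, offset = 127.5),
            class = "plane_scene")
}

# Sample the scene albedo at world (x, y), bilinear, intensities in
# [offset - contrast/2, offset + contrast/2].
scene_albedo <- function(scene, x, y) {
  gx <- (x - scene$x0) / scene$spacing
  gy <- (y - scene$y0) / scene$spacing
  nxg <- ncol(scene$grid)
  nyg <- nrow(scene$grid)
  gx <- pmin(pmax(gx, 0), nxg - 1.001)
  gy <- pmin(pmax(gy, 0), nyg - 1.001)
  i0 <- floor(gx)
  j0 <- floor(gy)
  fx <- gx - i0
  fy <- gy - j0
  g <- scene$grid
  v <- (1 - fy) * ((1 - fx) * g[cbind(j0 + 1, i0 + 1)] +
                   fx * g[cbind(j0 + 1, i0 + 2)]) +
       fy * ((1 - fx) * g[cbind(j0 + 2, i0 + 1)] +
             fx * g[cbind(j0 + 2, i0 + 2)])
  scene$offset + (v - 0.5) * scene$contrast
}

#' Render a reference/input stereo-time pair with known egomotion
#'
#' The reference view images the plane from the identity pose; the input
#' view is the same scene observed after the rigid motion `xi` (the warp
#' convention: reference-frame coordinates map to input-frame coordinates
#' through `se3_exp(xi)`). The true disparity map of the reference view is
#' derived from the plane depth (`round(f b / z)`, integers, matching the
#' no-subpixel disparity contract).
#'
#' @param scene `plane_scene`.
#' @param xi length-6 twist (zero motion gives identical images).
#' @param K `camera_intrinsics` with `width`/`height`.
#' @return list: `reference`, `input` (intensity matrices), `disparity`
#'   (integer matrix), `depth` (exact reference depths, meters).
#' @export
render_stereo_pair <- function(scene, xi, K) {
  w <- K$width
  h <- K$height
  u <- rep(0:(w - 1), each = h)
  v <- rep(0:(h - 1), times = w)
  rx <- (u - K$cu) / K$f
  ry <- (v - K$cv) / K$f
  denom_ref <- scene$n[1] * rx + scene$n[2] * ry + scene$n[3]
  if (any(denom_ref <= 0))
    stop("render_stereo_pair: plane not fully visible in the reference view")
  z_ref <- scene$d / denom_ref
  Iref <- matrix(scene_albedo(scene, z_ref * rx, z_ref * ry), h, w)
  T <- se3_exp(xi)
  Rt <- t(T$rot)
  tb <- as.numeric(Rt %*% T$trans)  # R^T t
  ray <- rbind(rx, ry, 1)
  rw <- Rt %*% ray                  # rays rotated into the reference frame
  denom_in <- scene$n[1] * rw[1, ] + scene$n[2] * rw[2, ] + scene$n[3] * rw[3, ]
  lambda <- (scene$d + sum(scene$n * tb)) / denom_in
  if (any(lambda <= 0))
    stop("render_stereo_pair: plane behind the input camera")
  xw <- lambda * rw[1, ] - tb[1]
  yw <- lambda * rw[2, ] - tb[2]
  Iin <- matrix(scene_albedo(scene, xw, yw), h, w)
  disparity <- matrix(round(K$f * K$baseline / z_ref), h, w)
  list(reference = Iref, input = Iin, disparity = disparity,
       depth = matrix(z_ref, h, w))
}
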