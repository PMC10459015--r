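# Canned simulation scenarios: the degraded-GPS, outlier and intermittent
# study conditions, with the baselines they are compared against. These
# fix the conditions in one place so tests, scripts and examples all run
# the same experiment.

#' Dead-reckoned odometry trajectory
#'
#' Chains the odometry edges and places the resulting track at a known
#' start pose (rotation by the start heading, translation to the start
#' position). Used as the no-GPS baseline.
#'
#' @param edges `odometry_edges`.
#' @param start_pose length-3 pose of the first frame.
#' @return n x 3 pose matrix.
#' @export
odometry_dead_reckoning <- function(edges, start_pose) {
  g <- build_graph(edges)
  R <- rot2(start_pose[3])
  xy <- g[, 1:2, drop = FALSE] %*% t(R)
  cbind(xy[, 1] + start_pose[1], xy[, 2] + start_pose[2],
        wrap_angle(g[, 3] + start_pose[3]))
}

#' Piecewise-linear GPS interpolation baseline
#'
#' Linear interpolation of the fix coordinates over the pose index,
#' constant-extrapolated outside the fixed range. The vision-free
#' baseline for intermittent reception.
#'
#' @param gps `gps_observations`.
#' @param n number of poses.
#' @return n x 2 matrix of interpolated positions.
#' @export
gps_interpolation_track <- function(gps, n) {
  cbind(stats::approx(gps$pose_index, gps$coords[, 1], xout = seq_len(n),
                      rule = 2)$y,
        stats::approx(gps$pose_index, gps$coords[, 2], xout = seq_len(n),
                      rule = 2)$y)
}

# Information settings used when odometry edges are emitted exactly
# (noise-free): the optimizer is told to trust them at the sub-millimeter
# / microradian level, so the chain behaves near-rigidly and the GPS
# constraints resolve only the global placement.
.EXACT_ODOM_SIGMA_T <- 1e-4
.EXACT_ODOM_SIGMA_THETA <- 1e-6

#' Degraded-GPS localization scenario
#'
#' The dense-reception study condition: a ~1115 m smooth trajectory at 10
#' poses/s, exact odometry edges carrying stiff information (heading
#' stiffer than translation), one GPS fix per pose with zero-mean
#' Gaussian noise of 5 m per axis and optionally a fraction of fixes
#' displaced by uniform radial outliers in [0, 200] m. Runs global
#' alignment followed by local refinement with the synthetic stem
#' detections and reports trajectory RMSE against the true path.
#'
#' @param seed scenario seed.
#' @param outlier_fraction fraction of outlier fixes (0 for the Gaussian
#'   condition, 0.05 for the outlier condition).
#' @param gps_sigma per-axis GPS noise (default 5 m).
#' @param spec `world_spec` overriding the default world.
#' @param cfg `lm_config` (default: robust GPS weighting on).
#' @return list: `rmse_aligned`, `rmse_refined`, `rmse_stems`,
#'   `n_poses`, `n_stems`, `world`, `fit` diagnostics.
#' @export
run_degraded_gps_scenario <- function(seed, outlier_fraction = 0,
                                      gps_sigma = 5,
                                      spec = world_spec(seed = seed),
                                      cfg = lm_config()) {
  w <- simulate_world(spec)
  edges <- odometry_edges(w$edges$motions,
                          sigma_t = .EXACT_ODOM_SIGMA_T,
                          sigma_theta = .EXACT_ODOM_SIGMA_THETA)
  gps <- simulate_gps_track(w$trajectory,
                            gps_noise_spec(sigma_m = gps_sigma,
                                           outlier_fraction = outlier_fraction,
                                           seed = seed + 1000L))
  obs <- simulate_stem_observations(w$trajectory, w$stems, w$spec,
                                    seed = seed + 2000L)
  al <- align_global(edges, gps, cfg)
  rf <- refine_map(al$poses, edges, gps, obs, cfg = cfg)
  ev <- evaluate_stem_map(rf$stem_map, w$stems)
  list(rmse_aligned = trajectory_rmse(al$poses, w$trajectory),
       rmse_refined = trajectory_rmse(rf$poses, w$trajectory),
       rmse_stems = ev$rmse, n_poses = nrow(w$trajectory),
       n_stems = nrow(rf$stem_map$centers), world = w,
       fit = list(align = al$fit[c("iterations", "objective", "converged")],
                  refine = rf$fit[c("iterations", "objective", "converged")]))
}

#' Intermittent-GPS localization scenario
#'
#' The sparse-reception study condition: the same world with drifting
#' odometry (per-edge Gaussian noise, information matched to it) and only
#' 12 GPS fixes along the ~1115 m path (first, last, one per 100 m
#' interval, 5 m noise). Reports the optimized trajectory RMSE together
#' with the two baselines it must beat: raw dead-reckoned odometry and
#' piecewise-linear interpolation of the fixes.
#'
#' @param seed scenario seed.
#' @param drift_sigma_t,drift_sigma_theta per-edge odometry noise
#'   (defaults 0.005 m, 5e-4 rad: ~1 degree and ~0.5% distance drift per
#'   100 frames).
#' @param gps_sigma per-axis GPS noise (default 5 m).
#' @param spec `world_spec`.
#' @param cfg `lm_config`.
#' @return list: `rmse_refined`, `rmse_aligned`, `rmse_dead`,
#'   `rmse_interp`, `n_poses`, `n_fixes`, covariance traces before/after
#'   refinement.
#' @export
run_intermittent_scenario <- function(seed, drift_sigma_t = 0.005,
                                      drift_sigma_theta = 5e-4,
                                      gps_sigma = 5,
                                      spec = world_spec(seed = seed),
                                      cfg = lm_config()) {
  w <- simulate_world(spec)
  n <- nrow(w$trajectory)
  edges <- perturb_odometry(w$edges, drift_sigma_t, drift_sigma_theta,
                            seed = seed + 100L)
  gps <- simulate_gps_track(w$trajectory,
                            gps_noise_spec(sigma_m = gps_sigma,
                                           mode = "intermittent",
                                           seed = seed + 200L))
  obs <- simulate_stem_observations(w$trajectory, w$stems, w$spec,
                                    seed = seed + 300L)
  dead <- odometry_dead_reckoning(edges, w$trajectory[1, ])
  interp <- gps_interpolation_track(gps, n)
  al <- align_global(edges, gps, cfg)
  rf <- refine_map(al$poses, edges, gps, obs, cfg = cfg)
  cov_trace <- function(covs)
    mean(apply(covs, 1, function(m) sum(diag(matrix(m, 2)))))
  list(rmse_refined = trajectory_rmse(rf$poses, w$trajectory),
       rmse_aligned = trajectory_rmse(al$poses, w$trajectory),
       rmse_dead = trajectory_rmse(dead, w$trajectory),
       rmse_interp = trajectory_rmse(cbind(interp, 0), w$trajectory),
       n_poses = n, n_fixes = gps$n_obs,
       cov_trace_pre = cov_trace(rf$pre_map$covariances),
       cov_trace_post = cov_trace(rf$stem_map$covariances))
}

#' GPS-only dead-mapping stem baseline
#'
#' Places every observation in the world using poses whose positions are
#' the raw GPS fixes (headings taken from the supplied trajectory) and
#' averages per generating stem using the known synthetic association.
#' The accuracy a mapper would get from the receiver alone.
#'
#' @param obs `stem_observations` with `truth_id` (from
#'   [simulate_stem_observations()]).
#' @param gps dense `gps_observations` (one fix per pose).
#' @param trajectory n x 3 true poses (headings only are used).
#' @param stems true stem positions.
#' @return list: `rmse`, `centers`, `stem_id`.
#' @export
dead_map_stems <- function(obs, gps, trajectory, stems) {
  poses <- trajectory
  poses[gps$pose_index, 1:2] <- gps$coords
  world <- observations_to_world(obs, poses)
  agg <- rowsum(world, obs$truth_id)
  cnt <- as.numeric(table(obs$truth_id))
  centers <- agg / cnt
  ids <- as.integer(rownames(agg))
  list(rmse = sqrt(mean(rowSums((centers - stems[ids, , drop = FALSE])^2))),
       centers = centers, stem_id = ids)
}
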