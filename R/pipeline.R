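# End-to-end pipeline and evaluation utilities.

#' Position RMSE between two index-aligned trajectories
#'
#' Root mean squared Euclidean position error over per-pose (x, y)
#' differences; headings are excluded.
#'
#' @param estimate,truth n x 3 (or n x 2) pose matrices of equal length.
#' @return scalar RMSE in meters.
#' @export
trajectory_rmse <- function(estimate, truth) {
  if (nrow(estimate) != nrow(truth))
    stop("trajectory_rmse: trajectories differ in length")
  dx <- estimate[, 1] - truth[, 1]
  dy <- estimate[, 2] - truth[, 2]
  sqrt(mean(dx^2 + dy^2))
}

#' Compare a predicted stem map against ground truth
#'
#' Mutual-nearest-neighbor association within `max_dist`: a prediction and
#' a truth stem are matched when each is the other's nearest neighbor and
#' they lie within the window. Surplus predictions whose nearest truth
#' stem is already matched (within the window) are counted as duplicates;
#' predictions with no truth stem within the window are false positives.
#'
#' @param predicted `stem_map` or L x 2 matrix of predicted centers.
#' @param truth S x 2 matrix of true stem positions.
#' @param max_dist association window in meters (default 5).
#' @return list: `rmse` (over matched pairs), `matches` (two-column
#'   matrix: predicted index, truth index), `n_matched`, `duplicates`,
#'   `false_positives`, `missed` (truth stems without a match).
#' @export
evaluate_stem_map <- function(predicted, truth, max_dist = 5) {
  P <- if (inherits(predicted, "stem_map")) predicted$centers else
    matrix(predicted, ncol = 2)
  Tm <- matrix(truth, ncol = 2)
  if (nrow(P) == 0 || nrow(Tm) == 0)
    stop("evaluate_stem_map: empty input")
  d2 <- outer(P[, 1], Tm[, 1], "-")^2 + outer(P[, 2], Tm[, 2], "-")^2
  near_t <- apply(d2, 1, which.min)          # nearest truth per prediction
  near_p <- apply(d2, 2, which.min)          # nearest prediction per truth
  dmin <- sqrt(d2[cbind(seq_len(nrow(P)), near_t)])
  mutual <- which(near_p[near_t] == seq_len(nrow(P)) & dmin <= max_dist)
  matches <- cbind(predicted = mutual, truth = near_t[mutual])
  rest <- setdiff(seq_len(nrow(P)), mutual)
  dup <- rest[dmin[rest] <= max_dist & near_t[rest] %in% near_t[mutual]]
  fp <- setdiff(rest, dup)
  rmse <- if (length(mutual) > 0)
    sqrt(mean(d2[cbind(mutual, near_t[mutual])])) else NA_real_
  list(rmse = rmse, matches = matches, n_matched = length(mutual),
       duplicates = length(dup), false_positives = length(fp),
       missed = setdiff(seq_len(nrow(Tm)), near_t[mutual]))
}

#' Pipeline configuration
#'
#' Validated key-value settings for [run_pipeline()]. Unknown keys are
#' rejected.
#'
#' @param calibration path to a calibration YAML (required when frames
#'   are processed).
#' @param frames optional list of `list(intensity=, disparity=)` file
#'   paths, consecutive frames of the left camera.
#' @param odometry optional path to a twists file written by
#'   [write_twists_file()] (used when `frames` is NULL).
#' @param gps path to a GPS track file.
#' @param detections optional path to a detections file.
#' @param output_dir directory for outputs (created if missing).
#' @param vo_percent pixel-selection percentage (default 25).
#' @param gps_sigma default GPS sigma in meters (default 5).
#' @param odom_sigma_t,odom_sigma_theta odometry information defaults.
#' @param use_pdop scale GPS sigma by PDOP when present (default FALSE).
#' @param cluster_radius,cluster_min_pts DBSCAN parameters (1 m, 10).
#' @param robust_gps Tukey-weight GPS residuals (default TRUE).
#' @param frame_rate_hz frame rate used to timestamp frames (default 10).
#' @param seed RNG seed recorded in the report.
#' @return list of class `run_config`.
#' @export
run_config <- function(calibration = NULL, frames = NULL, odometry = NULL,
                       gps = NULL, detections = NULL, output_dir = NULL,
                       vo_percent = 25, gps_sigma = 5, odom_sigma_t = 0.1,
                       odom_sigma_theta = 0.005, use_pdop = FALSE,
                       cluster_radius = 1, cluster_min_pts = 10,
                       robust_gps = TRUE, frame_rate_hz = 10, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full localization-and-mapping pipeline
#'
#' Visual odometry (when stereo frames are supplied) or ingestion of a
#' precomputed odometry file, global alignment against the GPS track, and
#' local refinement with the stem detections. Outputs (trajectories, stem
#' map) are written to `config$output_dir` when set.
#'
#' @param config `run_config`.
#' @return list: `poses` (refined UTM trajectory), `stem_map` (NULL when
#'   no detections), `aligned_poses`, `edges`, `report` (per-stage
#'   diagnostics).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list()
  tic <- function() proc.time()[["elapsed"]]
  # --- odometry ---
  t0 <- tic()
  if (!is.null(config$frames)) {
    if (is.null(config$calibration))
      stop("pipeline/configuration: calibration file required for visual odometry")
    K <- read_calibration(config$calibration)
    motions <- matrix(0, length(config$frames) - 1, 3)
    prev <- NULL
    for (fi in seq_along(config$frames)) {
      fr <- config$frames[[fi]]
      frame <- make_frame(read_image(fr$intensity),
                          read_disparity(fr$disparity), K)
      if (!is.null(prev)) {
        vo <- estimate_egomotion(prev, frame, K, percent = config$vo_percent)
        motions[fi - 1, ] <- vo_to_odometry(vo$xi)
      }
      prev <- frame
    }
  } else if (!is.null(config$odometry)) {
    tw <- read_twists_file(config$odometry)
    motions <- as.matrix(tw[, c("dx", "dy", "dtheta")])
  } else {
    stop("pipeline/odometry: neither frames nor an odometry file supplied")
  }
  edges <- odometry_edges(motions, sigma_t = config$odom_sigma_t,
                          sigma_theta = config$odom_sigma_theta)
  n <- edges$n_edges + 1
  report$odometry <- list(n_poses = n, seconds = tic() - t0)
  # --- global alignment ---
  t0 <- tic()
  if (is.null(config$gps)) stop("pipeline/gps: no GPS file supplied")
  gps_df <- read_gps_file(config$gps)
  frame_times <- (seq_len(n) - 1) / config$frame_rate_hz
  gps <- match_gps_to_frames(gps_df, frame_times, sigma = config$gps_sigma,
                             use_pdop = config$use_pdop)
  cfg <- lm_config(robust_gps = config$robust_gps)
  aligned <- align_global(edges, gps, cfg)
  report$alignment <- list(n_gps = gps$n_obs,
                           iterations = aligned$fit$iterations,
                           objective = aligned$fit$objective,
                           seconds = tic() - t0)
  # --- local refinement ---
  poses <- aligned$poses
  map <- NULL
  if (!is.null(config$detections)) {
    t0 <- tic()
    obs <- read_detections_file(config$detections)
    ref <- refine_map(poses, edges, gps, obs,
                      radius = config$cluster_radius,
                      min_pts = config$cluster_min_pts, cfg = cfg)
    poses <- ref$poses
    map <- ref$stem_map
    report$refinement <- list(n_obs = obs$n_obs,
                              n_stems = nrow(map$centers),
                              n_outliers = sum(ref$assignment$labels == 0),
                              iterations = ref$fit$iterations,
                              seconds = tic() - t0)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory_file(poses, file.path(config$output_dir,
                                           "trajectory.txt"))
    write_trajectory_file(aligned$poses,
                          file.path(config$output_dir,
                                    "trajectory_aligned.txt"))
    if (!is.null(map)) {
      write_stem_map(map, file.path(config$output_dir, "stem_map.txt"))
      write_stem_map(map, file.path(config$output_dir, "stem_map.geojson"))
    }
  }
  list(poses = poses, stem_map = map, aligned_poses = aligned$poses,
       edges = edges, report = report)
}
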