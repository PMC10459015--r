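# Landmark association and joint trajectory/stem refinement.
#
# Per-frame stem detections (camera-frame planar offsets) are transformed
# into the world frame with the globally aligned poses, associated into
# individual stems by density-based clustering, and the pose track and
# cluster centers are then optimized jointly. The global-orientation
# parameter is omitted here: poses are already in UTM, so the GPS residual
# reduces to a position difference with Jacobian (I2, 0).

#' Per-frame stem observations
#'
#' @param pose_index integer vector: pose from which each stem was
#'   observed.
#' @param offsets m x 2 matrix of camera-frame planar offsets in meters:
#'   lateral (x, right positive) and forward (y, must be positive).
#' @param sigma0,sigma_range range-dependent observation noise model
#'   `sigma(d) = sigma0 + sigma_range * d` (meters) used for the default
#'   isotropic information matrices; distant stems get weaker information.
#' @param info optional m x 2 x 2 array overriding the defaults.
#' @return list of class `stem_observations`.
#' @export
stem_observations <- function(pose_index, offsets, sigma0 = 0.1,
                              sigma_range = 0.05, info = NULL) {
  offsets <- matrix(as.numeric(offsets), ncol = 2)
  m <- nrow(offsets)
  pose_index <- as.integer(pose_index)
  stopifnot(length(pose_index) == m)
  if (any(offsets[, 2] <= 0))
    stop("stem_observations: forward component must be positive (stem in front of camera)")
  if (is.null(info)) {
    d <- sqrt(rowSums(offsets^2))
    s <- sigma0 + sigma_range * d
    info <- array(0, c(m, 2, 2))
    info[, 1, 1] <- 1 / s^2
    info[, 2, 2] <- 1 / s^2
  } else {
    stopifnot(all(dim(info) == c(m, 2, 2)))
  }
  structure(list(pose_index = pose_index, offsets = offsets, info = info,
                 n_obs = m), class = "stem_observations")
}

#' Transform camera-frame stem observations to the world frame
#'
#' Each offset is rotated by its pose heading and translated by the pose
#' position: `R(theta_i) z + t_i`.
#'
#' @param obs `stem_observations` (or an m x 2 offset matrix with
#'   `pose_index` attached as an attribute is not supported; use the
#'   constructor).
#' @param poses n x 3 pose matrix.
#' @return m x 2 matrix of world coordinates.
#' @export
observations_to_world <- function(obs, poses) {
  i <- obs$pose_index
  th <- poses[i, 3]
  cth <- cos(th)
  sth <- sin(th)
  zx <- obs$offsets[, 1]
  zy <- obs$offsets[, 2]
  cbind(cth * zx - sth * zy + poses[i, 1],
        sth * zx + cth * zy + poses[i, 2])
}

#' Density-based clustering (DBSCAN) of planar points
#'
#' Classic DBSCAN with Euclidean distance and a uniform-grid region query
#' (cells of side `radius`, 3 x 3 neighborhood scan). Points are processed
#' in input order, so the labeling is deterministic. Label 0 marks noise.
#'
#' @param points m x 2 matrix.
#' @param radius neighborhood radius in meters (default 1).
#' @param min_pts minimum neighborhood size (point itself included) for a
#'   core point (default 10).
#' @return list of class `cluster_assignment`: `labels` (integer, 0 =
#'   outlier), `n_clusters`, `sizes` (named table of cluster sizes).
#' @export
dbscan_cluster <- function(points, radius = 1, min_pts = 10) {
  stopifnot(radius > 0, min_pts >= 1)
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  cx <- floor(points[, 1] / radius)
  cy <- floor(points[, 2] / radius)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  keys <- paste(cx, cy)
  for (i in seq_len(n)) {
    k <- keys[i]
    grid[[k]] <- c(grid[[k]], i)
  }
  r2 <- radius^2
  region <- function(i) {
    cand <- integer(0)
    for (ddx in -1:1) for (ddy in -1:1) {
      k <- paste(cx[i] + ddx, cy[i] + ddy)
      cand <- c(cand, grid[[k]])
    }
    d2 <- (points[cand, 1] - points[i, 1])^2 +
      (points[cand, 2] - points[i, 2])^2
    cand[d2 <= r2]
  }
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    N <- region(i)
    if (length(N) < min_pts) next  # provisional noise; may become border
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- N[N != i]
    head <- 1L
    while (head <= length(seeds)) {
      j <- seeds[head]
      head <- head + 1L
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        Nj <- region(j)
        if (length(Nj) >= min_pts)
          seeds <- c(seeds, Nj[!visited[Nj] & labels[Nj] == 0L])
      }
    }
  }
  sizes <- if (cl > 0) tabulate(labels[labels > 0], nbins = cl) else integer(0)
  structure(list(labels = labels, n_clusters = cl, sizes = sizes),
            class = "cluster_assignment")
}

#' Cluster centers and empirical covariances
#'
#' Arithmetic mean of the member points per cluster; outliers (label 0)
#' are excluded from every mean. The per-cluster empirical 2 x 2
#' covariance is recorded for reporting (map ellipses).
#'
#' @param points m x 2 matrix of world coordinates.
#' @param assignment `cluster_assignment` (or an integer label vector).
#' @return list of class `stem_map`: `centers` (L x 2), `counts`,
#'   `covariances` (L x 2 x 2), `labels` (the cluster ids, 1..L).
#' @export
cluster_centers <- function(points, assignment) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  keep <- labels > 0
  if (!any(keep)) stop("cluster_centers: no clusters (empty map)")
  ids <- sort(unique(labels[keep]))
  L <- length(ids)
  centers <- matrix(0, L, 2)
  counts <- integer(L)
  covs <- array(0, c(L, 2, 2))
  for (a in seq_len(L)) {
    mem <- which(labels == ids[a])
    counts[a] <- length(mem)
    pts <- points[mem, , drop = FALSE]
    centers[a, ] <- colMeans(pts)
    covs[a, , ] <- if (length(mem) > 1) stats::cov(pts) else matrix(0, 2, 2)
  }
  structure(list(centers = centers, counts = counts, covariances = covs,
                 labels = ids), class = "stem_map")
}

#' Stem observation residual
#'
#' Maps a candidate stem center into the camera frame of a pose and
#' subtracts the observation: `R(theta)^T (m - t) - z`. Exact inverse of
#' [observations_to_world()]: the residual is zero when the center equals
#' the world-transformed observation.
#'
#' @param pose length-3 pose.
#' @param center length-2 stem center (world frame).
#' @param offset length-2 camera-frame observation.
#' @return length-2 residual.
#' @export
stem_error <- function(pose, center, offset) {
  as.numeric(t(rot2(pose[3])) %*% (center - pose[1:2]) - offset)
}

#' Augmented state for local refinement
#'
#' @param poses n x 3 UTM pose matrix.
#' @param centers L x 2 stem centers.
#' @return list of class `augmented_state`; packed length `3 n + 2 L`.
#' @export
augmented_state <- function(poses, centers) {
  structure(list(poses = poses, centers = matrix(centers, ncol = 2)),
            class = "augmented_state")
}

# Residuals of the refinement problem: odometry, GPS (position difference
# in UTM) and stem observation rows, for observations with cluster_id > 0.
refine_residuals <- function(aug, edges, gps, obs, cluster_id) {
  poses <- aug$poses
  m <- edges$n_edges
  i <- seq_len(m)
  thi <- poses[i, 3]
  thij <- edges$motions[, 3]
  dx <- poses[i + 1, 1] - poses[i, 1]
  dy <- poses[i + 1, 2] - poses[i, 2]
  ex <- cos(thi) * dx + sin(thi) * dy - edges$motions[, 1]
  ey <- -sin(thi) * dx + cos(thi) * dy - edges$motions[, 2]
  c2 <- cos(thij)
  s2 <- sin(thij)
  r_odo <- rbind(c2 * ex + s2 * ey,
                 -s2 * ex + c2 * ey,
                 wrap_angle(poses[i + 1, 3] - thi - thij))
  pi_ <- gps$pose_index
  r_gps <- rbind(poses[pi_, 1] - gps$coords[, 1],
                 poses[pi_, 2] - gps$coords[, 2])
  keep <- which(cluster_id > 0)
  oi <- obs$pose_index[keep]
  th <- poses[oi, 3]
  cth <- cos(th)
  sth <- sin(th)
  mx <- aug$centers[cluster_id[keep], 1] - poses[oi, 1]
  my <- aug$centers[cluster_id[keep], 2] - poses[oi, 2]
  r_stem <- rbind(cth * mx + sth * my - obs$offsets[keep, 1],
                  -sth * mx + cth * my - obs$offsets[keep, 2])
  list(odo = as.numeric(r_odo), gps = as.numeric(r_gps),
       stem = as.numeric(r_stem), gps_norms = sqrt(colSums(r_gps^2)),
       keep = keep)
}

refine_objective <- function(aug, edges, gps, obs, cluster_id, gps_weights) {
  r <- refine_residuals(aug, edges, gps, obs, cluster_id)
  ro <- matrix(r$odo, 3)
  obj <- sum(ro[1, ] * (edges$info[, 1, 1] * ro[1, ] + edges$info[, 1, 2] * ro[2, ] + edges$info[, 1, 3] * ro[3, ]) +
             ro[2, ] * (edges$info[, 2, 1] * ro[1, ] + edges$info[, 2, 2] * ro[2, ] + edges$info[, 2, 3] * ro[3, ]) +
             ro[3, ] * (edges$info[, 3, 1] * ro[1, ] + edges$info[, 3, 2] * ro[2, ] + edges$info[, 3, 3] * ro[3, ]))
  rg <- matrix(r$gps, 2)
  obj <- obj + sum(gps_weights *
                   (rg[1, ]^2 * gps$info[, 1, 1] +
                    2 * rg[1, ] * rg[2, ] * gps$info[, 1, 2] +
                    rg[2, ]^2 * gps$info[, 2, 2]))
  rs <- matrix(r$stem, 2)
  k <- r$keep
  obj + sum(rs[1, ]^2 * obs$info[k, 1, 1] +
            2 * rs[1, ] * rs[2, ] * obs$info[k, 1, 2] +
            rs[2, ]^2 * obs$info[k, 2, 2])
}

refine_assembly_cache <- function(edges, gps, obs, cluster_id, n, L) {
  m <- edges$n_edges
  K <- gps$n_obs
  keep <- which(cluster_id > 0)
  S <- length(keep)
  dim <- 3 * n + 2 * L
  e <- seq_len(m)
  ro <- 3 * (e - 1)
  ci <- 3 * (e - 1)
  cj <- 3 * e
  jrow_odo <- c(ro + 1, ro + 1, ro + 1, ro + 2, ro + 2, ro + 2, ro + 3,
                ro + 1, ro + 1, ro + 2, ro + 2, ro + 3)
  jcol_odo <- c(ci + 1, ci + 2, ci + 3, ci + 1, ci + 2, ci + 3, ci + 3,
                cj + 1, cj + 2, cj + 1, cj + 2, cj + 3)
  kk <- seq_len(K)
  rg <- 3 * m + 2 * (kk - 1)
  cg <- 3 * (gps$pose_index - 1)
  jrow_gps <- c(rg + 1, rg + 2)
  jcol_gps <- c(cg + 1, cg + 2)
  ss <- seq_len(S)
  rs <- 3 * m + 2 * K + 2 * (ss - 1)
  cp <- 3 * (obs$pose_index[keep] - 1)
  cm <- 3 * n + 2 * (cluster_id[keep] - 1)
  jrow_stem <- c(rs + 1, rs + 1, rs + 1, rs + 2, rs + 2, rs + 2,
                 rs + 1, rs + 1, rs + 2, rs + 2)
  jcol_stem <- c(cp + 1, cp + 2, cp + 3, cp + 1, cp + 2, cp + 3,
                 cm + 1, cm + 2, cm + 1, cm + 2)
  qrow_odo <- rep(ro, each = 9) + rep(rep(1:3, 3), m)
  qcol_odo <- rep(ro, each = 9) + rep(rep(1:3, each = 3), m)
  qval_odo <- as.numeric(aperm(edges$info, c(2, 3, 1)))
  qrow_gps <- rep(rg, each = 4) + rep(rep(1:2, 2), K)
  qcol_gps <- rep(rg, each = 4) + rep(rep(1:2, each = 2), K)
  qval_gps <- as.numeric(aperm(gps$info, c(2, 3, 1)))
  qrow_stem <- rep(rs, each = 4) + rep(rep(1:2, 2), S)
  qcol_stem <- rep(rs, each = 4) + rep(rep(1:2, each = 2), S)
  qval_stem <- as.numeric(aperm(obs$info[keep, , , drop = FALSE], c(2, 3, 1)))
  list(m = m, K = K, S = S, keep = keep, dim = dim,
       n_rows = 3 * m + 2 * K + 2 * S,
       jrow = c(jrow_odo, jrow_gps, jrow_stem),
       jcol = c(jcol_odo, jcol_gps, jcol_stem),
       qrow = c(qrow_odo, qrow_gps, qrow_stem),
       qcol = c(qcol_odo, qcol_gps, qcol_stem),
       qval_odo = qval_odo, qval_gps = qval_gps, qval_stem = qval_stem)
}

#' Assemble the sparse normal equations of the joint refinement
#'
#' Analytic blocks, validated against finite differences in the test
#' suite: odometry blocks as in the global alignment, the GPS block
#' reduced to (I2, 0) because the orientation parameter is gone, and per
#' observation the pose block `E = [-R(theta)^T | dR(theta)^T/dtheta (m - t)]`
#' and center block `F = R(theta)^T`.
#'
#' @param aug `augmented_state`.
#' @param edges `odometry_edges`.
#' @param gps `gps_observations` in UTM (not anchored).
#' @param obs `stem_observations`.
#' @param cluster_id integer per-observation cluster index (0 = outlier,
#'   excluded), indexing rows of `aug$centers`.
#' @param gps_weights per-fix robust weights.
#' @param cache internal assembly cache; rebuilt when NULL.
#' @return list with sparse `H` ((3n+2L) x (3n+2L)), `b`, `objective`,
#'   `cache`.
#' @export
assemble_refinement_system <- function(aug, edges, gps, obs, cluster_id,
                                       gps_weights = rep(1, gps$n_obs),
                                       cache = NULL) {
  n <- nrow(aug$poses)
  L <- nrow(aug$centers)
  if (is.null(cache))
    cache <- refine_assembly_cache(edges, gps, obs, cluster_id, n, L)
  poses <- aug$poses
  m <- cache$m
  i <- seq_len(m)
  thi <- poses[i, 3]
  thij <- edges$motions[, 3]
  dx <- poses[i + 1, 1] - poses[i, 1]
  dy <- poses[i + 1, 2] - poses[i, 2]
  cs <- cos(thi + thij)
  sn <- sin(thi + thij)
  q1 <- -sin(thi) * dx + cos(thi) * dy
  q2 <- -cos(thi) * dx - sin(thi) * dy
  c2 <- cos(thij)
  s2 <- sin(thij)
  a13 <- c2 * q1 + s2 * q2
  a23 <- -s2 * q1 + c2 * q2
  vals_odo <- c(-cs, -sn, a13, sn, -cs, a23, rep(-1, m),
                cs, sn, -sn, cs, rep(1, m))
  vals_gps <- rep(1, 2 * cache$K)
  keep <- cache$keep
  oi <- obs$pose_index[keep]
  th <- poses[oi, 3]
  cth <- cos(th)
  sth <- sin(th)
  mx <- aug$centers[cluster_id[keep], 1] - poses[oi, 1]
  my <- aug$centers[cluster_id[keep], 2] - poses[oi, 2]
  e13 <- -sth * mx + cth * my
  e23 <- -cth * mx - sth * my
  vals_stem <- c(-cth, -sth, e13, sth, -cth, e23,
                 cth, sth, -sth, cth)
  J <- Matrix::sparseMatrix(i = cache$jrow, j = cache$jcol,
                            x = c(vals_odo, vals_gps, vals_stem),
                            dims = c(cache$n_rows, cache$dim))
  wq <- rep(gps_weights, each = 4)
  Q <- Matrix::sparseMatrix(i = cache$qrow, j = cache$qcol,
                            x = c(cache$qval_odo, cache$qval_gps * wq,
                                  cache$qval_stem),
                            dims = c(cache$n_rows, cache$n_rows))
  res <- refine_residuals(aug, edges, gps, obs, cluster_id)
  r <- c(res$odo, res$gps, res$stem)
  QJ <- Q %*% J
  H <- Matrix::forceSymmetric(Matrix::crossprod(J, QJ))
  Qr <- Q %*% r
  b <- as.numeric(Matrix::crossprod(J, Qr))
  list(H = H, b = b, r = r, gps_norms = res$gps_norms,
       objective = sum(r * as.numeric(Qr)), cache = cache)
}

#' Jointly refine the trajectory and the stem map
#'
#' Pipeline of the local-refinement phase: transform observations with the
#' aligned poses, cluster them (once; the association is fixed during
#' optimization), initialize centers at the cluster means, and optimize
#' poses and centers together with the same damping schedule and step-norm
#' termination as the global alignment. Cluster covariances are recorded
#' before and after refinement.
#'
#' @param poses n x 3 globally aligned UTM poses.
#' @param edges `odometry_edges`.
#' @param gps `gps_observations` in UTM.
#' @param obs `stem_observations`.
#' @param radius,min_pts DBSCAN parameters (defaults 1 m and 10).
#' @param cfg `lm_config`.
#' @return list: refined `poses`, `stem_map` (refined centers, counts and
#'   post-refinement covariances), `pre_map` (means/covariances before
#'   refinement), `assignment`, `cluster_id` (per observation), `fit`.
#' @export
refine_map <- function(poses, edges, gps, obs, radius = 1, min_pts = 10,
                       cfg = lm_config()) {
  world <- observations_to_world(obs, poses)
  assignment <- dbscan_cluster(world, radius, min_pts)
  pre_map <- cluster_centers(world, assignment)
  cluster_id <- match(assignment$labels, pre_map$labels)
  cluster_id[is.na(cluster_id)] <- 0L
  aug <- augmented_state(poses, pre_map$centers)
  cache <- refine_assembly_cache(edges, gps, obs, cluster_id,
                                 nrow(poses), nrow(pre_map$centers))
  n3 <- 3 * nrow(poses)
  weights_last <- rep(1, gps$n_obs)
  linearize <- function(s) {
    res <- refine_residuals(s, edges, gps, obs, cluster_id)
    w <- gps_robust_weights(res$gps_norms, cfg$robust_gps, cfg$tukey_c,
                            cfg$mad_k)
    weights_last <<- w
    sys <- assemble_refinement_system(s, edges, gps, obs, cluster_id, w,
                                      cache)
    list(H = sys$H, b = sys$b, objective = sys$objective, weights = w)
  }
  objective <- function(s, w)
    refine_objective(s, edges, gps, obs, cluster_id, w)
  update <- function(s, ds) {
    dp <- matrix(ds[seq_len(n3)], ncol = 3, byrow = TRUE)
    s$poses[, 1] <- s$poses[, 1] + dp[, 1]
    s$poses[, 2] <- s$poses[, 2] + dp[, 2]
    s$poses[, 3] <- wrap_angle(s$poses[, 3] + dp[, 3])
    s$centers <- s$centers + matrix(ds[-seq_len(n3)], ncol = 2, byrow = TRUE)
    s
  }
  out <- lm_driver(aug, linearize, objective, update, cfg)
  world_post <- observations_to_world(obs, out$state$poses)
  post_map <- structure(list(centers = out$state$centers,
                             counts = pre_map$counts,
                             covariances = pre_map$covariances,
                             labels = pre_map$labels),
                        class = "stem_map")
  for (a in seq_along(pre_map$labels)) {
    mem <- which(cluster_id == a)
    pts <- world_post[mem, , drop = FALSE]
    post_map$covariances[a, , ] <- if (length(mem) > 1) stats::cov(pts)
      else matrix(0, 2, 2)
  }
  list(poses = out$state$poses, stem_map = post_map, pre_map = pre_map,
       assignment = assignment, cluster_id = cluster_id,
       fit = list(objective = out$objective, iterations = out$iterations,
                  converged = out$converged, gps_weights = weights_last,
                  log = out$log))
}
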