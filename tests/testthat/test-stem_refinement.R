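test_that("camera-frame observations transform to the world and back", {
  obs <- stem_observations(c(1, 2), rbind(c(1, 2), c(1, 0.5)))
  poses <- rbind(c(0, 0, 0), c(10, 0, pi / 2))
  w <- observations_to_world(obs, poses)
  expect_equal(w[1, ], c(1, 2))
  expect_equal(w[2, ], c(10 - 0.5, 1), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:15) {
    pose <- stats::runif(3, -3, 3)
    off <- c(stats::runif(1, -2, 2), stats::runif(1, 0.1, 8))
    o1 <- stem_observations(1, rbind(off))
    ww <- observations_to_world(o1, rbind(pose))
    expect_equal(as.numeric(ww),
                 as.numeric(rot2(pose[3]) %*% off + pose[1:2]),
                 tolerance = 1e-12)
    # stem_error is the exact inverse of the world transform
    expect_lt(max(abs(stem_error(pose, as.numeric(ww), off))), 1e-12)
  }
  expect_error(stem_observations(1, rbind(c(0, -1))), "forward")
})

test_that("stem error at the identity pose is center minus observation", {
  expect_equal(stem_error(c(0, 0, 0), c(3, 4), c(1, 2)), c(2, 2))
  set.seed(2)
  for (i in 1:15) {
    pose <- stats::runif(3, -3, 3)
    ctr <- stats::runif(2, -5, 5)
    off <- c(stats::runif(1, -2, 2), stats::runif(1, 0.1, 8))
    expect_equal(stem_error(pose, ctr, off),
                 stem_residual_bf(pose, ctr, off), tolerance = 1e-12)
  }
})

test_that("DBSCAN separates well-spaced groups and flags sparse noise", {
  set.seed(3)
  g1 <- cbind(stats::rnorm(20, 0, 0.05), stats::rnorm(20, 0, 0.05))
  g2 <- cbind(stats::rnorm(20, 10, 0.05), stats::rnorm(20, 0, 0.05))
  pts <- rbind(g1, g2)
  a <- dbscan_cluster(pts, radius = 1, min_pts = 10)
  expect_equal(a$n_clusters, 2)
  expect_true(all(a$labels > 0))
  expect_equal(length(unique(a$labels[1:20])), 1)
  expect_equal(length(unique(a$labels[21:40])), 1)
  # five isolated points are all below the min_pts threshold
  iso <- cbind(seq(0, 40, 10), rep(50, 5))
  expect_true(all(dbscan_cluster(iso, 1, 10)$labels == 0))
})

test_that("DBSCAN matches a brute-force reference on random point sets", {
  set.seed(4)
  for (rep in 1:5) {
    centers <- cbind(stats::runif(6, 0, 30), stats::runif(6, 0, 30))
    pts <- do.call(rbind, lapply(1:6, function(a)
      cbind(stats::rnorm(15, centers[a, 1], 0.4),
            stats::rnorm(15, centers[a, 2], 0.4))))
    pts <- rbind(pts, cbind(stats::runif(10, 0, 30),
                            stats::runif(10, 0, 30)))
    got <- dbscan_cluster(pts, radius = 1, min_pts = 8)$labels
    want <- dbscan_bf(pts, eps = 1, min_pts = 8)
    expect_equal(canon_labels(got), canon_labels(want))
    expect_equal(got == 0, want == 0)
  }
})

test_that("cluster labels are invariant under rigid transformation", {
  set.seed(5)
  pts <- cbind(stats::runif(60, 0, 20), stats::runif(60, 0, 20))
  a1 <- dbscan_cluster(pts, 1.5, 4)$labels
  R <- rot2(0.83)
  pts2 <- sweep(pts %*% t(R), 2, c(-40, 17), "+")
  a2 <- dbscan_cluster(pts2, 1.5, 4)$labels
  expect_equal(canon_labels(a1), canon_labels(a2))
})

test_that("cluster centers are member means with outliers excluded", {
  pts <- rbind(c(0, 0), c(2, 0), c(100, 100))
  m <- cluster_centers(pts, c(1L, 1L, 0L))
  expect_equal(m$centers, rbind(c(1, 0)))
  expect_equal(m$counts, 2L)
  set.seed(6)
  pts <- cbind(stats::rnorm(50), stats::rnorm(50))
  labels <- sample(0:3, 50, replace = TRUE)
  m <- cluster_centers(pts, labels)
  for (a in seq_along(m$labels)) {
    mem <- labels == m$labels[a]
    expect_equal(m$centers[a, ], colMeans(pts[mem, , drop = FALSE]))
    expect_equal(matrix(m$covariances[a, , ], 2),
                 stats::cov(pts[mem, , drop = FALSE]))
  }
  expect_error(cluster_centers(pts, rep(0L, 50)), "empty")
})

test_that("refinement blocks E and F match finite differences", {
  set.seed(7)
  motions <- rbind(c(0.9, 0.05, 0.2), c(1, -0.05, -0.1))
  poses <- build_graph(motions) + matrix(stats::rnorm(9, 0, 0.2), 3, 3)
  centers <- rbind(c(1.5, 2), c(0.5, 3.5))
  offsets <- rbind(c(0.4, 2.2), c(-0.3, 3), c(0.2, 2.8))
  obs_idx <- c(1L, 2L, 3L)
  obs_cluster <- c(1L, 1L, 2L)
  obs <- stem_observations(obs_idx, offsets)
  gps_coords <- poses[c(1, 3), 1:2] + 0.3
  gps <- gps_track(gps_coords, c(1, 3), sigma = 2)
  edges <- odometry_edges(motions, sigma_t = 0.5, sigma_theta = 0.3)
  aug <- augmented_state(poses, centers)
  sys <- assemble_refinement_system(aug, edges, gps, obs, obs_cluster)
  x <- c(as.numeric(t(poses)), as.numeric(t(centers)))
  res_fn <- function(xx) refine_residual_stack_bf(xx, 3, motions, gps_coords,
                                                  c(1, 3), offsets, obs_idx,
                                                  obs_cluster)
  Jfd <- fd_jacobian(res_fn, x)
  d <- sqrt(rowSums(offsets^2))
  Qd <- diag(c(rep(c(4, 4, 1 / 0.09), 2), rep(0.25, 4),
               rep(1 / (0.1 + 0.05 * d)^2, each = 2)))
  expect_lt(max(abs(as.matrix(sys$H) - t(Jfd) %*% Qd %*% Jfd)), 1e-6)
  expect_lt(max(abs(sys$b - as.numeric(t(Jfd) %*% Qd %*% res_fn(x)))), 1e-6)
})

test_that("zero-residual refinement configuration has zero gradient", {
  motions <- rbind(c(1, 0, 0.1), c(1, 0, -0.2))
  poses <- build_graph(motions)
  stems_true <- rbind(c(0.5, 3), c(-1, 4))
  obs_idx <- c(1L, 2L, 3L, 3L)
  obs_cluster <- c(1L, 1L, 2L, 1L)
  offsets <- do.call(rbind, lapply(seq_along(obs_idx), function(q) {
    p <- poses[obs_idx[q], ]
    as.numeric(t(rot2(p[3])) %*% (stems_true[obs_cluster[q], ] - p[1:2]))
  }))
  obs <- stem_observations(obs_idx, offsets)
  gps <- gps_track(poses[c(1, 3), 1:2], c(1, 3))
  edges <- odometry_edges(motions)
  sys <- assemble_refinement_system(augmented_state(poses, stems_true),
                                    edges, gps, obs, obs_cluster)
  expect_lt(max(abs(sys$b)), 1e-10)
  expect_equal(sys$objective, 0, tolerance = 1e-12)
})

test_that("sparse refinement equals a dense brute-force optimizer", {
  set.seed(8)
  motions <- cbind(stats::runif(2, 0.8, 1.2), stats::runif(2, -0.1, 0.1),
                   stats::runif(2, -0.2, 0.2))
  poses <- build_graph(motions)
  stems_true <- rbind(c(1, 3), c(-1.5, 2.5))
  obs_idx <- rep(1:3, each = 2)
  obs_cluster <- rep(c(1L, 2L), 3)
  offsets <- do.call(rbind, lapply(seq_along(obs_idx), function(q) {
    p <- poses[obs_idx[q], ]
    as.numeric(t(rot2(p[3])) %*% (stems_true[obs_cluster[q], ] - p[1:2])) +
      stats::rnorm(2, 0, 0.1)
  }))
  sig <- 0.4
  info <- array(0, c(6, 2, 2))
  info[, 1, 1] <- info[, 2, 2] <- 1 / sig^2
  obs <- stem_observations(obs_idx, offsets, info = info)
  gps_coords <- poses[c(1, 3), 1:2] + matrix(stats::rnorm(4, 0, 0.3), 2, 2)
  gps <- gps_track(gps_coords, c(1, 3), sigma = 1)
  edges <- odometry_edges(motions, sigma_t = 0.3, sigma_theta = 0.2)
  centers0 <- stems_true + matrix(stats::rnorm(4, 0, 0.2), 2, 2)

  cfg <- lm_config(robust_gps = FALSE, step_tol = 1e-10)
  n3 <- 3 * nrow(poses)
  cluster_id <- obs_cluster
  # drive the package path directly at fixed association
  aug <- augmented_state(poses, centers0)
  linearize <- function(s) {
    sys <- assemble_refinement_system(s, edges, gps, obs, cluster_id)
    list(H = sys$H, b = sys$b, objective = sys$objective,
         weights = rep(1, gps$n_obs))
  }
  objective <- function(s, w)
    stemmapr:::refine_objective(s, edges, gps, obs, cluster_id, w)
  update <- function(s, ds) {
    dp <- matrix(ds[seq_len(n3)], ncol = 3, byrow = TRUE)
    s$poses <- s$poses + dp
    s$centers <- s$centers + matrix(ds[-seq_len(n3)], ncol = 2, byrow = TRUE)
    s
  }
  out <- stemmapr:::lm_driver(aug, linearize, objective, update, cfg)
  got <- c(as.numeric(t(out$state$poses)), as.numeric(t(out$state$centers)))

  x0 <- c(as.numeric(t(poses)), as.numeric(t(centers0)))
  Qdiag <- c(rep(c(1 / 0.09, 1 / 0.09, 1 / 0.04), 2), rep(1, 4),
             rep(1 / sig^2, 12))
  xo <- dense_lm_oracle(function(xx)
    refine_residual_stack_bf(xx, 3, motions, gps_coords, c(1, 3),
                             offsets, obs_idx, obs_cluster), x0, Qdiag)
  expect_lt(max(abs(got - xo)), 1e-7)
})

test_that("noiseless world is a fixed point of refinement", {
  w <- tiny_world(seed = 11)
  gps <- simulate_gps_track(w$trajectory, gps_noise_spec(sigma_m = 0))
  obs <- simulate_stem_observations(w$trajectory, w$stems, w$spec,
                                    noiseless = TRUE)
  rf <- refine_map(w$trajectory, w$edges, gps, obs,
                   cfg = lm_config(step_tol = 1e-9))
  expect_lt(trajectory_rmse(rf$poses, w$trajectory), 1e-8)
  ev <- evaluate_stem_map(rf$stem_map, w$stems)
  expect_lt(ev$rmse, 1e-6)
  expect_equal(ev$duplicates, 0)
  expect_equal(ev$false_positives, 0)
})

test_that("refinement does not increase the objective across accepted steps", {
  w <- tiny_world(seed = 12, length_m = 80)
  edges <- perturb_odometry(w$edges, 0.01, 0.002, seed = 3)
  gps <- simulate_gps_track(w$trajectory,
                            gps_noise_spec(sigma_m = 5, seed = 4))
  obs <- simulate_stem_observations(w$trajectory, w$stems, w$spec)
  al <- align_global(edges, gps, lm_config())
  rf <- refine_map(al$poses, edges, gps, obs)
  expect_true(all(diff(rf$fit$log[, "objective"]) <= 1e-9))
})
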