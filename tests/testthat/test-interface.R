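test_that("trajectory RMSE: identity, Pythagorean offset, loop oracle", {
  tr <- cbind(1:5, (1:5)^1.5, 0)
  expect_equal(trajectory_rmse(tr, tr), 0)
  off <- tr
  off[, 1] <- off[, 1] + 3
  off[, 2] <- off[, 2] + 4
  expect_equal(trajectory_rmse(off, tr), 5)
  set.seed(1)
  est <- tr + cbind(stats::rnorm(5), stats::rnorm(5), 0)
  want <- sqrt(mean(sapply(1:5, function(i)
    sum((est[i, 1:2] - tr[i, 1:2])^2))))
  expect_equal(trajectory_rmse(est, tr), want)
  expect_error(trajectory_rmse(tr[1:3, ], tr), "length")
})

test_that("stem-map evaluation: perfect, offset, duplicates, false positives", {
  truth <- rbind(c(0, 0), c(10, 0), c(0, 10))
  perfect <- evaluate_stem_map(truth, truth)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$n_matched, 3)
  expect_equal(perfect$duplicates, 0)
  expect_equal(perfect$false_positives, 0)
  # uniform 1 m offset
  shifted <- sweep(truth, 2, c(1, 0), "+")
  expect_equal(evaluate_stem_map(shifted, truth)$rmse, 1)
  # two predictions on one truth stem: one match, one duplicate
  pred <- rbind(c(0.2, 0), c(-0.3, 0.1), c(10, 0.1), c(40, 40))
  ev <- evaluate_stem_map(pred, truth)
  expect_equal(ev$n_matched, 2)
  expect_equal(ev$duplicates, 1)
  expect_equal(ev$false_positives, 1)
  expect_true(3 %in% ev$missed)
})

test_that("calibration, image and disparity files round-trip", {
  K <- camera_intrinsics(350, 160.5, 120.25, 0.12, width = 320, height = 240)
  f <- tempfile(fileext = ".yaml")
  write_calibration(K, f)
  K2 <- read_calibration(f)
  expect_equal(K2[c("f", "cu", "cv", "baseline", "width", "height")],
               K[c("f", "cu", "cv", "baseline", "width", "height")])
  expect_error(read_calibration(tempfile()), "not found")

  set.seed(2)
  img <- matrix(sample(0:255, 30 * 40, replace = TRUE), 30, 40)
  fp <- tempfile(fileext = ".png")
  write_image(img, fp)
  expect_equal(read_image(fp), img, tolerance = 1e-9, ignore_attr = TRUE)
  ft <- tempfile(fileext = ".txt")
  write_image(img, ft)
  expect_equal(read_image(ft), img, ignore_attr = TRUE)

  d <- matrix(sample(0:90, 30 * 40, replace = TRUE), 30, 40)
  fd <- tempfile(fileext = ".png")
  write_disparity(d, fd)
  expect_identical(read_disparity(fd), d)
  fdt <- tempfile(fileext = ".dat")
  write_disparity(d, fdt)
  expect_identical(read_disparity(fdt), d)
})

test_that("GPS, detections, trajectory and stem-map files round-trip", {
  w <- tiny_world(seed = 31)
  gps <- simulate_gps_track(w$trajectory, gps_noise_spec(sigma_m = 2,
                                                         seed = 1))
  f <- tempfile(fileext = ".txt")
  write_gps_file(gps, f, timestamps = (gps$pose_index - 1) / 10)
  df <- read_gps_file(f)
  g2 <- match_gps_to_frames(df, (seq_len(nrow(w$trajectory)) - 1) / 10,
                            sigma = 5)
  expect_equal(g2$coords, gps$coords, ignore_attr = TRUE)
  expect_equal(g2$pose_index, gps$pose_index)

  obs <- simulate_stem_observations(w$trajectory, w$stems, w$spec)
  fo <- tempfile(fileext = ".txt")
  write_detections_file(obs, fo)
  o2 <- read_detections_file(fo)
  expect_equal(o2$offsets, obs$offsets, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(o2$pose_index, obs$pose_index)

  ftr <- tempfile(fileext = ".txt")
  write_trajectory_file(w$trajectory, ftr)
  expect_equal(read_trajectory_file(ftr), w$trajectory, tolerance = 1e-12,
               ignore_attr = TRUE)

  world <- observations_to_world(obs, w$trajectory)
  map <- cluster_centers(world, dbscan_cluster(world, 1, 10))
  fm <- tempfile(fileext = ".txt")
  write_stem_map(map, fm)
  m2 <- read_stem_map(fm)
  expect_equal(m2$centers, map$centers, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(m2$counts, map$counts)
  expect_equal(m2$covariances, map$covariances, tolerance = 1e-9)
  # GeoJSON output is valid JSON with one feature per stem
  fg <- tempfile(fileext = ".geojson")
  write_stem_map(map, fg)
  gj <- jsonlite::read_json(fg)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(map$centers))
  expect_equal(unlist(gj$features[[1]]$geometry$coordinates),
               map$centers[1, ], tolerance = 1e-9)
})

test_that("sparse timestamp matching attaches fixes to nearest frames", {
  df <- data.frame(timestamp = c(0, 1.04, 7.3), easting_m = 1:3,
                   northing_m = 4:6)
  g <- match_gps_to_frames(df, seq(0, 10, 0.1))
  expect_equal(g$pose_index, c(1L, 11L, 74L))
  # fixes outside the window are dropped
  df2 <- rbind(df, data.frame(timestamp = 30, easting_m = 9, northing_m = 9))
  expect_equal(match_gps_to_frames(df2, seq(0, 10, 0.1))$n_obs, 3)
})

test_that("run configuration validates keys", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(gps_sigma = 3, bogus_key = 1), f)
  expect_error(read_run_config(f), "unknown configuration keys")
  yaml::write_yaml(list(gps_sigma = 3, cluster_radius = 2), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$gps_sigma, 3)
  expect_equal(cfg$cluster_radius, 2)
})

test_that("file-based pipeline reproduces the in-memory result", {
  w <- tiny_world(seed = 32)
  dir <- tempfile()
  dir.create(dir)
  gps <- simulate_gps_track(w$trajectory,
                            gps_noise_spec(sigma_m = 3, seed = 2))
  obs <- simulate_stem_observations(w$trajectory, w$stems, w$spec)
  fgps <- file.path(dir, "gps.txt")
  write_gps_file(gps, fgps, timestamps = (gps$pose_index - 1) / 10)
  fobs <- file.path(dir, "detections.txt")
  write_detections_file(obs, fobs)
  # odometry supplied as a twists file: build warp twists whose planar
  # reduction reproduces the exact edges
  tw <- t(apply(w$edges$motions, 1, function(mo) {
    yaw <- -mo[3]
    M <- rigid3(matrix(c(cos(yaw), 0, -sin(yaw), 0, 1, 0,
                         sin(yaw), 0, cos(yaw)), 3, 3),
                c(mo[1], 0, mo[2]))
    as.numeric(se3_log(rigid3_inverse(M)))
  }))
  ftw <- file.path(dir, "twists.txt")
  write_twists_file(tw, ftw)
  out <- run_pipeline(run_config(odometry = ftw, gps = fgps,
                                 detections = fobs, output_dir = dir,
                                 odom_sigma_t = 1e-4,
                                 odom_sigma_theta = 1e-6))
  expect_lt(trajectory_rmse(out$poses, w$trajectory), 1.5)
  expect_true(file.exists(file.path(dir, "trajectory.txt")))
  expect_true(file.exists(file.path(dir, "stem_map.geojson")))
  expect_gt(nrow(out$stem_map$centers), 0)
  # reported planar motions written to the twists file match the edges
  rt <- read_twists_file(ftw)
  expect_equal(as.matrix(rt[, c("dx", "dy", "dtheta")]),
               w$edges$motions, tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(run_pipeline(run_config(gps = fgps)), "odometry")
  expect_error(run_pipeline(run_config(frames = list(list()), gps = fgps)),
               "calibration")
})

test_that("pipeline runs visual odometry from image files", {
  dir <- tempfile()
  dir.create(dir)
  K <- camera_intrinsics(350, 160, 120, 0.12, width = 320, height = 240)
  write_calibration(K, file.path(dir, "calib.yaml"))
  # three frames of a camera translating laterally over a fronto-parallel
  # plane: depth (hence integer disparity) is identical in every frame
  sc <- plane_scene(K, depth_m = 3, seed = 3)
  xi <- c(0, 0, 0, 0.05, 0, 0)
  frames <- list()
  for (k in 0:2) {
    pr <- render_stereo_pair(sc, k * xi, K)
    fi <- file.path(dir, sprintf("img%d.txt", k))
    fd <- file.path(dir, sprintf("disp%d.txt", k))
    write_image(pr$input, fi)
    write_disparity(pr$disparity, fd)
    frames[[k + 1]] <- list(intensity = fi, disparity = fd)
  }
  # the warp +x twist means the camera moved -x: planar edges (-0.05, 0, 0)
  gps <- gps_track(rbind(c(0, 0), c(-0.05, 0), c(-0.1, 0)), 1:3, sigma = 1)
  write_gps_file(gps, file.path(dir, "gps.txt"), timestamps = (0:2) / 10)
  out <- run_pipeline(run_config(calibration = file.path(dir, "calib.yaml"),
                                 frames = frames,
                                 gps = file.path(dir, "gps.txt")))
  expect_equal(out$edges$motions,
               rbind(c(-0.05, 0, 0), c(-0.05, 0, 0)), tolerance = 0.02)
})
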