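# File formats: calibration (YAML), images and disparity maps (PNG or
# plain-text grids), GPS tracks, detections, trajectories and stem maps
# (delimited text with headers), stem maps additionally as GeoJSON.

#' Read / write a camera calibration file
#'
#' Structured YAML with fields `f`, `cu`, `cv`, `baseline_m`, `width`,
#' `height`. Baselines are meters on disk and in memory.
#'
#' @param path file path.
#' @return `camera_intrinsics`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("f", "cu", "cv", "baseline_m")
  if (!all(need %in% names(y)))
    stop("calibration file missing fields: ",
         paste(setdiff(need, names(y)), collapse = ", "))
  camera_intrinsics(y$f, y$cu, y$cv, y$baseline_m,
                    width = y$width %||% NA, height = y$height %||% NA)
}

#' @rdname read_calibration
#' @param K `camera_intrinsics`.
#' @export
write_calibration <- function(K, path) {
  yaml::write_yaml(list(f = K$f, cu = K$cu, cv = K$cv,
                        baseline_m = K$baseline, width = K$width,
                        height = K$height), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a grayscale image
#'
#' PNG files (values rescaled to [0, 255]) or whitespace-delimited text
#' grids (one image row per line).
#'
#' @param path file path; format chosen by extension (`.png` vs text).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) {  # luma conversion for color input
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    img * 255
  } else {
    as.matrix(utils::read.table(path))
  }
}

#' @rdname read_image
#' @param img numeric matrix in [0, 255].
#' @export
write_image <- function(img, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  } else {
    utils::write.table(img, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write an integer disparity map
#'
#' Single-channel PNG (disparity stored as the gray code value, 8-bit or
#' 16-bit on read; writes are 8-bit, which is lossless for the < 256 px
#' disparities of VGA-class stereo) or a dense text grid for arbitrary
#' ranges. Zero marks invalid pixels.
#'
#' @param path file path; `.png` or text.
#' @return integer-valued matrix.
#' @export
read_disparity <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    raw <- png::readPNG(path)
    att <- attr(raw, "bit.depth") %||% 8
    d <- round(raw * (2^att - 1))
  } else {
    d <- as.matrix(utils::read.table(path))
  }
  d <- unname(d)
  storage.mode(d) <- "integer"
  check_disparity(d)
  d
}

#' @rdname read_disparity
#' @param d integer-valued disparity matrix.
#' @export
write_disparity <- function(d, path) {
  check_disparity(d)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(d) > 255)
      stop("write_disparity: PNG output is 8-bit; use a text grid for disparities above 255")
    png::writePNG(d / 255, path)
  } else {
    utils::write.table(d, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a GPS track file
#'
#' Delimited text with a header line: `timestamp`, `easting_m`,
#' `northing_m` and optionally `pdop`. Coordinates are UTM meters in a
#' single zone.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_gps_file <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  need <- c("timestamp", "easting_m", "northing_m")
  if (!all(need %in% names(df)))
    stop("GPS file must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_gps_file
#' @param gps `gps_observations`.
#' @param timestamps per-fix timestamps (defaults to the pose index).
#' @export
write_gps_file <- function(gps, path, timestamps = NULL) {
  df <- data.frame(timestamp = timestamps %||% gps$pose_index,
                   easting_m = gps$coords[, 1],
                   northing_m = gps$coords[, 2])
  if (!is.null(gps$pdop)) df$pdop <- gps$pdop
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match GPS fixes to frames
#'
#' When the fix count equals the frame count the correspondence is
#' one-to-one (the receiver was queried after each frame capture);
#' otherwise each fix is matched to the nearest frame timestamp within a
#' 0.5 s window and unmatched fixes are dropped.
#'
#' @param gps_df data.frame from [read_gps_file()].
#' @param frame_times frame timestamps (seconds), one per pose.
#' @param sigma,use_pdop forwarded to [gps_track()].
#' @param window_s matching window (default 0.5).
#' @return `gps_observations`.
#' @export
match_gps_to_frames <- function(gps_df, frame_times, sigma = 5,
                                use_pdop = FALSE, window_s = 0.5) {
  K <- nrow(gps_df)
  if (K == length(frame_times)) {
    idx <- seq_len(K)
    keep <- idx
  } else {
    idx <- vapply(gps_df$timestamp, function(tt)
      which.min(abs(frame_times - tt)), integer(1))
    keep <- which(abs(frame_times[idx] - gps_df$timestamp) <= window_s)
    idx <- idx[keep]
  }
  gps_track(as.matrix(gps_df[keep, c("easting_m", "northing_m")]),
            idx, sigma = sigma, pdop = gps_df$pdop[keep],
            use_pdop = use_pdop)
}

#' Read a stem detections file
#'
#' Delimited text with a header: `frame_index` (0-based), `lateral_m`,
#' `forward_m`, optional `range_m`.
#'
#' @param path file path.
#' @param sigma0,sigma_range observation noise model for the information
#'   matrices (see [stem_observations()]).
#' @return `stem_observations`.
#' @export
read_detections_file <- function(path, sigma0 = 0.1, sigma_range = 0.05) {
  df <- utils::read.table(path, header = TRUE)
  need <- c("frame_index", "lateral_m", "forward_m")
  if (!all(need %in% names(df)))
    stop("detections file must have columns: ", paste(need, collapse = ", "))
  stem_observations(df$frame_index + 1L,
                    cbind(df$lateral_m, df$forward_m),
                    sigma0 = sigma0, sigma_range = sigma_range)
}

#' @rdname read_detections_file
#' @param obs `stem_observations`.
#' @export
write_detections_file <- function(obs, path) {
  d <- sqrt(rowSums(obs$offsets^2))
  utils::write.table(data.frame(frame_index = obs$pose_index - 1L,
                                lateral_m = obs$offsets[, 1],
                                forward_m = obs$offsets[, 2],
                                range_m = d),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a trajectory file
#'
#' Delimited text with header `index` (0-based frame index), `x`, `y`,
#' `theta`; coordinates UTM meters.
#'
#' @param path file path.
#' @return n x 3 pose matrix.
#' @export
read_trajectory_file <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  as.matrix(df[order(df$index), c("x", "y", "theta")])
}

#' @rdname read_trajectory_file
#' @param poses n x 3 pose matrix.
#' @export
write_trajectory_file <- function(poses, path) {
  utils::write.table(data.frame(index = seq_len(nrow(poses)) - 1L,
                                x = poses[, 1], y = poses[, 2],
                                theta = poses[, 3]),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-frame egomotion estimates
#'
#' One row per frame-to-frame estimate: 0-based frame index, the six twist
#' parameters (rotation then translation) and the reduced planar motion.
#'
#' @param twists list or matrix (m x 6) of twists.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_twists_file <- function(twists, path) {
  tw <- if (is.list(twists)) do.call(rbind, twists) else as.matrix(twists)
  planar <- t(apply(tw, 1, vo_to_odometry))
  df <- data.frame(frame_index = seq_len(nrow(tw)) - 1L, tw, planar)
  names(df) <- c("frame_index", "wx", "wy", "wz", "tx", "ty", "tz",
                 "dx", "dy", "dtheta")
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_twists_file
#' @export
read_twists_file <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  df[order(df$frame_index), ]
}

#' Write a stem map
#'
#' Delimited text (`stem_id`, `x`, `y`, `count`, covariance entries) and,
#' with a `.geojson` path, GeoJSON points carrying the same properties.
#'
#' @param map `stem_map`.
#' @param path output path; `.geojson` selects GeoJSON.
#' @return the path, invisibly.
#' @export
write_stem_map <- function(map, path) {
  L <- nrow(map$centers)
  if (grepl("\\.geojson$", path, ignore.case = TRUE)) {
    features <- lapply(seq_len(L), function(a) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = as.numeric(map$centers[a, ])),
           properties = list(stem_id = a, count = map$counts[a],
                             cov_xx = map$covariances[a, 1, 1],
                             cov_xy = map$covariances[a, 1, 2],
                             cov_yy = map$covariances[a, 2, 2]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(data.frame(stem_id = seq_len(L),
                                  x = map$centers[, 1], y = map$centers[, 2],
                                  count = map$counts,
                                  cov_xx = map$covariances[, 1, 1],
                                  cov_xy = map$covariances[, 1, 2],
                                  cov_yy = map$covariances[, 2, 2]),
                       path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_stem_map
#' @export
read_stem_map <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  L <- nrow(df)
  covs <- array(0, c(L, 2, 2))
  covs[, 1, 1] <- df$cov_xx
  covs[, 1, 2] <- covs[, 2, 1] <- df$cov_xy
  covs[, 2, 2] <- df$cov_yy
  structure(list(centers = cbind(df$x, df$y), counts = df$count,
                 covariances = covs, labels = df$stem_id),
            class = "stem_map")
}
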