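# Independent oracles used across the suite: finite differences, dense
# brute-force optimization, reference clustering. These deliberately avoid
# the package's own analytic code paths.

# Central-difference Jacobian of a vector-valued function (5-point rule,
# O(h^4) truncation error).
fd_jacobian <- function(f, x, h = 1e-4) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    e <- numeric(length(x))
    e[k] <- h
    J[, k] <- (8 * (f(x + e) - f(x - e)) - (f(x + 2 * e) - f(x - 2 * e))) /
      (12 * h)
  }
  J
}

# Homogeneous 4x4 from a twist via the generic matrix exponential
# (Matrix::expm), independent of the closed-form Rodrigues path.
expm_oracle <- function(xi) {
  S <- rbind(cbind(matrix(c(0, xi[3], -xi[2],
                            -xi[3], 0, xi[1],
                            xi[2], -xi[1], 0), 3, 3), xi[4:6]),
             c(0, 0, 0, 0))
  as.matrix(Matrix::expm(Matrix::Matrix(S)))
}

rigid_to_mat <- function(T) rbind(cbind(T$rot, T$trans), c(0, 0, 0, 1))

# Direct (loop-based) evaluation of the planar odometry residual.
odo_residual_bf <- function(vi, vj, motion) {
  Ri <- matrix(c(cos(vi[3]), sin(vi[3]), -sin(vi[3]), cos(vi[3])), 2, 2)
  Rij <- matrix(c(cos(motion[3]), sin(motion[3]),
                  -sin(motion[3]), cos(motion[3])), 2, 2)
  tr <- t(Rij) %*% (t(Ri) %*% (vj[1:2] - vi[1:2]) - motion[1:2])
  ang <- vj[3] - vi[3] - motion[3]
  ang <- atan2(sin(ang), cos(ang))
  c(as.numeric(tr), ang)
}

gps_residual_bf <- function(vi, phi, g) {
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  as.numeric(R %*% vi[1:2] - g)
}

stem_residual_bf <- function(pose, center, offset) {
  R <- matrix(c(cos(pose[3]), sin(pose[3]),
                -sin(pose[3]), cos(pose[3])), 2, 2)
  as.numeric(t(R) %*% (center - pose[1:2]) - offset)
}

# Stacked residual of a small global-alignment problem for a packed state
# (phi, v1..vn), built on the brute-force residuals above.
global_residual_stack_bf <- function(x, motions, gps_coords, gps_idx) {
  phi <- x[1]
  poses <- matrix(x[-1], ncol = 3, byrow = TRUE)
  m <- nrow(motions)
  out <- numeric(0)
  for (e in seq_len(m))
    out <- c(out, odo_residual_bf(poses[e, ], poses[e + 1, ], motions[e, ]))
  for (k in seq_along(gps_idx))
    out <- c(out, gps_residual_bf(poses[gps_idx[k], ], phi, gps_coords[k, ]))
  out
}

# Stacked residual of a small refinement problem for a packed state
# (v1..vn, m1..mL): odometry, GPS as plain position difference, stems.
refine_residual_stack_bf <- function(x, n, motions, gps_coords, gps_idx,
                                     offsets, obs_idx, obs_cluster) {
  poses <- matrix(x[seq_len(3 * n)], ncol = 3, byrow = TRUE)
  centers <- matrix(x[-seq_len(3 * n)], ncol = 2, byrow = TRUE)
  out <- numeric(0)
  for (e in seq_len(nrow(motions)))
    out <- c(out, odo_residual_bf(poses[e, ], poses[e + 1, ], motions[e, ]))
  for (k in seq_along(gps_idx))
    out <- c(out, poses[gps_idx[k], 1:2] - gps_coords[k, ])
  for (q in seq_along(obs_idx))
    out <- c(out, stem_residual_bf(poses[obs_idx[q], ],
                                   centers[obs_cluster[q], ], offsets[q, ]))
  out
}

# Dense Levenberg-Marquardt with numerically differentiated Jacobians,
# mirroring the package's damping schedule (Marquardt scaling, x2 / x0.5,
# step-norm termination) but sharing no code with it.
dense_lm_oracle <- function(res_fn, x0, Qdiag, step_tol = 1e-10,
                            max_iters = 100, lambda0 = 1e-5, h = 1e-3) {
  x <- x0
  lambda <- lambda0
  obj_of <- function(r) sum(r^2 * Qdiag)
  for (it in seq_len(max_iters)) {
    r <- res_fn(x)
    J <- fd_jacobian(res_fn, x, h = h)
    H <- t(J) %*% (Qdiag * J)
    b <- as.numeric(t(J) %*% (Qdiag * r))
    obj <- obj_of(r)
    dscale <- pmax(diag(H), 1e-12)
    accepted <- FALSE
    step <- NA
    for (inner in 1:60) {
      ds <- tryCatch(solve(H + diag(lambda * dscale, length(x)), -b),
                     error = function(e) NULL)
      if (!is.null(ds)) {
        cand <- x + as.numeric(ds)
        if (obj_of(res_fn(cand)) < obj) {
          x <- cand
          lambda <- lambda * 0.5
          step <- sqrt(sum(ds^2))
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 2
    }
    if (!accepted || step < step_tol) break
  }
  x
}

# Reference DBSCAN on a full distance matrix (O(n^2)), classic
# formulation with explicit neighbor lists.
dbscan_bf <- function(points, eps, min_pts) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(nbrs[[i]]) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        if (length(nbrs[[j]]) >= min_pts)
          queue <- c(queue, setdiff(nbrs[[j]],
                                    which(visited | labels > 0L)))
      }
    }
  }
  labels
}

# Canonical relabeling by order of first appearance, for comparing
# partitions up to label permutation (noise label 0 kept fixed).
canon_labels <- function(labels) {
  out <- integer(length(labels))
  map <- integer(0)
  nxt <- 0L
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l == 0L) next
    pos <- match(l, map)
    if (is.na(pos)) {
      map <- c(map, l)
      nxt <- nxt + 1L
      pos <- nxt
    }
    out[i] <- pos
  }
  out
}

# Small deterministic test world shared by several files.
tiny_world <- function(seed = 42, length_m = 60) {
  simulate_world(world_spec(seed = seed, path_length_m = length_m,
                            stem_count = 12, stem_margin_m = 8,
                            max_range_m = 10))
}

mean_cov_trace <- function(covs)
  mean(apply(covs, 1, function(m) sum(diag(matrix(m, 2)))))
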