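# Planar pose-graph fusion of odometry and GPS.
#
# The state is (phi, v1..vn): a single global-orientation angle aligning
# the odometry frame to the UTM frame, followed by the planar poses.
# Odometry edges constrain consecutive poses; each GPS fix constrains the
# rotated position of its corresponding pose. The normal equations are
# assembled as a sparse system (Matrix) from analytic Jacobian blocks and
# solved with Levenberg-Marquardt using a sparse Cholesky factorization.

#' Odometry edge set
#'
#' Consecutive-pose motion constraints. The default information matrix is
#' `diag(1/sigma_t^2, 1/sigma_t^2, 1/sigma_theta^2)`; the heading entry is
#' deliberately much stiffer than the translation entries so the chain
#' stays rotationally rigid while conforming to the GPS track.
#'
#' @param motions m x 3 matrix (dx, dy, dtheta) of relative motions, meters
#'   and radians, edge i connecting poses i and i+1.
#' @param sigma_t,sigma_theta per-edge standard deviations used for the
#'   default information matrix (m, rad).
#' @param info optional m x 3 x 3 array of information matrices overriding
#'   the defaults.
#' @return list of class `odometry_edges`.
#' @export
odometry_edges <- function(motions, sigma_t = 0.1, sigma_theta = 0.005,
                           info = NULL) {
  motions <- matrix(as.numeric(motions), ncol = 3)
  m <- nrow(motions)
  if (is.null(info)) {
    info <- array(0, c(m, 3, 3))
    info[, 1, 1] <- 1 / sigma_t^2
    info[, 2, 2] <- 1 / sigma_t^2
    info[, 3, 3] <- 1 / sigma_theta^2
  } else {
    stopifnot(all(dim(info) == c(m, 3, 3)))
  }
  structure(list(motions = motions, info = info, n_edges = m),
            class = "odometry_edges")
}

#' GPS observation set
#'
#' @param coords K x 2 matrix of UTM coordinates (m).
#' @param pose_index integer vector: pose corresponding to each fix.
#' @param sigma GPS standard deviation in meters for the default isotropic
#'   information matrix (default 5, consumer-grade under canopy).
#' @param pdop optional per-fix PDOP values.
#' @param use_pdop when TRUE, the per-fix sigma is scaled by PDOP.
#' @param info optional K x 2 x 2 array overriding the defaults.
#' @return list of class `gps_observations`.
#' @export
gps_track <- function(coords, pose_index, sigma = 5, pdop = NULL,
                      use_pdop = FALSE, info = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  K <- nrow(coords)
  pose_index <- as.integer(pose_index)
  stopifnot(length(pose_index) == K)
  if (is.null(info)) {
    s <- rep(sigma, K)
    if (use_pdop && !is.null(pdop)) s <- s * pdop
    info <- array(0, c(K, 2, 2))
    info[, 1, 1] <- 1 / s^2
    info[, 2, 2] <- 1 / s^2
  } else {
    stopifnot(all(dim(info) == c(K, 2, 2)))
  }
  structure(list(coords = coords, pose_index = pose_index, info = info,
                 pdop = pdop, n_obs = K),
            class = "gps_observations")
}

#' Chain odometry edges into an initial pose list
#'
#' The first pose is the zero vector; each subsequent pose composes the
#' previous pose with the edge motion (edge translation rotated by the
#' previous heading, headings added and wrapped).
#'
#' @param edges `odometry_edges` (or an m x 3 motion matrix).
#' @return (m + 1) x 3 matrix of poses (x, y, theta).
#' @export
build_graph <- function(edges) {
  motions <- if (inherits(edges, "odometry_edges")) edges$motions else
    matrix(as.numeric(edges), ncol = 3)
  m <- nrow(motions)
  poses <- matrix(0, m + 1, 3)
  if (m == 0) return(poses)
  th <- cumsum(c(0, motions[, 3]))
  cth <- cos(th[seq_len(m)])
  sth <- sin(th[seq_len(m)])
  dx <- cth * motions[, 1] - sth * motions[, 2]
  dy <- sth * motions[, 1] + cth * motions[, 2]
  poses[, 1] <- cumsum(c(0, dx))
  poses[, 2] <- cumsum(c(0, dy))
  poses[, 3] <- wrap_angle(th)
  poses
}

#' Anchor a GPS track at its first correspondence
#'
#' Stores the first fix as the anchor g0 and subtracts it from every
#' coordinate, so the optimization works near the origin; the anchor is
#' re-added on recovery. At least two fixes are required to resolve the
#' global orientation.
#'
#' @param gps `gps_observations`.
#' @return list with `gps` (anchored) and `g0` (length-2 anchor).
#' @export
anchor_gps <- function(gps) {
  if (gps$n_obs < 2)
    stop("anchor_gps: at least two GPS observations are required to resolve the global orientation")
  g0 <- gps$coords[1, ]
  gps$coords <- sweep(gps$coords, 2, g0)
  list(gps = gps, g0 = g0)
}

#' Odometry residual between two poses
#'
#' The planar relative-pose error `T(xi_ij)^-1 T(v_i)^-1 T(v_j)`:
#' translation part `R(theta_ij)^T (R(theta_i)^T (t_j - t_i) - t_ij)`,
#' angle part `theta_j - theta_i - theta_ij` wrapped to (-pi, pi]. Zero
#' exactly when `v_j` is the composition of `v_i` with the edge motion.
#'
#' @param vi,vj length-3 poses.
#' @param motion length-3 edge motion.
#' @return length-3 residual.
#' @export
odometry_error <- function(vi, vj, motion) {
  d <- vj[1:2] - vi[1:2]
  rt <- t(rot2(motion[3])) %*% (t(rot2(vi[3])) %*% d - motion[1:2])
  c(as.numeric(rt), wrap_angle(vj[3] - vi[3] - motion[3]))
}

#' GPS residual of a pose under the global orientation
#'
#' `R(phi) t_i - g`, the anchored pose position rotated about the anchored
#' origin minus the (anchored) GPS coordinate.
#'
#' @param vi length-3 pose.
#' @param phi global orientation (rad).
#' @param g length-2 GPS coordinate.
#' @return length-2 residual.
#' @export
gps_error <- function(vi, phi, g) {
  as.numeric(rot2(phi) %*% vi[1:2] - g)
}

#' Global-alignment state
#'
#' @param phi global orientation (rad).
#' @param poses n x 3 matrix of planar poses.
#' @param anchor length-2 UTM anchor g0.
#' @return list of class `global_state`; the packed state length is
#'   `1 + 3 n`.
#' @export
global_state <- function(phi, poses, anchor = c(0, 0)) {
  structure(list(phi = phi, poses = poses, anchor = anchor),
            class = "global_state")
}

# Stacked residual vector (odometry rows then GPS rows) for a state.
global_residuals <- function(state, edges, gps) {
  poses <- state$poses
  m <- edges$n_edges
  i <- seq_len(m)
  thi <- poses[i, 3]
  thij <- edges$motions[, 3]
  dx <- poses[i + 1, 1] - poses[i, 1]
  dy <- poses[i + 1, 2] - poses[i, 2]
  # e = R(thi)^T d - t_ij, then rotate by R(thij)^T
  ex <- cos(thi) * dx + sin(thi) * dy - edges$motions[, 1]
  ey <- -sin(thi) * dx + cos(thi) * dy - edges$motions[, 2]
  c2 <- cos(thij)
  s2 <- sin(thij)
  r_odo <- rbind(c2 * ex + s2 * ey,
                 -s2 * ex + c2 * ey,
                 wrap_angle(poses[i + 1, 3] - thi - thij))
  pi_ <- gps$pose_index
  cphi <- cos(state$phi)
  sphi <- sin(state$phi)
  r_gps <- rbind(cphi * poses[pi_, 1] - sphi * poses[pi_, 2] - gps$coords[, 1],
                 sphi * poses[pi_, 1] + cphi * poses[pi_, 2] - gps$coords[, 2])
  list(odo = as.numeric(r_odo), gps = as.numeric(r_gps),
       gps_norms = sqrt(colSums(r_gps^2)))
}

# Weighted objective: sum r^T Q r with robust weights scaling the GPS
# information blocks.
global_objective <- function(state, edges, gps, gps_weights) {
  r <- global_residuals(state, edges, gps)
  ro <- matrix(r$odo, 3)
  obj_odo <- sum(ro[1, ] * (edges$info[, 1, 1] * ro[1, ] + edges$info[, 1, 2] * ro[2, ] + edges$info[, 1, 3] * ro[3, ]) +
                 ro[2, ] * (edges$info[, 2, 1] * ro[1, ] + edges$info[, 2, 2] * ro[2, ] + edges$info[, 2, 3] * ro[3, ]) +
                 ro[3, ] * (edges$info[, 3, 1] * ro[1, ] + edges$info[, 3, 2] * ro[2, ] + edges$info[, 3, 3] * ro[3, ]))
  rg <- matrix(r$gps, 2)
  obj_gps <- sum(gps_weights *
                 (rg[1, ] * (gps$info[, 1, 1] * rg[1, ] + gps$info[, 1, 2] * rg[2, ]) +
                  rg[2, ] * (gps$info[, 2, 1] * rg[1, ] + gps$info[, 2, 2] * rg[2, ])))
  obj_odo + obj_gps
}

# Robust (Tukey/MAD) weights on GPS residual norms; all ones when disabled
# or when the scale degenerates to zero.
gps_robust_weights <- function(gps_norms, robust, c = 4.6851, k = 1.4826) {
  K <- length(gps_norms)
  if (!robust) return(rep(1, K))
  s <- k * stats::median(gps_norms)
  if (s == 0) return(rep(1, K))
  u <- gps_norms / s
  w <- (1 - (u / c)^2)^2
  w[u > c] <- 0
  w
}

# Constant sparsity pattern and information triplets for the global system.
global_assembly_cache <- function(edges, gps, n) {
  m <- edges$n_edges
  K <- gps$n_obs
  dim <- 1 + 3 * n
  e <- seq_len(m)
  ro <- 3 * (e - 1)
  ci <- 1 + 3 * (e - 1)
  cj <- 1 + 3 * e
  jrow_odo <- c(ro + 1, ro + 1, ro + 1, ro + 2, ro + 2, ro + 2, ro + 3,
                ro + 1, ro + 1, ro + 2, ro + 2, ro + 3)
  jcol_odo <- c(ci + 1, ci + 2, ci + 3, ci + 1, ci + 2, ci + 3, ci + 3,
                cj + 1, cj + 2, cj + 1, cj + 2, cj + 3)
  kk <- seq_len(K)
  rg <- 3 * m + 2 * (kk - 1)
  cg <- 1 + 3 * (gps$pose_index - 1)
  jrow_gps <- c(rg + 1, rg + 2, rg + 1, rg + 1, rg + 2, rg + 2)
  jcol_gps <- c(rep(1, 2 * K), cg + 1, cg + 2, cg + 1, cg + 2)
  # block-diagonal information matrix triplets
  qrow_odo <- rep(ro, each = 9) + rep(rep(1:3, 3), m)
  qcol_odo <- rep(ro, each = 9) + rep(rep(1:3, each = 3), m)
  qval_odo <- as.numeric(aperm(edges$info, c(2, 3, 1)))
  qrow_gps <- rep(rg, each = 4) + rep(rep(1:2, 2), K)
  qcol_gps <- rep(rg, each = 4) + rep(rep(1:2, each = 2), K)
  qval_gps <- as.numeric(aperm(gps$info, c(2, 3, 1)))
  list(m = m, K = K, n = n, dim = dim, n_rows = 3 * m + 2 * K,
       jrow = c(jrow_odo, jrow_gps), jcol = c(jcol_odo, jcol_gps),
       qrow = c(qrow_odo, qrow_gps), qcol = c(qcol_odo, qcol_gps),
       qval_odo = qval_odo, qval_gps = qval_gps)
}

#' Assemble the sparse normal equations of the global alignment
#'
#' Linearizes the odometry and GPS error functions at the current state
#' and forms `H = J^T Q J` and `b = J^T Q r` with analytic Jacobian
#' blocks. GPS information is scaled by the supplied robust weights.
#'
#' @param state `global_state`.
#' @param edges `odometry_edges`.
#' @param gps anchored `gps_observations`.
#' @param gps_weights per-fix robust weights (default all 1).
#' @param cache internal assembly cache; rebuilt when NULL.
#' @return list with sparse `H` ((1+3n) x (1+3n)), dense `b`, the stacked
#'   residual vector `r`, the GPS residual norms and the objective value.
#' @export
assemble_normal_equations <- function(state, edges, gps,
                                      gps_weights = rep(1, gps$n_obs),
                                      cache = NULL) {
  n <- nrow(state$poses)
  if (is.null(cache)) cache <- global_assembly_cache(edges, gps, n)
  poses <- state$poses
  m <- cache$m
  i <- seq_len(m)
  thi <- poses[i, 3]
  thij <- edges$motions[, 3]
  dx <- poses[i + 1, 1] - poses[i, 1]
  dy <- poses[i + 1, 2] - poses[i, 2]
  cs <- cos(thi + thij)
  sn <- sin(thi + thij)
  # A: d r_ij / d v_i ; B: d r_ij / d v_j
  q1 <- -sin(thi) * dx + cos(thi) * dy
  q2 <- -cos(thi) * dx - sin(thi) * dy
  c2 <- cos(thij)
  s2 <- sin(thij)
  a13 <- c2 * q1 + s2 * q2
  a23 <- -s2 * q1 + c2 * q2
  vals_odo <- c(-cs, -sn, a13, sn, -cs, a23, rep(-1, m),
                cs, sn, -sn, cs, rep(1, m))
  pi_ <- gps$pose_index
  cphi <- cos(state$phi)
  sphi <- sin(state$phi)
  # C = dR(phi)/dphi t_i ; D = [R(phi) 0]
  C1 <- -sphi * poses[pi_, 1] - cphi * poses[pi_, 2]
  C2 <- cphi * poses[pi_, 1] - sphi * poses[pi_, 2]
  K <- cache$K
  vals_gps <- c(C1, C2, rep(cphi, K), rep(-sphi, K), rep(sphi, K),
                rep(cphi, K))
  J <- Matrix::sparseMatrix(i = cache$jrow, j = cache$jcol,
                            x = c(vals_odo, vals_gps),
                            dims = c(cache$n_rows, cache$dim))
  wq <- rep(gps_weights, each = 4)
  Q <- Matrix::sparseMatrix(i = cache$qrow, j = cache$qcol,
                            x = c(cache$qval_odo, cache$qval_gps * wq),
                            dims = c(cache$n_rows, cache$n_rows))
  res <- global_residuals(state, edges, gps)
  r <- c(res$odo, res$gps)
  QJ <- Q %*% J
  H <- Matrix::forceSymmetric(Matrix::crossprod(J, QJ))
  Qr <- Q %*% r
  b <- as.numeric(Matrix::crossprod(J, Qr))
  list(H = H, b = b, r = r, gps_norms = res$gps_norms,
       objective = sum(r * as.numeric(Qr)), cache = cache)
}

#' Levenberg-Marquardt settings for graph optimization
#'
#' @param step_tol terminate when the state increment norm drops below
#'   this (default 0.001).
#' @param max_iters maximum accepted linearizations (default 100).
#' @param damping `"marquardt"` (default) damps with
#'   `lambda * diag(H)`, which is invariant to the very different scales
#'   of heading, position and landmark blocks; `"identity"` damps with
#'   `lambda * I`.
#' @param lambda0 initial damping factor: default 1e-5 for
#'   `"marquardt"`; for `"identity"` the default is `trace(H)`.
#' @param lambda_up,lambda_down factors applied on objective increase /
#'   decrease (defaults 2 and 0.5).
#' @param robust_gps apply Tukey-biweight weights to GPS residual norms,
#'   recomputed at every linearization (default TRUE).
#' @param tukey_c,mad_k robust constants (4.6851, 1.4826).
#' @param max_inner maximum damping retries per linearization (default 60).
#' @return list of class `lm_config`.
#' @export
lm_config <- function(step_tol = 0.001, max_iters = 100,
                      damping = c("marquardt", "identity"), lambda0 = NULL,
                      lambda_up = 2, lambda_down = 0.5, robust_gps = TRUE,
                      tukey_c = 4.6851, mad_k = 1.4826, max_inner = 60) {
  damping <- match.arg(damping)
  if (is.null(lambda0) && damping == "marquardt") lambda0 <- 1e-5
  stopifnot(lambda_up > 0, lambda_down > 0)
  structure(list(step_tol = step_tol, max_iters = max_iters,
                 damping = damping, lambda0 = lambda0,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 robust_gps = robust_gps, tukey_c = tukey_c, mad_k = mad_k,
                 max_inner = max_inner),
            class = "lm_config")
}

# Solve (H + lambda * D) d = -b with D the damping scale (diag(H) for
# Marquardt damping, ones for identity damping); sparse Cholesky with a
# dense fallback for small systems. Returns NULL when the damped system
# is not positive definite.
lm_solve <- function(H, b, lambda, dscale) {
  d <- length(b)
  if (d < 200) {
    Hd <- as.matrix(H) + diag(lambda * dscale, d)
    return(tryCatch(solve(Hd, -b), error = function(e) NULL))
  }
  tryCatch({
    Hd <- H + Matrix::Diagonal(d, lambda * dscale)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Hd), LDL = FALSE,
                           perm = TRUE)
    as.numeric(Matrix::solve(ch, -b))
  }, error = function(e) NULL)
}

# Generic sparse LM driver shared by global alignment and local
# refinement. `linearize(state)` returns H, b, objective and the robust
# weights it used; `objective(state, weights)` evaluates a candidate under
# frozen weights; `update(state, ds)` applies an increment.
lm_driver <- function(state, linearize, objective, update, cfg) {
  lambda <- NULL
  log <- list()
  converged <- FALSE
  iters <- 0
  obj <- NA_real_
  for (iter in seq_len(cfg$max_iters)) {
    iters <- iter
    lin <- linearize(state)
    obj <- lin$objective
    dH <- Matrix::diag(lin$H)
    dscale <- if (cfg$damping == "marquardt") pmax(dH, 1e-12)
              else rep(1, length(dH))
    if (is.null(lambda))
      lambda <- if (!is.null(cfg$lambda0)) cfg$lambda0 else sum(dH)
    accepted <- FALSE
    step_norm <- NA_real_
    for (inner in seq_len(cfg$max_inner)) {
      ds <- lm_solve(lin$H, lin$b, lambda, dscale)
      if (is.null(ds)) {
        lambda <- lambda * cfg$lambda_up
        next
      }
      cand <- update(state, ds)
      obj_new <- objective(cand, lin$weights)
      if (is.finite(obj_new) && obj_new < obj) {
        state <- cand
        obj <- obj_new
        lambda <- lambda * cfg$lambda_down
        step_norm <- sqrt(sum(ds^2))
        accepted <- TRUE
        break
      }
      lambda <- lambda * cfg$lambda_up
    }
    log[[iter]] <- c(iter = iter, lambda = lambda, objective = obj,
                     step_norm = step_norm)
    if (!accepted) {
      converged <- TRUE  # no decreasing step exists at reachable damping
      break
    }
    if (step_norm < cfg$step_tol) {
      converged <- TRUE
      break
    }
  }
  list(state = state, objective = obj, iterations = iters,
       converged = converged,
       log = do.call(rbind, log))
}

#' Optimize the global alignment with sparse Levenberg-Marquardt
#'
#' Iterates linearization, damped sparse solves and candidate acceptance:
#' steps that increase the (robust-weighted) objective are rejected with
#' the damping doubled, accepted steps halve it, and the algorithm stops
#' when the increment norm falls below `cfg$step_tol`. Robust GPS weights
#' are recomputed at every linearization from the MAD-standardized
#' residual norms.
#'
#' @param state initial `global_state` (poses from [build_graph()],
#'   `phi = 0`, anchored GPS).
#' @param edges `odometry_edges`.
#' @param gps anchored `gps_observations` (see [anchor_gps()]).
#' @param cfg `lm_config`.
#' @return list: optimized `state`, `objective`, `iterations`,
#'   `converged`, `gps_weights`, and an iteration `log`.
#' @export
lm_optimize <- function(state, edges, gps, cfg = lm_config()) {
  if (gps$n_obs < 2)
    stop("lm_optimize: at least two GPS observations are required")
  cache <- global_assembly_cache(edges, gps, nrow(state$poses))
  weights_last <- rep(1, gps$n_obs)
  linearize <- function(s) {
    res <- global_residuals(s, edges, gps)
    w <- gps_robust_weights(res$gps_norms, cfg$robust_gps, cfg$tukey_c,
                            cfg$mad_k)
    weights_last <<- w
    sys <- assemble_normal_equations(s, edges, gps, w, cache)
    list(H = sys$H, b = sys$b, objective = sys$objective, weights = w)
  }
  objective <- function(s, w) global_objective(s, edges, gps, w)
  update <- function(s, ds) {
    s$phi <- s$phi + ds[1]
    dp <- matrix(ds[-1], ncol = 3, byrow = TRUE)
    s$poses[, 1] <- s$poses[, 1] + dp[, 1]
    s$poses[, 2] <- s$poses[, 2] + dp[, 2]
    s$poses[, 3] <- wrap_angle(s$poses[, 3] + dp[, 3])
    s
  }
  out <- lm_driver(state, linearize, objective, update, cfg)
  list(state = out$state, objective = out$objective,
       iterations = out$iterations, converged = out$converged,
       gps_weights = weights_last, log = out$log)
}

#' Rotate and translate the optimized state back to UTM
#'
#' Applies the optimized global orientation to every pose, re-adds the
#' anchor, and increments the headings by `phi`; the orientation parameter
#' is dropped thereafter.
#'
#' @param state optimized `global_state`.
#' @return n x 3 matrix of UTM poses.
#' @export
recover_global <- function(state) {
  R <- rot2(state$phi)
  xy <- state$poses[, 1:2, drop = FALSE] %*% t(R)
  cbind(xy[, 1] + state$anchor[1], xy[, 2] + state$anchor[2],
        wrap_angle(state$poses[, 3] + state$phi))
}

#' Align an odometry chain with a GPS track
#'
#' Convenience wrapper: builds the initial graph from the edges, anchors
#' the GPS track, optimizes (phi, v1..vn) and recovers UTM poses.
#'
#' @param edges `odometry_edges`.
#' @param gps `gps_observations` in UTM.
#' @param cfg `lm_config`.
#' @return list: `poses` (n x 3, UTM), `state`, `fit` (optimizer
#'   diagnostics).
#' @export
align_global <- function(edges, gps, cfg = lm_config()) {
  anchored <- anchor_gps(gps)
  state <- global_state(0, build_graph(edges), anchored$g0)
  fit <- lm_optimize(state, edges, anchored$gps, cfg)
  list(poses = recover_global(fit$state), state = fit$state, fit = fit)
}
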