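# Rigid and multi-resolution diffeomorphic registration.
#
# The deformable stage is a greedy demons variant: at each iteration the
# force (F - M.phi) grad(M.phi) / (|grad|^2 + kappa (F - M.phi)^2) is
# smoothed (fluid regularization), capped at 0.4 voxel, composed into the
# running field, and the field itself is smoothed (diffusion
# regularization). The step cap plus per-iteration smoothing keeps the
# Jacobian determinant positive, which is checked at emission. There is no
# randomness anywhere in this module.

#' Multi-resolution schedule
#'
#' Ordered `(subsample_factor, max_iterations)` levels; the default is the
#' coarse/middle/fine schedule of a maximum of 80 iterations at 4x
#' subsampling, 80 at 2x, and 30 at full resolution.
#'
#' @param levels List of length-2 integer vectors `(factor, max_iter)`.
#' @export
reg_schedule <- function(levels = list(c(4L, 80L), c(2L, 80L), c(1L, 30L))) {
  f <- vapply(levels, `[`, 0, 1)
  it <- vapply(levels, `[`, 0, 2)
  if (any(diff(f) > 0)) stop("subsampling factors must be non-increasing")
  if (f[length(f)] != 1) stop("last level must be full resolution (factor 1)")
  if (any(it < 1)) stop("iteration counts must be >= 1")
  structure(list(factors = as.integer(f), iters = as.integer(it)),
            class = "reg_schedule")
}

#' Default deformable registration parameters
#'
#' `kappa` is the demons normalization constant, `fluid_sigma` /
#' `diffusion_sigma` the update/field smoothing sigmas in voxels,
#' `step_max` the per-iteration displacement cap in voxels, and `tol` the
#' relative metric improvement under which an iteration counts as stalled
#' (5 stalled iterations stop a level).
#'
#' @export
default_reg_params <- function() {
  list(kappa = 1.0, fluid_sigma = 1.0, diffusion_sigma = 1.0,
       step_max = 0.4, tol = 1e-4, stall_limit = 5L)
}

# ---- rigid ------------------------------------------------------------------

euler_matrix <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Rigid-body transform
#' @param angles Euler angles (radians, x/y/z).
#' @param translation Translation in mm.
#' @param center Rotation centre in world mm.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "amy_rigid")
}

#' Invert a rigid transform
#' @param tr An `amy_rigid` (inverse returned with the same centre).
#' @export
invert_rigid <- function(tr) {
  R <- euler_matrix(tr$angles)
  # x' = R (x - c) + c + t  =>  x = R^T (x' - c - t) + c
  Rt <- t(R)
  # recover ZYX Euler angles of Rt
  ay <- asin(-Rt[3, 1])
  ax <- atan2(Rt[3, 2], Rt[3, 3])
  az <- atan2(Rt[2, 1], Rt[1, 1])
  rigid_transform(c(ax, ay, az), as.vector(-Rt %*% tr$translation), tr$center)
}

#' Resample an image through a rigid transform
#'
#' `out(x) = in(R (x - c) + c + t)` in world coordinates, sampled on the
#' grid of `grid_like` (defaults to the input grid).
#'
#' @param v `amy_volume` or `amy_labelmap`.
#' @param tr An `amy_rigid`.
#' @param grid_like Object providing the output grid/spacing/origin.
#' @param interp Interpolation (labels force nearest).
#' @export
apply_rigid <- function(v, tr, grid_like = v,
                        interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  lab <- is_labelmap(v)
  if (lab) interp <- "nearest"
  R <- euler_matrix(tr$angles)
  sp_in <- v$spacing; or_in <- v$origin
  sp_out <- grid_like$spacing; or_out <- grid_like$origin
  # voxel_out -> world -> rigid -> voxel_in
  M <- diag(1 / sp_in) %*% R %*% diag(sp_out)
  off <- (R %*% (or_out - tr$center) + tr$center + tr$translation - or_in) / sp_in
  dat <- cpp_affine_warp(array(as.double(values_of(v)), grid_of(v)), M,
                         as.numeric(off), as.integer(grid_of(grid_like)),
                         interp == "nearest", !lab, 0)
  if (lab) labelmap(dat, sp_out, or_out) else volume(dat, sp_out, or_out)
}

world_centroid <- function(v) {
  w <- pmax(v$data, 0)
  sw <- sum(w)
  if (sw == 0) return(v$origin + (dim(v$data) - 1) / 2 * v$spacing)
  co <- phantom_coords(dim(v$data))
  ctr <- (dim(v$data) - 1) / 2
  idx <- c(sum(w * (co$x + ctr[1])), sum(w * (co$y + ctr[2])),
           sum(w * (co$z + ctr[3]))) / sw
  v$origin + idx * v$spacing
}

rigid_msd <- function(moving, fixed, tr) {
  w <- apply_rigid(moving, tr, fixed)
  mean((w$data - fixed$data)^2)
}

#' Rigid registration by coordinate descent
#'
#' 6-dof (3 rotations, 3 translations) minimization of the mean squared
#' intensity difference, initialized from intensity-centroid alignment and
#' refined by per-parameter coordinate descent with step halving.
#' Deterministic.
#'
#' @param moving,fixed `amy_volume`s with overlapping fields of view.
#' @param max_iter Maximum number of descent sweeps.
#' @return An `amy_rigid` mapping fixed-grid points into the moving image.
#' @export
rigid_register <- function(moving, fixed, max_iter = 60) {
  center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
  p <- c(0, 0, 0, world_centroid(moving) - world_centroid(fixed))
  obj <- function(p) rigid_msd(moving, fixed,
                               rigid_transform(p[1:3], p[4:6], center))
  cur <- obj(p)
  if (!is.finite(cur)) stop("non-finite registration metric")
  steps <- c(rep(0.05, 3), rep(2 * max(fixed$spacing), 3))
  for (sweep in seq_len(max_iter)) {
    improved <- FALSE
    for (i in 1:6) {
      for (s in c(steps[i], -steps[i])) {
        cand <- p; cand[i] <- cand[i] + s
        val <- obj(cand)
        if (val < cur - 1e-12) { p <- cand; cur <- val; improved <- TRUE; break }
      }
    }
    if (!improved) {
      steps <- steps / 2
      if (steps[1] < 5e-4 && steps[4] < 0.02 * max(fixed$spacing)) break
    }
  }
  rigid_transform(p[1:3], p[4:6], center)
}

# ---- deformable -------------------------------------------------------------

scale_disp_grid <- function(disp, odim, ratio) {
  # transfer a displacement field between resolutions: sample at
  # out_index -> in_coord = (j - (r-1)/2)/r and scale magnitudes by r
  a <- rep(1 / ratio, 3)
  b <- rep(-(ratio - 1) / 2 / ratio, 3)
  out <- array(0, c(odim, 3))
  for (c3 in 1:3)
    out[, , , c3] <- cpp_resample_grid(disp[, , , c3], as.integer(odim), a, b) * ratio
  out
}

#' Multi-resolution diffeomorphic registration
#'
#' Aligns `moving` onto the grid of `fixed` (which should already be
#' rigidly pre-aligned) over the levels of `schedule`, returning the
#' deformation field, the metric trace and a convergence flag. The metric
#' is always evaluated at full resolution (the level field is upsampled
#' for each evaluation), so trace entries are comparable across levels;
#' only metric-improving steps are accepted (with up to three step
#' halvings per iteration), making the whole trace non-increasing.
#'
#' @param moving,fixed `amy_volume`s on the same grid.
#' @param schedule A [reg_schedule()].
#' @param params See [default_reg_params()].
#' @param init Optional initial `amy_defield` on the fixed grid.
#' @return A `reg_result` list: `field`, `metric_trace`, `level_id`,
#'   `converged`.
#' @export
diffeo_register <- function(moving, fixed, schedule = reg_schedule(),
                            params = default_reg_params(), init = NULL) {
  if (!identical(dim(moving$data), dim(fixed$data)))
    stop("moving and fixed must share a grid (rigidly pre-align first)")
  full_dim <- dim(fixed$data)
  pyr_f <- lapply(schedule$factors, function(f)
    if (f == 1) fixed$data else cpp_block_mean(fixed$data, f))
  pyr_m <- lapply(schedule$factors, function(f)
    if (f == 1) moving$data else cpp_block_mean(moving$data, f))
  full_msd <- function(disp_l, f) {
    dfull <- if (f == 1) disp_l else scale_disp_grid(disp_l, full_dim, f)
    w <- cpp_warp(moving$data, dfull, FALSE, TRUE, 0)
    mean((w - fixed$data)^2)
  }
  disp <- NULL
  trace <- numeric(0)
  level_id <- integer(0)
  converged <- FALSE
  prev_factor <- NULL
  for (li in seq_along(schedule$factors)) {
    f <- schedule$factors[li]
    Fv <- pyr_f[[li]]; Mv <- pyr_m[[li]]
    ldim <- dim(Fv)
    if (is.null(disp)) {
      if (!is.null(init)) {
        disp <- if (f == 1) init$disp else scale_disp_grid(init$disp, ldim, 1 / f)
      } else disp <- array(0, c(ldim, 3))
    } else if (f != prev_factor) {
      disp <- scale_disp_grid(disp, ldim, prev_factor / f)
    }
    prev_factor <- f
    cur <- full_msd(disp, f)
    trace <- c(trace, cur); level_id <- c(level_id, li)
    stalls <- 0L
    converged <- FALSE
    for (it in seq_len(schedule$iters[li])) {
      warped <- cpp_warp(Mv, disp, FALSE, TRUE, 0)
      upd <- cpp_demons_update(Fv, warped, params$kappa)
      u <- cpp_smooth_field(upd$u, as.integer(ldim), params$fluid_sigma)
      mx <- cpp_max_norm(u, ldim)
      if (mx > params$step_max) u <- u * (params$step_max / mx)
      accepted <- FALSE
      for (halve in 0:3) {
        cand <- cpp_compose(u, disp, as.integer(ldim))
        if (params$diffusion_sigma > 0)
          cand <- cpp_smooth_field(cand, as.integer(ldim),
                                   params$diffusion_sigma)
        val <- full_msd(cand, f)
        if (val <= cur) {
          rel <- if (cur > 0) (cur - val) / cur else 0
          disp <- cand; cur <- val
          trace <- c(trace, cur); level_id <- c(level_id, li)
          stalls <- if (rel < params$tol) stalls + 1L else 0L
          accepted <- TRUE
          break
        }
        u <- u * 0.5
      }
      if (!accepted || stalls >= params$stall_limit) { converged <- TRUE; break }
    }
  }
  field <- defield(if (prev_factor == 1) disp
                   else scale_disp_grid(disp, full_dim, prev_factor),
                   fixed$spacing, fixed$origin)
  jmin <- min(jacobian_determinant(field)$data)
  if (jmin <= 0)
    stop("emitted deformation field is not diffeomorphic (min |J| = ",
         signif(jmin, 4), ")")
  structure(list(field = field, metric_trace = trace, level_id = level_id,
                 converged = converged),
            class = "reg_result")
}

#' @export
print.reg_result <- function(x, ...) {
  cat(sprintf("<reg_result: MSD %.4g -> %.4g over %d evaluations, %s>\n",
              x$metric_trace[1], x$metric_trace[length(x$metric_trace)],
              length(x$metric_trace),
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}
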