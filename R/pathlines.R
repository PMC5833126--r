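# Pathline engine: one pathline per ED voxel, integrated forwards to the
# next ES and backwards to the preceding ES through the periodic velocity
# field with fixed-step fourth-order Runge-Kutta.

# Core RK4 advection over a velocity closure.
#
# vfun(pos_matrix_mm, time_ms) must return an n x 3 matrix of velocities in
# cm/s with attribute "oob" flagging positions outside the sampling domain.
# Positions whose current location is out of bounds are frozen: they stop
# moving and keep their first out-of-bounds position (their stored velocity
# is zero from there on). Backward integration advances with negative time
# steps through the same field (the cycle is a closed loop, so no reversed
# dataset is needed).
#
# Returns list(t, pos [n x 3 x k1], vel [n x 3 x k1], left_fov).
rk4_advect <- function(vfun, seeds, t_start, duration,
                       direction = c("forward", "backward"), step) {
  direction <- match.arg(direction)
  if (step <= 0) stop("step must be > 0")
  if (duration < 0) stop("duration must be >= 0")
  sgn <- if (direction == "forward") 1 else -1
  n_full <- floor(duration / step + 1e-9)
  dts <- rep(step, n_full)
  rem <- duration - n_full * step
  if (rem > 1e-9 * max(step, 1)) dts <- c(dts, rem)
  k1n <- length(dts) + 1L

  n <- nrow(seeds)
  pos <- array(NA_real_, c(n, 3L, k1n))
  vel <- array(0, c(n, 3L, k1n))
  tt <- t_start + sgn * c(0, cumsum(dts))
  cur <- seeds
  frozen <- rep(FALSE, n)
  conv <- 0.01  # cm/s -> mm/ms

  for (i in seq_len(k1n)) {
    v <- vfun(cur, tt[i])
    oob <- attr(v, "oob")
    frozen <- frozen | oob
    v[frozen, ] <- 0
    pos[, , i] <- cur
    vel[, , i] <- v
    if (i == k1n) break
    dt <- sgn * dts[i]
    h <- dt * conv
    k1 <- v
    k2 <- vfun(cur + (h / 2) * k1, tt[i] + dt / 2)
    k3 <- vfun(cur + (h / 2) * k2, tt[i] + dt / 2)
    k4 <- vfun(cur + h * k3, tt[i] + dt)
    stepv <- (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(stepv[!frozen, ])))
      stop("non-finite pathline position at step ", i,
           " (seed row ", which(!is.finite(rowSums(stepv)))[1], ")")
    upd <- !frozen
    cur[upd, ] <- cur[upd, ] + stepv[upd, , drop = FALSE]
  }
  list(t = tt, pos = pos, vel = vel, left_fov = frozen)
}

# velocity closure over a discrete field
field_velocity_fun <- function(field) {
  force(field)
  function(pos, t) sample_velocity(field, pos, t)
}

#' Emit pathline seeds from the ED mask
#'
#' One seed at the centre of each flow voxel inside the resampled ED mask,
#' in deterministic raster order (x fastest). The seed count times the flow
#' voxel volume equals the seeding EDV by construction.
#'
#' @param ed_mask_flow logical 3-D array on the flow grid.
#' @param field a [velocity_field()].
#' @return n x 3 matrix of world positions in mm.
#' @export
emit_seeds <- function(ed_mask_flow, field) {
  if (!any(ed_mask_flow)) stop("ED mask is empty")
  centres <- voxel_centres(field$dim, field$voxel_spacing, field$origin)
  centres[which(ed_mask_flow), , drop = FALSE]
}

#' Integrate a single pathline
#'
#' Fixed-step fourth-order Runge-Kutta integration of dx/dt = v(x, t)
#' through the periodic velocity field, from \code{t_start} to \code{t_end}.
#' Positions are stored at every step and at \code{t_end} exactly (the final
#' partial step is shortened). If the trajectory leaves the field of view it
#' is frozen at its first out-of-bounds position and flagged.
#'
#' @param field a [velocity_field()].
#' @param seed world position (mm), length 3.
#' @param t_start,t_end times in ms on the wrapped cycle axis; for backward
#'   integration \code{t_end < t_start}.
#' @param direction \code{"forward"} or \code{"backward"}.
#' @param step time step in ms (> 0).
#' @return list with \code{t} (ms), \code{positions} (k x 3), \code{velocities}
#'   (k x 3, cm/s) and \code{left_fov} (logical).
#' @export
integrate_pathline <- function(field, seed, t_start, t_end,
                               direction = c("forward", "backward"),
                               step = field$frame_interval / 10) {
  direction <- match.arg(direction)
  duration <- abs(t_end - t_start)
  if ((direction == "forward" && t_end < t_start) ||
      (direction == "backward" && t_end > t_start))
    stop("t_end is on the wrong side of t_start for direction '",
         direction, "'")
  tr <- rk4_advect(field_velocity_fun(field), matrix(seed, 1L, 3L),
                   t_start, duration, direction, step)
  list(t = tr$t,
       positions = t(tr$pos[1L, , ]),
       velocities = t(tr$vel[1L, , ]),
       left_fov = tr$left_fov[1L])
}

#' Track all ED-voxel pathlines over one cardiac cycle
#'
#' For every seed, forward integration from the ED time to the next
#' occurrence of the ES time in wrapped time, and backward integration to
#' the preceding ES. The two intervals together cover exactly one cycle
#' length, so the combined tracks represent the whole EDV followed over one
#' complete cardiac cycle.
#'
#' @param field a [velocity_field()].
#' @param ed_mask_flow logical 3-D array on the flow grid.
#' @param ed_frame,es_frame 0-based timeframe indices.
#' @param step integration step in ms; default \code{frame_interval / 10}.
#' @return An object of class \code{lv_pathlines}: seeds, per-direction node
#'   times (ms relative to ED; backward times are negative), position and
#'   velocity arrays (n x 3 x k), out-of-FOV flags, the voxel volume (ml)
#'   and the grid geometry.
#' @export
track_all <- function(field, ed_mask_flow, ed_frame, es_frame,
                      step = field$frame_interval / 10) {
  nf <- field$n_frames
  if (ed_frame < 0 || ed_frame >= nf || es_frame < 0 || es_frame >= nf)
    stop("ed_frame and es_frame must be in [0, n_frames)")
  if (ed_frame == es_frame) stop("ed_frame and es_frame must differ")
  seeds <- emit_seeds(ed_mask_flow, field)
  dt <- field$frame_interval
  t_ed <- ed_frame * dt
  span_fwd <- ((es_frame - ed_frame) %% nf)
  dur_fwd <- span_fwd * dt
  dur_bwd <- cycle_length(field) - dur_fwd
  vfun <- field_velocity_fun(field)
  fwd <- rk4_advect(vfun, seeds, t_ed, dur_fwd, "forward", step)
  bwd <- rk4_advect(vfun, seeds, t_ed, dur_bwd, "backward", step)
  structure(
    list(seeds = seeds,
         voxel_volume_ml = prod(field$voxel_spacing) / 1000,
         t_fwd = fwd$t - t_ed, pos_fwd = fwd$pos, vel_fwd = fwd$vel,
         left_fov_fwd = fwd$left_fov,
         t_bwd = bwd$t - t_ed, pos_bwd = bwd$pos, vel_bwd = bwd$vel,
         left_fov_bwd = bwd$left_fov,
         ed_frame = as.integer(ed_frame), es_frame = as.integer(es_frame),
         step = step,
         grid = list(dim = field$dim, spacing = field$voxel_spacing,
                     origin = field$origin)),
    class = "lv_pathlines"
  )
}

#' @export
print.lv_pathlines <- function(x, ...) {
  cat(sprintf("LV pathlines: %d seeds (%.1f ml EDV)\n",
              nrow(x$seeds), nrow(x$seeds) * x$voxel_volume_ml))
  cat(sprintf("  forward %.0f ms (%d nodes), backward %.0f ms (%d nodes), step %.2f ms\n",
              max(x$t_fwd), length(x$t_fwd),
              -min(x$t_bwd), length(x$t_bwd), x$step))
  cat(sprintf("  left FOV: %d forward, %d backward\n",
              sum(x$left_fov_fwd), sum(x$left_fov_bwd)))
  invisible(x)
}

#' Export pathline tracks as a long-format data frame
#'
#' @param x an \code{lv_pathlines} object.
#' @param every store every n-th node (endpoints always kept).
#' @return data frame with seed id, direction, t_ms (relative to ED),
#'   positions (mm) and velocities (cm/s).
#' @export
pathline_tracks <- function(x, every = 1L) {
  pick <- function(tv) {
    k <- length(tv)
    sort(unique(c(seq(1L, k, by = every), k)))
  }
  build <- function(tv, pos, vel, dirn) {
    ii <- pick(tv)
    n <- dim(pos)[1]
    data.frame(
      seed = rep(seq_len(n), times = length(ii)),
      direction = dirn,
      t_ms = rep(tv[ii], each = n),
      x = as.vector(pos[, 1, ii]), y = as.vector(pos[, 2, ii]),
      z = as.vector(pos[, 3, ii]),
      vx = as.vector(vel[, 1, ii]), vy = as.vector(vel[, 2, ii]),
      vz = as.vector(vel[, 3, ii])
    )
  }
  rbind(build(x$t_fwd, x$pos_fwd, x$vel_fwd, "forward"),
        build(x$t_bwd, x$pos_bwd, x$vel_bwd, "backward"))
}
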