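#' 4D velocity field
#'
#' Container for a three-directional, time-resolved velocity dataset on a
#' regular grid, as acquired by 4D-flow phase-contrast CMR. The time axis is
#' periodic: the acquisition covers one complete cardiac cycle and forms a
#' closed loop in which the last frame is followed by the first.
#'
#' @param data five-dimensional numeric array with dimensions
#'   (x, y, z, timeframe, direction); velocities in cm/s, three directions.
#' @param voxel_spacing per-axis voxel edge length in mm (length 1 or 3).
#' @param frame_interval time between consecutive frames in ms.
#' @param venc velocity-encoding limit in cm/s. Stored velocity magnitudes
#'   above \code{venc * sqrt(3)} are flagged with a warning, not an error,
#'   since residual aliasing is a data-quality issue rather than a structural
#'   one.
#' @param origin world position (mm) of the centre of voxel (0, 0, 0).
#'
#' @return An object of class \code{velocity_field}: a list with elements
#'   \code{data}, \code{dim} (spatial grid size), \code{n_frames},
#'   \code{voxel_spacing}, \code{frame_interval}, \code{venc}, \code{origin}.
#' @seealso [sample_velocity()], [load_velocity_field()]
#' @export
velocity_field <- function(data, voxel_spacing, frame_interval, venc = 100,
                           origin = c(0, 0, 0)) {
  if (length(dim(data)) != 5L)
    stop("data must be a 5-axis array (x, y, z, timeframe, direction); got ",
         length(dim(data)), " axes")
  if (dim(data)[5] != 3L)
    stop("data must have 3 velocity directions on the fifth axis")
  if (dim(data)[4] < 2L)
    stop("n_frames must be >= 2")
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  stopifnot(length(voxel_spacing) == 3L, length(origin) == 3L)
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be > 0")
  if (length(frame_interval) != 1L || !is.finite(frame_interval) ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number (ms)")
  if (length(venc) != 1L || venc <= 0) stop("venc must be > 0")
  field <- structure(
    list(
      data = data,
      dim = dim(data)[1:3],
      n_frames = dim(data)[4],
      voxel_spacing = as.numeric(voxel_spacing),
      frame_interval = as.numeric(frame_interval),
      venc = as.numeric(venc),
      origin = as.numeric(origin)
    ),
    class = "velocity_field"
  )
  vmax <- sqrt(max(.speed_sq_max(data)))
  if (vmax > venc * sqrt(3) * (1 + 1e-12))
    warning(sprintf(
      "maximum velocity magnitude %.1f cm/s exceeds venc * sqrt(3) = %.1f cm/s; residual aliasing suspected",
      vmax, venc * sqrt(3)))
  field
}

.speed_sq_max <- function(data) {
  d <- dim(data)
  m <- matrix(data, prod(d[1:4]), 3L)
  max(rowSums(m^2))
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("4D velocity field\n")
  cat(sprintf("  grid: %d x %d x %d voxels, spacing %s mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(format(x$voxel_spacing), collapse = " x ")))
  cat(sprintf("  frames: %d, interval %.1f ms (cycle %.1f ms)\n",
              x$n_frames, x$frame_interval, cycle_length(x)))
  cat(sprintf("  venc: %.0f cm/s, origin (%s) mm\n",
              x$venc, paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Cardiac cycle length of a velocity field
#'
#' @param field a [velocity_field()].
#' @return cycle length in ms (\code{n_frames * frame_interval}).
#' @export
cycle_length <- function(field) {
  field$n_frames * field$frame_interval
}

#' Sample a velocity field at arbitrary positions and time
#'
#' Trilinear interpolation in space and linear interpolation in time, with
#' periodic wrap of the time axis (the cycle is a closed loop, so the frame
#' after the last is the first). Positions outside the spatial interpolation
#' domain (the convex hull of voxel centres) return the zero vector and are
#' flagged; the sampler is total and never errors on position.
#'
#' @param field a [velocity_field()].
#' @param position numeric vector of length 3 or an n x 3 matrix of world
#'   positions in mm.
#' @param time time in ms (scalar); interpreted modulo the cycle length.
#' @return an n x 3 matrix of velocities in cm/s with attribute \code{"oob"},
#'   a logical vector marking positions outside the spatial grid.
#' @export
sample_velocity <- function(field, position, time) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3L)
  n <- nrow(position)
  d3 <- field$dim
  u <- sweep(sweep(position, 2L, field$origin, `-`), 2L,
             field$voxel_spacing, `/`)
  inside <- u[, 1] >= 0 & u[, 1] <= d3[1] - 1L &
    u[, 2] >= 0 & u[, 2] <= d3[2] - 1L &
    u[, 3] >= 0 & u[, 3] <= d3[3] - 1L
  inside[is.na(inside)] <- FALSE
  out <- matrix(0, n, 3L)
  attr(out, "oob") <- !inside
  if (!any(inside)) return(out)

  # temporal bracket with periodic wrap
  tc <- time %% cycle_length(field)
  f <- tc / field$frame_interval
  j0 <- floor(f) %% field$n_frames
  j1 <- (j0 + 1) %% field$n_frames
  at <- f - floor(f)

  ui <- u[inside, , drop = FALSE]
  i0 <- pmin(floor(ui), matrix(rep(d3 - 2L, each = nrow(ui)), ncol = 3L))
  i0 <- pmax(i0, 0)
  w <- ui - i0

  nx <- d3[1]; ny <- d3[2]; nz <- d3[3]
  nvox <- nx * ny * nz
  nt <- field$n_frames
  base <- 1 + i0[, 1] + nx * (i0[, 2] + ny * i0[, 3])
  off_t0 <- nvox * j0
  off_t1 <- nvox * j1
  dat <- field$data

  acc <- matrix(0, nrow(ui), 3L)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx == 1) w[, 1] else 1 - w[, 1]) *
      (if (cy == 1) w[, 2] else 1 - w[, 2]) *
      (if (cz == 1) w[, 3] else 1 - w[, 3])
    if (all(wt == 0)) next
    corner <- base + cx + nx * cy + nx * ny * cz
    for (dirn in 1:3) {
      off_d <- nvox * nt * (dirn - 1)
      v0 <- dat[corner + off_t0 + off_d]
      v1 <- dat[corner + off_t1 + off_d]
      acc[, dirn] <- acc[, dirn] + wt * ((1 - at) * v0 + at * v1)
    }
  }
  out[inside, ] <- acc
  out
}
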