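# shared fixtures, built in code

# uniform constant field: v cm/s along x everywhere
make_uniform_field <- function(v = 10, n = 8, h = 3, nt = 2, dt = 100) {
  dat <- array(0, c(n, n, n, nt, 3))
  dat[, , , , 1] <- v
  velocity_field(dat, h, dt)
}

# rigid rotation about the z axis through the grid centre; time-constant.
# omega in rad/ms; velocities linear in space so trilinear interpolation is
# exact and integration error isolates the RK4 scheme.
make_rotation_field <- function(omega = 2 * pi / 1000, n = 32, h = 3,
                                nt = 2, dt = 500) {
  ctr <- (n - 1) * h / 2
  cen <- voxel_centres(c(n, n, n), rep(h, 3), c(0, 0, 0))
  vx <- -omega * (cen[, 2] - ctr) * 100  # mm/ms -> cm/s
  vy <- omega * (cen[, 1] - ctr) * 100
  dat <- array(0, c(n, n, n, nt, 3))
  for (j in seq_len(nt)) {
    dat[, , , j, 1] <- array(vx, c(n, n, n))
    dat[, , , j, 2] <- array(vy, c(n, n, n))
  }
  velocity_field(dat, h, dt)
}

# the default noise-free reference phantom, generated once per test run
reference_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec(seed = 1))
    cache
  }
})

grid_centres <- function(field) {
  voxel_centres(field$dim, field$voxel_spacing, field$origin)
}
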