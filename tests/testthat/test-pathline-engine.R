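test_that("seeds sit at every inside-voxel centre in raster order", {
  fld <- make_uniform_field(v = 0, n = 8)
  mask <- array(FALSE, rep(8, 3))
  mask[3:4, 3:4, 3:4] <- TRUE
  seeds <- emit_seeds(mask, fld)
  expect_equal(nrow(seeds), 8L)
  expected <- as.matrix(expand.grid(x = c(6, 9), y = c(6, 9), z = c(6, 9)))
  expect_equal(unname(seeds), unname(expected), ignore_attr = TRUE)
  one <- array(FALSE, rep(8, 3)); one[5, 2, 7] <- TRUE
  expect_equal(as.numeric(emit_seeds(one, fld)), c(4, 1, 6) * 3)
  expect_error(emit_seeds(array(FALSE, rep(8, 3)), fld), "empty")
})

test_that("seed count times voxel volume equals the EDV by shared definition", {
  ph <- reference_phantom()
  seeds <- emit_seeds(ph$seg$ed_mask, ph$field)
  vi <- compute_volumetric_indices(ph$seg$ed_mask, ph$seg$es_mask,
                                   prod(ph$field$voxel_spacing) / 1000)
  expect_identical(nrow(seeds) * 0.027, vi$edv_ml)
})

test_that("a uniform field advects by the exact closed-form displacement", {
  fld <- make_uniform_field(v = 10, n = 16, dt = 100)  # 10 cm/s = 0.1 mm/ms
  tr <- integrate_pathline(fld, c(3, 20, 20), 0, 100, "forward", step = 7)
  expect_equal(tr$positions[nrow(tr$positions), ] - c(3, 20, 20), c(10, 0, 0),
               tolerance = 1e-12)
  expect_equal(tr$t[length(tr$t)], 100)  # final partial step lands exactly
  trb <- integrate_pathline(fld, c(23, 20, 20), 100, 0, "backward", step = 7)
  expect_equal(trb$positions[nrow(trb$positions), ], c(13, 20, 20),
               tolerance = 1e-12)
})

test_that("rigid-rotation radius drift over one cycle is below 0.01 mm", {
  fld <- make_rotation_field(omega = 2 * pi / 1000)
  ctr <- (32 - 1) * 3 / 2
  seed <- c(ctr + 20, ctr, ctr)
  tr <- integrate_pathline(fld, seed, 0, 1000, "forward", step = 5)
  endp <- tr$positions[nrow(tr$positions), ]
  expect_lt(sqrt(sum((endp - seed)^2)), 0.01)
  expect_false(tr$left_fov)
})

test_that("forward-then-backward integration returns to the seed within 1e-6 mm", {
  fld <- make_rotation_field(omega = 2 * pi / 1000)
  ctr <- (32 - 1) * 3 / 2
  for (seed in list(c(ctr + 20, ctr, ctr), c(ctr + 5, ctr - 12, ctr + 9))) {
    fwd <- integrate_pathline(fld, seed, 0, 200, "forward", step = 5)
    endp <- fwd$positions[nrow(fwd$positions), ]
    bwd <- integrate_pathline(fld, endp, 200, 0, "backward", step = 5)
    back <- bwd$positions[nrow(bwd$positions), ]
    expect_lt(sqrt(sum((back - seed)^2)), 1e-6)
  }
})

test_that("trajectories that leave the FOV freeze and are flagged", {
  fld <- make_uniform_field(v = 50, n = 8, dt = 100)  # 0.5 mm/ms
  tr <- integrate_pathline(fld, c(18, 10, 10), 0, 100, "forward", step = 2)
  expect_true(tr$left_fov)
  k <- nrow(tr$positions)
  expect_equal(tr$positions[k, ], tr$positions[k - 1, ])  # frozen
  expect_true(tr$positions[k, 1] >= 21 - 1e-9)
  expect_equal(tr$velocities[k, ], c(0, 0, 0))
})

test_that("forward and backward spans partition the cycle for any ED/ES pair", {
  fld <- make_uniform_field(v = 0, n = 8, nt = 20, dt = 52)
  mask <- array(FALSE, rep(8, 3)); mask[4, 4, 4] <- TRUE
  for (frames in list(c(0, 8), c(18, 6), c(5, 19), c(10, 0))) {
    pl <- track_all(fld, mask, frames[1], frames[2], step = 5.2)
    span_f <- max(pl$t_fwd)
    span_b <- -min(pl$t_bwd)
    expect_equal(span_f, ((frames[2] - frames[1]) %% 20) * 52)
    expect_equal(span_f + span_b, cycle_length(fld))
    expect_equal(pl$pos_fwd[, , 1], pl$seeds, ignore_attr = TRUE)
    expect_equal(pl$pos_bwd[, , 1], pl$seeds, ignore_attr = TRUE)
  }
})

test_that("halving the step barely moves endpoints or changes labels", {
  ph <- reference_phantom()
  step <- ph$field$frame_interval / 10
  pl1 <- track_all(ph$field, ph$seg$ed_mask, 0, 8, step = step)
  pl2 <- track_all(ph$field, ph$seg$ed_mask, 0, 8, step = step / 2)
  lab1 <- classify_pathlines(pl1, ph$seg$es_mask)
  lab2 <- classify_pathlines(pl2, ph$seg$es_mask)
  expect_gte(mean(lab1 == lab2), 0.995)
  end1 <- pl1$pos_fwd[, , dim(pl1$pos_fwd)[3]]
  end2 <- pl2$pos_fwd[, , dim(pl2$pos_fwd)[3]]
  moved <- sqrt(rowSums((end1 - end2)^2))
  expect_lt(stats::median(moved), 0.05)
})

test_that("a seeded cube preserves its volume in the divergence-free channel", {
  ph <- reference_phantom()
  geo <- ph$truth$geometry
  # a 2-voxel cube inside the channel, retained-inflow region (never leaves)
  ctr_y <- (geo$chan_block["ylo"] + geo$chan_block["yhi"]) / 2
  ctr_z <- (geo$chan_block["zlo"] + geo$chan_block["zhi"]) / 2
  base <- c(geo$a + 3, ctr_y, ctr_z)
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 3
  cube <- sweep(offs, 2, base, `+`)
  vfun <- function(p, t) sample_velocity(ph$field, p, t)
  tr <- lv4dflow:::rk4_advect(vfun, cube, 0, cycle_length(ph$field),
                              "forward", step = 5.2)
  endp <- tr$pos[, , dim(tr$pos)[3]]
  # uniform translation preserves all pairwise distances, hence the volume
  d0 <- as.matrix(dist(cube)); d1 <- as.matrix(dist(endp))
  expect_lt(max(abs(d1 - d0)) / max(d0), 0.02)
})

test_that("track export produces a tidy long table", {
  fld <- make_uniform_field(v = 10, n = 8, nt = 4, dt = 52)
  mask <- array(FALSE, rep(8, 3)); mask[3:4, 4, 4] <- TRUE
  pl <- track_all(fld, mask, 0, 2, step = 10)
  tab <- pathline_tracks(pl, every = 2)
  expect_true(all(c("seed", "direction", "t_ms", "x", "vx") %in% names(tab)))
  expect_setequal(unique(tab$direction), c("forward", "backward"))
  expect_equal(sort(unique(tab$seed)), 1:2)
})
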