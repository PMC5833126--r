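test_that("static tissue mask matches the still background by construction", {
  ph <- generate_phantom(phantom_spec(seed = 5))  # noise-free
  static <- identify_static_tissue(ph$field, 2)
  # every truly zero-velocity voxel must be selected
  nvox <- prod(ph$field$dim)
  moving <- apply(abs(ph$field$data), 1:3, max) > 0
  expect_true(all(static[!moving]))
  expect_false(any(static & array(!is.na(ph$truth$labels) &
                                    ph$truth$labels != "residual_volume",
                                  ph$field$dim)))
})

test_that("static-tissue threshold zero on noisy data is an explicit error", {
  ph <- generate_phantom(phantom_spec(seed = 5, noise_sigma = 1))
  expect_error(identify_static_tissue(ph$field, 0), "threshold")
})

test_that("threshold 3 cm/s captures at least 99% of 1 cm/s-noise background", {
  ph <- generate_phantom(phantom_spec(seed = 6, noise_sigma = 1))
  static <- identify_static_tissue(ph$field, 3)
  moving <- apply(abs(generate_phantom(phantom_spec(seed = 6))$field$data),
                  1:3, max) > 0
  frac <- sum(static[!moving]) / sum(!moving)
  expect_gte(frac, 0.99)
})

test_that("a linear-in-x offset is recovered exactly in world coordinates", {
  n <- c(16, 16, 16); h <- 3
  cen <- voxel_centres(n, rep(h, 3), c(0, 0, 0))
  dat <- array(0, c(n, 3, 3))
  for (j in 1:3) dat[, , , j, 1] <- array(0.8 + 0.002 * cen[, 1], n)
  fld <- velocity_field(dat, h, 52)
  mod <- fit_background_polynomial(fld, array(TRUE, n))
  wc <- coef(mod, basis = "world")
  expect_equal(unname(wc["x0y0z0", 1]), 0.8, tolerance = 1e-6)
  expect_equal(unname(wc["x1y0z0", 1]), 0.002, tolerance = 1e-6)
  others <- wc[!(rownames(wc) %in% c("x0y0z0", "x1y0z0")), 1]
  expect_lt(max(abs(others)), 1e-9)
  expect_lt(max(abs(wc[, 2:3])), 1e-9)
})

test_that("a zero-offset field yields a null model", {
  fld <- make_uniform_field(v = 0, n = 10)
  mod <- fit_background_polynomial(fld, array(TRUE, rep(10, 3)))
  expect_lt(max(abs(mod$coefficients)), 1e-9)
})

test_that("a full cubic offset drawn from a fixed seed is recovered exactly", {
  set.seed(7)
  coefs <- matrix(rnorm(60, sd = 0.5), 20, 3)
  ph <- generate_phantom(phantom_spec(seed = 4, background_coef = coefs))
  static <- identify_static_tissue(ph$field, 2)
  expect_gte(sum(static), 200)
  mod <- fit_background_polynomial(ph$field, static)
  expect_lt(max(abs(mod$coefficients - coefs)) / max(abs(coefs)), 1e-6)
})

test_that("fitting on degenerate (coplanar) static voxels errors", {
  fld <- make_uniform_field(v = 0, n = 10)
  plane <- array(FALSE, rep(10, 3))
  plane[, , 4] <- TRUE  # single z-slice: z-monomials unidentifiable
  expect_error(fit_background_polynomial(fld, plane, min_voxels = 50),
               "rank-deficient")
  expect_error(fit_background_polynomial(fld, array(FALSE, rep(10, 3))),
               "static voxels")
})

test_that("phase correction is a projection and preserves temporal differences", {
  set.seed(7)
  coefs <- matrix(rnorm(60, sd = 0.5), 20, 3)
  ph <- generate_phantom(phantom_spec(seed = 4, background_coef = coefs,
                                      noise_sigma = 0.5))
  static <- identify_static_tissue(ph$field, 3)
  mod <- fit_background_polynomial(ph$field, static)
  corr <- apply_phase_correction(ph$field, mod)
  # idempotence: refitting on the corrected field gives a null model
  mod2 <- fit_background_polynomial(corr, static)
  expect_lt(max(abs(mod2$coefficients)), 1e-9)
  # temporal differences are untouched exactly
  d_before <- ph$field$data[, , , 2, ] - ph$field$data[, , , 1, ]
  d_after <- corr$data[, , , 2, ] - corr$data[, , , 1, ]
  expect_equal(d_after, d_before, tolerance = 1e-13)
  # the input object is unmodified
  expect_false(identical(corr$data, ph$field$data))
})

test_that("a zero model leaves the field bitwise unchanged", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  fld <- make_uniform_field(v = 0, n = 10)
  null_mod <- fit_background_polynomial(fld, array(TRUE, rep(10, 3)))
  null_mod$coefficients[] <- 0
  corr <- apply_phase_correction(ph$field, null_mod)
  expect_identical(corr$data, ph$field$data)
})

test_that("corrected background mean speed drops to the noise floor", {
  set.seed(7)
  coefs <- matrix(rnorm(60, sd = 0.5), 20, 3)
  ph <- generate_phantom(phantom_spec(seed = 9, background_coef = coefs,
                                      noise_sigma = 0.5))
  static <- identify_static_tissue(ph$field, 3)
  mod <- fit_background_polynomial(ph$field, static)
  corr <- apply_phase_correction(ph$field, mod)
  tavg <- function(f, d) apply(f$data[, , , , d], 1:3, mean)
  for (d in 1:3) {
    resid <- tavg(corr, d)[static]
    # time-averaged static velocity after correction is pure averaged noise
    expect_lt(sqrt(mean(resid^2)), 2 * 0.5 / sqrt(ph$field$n_frames))
  }
})

test_that("identity resampling returns the mask unchanged", {
  ph <- reference_phantom()
  out <- resample_ed_mask(ph$seg, ph$field, "ed")
  expect_identical(out, ph$seg$ed_mask)
  out_es <- resample_ed_mask(ph$seg, ph$field, "es")
  expect_identical(out_es, ph$seg$es_mask)
})

test_that("anisotropic cine ellipsoid resamples to the analytic volume", {
  # ellipsoid semi-axes (30, 25, 40) mm, volume 4/3*pi*a*b*c = 125.66 ml
  semi <- c(30, 25, 40)
  vol_true <- 4 / 3 * pi * prod(semi) / 1000
  cine_sp <- c(1.5, 1.5, 8)
  cine_dim <- c(64, 64, 16)
  cine_origin <- c(0, 0, 0)
  ctr <- (cine_dim - 1) * cine_sp / 2
  cen <- voxel_centres(cine_dim, cine_sp, cine_origin)
  inside <- rowSums(sweep(sweep(cen, 2, ctr, `-`), 2, semi, `/`)^2) <= 1
  ed <- array(inside, cine_dim)
  es <- array(FALSE, cine_dim); es[28:36, 28:36, 7:10] <- TRUE
  seg <- lv_segmentation(ed, es, 0, 8, cine_sp, cine_origin,
                         check_connectivity = FALSE)
  fdat <- array(0, c(32, 32, 32, 2, 3))
  fld <- velocity_field(fdat, 3, 52)  # 3 mm flow grid over the same extent
  res <- resample_ed_mask(seg, fld, "ed")
  vol_res <- sum(res) * prod(fld$voxel_spacing) / 1000
  expect_lt(abs(vol_res - vol_true) / vol_true, 0.05)
  # convergence: a finer cine grid gives a closer volume
  cine_sp2 <- c(1.5, 1.5, 3)
  cine_dim2 <- c(64, 64, 42)
  ctr2 <- (cine_dim2 - 1) * cine_sp2 / 2
  cen2 <- voxel_centres(cine_dim2, cine_sp2, cine_origin)
  # recentre so the ellipsoid sits at the same world position
  inside2 <- rowSums(sweep(sweep(cen2, 2, ctr, `-`), 2, semi, `/`)^2) <= 1
  seg2 <- lv_segmentation(array(inside2, cine_dim2), array(inside2, cine_dim2),
                          ed_frame = 0, es_frame = 8, spacing = cine_sp2,
                          origin = cine_origin, check_connectivity = FALSE)
  res2 <- resample_ed_mask(seg2, fld, "ed")
  vol_res2 <- sum(res2) * prod(fld$voxel_spacing) / 1000
  expect_lte(abs(vol_res2 - vol_true), abs(vol_res - vol_true) + 0.3)
})

test_that("a mask entirely outside the flow FOV errors", {
  ed <- array(FALSE, c(8, 8, 8)); ed[2:3, 2:3, 2:3] <- TRUE
  seg <- lv_segmentation(ed, ed, 0, 4, spacing = 3, origin = c(500, 500, 500),
                         check_connectivity = FALSE)
  fld <- make_uniform_field(v = 0, n = 8)
  expect_error(resample_ed_mask(seg, fld, "ed"), "empty")
})

test_that("volumetric indices reproduce the worked cohort-mean arithmetic", {
  # EDV 155 ml, ESV 52 ml at 0.027 ml voxels
  n_ed <- round(155 / 0.027); n_es <- round(52 / 0.027)
  ed <- array(seq_len(50^3) <= n_ed, c(50, 50, 50))
  es <- array(seq_len(50^3) <= n_es, c(50, 50, 50))
  vi <- compute_volumetric_indices(ed, es, 0.027, heart_rate = 65)
  expect_equal(vi$sv_ml, vi$edv_ml - vi$esv_ml)
  expect_equal(vi$sv_ml, 103, tolerance = 1e-3)
  expect_equal(vi$ef_pct, 100 * 103 / 155, tolerance = 1e-3)  # 66.5%
  expect_equal(vi$cardiac_output_l_min, 103 * 65 / 1000, tolerance = 1e-3)
  expect_error(compute_volumetric_indices(ed, ed, 0.027, 65), "swapped")
})

test_that("volumetric identities hold on phantom analyses", {
  ph <- reference_phantom()
  fit <- lv4dflow(ph$field, ph$seg, heart_rate = ph$heart_rate)
  vi <- fit$volumetrics
  expect_identical(vi$sv_ml + vi$esv_ml, vi$edv_ml)
  expect_gt(vi$ef_pct, 0)
  expect_lt(vi$ef_pct, 100)
})
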