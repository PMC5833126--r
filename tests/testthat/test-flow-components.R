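# build a minimal lv_pathlines object with prescribed track endpoints
fake_pathlines <- function(seeds, end_fwd, end_bwd,
                           left_fwd = rep(FALSE, nrow(seeds)),
                           left_bwd = rep(FALSE, nrow(seeds)),
                           grid_dim = c(8, 8, 8), spacing = 3) {
  n <- nrow(seeds)
  arr <- function(a, b) {
    out <- array(NA_real_, c(n, 3, 2))
    out[, , 1] <- a; out[, , 2] <- b
    out
  }
  structure(
    list(seeds = seeds, voxel_volume_ml = prod(rep(spacing, 3)) / 1000,
         t_fwd = c(0, 100), pos_fwd = arr(seeds, end_fwd),
         vel_fwd = array(0, c(n, 3, 2)), left_fov_fwd = left_fwd,
         t_bwd = c(0, -100), pos_bwd = arr(seeds, end_bwd),
         vel_bwd = array(0, c(n, 3, 2)), left_fov_bwd = left_bwd,
         ed_frame = 0L, es_frame = 4L, step = 100,
         grid = list(dim = grid_dim, spacing = rep(spacing, 3),
                     origin = c(0, 0, 0))),
    class = "lv_pathlines"
  )
}

test_that("the four endpoint combinations map to the four components", {
  es <- array(FALSE, c(8, 8, 8))
  es[3:5, 3:5, 3:5] <- TRUE  # inside = x,y,z in [6,12] voxel centres
  inside_pt <- c(9, 9, 9); outside_pt <- c(21, 9, 9)
  seeds <- matrix(rep(c(9, 9, 9), 4), ncol = 3, byrow = TRUE)
  end_bwd <- rbind(outside_pt, outside_pt, inside_pt, inside_pt)
  end_fwd <- rbind(outside_pt, inside_pt, outside_pt, inside_pt)
  lab <- classify_pathlines(fake_pathlines(seeds, end_fwd, end_bwd), es)
  expect_equal(as.character(lab),
               c("direct_flow", "retained_inflow",
                 "delayed_ejection_flow", "residual_volume"))
})

test_that("frozen or out-of-grid endpoints count as outside the LV", {
  es <- array(TRUE, c(8, 8, 8))  # everything inside
  seeds <- matrix(rep(c(9, 9, 9), 3), ncol = 3, byrow = TRUE)
  inside_pt <- matrix(rep(c(9, 9, 9), 3), ncol = 3, byrow = TRUE)
  beyond <- rbind(c(9, 9, 9), c(500, 9, 9), c(9, 9, 9))
  pl <- fake_pathlines(seeds, end_fwd = beyond, end_bwd = inside_pt,
                       left_fwd = c(TRUE, FALSE, FALSE))
  lab <- classify_pathlines(pl, es)
  # 1: frozen forward -> outside; 2: forward endpoint off-grid -> outside
  expect_equal(as.character(lab),
               c("delayed_ejection_flow", "delayed_ejection_flow",
                 "residual_volume"))
})

test_that("component volumes and ratios mirror the cohort worked example", {
  labels <- factor(rep(c("direct_flow", "retained_inflow",
                         "delayed_ejection_flow", "residual_volume"),
                       times = c(380, 160, 160, 300)),
                   levels = lv4dflow:::COMPONENT_LEVELS)
  cv <- component_volumes(labels, 0.027)
  expect_equal(cv$pct_edv, c(38, 16, 16, 30))
  expect_equal(sum(cv$volume_ml), 1000 * 0.027)
  expect_equal(sum(cv$pct_edv), 100, tolerance = 1e-9)
})

test_that("single-label inputs and empty components are reported, not dropped", {
  labels <- factor(rep("direct_flow", 50),
                   levels = lv4dflow:::COMPONENT_LEVELS)
  cv <- component_volumes(labels, 0.027)
  expect_equal(cv$pct_edv, c(100, 0, 0, 0))
  expect_equal(nrow(cv), 4L)
})

test_that("the inflow/outflow QC rule reproduces the worked checks", {
  qc <- qc_inflow_outflow(c(direct_flow = 60, retained_inflow = 22,
                            delayed_ejection_flow = 21, residual_volume = 30))
  expect_equal(qc$inflow_ml, 82)
  expect_equal(qc$outflow_ml, 81)
  expect_equal(qc$rel_diff, 1 / 81.5, tolerance = 1e-12)  # 1.2%
  expect_true(qc$pass)
  qc2 <- qc_inflow_outflow(c(direct_flow = 30, retained_inflow = 30,
                             delayed_ejection_flow = 10, residual_volume = 0))
  expect_equal(qc2$rel_diff, 20 / 50)  # 40% > 10%
  expect_false(qc2$pass)
  qc3 <- qc_inflow_outflow(c(direct_flow = 40, retained_inflow = 10,
                             delayed_ejection_flow = 10, residual_volume = 0))
  expect_equal(qc3$rel_diff, 0)
  expect_true(qc3$pass)
  qc4 <- qc_inflow_outflow(c(direct_flow = 0, retained_inflow = 0,
                             delayed_ejection_flow = 0, residual_volume = 1))
  expect_false(qc4$pass)
  expect_match(qc4$message, "zero")
})

test_that("kinetic energy follows the half-rho-V-v-squared closed form", {
  # one pathline, V = 27 mm^3, rho = 1060 kg/m^3, |v| = 1 m/s -> 14.31 uJ
  seeds <- matrix(c(9, 9, 9), 1)
  pl <- fake_pathlines(seeds, seeds, seeds)
  pl$vel_fwd[1, , ] <- c(100, 0, 0)  # 100 cm/s = 1 m/s at both nodes
  pl$vel_bwd[1, , ] <- c(100, 0, 0)
  labels <- factor("direct_flow", levels = lv4dflow:::COMPONENT_LEVELS)
  kc <- kinetic_energy_curves(pl, labels, rho_blood = 1060)
  ke_ed <- kc$ke_uJ[kc$component == "direct_flow" & kc$t_ms == 0]
  expect_equal(ke_ed, 0.5 * 1060 * 2.7e-8 * 1 * 1e6, tolerance = 1e-12)
  expect_equal(ke_ed, 14.31, tolerance = 1e-3)
  # zero velocity -> zero KE everywhere
  pl0 <- fake_pathlines(seeds, seeds, seeds)
  kc0 <- kinetic_energy_curves(pl0, labels)
  expect_true(all(kc0$ke_uJ == 0))
  expect_error(kinetic_energy_curves(pl, labels, rho_blood = -1), "rho")
})

test_that("doubling every speed quadruples KE exactly", {
  ph <- reference_phantom()
  pl <- track_all(ph$field, ph$seg$ed_mask, 0, 8)
  labels <- classify_pathlines(pl, ph$seg$es_mask)
  kc1 <- kinetic_energy_curves(pl, labels)
  pl2 <- pl
  pl2$vel_fwd <- pl$vel_fwd * 2
  pl2$vel_bwd <- pl$vel_bwd * 2
  kc2 <- kinetic_energy_curves(pl2, labels)
  expect_equal(kc2$ke_uJ, 4 * kc1$ke_uJ, tolerance = 1e-12)
})

test_that("KE per millilitre divides by component volume, NA when empty", {
  vols <- data.frame(
    component = factor(lv4dflow:::COMPONENT_LEVELS,
                       levels = lv4dflow:::COMPONENT_LEVELS),
    n_pathlines = c(100L, 50L, 0L, 10L),
    volume_ml = c(50, 25, 0, 5), pct_edv = c(62.5, 31.25, 0, 6.25))
  kc <- data.frame(
    component = factor(lv4dflow:::COMPONENT_LEVELS,
                       levels = lv4dflow:::COMPONENT_LEVELS),
    t_ms = 0, ke_uJ = c(100, 10, 0, 1))
  ke <- ke_at_ed_per_ml(kc, vols)
  expect_equal(ke$ke_ed_uJ_per_ml[1], 2)
  expect_true(is.na(ke$ke_ed_uJ_per_ml[3]))
})

test_that("KE curves span the full cycle and are defined at every node", {
  ph <- reference_phantom()
  fit <- lv4dflow(ph$field, ph$seg)
  kc <- fit$ke_curves
  expect_equal(max(kc$t_ms) - min(kc$t_ms), cycle_length(ph$field))
  expect_true(all(kc$ke_uJ >= 0))
  expect_equal(sum(kc$t_ms == 0), 4L)  # one ED node per component
})
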