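test_that("an empty tissue renders as pure background noise", {
  cfg <- small_scenario(n_cells_per_layer = 0L)
  tr <- simulate_events(build_tissue(cfg, seed = 1), seed = 1)
  v <- render_volume(tr, seed = 1, frames = c(1L, 24L))
  bg <- cfg$optics$background
  m <- mean(v$channels$tubulin)
  # per-frame mean within the Poisson CI of the background level
  se <- sqrt(bg / length(v$channels$tubulin))
  expect_lt(abs(m - bg), 5 * se)
  v0 <- render_volume(tr, seed = 1, frames = 1L, noise_model = "none")
  expect_true(all(v0$channels$tubulin == bg))
  expect_true(all(v0$channels$cnn == bg))
})

test_that("a contacting cell produces a column exactly at its position in the gap", {
  cfg <- scenario_config(
    n_cells_per_layer = 1L, roi_px = c(11L, 21L), grid_jitter = 0,
    foci_mean = 0,
    optics = list(blur_sigma_um = 0, attenuation_alpha = 0,
                  compensation_beta = 0, noise_model = "none",
                  background = 0)
  )
  tr <- simulate_events(build_tissue(cfg, seed = 1), seed = 1)
  expect_true(all(state_at(tr, 0) == "CONTACT"))
  v <- render_volume(tr, seed = 1, frames = 1L)
  a <- v$channels$tubulin[1, , , ]
  # gap region well between the slabs
  gap_lo <- cfg$dorsal_z_um + cfg$layer_halfwidth_um + 2 * cfg$dz_um
  gap_hi <- min(ipanr:::ventral_surface_z(cfg, c(1, 21))) -
    cfg$layer_halfwidth_um - 2 * cfg$dz_um
  zs <- which((seq_len(cfg$z_slices) - 1) * cfg$dz_um >= gap_lo &
                (seq_len(cfg$z_slices) - 1) * cfg$dz_um <= gap_hi)
  gap <- a[zs, , ]
  nz_idx <- which(gap > 0, arr.ind = TRUE)
  expect_gt(nrow(nz_idx), 0)
  cell_px <- unique(cbind(round(tr$cells$y), round(tr$cells$x)))
  expect_true(all(paste(nz_idx[, 2], nz_idx[, 3]) %in%
                    paste(cell_px[, 1], cell_px[, 2])))
  # with aligned grids the dorsal and ventral cells sit at the same (y, x),
  # so their columns superpose
  expect_true(all(gap[nz_idx] %in%
                    (cfg$intensity$column * c(1, 2))))
})

test_that("full depth compensation equalises dorsal and ventral slab peaks", {
  cfg <- scenario_config(
    n_cells_per_layer = 4L, roi_px = c(10L, 20L),
    ventral_z_um_range = c(62, 62), foci_mean = 0,
    optics = list(blur_sigma_um = 0, attenuation_alpha = 0.01,
                  compensation_beta = 0.01, noise_model = "none",
                  background = 0)
  )
  tr <- simulate_events(build_tissue(cfg, seed = 2), seed = 2)
  v <- render_volume(tr, seed = 2, frames = 1L)
  prof <- z_profile(v)
  peaks <- find_layer_peaks(prof)
  expect_equal(peaks$i_d, peaks$i_v, tolerance = 1e-9)
  # without compensation the deeper ventral peak is dimmer
  cfg2 <- cfg; cfg2$optics$compensation_beta <- 0
  tr2 <- simulate_events(build_tissue(cfg2, seed = 2), seed = 2)
  v2 <- render_volume(tr2, seed = 2, frames = 1L)
  peaks2 <- find_layer_peaks(z_profile(v2))
  expect_lt(peaks2$i_v, peaks2$i_d)
})

test_that("rendering is bit-identical under the same seed, including noise", {
  cfg <- small_scenario(n_cells_per_layer = 10L)
  tr <- simulate_events(build_tissue(cfg, seed = 5), seed = 5)
  v1 <- render_volume(tr, seed = 5, frames = c(1L, 30L))
  v2 <- render_volume(tr, seed = 5, frames = c(1L, 30L))
  expect_identical(v1$channels, v2$channels)
  v3 <- render_volume(tr, seed = 6, frames = c(1L, 30L))
  expect_false(identical(v1$channels$tubulin, v3$channels$tubulin))
})

test_that("pre-noise interepithelial tubulin is non-increasing over a control run", {
  cfg <- small_scenario()
  tr <- simulate_events(build_tissue(cfg, seed = 9), seed = 9)
  v <- render_volume(tr, seed = 9, noise_model = "none")
  gap_lo <- cfg$dorsal_z_um + cfg$layer_halfwidth_um + 4.5
  gap_hi <- cfg$ventral_z_um_range[1] - cfg$layer_halfwidth_um - 4.5
  zs <- which((seq_len(cfg$z_slices) - 1) * cfg$dz_um >= gap_lo &
                (seq_len(cfg$z_slices) - 1) * cfg$dz_um <= gap_hi)
  gap_sum <- vapply(seq_len(n_frames(v)), function(f) {
    sum(v$channels$tubulin[f, zs, , ])
  }, 0)
  expect_true(all(diff(gap_sum) <= 1e-6 * gap_sum[1]))
})

test_that("layer peaks are recovered within one slice on noise-free renders", {
  cfg <- small_scenario()
  tr <- simulate_events(build_tissue(cfg, seed = 10), seed = 10)
  v <- render_volume(tr, seed = 10, frames = c(1L, 24L, 48L),
                     noise_model = "none")
  peaks <- find_layer_peaks(z_profile(downsample_xy(v, 5, 10)))
  # detected peaks lie inside the rendered slabs (one slice of slack for
  # discretisation)
  tol <- cfg$layer_halfwidth_um + cfg$dz_um
  expect_true(all(abs((peaks$z_d - 1) * cfg$dz_um - cfg$dorsal_z_um) <= tol))
  vz_range <- range(ipanr:::ventral_surface_z(cfg, c(1, cfg$roi_px[2])))
  zv_um <- (peaks$z_v - 1) * cfg$dz_um
  expect_true(all(zv_um >= vz_range[1] - tol & zv_um <= vz_range[2] + tol))
})

test_that("every preset simulates and renders without error at smoke scale", {
  presets <- preset_scenarios(n_cells_per_layer = 20L, roi_px = c(30L, 60L))
  expect_named(presets, c("control", "hTau_both", "hTau_dorsal",
                          "kat60_dorsal", "patronin_both", "patronin_dorsal",
                          "shot_dorsal", "stg_dorsal", "polo_dorsal"))
  expect_equal(presets$control$perturbation_d, "control")
  expect_equal(presets$control$perturbation_v, "control")
  expect_equal(presets$control$rate_modifiers[["control"]], 1)
  # a one-layer preset differs from control only in that layer's perturbation
  expect_equal(presets$hTau_dorsal$perturbation_v, "control")
  expect_equal(presets$hTau_dorsal$perturbation_d, "hTau")
  for (nm in names(presets)) {
    tr <- simulate_events(build_tissue(presets[[nm]], seed = 1), seed = 1)
    v <- render_volume(tr, seed = 1, frames = 24L)
    expect_equal(dim(v$channels$tubulin), c(1, 85, 30, 60))
  }
})

test_that("the apical render keeps per-cell foci separated and masked", {
  cfg <- scenario_config(n_cells_per_layer = 12L, roi_px = c(40L, 80L))
  tr <- simulate_events(build_tissue(cfg, seed = 4), seed = 4)
  ap <- render_apical(tr, frame = 1)
  expect_equal(sort(unique(as.integer(ap$mask[ap$mask > 0]))),
               sort(ap$truth$cell_id))
  expect_equal(nrow(ap$truth), 12)
  # rendering is deterministic under the seed
  ap2 <- render_apical(tr, frame = 1)
  expect_identical(ap$volume$channels$tubulin, ap2$volume$channels$tubulin)
})
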