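test_that("block-mean downsampling preserves constants and the global mean", {
  arr <- array(3.7, dim = c(2, 4, 10, 20))
  v <- volume_series(list(tubulin = arr))
  ds <- downsample_xy(v, 5, 10)
  expect_true(all(abs(ds$channels$tubulin - 3.7) < 1e-12))
  set.seed(21)
  arr2 <- array(runif(2 * 4 * 10 * 20), dim = c(2, 4, 10, 20))
  v2 <- volume_series(list(tubulin = arr2))
  ds2 <- downsample_xy(v2, 5, 10)  # blocks tile 10x20 evenly
  expect_equal(mean(ds2$channels$tubulin), mean(arr2), tolerance = 1e-12)
})

test_that("downsampling a 4x4 frame of 1..16 to 2x2 gives the hand-computed block means", {
  arr <- array(0, dim = c(1, 1, 4, 4))
  arr[1, 1, , ] <- matrix(1:16, 4, 4, byrow = TRUE)
  v <- volume_series(list(tubulin = arr))
  ds <- downsample_xy(v, 2, 2)
  expect_equal(as.vector(t(ds$channels$tubulin[1, 1, , ])),
               c(3.5, 5.5, 11.5, 13.5))
})

test_that("downsampling folds remainder pixels into the last block (1025x510 case)", {
  # mean-preservation on the reference geometry, x and y swapped to our
  # (y, x) = (510, 1025) convention
  arr <- array(0, dim = c(1, 1, 510, 1025))
  arr[1, 1, , ] <- outer(seq_len(510), seq_len(1025), function(a, b) (a + b) %% 7)
  v <- volume_series(list(tubulin = arr))
  ds <- downsample_xy(v, 5, 10)
  expect_equal(dim(ds$channels$tubulin), c(1, 1, 5, 10))
  # last block along x spans columns 919..1025 (remainder folded in)
  expect_equal(ds$channels$tubulin[1, 1, 5, 10],
               mean(arr[1, 1, 409:510, 919:1025]))
  expect_error(downsample_xy(v, 511, 10), class = "ipan_config_error")
})

test_that("z-profile is the per-slice lateral mean", {
  v <- blank_volume(nt = 2, nz = 5, ny = 3, nx = 4, value = 1)
  p <- z_profile(v)
  expect_true(all(p$intensity == 1))
  # single bright voxel: V/(Y*X) in its slice, zero elsewhere
  arr <- array(0, dim = c(1, 6, 3, 4))
  arr[1, 4, 2, 3] <- 60
  v2 <- volume_series(list(tubulin = arr))
  p2 <- z_profile(v2)
  expect_equal(p2$intensity[p2$z == 4], 60 / 12)
  expect_true(all(p2$intensity[p2$z != 4] == 0))
})

test_that("z-profile is invariant to prior downsampling when blocks tile evenly", {
  set.seed(22)
  arr <- array(runif(2 * 6 * 10 * 20, 0, 9), dim = c(2, 6, 10, 20))
  v <- volume_series(list(tubulin = arr))
  p1 <- z_profile(v)
  p2 <- z_profile(downsample_xy(v, 5, 10))
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-12)
})

test_that("layer peaks follow the constrained dual-argmax rule", {
  p <- rep(0, 60)
  p[6] <- 100  # within the dorsal search range (first 30 slices)
  p[51] <- 80
  v <- volume_from_profile(p)
  peaks <- find_layer_peaks(z_profile(v))
  expect_equal(peaks$z_d, 6)
  expect_equal(peaks$i_d, 100)
  expect_equal(peaks$z_v, 51)
  expect_equal(peaks$i_v, 80)
})

test_that("ties break toward the lower (more apical) slice", {
  v <- volume_from_profile(rep(2, 60))
  peaks <- find_layer_peaks(z_profile(v))
  expect_equal(peaks$z_d, 1)
  expect_equal(peaks$z_v, 1 + 25)
})

test_that("peak search errors on too-short profiles and empty ventral ranges", {
  expect_error(find_layer_peaks(z_profile(volume_from_profile(rep(1, 20)))),
               class = "ipan_geometry_error")
  # dorsal peak so deep that z_d + h_expected exceeds the profile
  p <- rep(0, 40); p[30] <- 5
  expect_error(find_layer_peaks(z_profile(volume_from_profile(p))),
               class = "ipan_geometry_error")
})

test_that("peak finder matches an exhaustive oracle on random smooth profiles", {
  set.seed(23)
  for (i in 1:200) {
    base <- runif(1, 1, 5)
    p <- base + abs(stats::filter(rnorm(70, sd = 3), rep(1 / 7, 7),
                                  circular = TRUE))
    p <- as.numeric(p)
    i_d <- sample(1:30, 1); i_v <- sample(36:70, 1)
    p[i_d] <- p[i_d] + runif(1, 0, 50)
    p[i_v] <- p[i_v] + runif(1, 0, 50)
    got <- find_layer_peaks(z_profile(volume_from_profile(p)))
    want <- oracle_peaks(p)
    expect_equal(got$z_d, want$z_d)
    expect_equal(got$z_v, want$z_v)
    expect_equal(got$i_d, want$i_d)
    expect_equal(got$i_v, want$i_v)
  }
})

test_that("uniform profiles give ratio exactly 1; spike-only profiles give 0", {
  v <- volume_from_profile(rep(3, 60))
  rt <- ratio_timeseries(v)
  expect_identical(rt$ratio, 1)
  p <- rep(0, 60); p[6] <- 100; p[51] <- 80
  rt0 <- ratio_timeseries(volume_from_profile(p))
  expect_identical(rt0$ratio, 0)
})

test_that("the documented hand-computed fixture gives ratio 0.25", {
  p <- rep(0, 60)
  p[6] <- 100
  p[51] <- 60
  p[16:41] <- 20  # inclusive window [z_d + 10, z_v - 10]
  rt <- ratio_timeseries(volume_from_profile(p))
  expect_equal(rt$ratio, 0.25, tolerance = 1e-12)
  expect_equal(rt$i_int, 20, tolerance = 1e-12)
})

test_that("the interepithelial window is inclusive at both endpoints", {
  p <- rep(0, 60)
  p[6] <- 100; p[51] <- 100
  p[16] <- 26; p[41] <- 26  # only the endpoints of [16, 41] are nonzero
  rt <- ratio_timeseries(volume_from_profile(p))
  expect_equal(rt$i_int, 2 * 26 / 26, tolerance = 1e-12)
})

test_that("degenerate ratio inputs raise typed errors", {
  # empty window: with z_v = z_d + 25 a margin of 15 makes
  # [z_d + 15, z_v - 15] empty
  p <- rep(0, 40); p[1] <- 10; p[26] <- 9
  profiles <- z_profile(volume_from_profile(p))
  peaks <- find_layer_peaks(profiles)
  expect_error(interepithelial_ratio(profiles, peaks, ratio_params(margin = 15)),
               class = "ipan_geometry_error")
  # all-zero profile: i_d + i_v = 0
  profiles0 <- z_profile(volume_from_profile(rep(0, 60)))
  peaks0 <- find_layer_peaks(profiles0)
  expect_error(interepithelial_ratio(profiles0, peaks0),
               class = "ipan_ratio_error")
})

test_that("the full pipeline equals a straight-line reimplementation on random volumes", {
  set.seed(24)
  for (i in 1:10) {
    arr <- array(runif(2 * 60 * 10 * 20, 0, 50), dim = c(2, 60, 10, 20))
    # add layer-like structure so peaks are well defined
    arr[, 8:12, , ] <- arr[, 8:12, , ] + 100
    arr[, 48:55, , ] <- arr[, 48:55, , ] + 80
    v <- volume_series(list(tubulin = arr))
    got <- ratio_timeseries(v)$ratio
    want <- oracle_ratio_series(arr)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a static volume repeated over frames gives a constant series", {
  p <- rep(0, 60); p[10] <- 50; p[50] <- 40; p[25:35] <- 10
  v <- volume_from_profile(p, n_frames = 48)
  rt <- ratio_timeseries(v)
  expect_equal(nrow(rt), 48)
  expect_true(all(abs(rt$ratio - rt$ratio[1]) < 1e-12))
})

test_that("the ratio is scale invariant but not shift invariant", {
  set.seed(25)
  p <- c(runif(9, 0, 5), 80, runif(35, 0, 5), 60, runif(14, 0, 5))
  v1 <- volume_from_profile(p)
  v2 <- volume_from_profile(p * 7.3)
  v3 <- volume_from_profile(p + 5)
  r1 <- ratio_timeseries(v1)$ratio
  expect_equal(ratio_timeseries(v2)$ratio, r1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ratio_timeseries(v3)$ratio, r1)))
})

test_that("uint8 quantization is a no-op on 8-bit integer data and truncates otherwise", {
  set.seed(26)
  p_int <- c(sample(0:255, 9, TRUE), 250, sample(0:255, 35, TRUE), 240,
             sample(0:255, 15, TRUE))
  p_int[10] <- 255; p_int[45] <- 254  # force clean peaks
  v <- volume_from_profile(p_int)
  r_off <- ratio_timeseries(v, ratio_params(quantize_uint8 = FALSE))
  r_on <- ratio_timeseries(v, ratio_params(quantize_uint8 = TRUE))
  expect_equal(r_on$ratio, r_off$ratio, tolerance = 1e-12)
  # fractional data is floored before profiling when quantization is on
  p_frac <- p_int + 0.6
  r_frac <- ratio_timeseries(volume_from_profile(p_frac),
                             ratio_params(quantize_uint8 = TRUE))
  expect_equal(r_frac$ratio, r_off$ratio, tolerance = 1e-12)
})

test_that("micrometre-denominated margins convert with half-up rounding", {
  expect_equal(ratio_params(margin_um = 10.4093)$margin, 10)
  expect_equal(ratio_params(margin_um = 11)$margin, 11)
  expect_equal(ratio_params(margin_um = 5.2)$margin, 5)
})
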