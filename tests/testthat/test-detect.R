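make_foci_volume <- function(points, amp = 100, nz = 60, ny = 25, nx = 25,
                             bar = NULL, bar_amp = 120) {
  cnn <- array(0, dim = c(1, nz, ny, nx))
  tub <- array(0, dim = c(1, nz, ny, nx))
  for (i in seq_len(nrow(points))) {
    cnn[1, points[i, 1], points[i, 2], points[i, 3]] <- amp
  }
  if (!is.null(bar)) {
    for (i in seq_len(nrow(bar))) {
      tub[1, bar[i, 1], bar[i, 2], bar[i, 3]] <- bar_amp
    }
  }
  volume_series(list(tubulin = tub, cnn = cnn))
}

test_that("noise-free foci are each recovered within one voxel", {
  pts <- rbind(c(10, 5, 5), c(10, 5, 20), c(30, 12, 12), c(50, 20, 5),
               c(50, 20, 20))
  v <- make_foci_volume(pts)
  det <- detect_cnn_foci(v, 1)
  expect_equal(nrow(det), nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((det$z - pts[i, 1])^2 + (det$y - pts[i, 2])^2 +
                (det$x - pts[i, 3])^2)
    expect_lte(min(d), 1)
  }
})

test_that("a pure-background frame yields no detections at the default threshold", {
  arr <- withr::with_seed(31, array(rpois(60 * 25 * 25, 5),
                                    dim = c(1, 60, 25, 25)))
  v <- volume_series(list(tubulin = arr, cnn = arr))
  det <- detect_cnn_foci(v, 1)
  expect_equal(nrow(det), 0)
})

test_that("detections are invariant to global intensity rescaling", {
  pts <- rbind(c(20, 8, 8), c(40, 18, 18))
  v1 <- make_foci_volume(pts, amp = 60)
  v2 <- make_foci_volume(pts, amp = 120)
  d1 <- detect_cnn_foci(v1, 1)
  d2 <- detect_cnn_foci(v2, 1)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1[, c("z", "y", "x")], d2[, c("z", "y", "x")],
               tolerance = 1)
})

test_that("two foci with a bright tubulin bar between them form one candidate", {
  # foci 4 um apart (4 px laterally at 1 um/px), spindle bar between
  bar <- cbind(30, 12, 9:13)
  pts <- rbind(c(30, 12, 9), c(30, 12, 13))
  v <- make_foci_volume(pts, bar = bar)
  foci <- detect_cnn_foci(v, 1)
  cand <- pair_and_confirm(foci, v, 1)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$y, 12, tolerance = 0.6)
  expect_equal(cand$x, 11, tolerance = 0.6)
  expect_equal(cand$sep_um, 4, tolerance = 0.8)
})

test_that("an isolated focus or an over-separated pair yields no candidate", {
  v1 <- make_foci_volume(rbind(c(30, 12, 12)))
  f1 <- detect_cnn_foci(v1, 1)
  expect_equal(nrow(pair_and_confirm(f1, v1, 1)), 0)
  v2 <- make_foci_volume(rbind(c(30, 12, 3), c(30, 12, 23)))  # 20 um apart
  f2 <- detect_cnn_foci(v2, 1)
  expect_equal(nrow(f2), 2)
  expect_equal(nrow(pair_and_confirm(f2, v2, 1)), 0)
})

test_that("spindle confirmation rejects focus pairs without a tubulin bar", {
  pts <- rbind(c(30, 12, 9), c(30, 12, 13))
  v <- make_foci_volume(pts, bar = NULL)
  foci <- detect_cnn_foci(v, 1)
  expect_equal(nrow(pair_and_confirm(foci, v, 1, confirm = TRUE)), 0)
  expect_equal(nrow(pair_and_confirm(foci, v, 1, confirm = FALSE)), 1)
})

test_that("layer assignment places candidates in slabs and drops the rest", {
  peaks_frame <- tibble::tibble(frame = 1L, z_d = 11, i_d = 60,
                                z_v = 61, i_v = 50)
  dz <- 1.0409333
  cand <- tibble::tibble(z_um = c((11 - 1) * dz, 35, (61 - 1) * dz + 3))
  out <- assign_layer(cand, peaks_frame, dz)
  expect_equal(out$layer, c("dorsal", NA, "ventral"))
})

test_that("one cell mitotic across five frames is a single event", {
  cand <- tibble::tibble(
    frame = 10:14, z_um = 10.4, y = 5 + runif(5, -0.2, 0.2),
    x = 7 + runif(5, -0.2, 0.2), layer = "dorsal"
  )
  v <- blank_volume(nt = 20)
  ev <- cumulate_events(cand, v)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 10)
})

test_that("simultaneous distant candidates stay separate events", {
  cand <- tibble::tibble(
    frame = c(10L, 10L, 11L, 11L), z_um = 10.4,
    y = c(5, 25, 5, 25), x = c(5, 25, 5, 25), layer = "dorsal"
  )
  ev <- cumulate_events(cand, blank_volume(nt = 20))
  expect_equal(nrow(ev), 2)
})

test_that("short-lived candidates are pruned unless right-censored", {
  v <- blank_volume(nt = 20)
  one_frame <- tibble::tibble(frame = 10L, z_um = 10.4, y = 5, x = 5,
                              layer = "dorsal")
  expect_equal(nrow(cumulate_events(one_frame, v)), 0)
  last_frame <- tibble::tibble(frame = 20L, z_um = 10.4, y = 5, x = 5,
                               layer = "dorsal")
  expect_equal(nrow(cumulate_events(last_frame, v)), 1)
})

test_that("detection recovers ground truth exactly on noise-free renders", {
  cfg <- small_scenario()
  tr <- simulate_events(build_tissue(cfg, seed = 2), seed = 2)
  v <- render_volume(tr, seed = 2, noise_model = "none")
  det <- detect_mitoses(v)
  m <- match_events(det, tr$events, v)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$layer_agreement, 1)
  cc <- cumulative_counts(det)
  cc_true <- cumulative_counts(tr$events)
  expect_true(all(abs(cc$dorsal - cc_true$dorsal) <= 1))
  expect_true(all(diff(cc$dorsal) >= 0) && all(diff(cc$ventral) >= 0))
  # determinism of the full detector
  det2 <- detect_mitoses(v)
  expect_identical(det, det2)
})

test_that("apical focus counting recovers rendered counts per cell", {
  cfg <- scenario_config(n_cells_per_layer = 15L, roi_px = c(40L, 80L))
  tr <- simulate_events(build_tissue(cfg, seed = 6), seed = 6)
  ap <- render_apical(tr, frame = 1)
  det <- detect_apical_foci(ap$volume, frame = 1, cell_mask = ap$mask)
  joined <- merge(det, ap$truth, by = "cell_id")
  expect_equal(nrow(joined), 15)
  expect_true(all(abs(joined$n_foci.x - joined$n_foci.y) <= 2))
  expect_equal(mean(joined$n_foci.x), mean(joined$n_foci.y), tolerance = 0.05)
})

test_that("apical counts with an empty mask are empty, and shapes must match", {
  cfg <- scenario_config(n_cells_per_layer = 5L, roi_px = c(30L, 60L))
  tr <- simulate_events(build_tissue(cfg, seed = 6), seed = 6)
  ap <- render_apical(tr, frame = 1)
  empty <- matrix(0L, nrow(ap$mask), ncol(ap$mask))
  det <- detect_apical_foci(ap$volume, frame = 1, cell_mask = empty)
  expect_equal(nrow(det), 0)
  expect_error(
    detect_apical_foci(ap$volume, frame = 1, cell_mask = empty[-1, ]),
    class = "ipan_format_error"
  )
})

test_that("mean apical counts are non-increasing over a control time course", {
  cfg <- scenario_config(n_cells_per_layer = 12L, roi_px = c(40L, 80L))
  tr <- simulate_events(build_tissue(cfg, seed = 7), seed = 7)
  means <- vapply(c(1L, 24L, 40L, 48L), function(f) {
    ap <- render_apical(tr, frame = f)
    det <- detect_apical_foci(ap$volume, frame = 1, cell_mask = ap$mask)
    mean(det$n_foci)
  }, 0)
  expect_true(all(diff(means) <= 0.5))
  expect_lt(means[4], means[1])
})
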