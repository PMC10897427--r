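# Shared fixtures, built in code at test time.

# A small, fast scenario that keeps the full default geometry (layer depths,
# slant, z sampling, 48-frame schedule) but fewer cells in a smaller ROI.
small_scenario <- function(name = "control", n_cells_per_layer = 30L,
                           roi_px = c(40L, 80L), ...) {
  scenario_config(name = name, n_cells_per_layer = n_cells_per_layer,
                  roi_px = roi_px, ...)
}

# Volume whose z-profile equals a given per-slice vector (constant laterally),
# replicated over n_frames.
volume_from_profile <- function(profile, n_frames = 1L, ny = 10L, nx = 20L,
                                dz_um = 1.0409333) {
  nz <- length(profile)
  arr <- array(0, dim = c(n_frames, nz, ny, nx))
  for (t in seq_len(n_frames)) {
    for (k in seq_len(nz)) arr[t, k, , ] <- profile[k]
  }
  volume_series(list(tubulin = arr), dz_um = dz_um)
}

# Two-channel volume of given dims filled with constants.
blank_volume <- function(nt = 1L, nz = 60L, ny = 20L, nx = 30L, value = 0) {
  arr <- array(value, dim = c(nt, nz, ny, nx))
  volume_series(list(tubulin = arr, cnn = arr))
}

# Brute-force reference for the dual-peak search on one profile vector:
# exhaustive scan over all admissible (z_d, z_v), first maximum wins.
oracle_peaks <- function(p, dallow = 10L, h_expected = 25L) {
  best_d <- 1L
  for (k in seq_len(min(3L * dallow, length(p)))) {
    if (p[k] > p[best_d]) best_d <- k
  }
  best_v <- best_d + h_expected
  for (k in (best_d + h_expected):length(p)) {
    if (p[k] > p[best_v]) best_v <- k
  }
  list(z_d = best_d, i_d = p[best_d], z_v = best_v, i_v = p[best_v])
}

# Straight-line reference implementation of the whole ratio statistic on a
# raw array (t, z, y, x): explicit loops, no shared code with the package.
oracle_ratio_series <- function(arr, dallow = 10L, h_expected = 25L,
                                margin = 10L, y_blocks = 5L, x_blocks = 10L) {
  d <- dim(arr)
  bounds <- function(n, b) {
    size <- n %/% b
    starts <- (seq_len(b) - 1L) * size + 1L
    ends <- starts + size - 1L
    ends[b] <- n
    cbind(starts, ends)
  }
  by <- bounds(d[3], y_blocks); bx <- bounds(d[4], x_blocks)
  out <- numeric(d[1])
  for (t in seq_len(d[1])) {
    ds <- matrix(0, d[2], y_blocks * x_blocks)
    col <- 0L
    for (i in seq_len(y_blocks)) for (j in seq_len(x_blocks)) {
      col <- col + 1L
      for (k in seq_len(d[2])) {
        ds[k, col] <- mean(arr[t, k, by[i, 1]:by[i, 2], bx[j, 1]:bx[j, 2]])
      }
    }
    prof <- rowMeans(ds)
    pk <- oracle_peaks(prof, dallow, h_expected)
    w <- (pk$z_d + margin):(pk$z_v - margin)
    out[t] <- 2 * mean(prof[w]) / (pk$i_d + pk$i_v)
  }
  out
}
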