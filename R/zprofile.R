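#' Parameters of the interepithelial ratio statistic
#'
#' Controls the dual-peak layer search and the interepithelial averaging
#' window, all in z-slice units (one slice = `dz_um`, 1.0409333 um by
#' default).
#'
#' * `dallow` - half z-height of the dorsal layer; the dorsal peak is the
#'   brightest slice among the first `3 * dallow` slices.
#' * `h_expected` - half of the approximate dorsal-ventral gap; the ventral
#'   peak is searched from `h_expected` slices below the dorsal peak.
#' * `margin` - slices excluded below the dorsal and above the ventral peak;
#'   the interepithelial window is `[z_d + margin, z_v - margin]`, both
#'   endpoints inclusive.
#' * `margin_um` - optional micrometre-denominated margin; converted to
#'   slices by `dz_um` with half-up rounding and overriding `margin`.
#' * `downsample_to` - `(y_blocks, x_blocks)` lateral block-mean reduction
#'   applied before profiling (the full-resolution statistic is identical
#'   when blocks tile the image evenly).
#' * `quantize_uint8` - compatibility switch truncating intensities to
#'   unsigned 8-bit before profiling. Off by default: quantization is an
#'   implementation detail of legacy workflows, not part of the statistic.
#'   On integer inputs within 0-255 the results are identical either way.
#'
#' @param dallow,h_expected,margin Integer slice counts (see above).
#' @param margin_um Optional margin in micrometres.
#' @param dz_um z-step used for unit conversions.
#' @param downsample_to Integer pair `(y_blocks, x_blocks)`.
#' @param quantize_uint8 Logical.
#' @return An object of class `ipan_ratio_params`.
#' @export
ratio_params <- function(dallow = 10L,
                         h_expected = 25L,
                         margin = 10L,
                         margin_um = NULL,
                         dz_um = 1.0409333,
                         downsample_to = c(5L, 10L),
                         quantize_uint8 = FALSE) {
  if (!is_scalar_number(dallow) || dallow < 1) {
    stop_config("`dallow` must be >= 1")
  }
  if (!is.null(margin_um)) {
    margin <- floor(margin_um / dz_um + 0.5)
  }
  structure(
    list(
      dallow = as.integer(dallow), h_expected = as.integer(h_expected),
      margin = as.integer(margin), dz_um = dz_um,
      downsample_to = as.integer(downsample_to),
      quantize_uint8 = isTRUE(quantize_uint8)
    ),
    class = "ipan_ratio_params"
  )
}

block_bounds <- function(n, blocks) {
  # Even partition; remainder pixels are folded into the final block.
  size <- n %/% blocks
  starts <- (seq_len(blocks) - 1L) * size + 1L
  ends <- starts + size - 1L
  ends[blocks] <- n
  list(starts = starts, ends = ends)
}

#' Lateral block-mean downsampling
#'
#' Reduces the (y, x) extent of every z-slice to `y_blocks` by `x_blocks`
#' pixels, each output pixel being the mean of its block. Blocks partition
#' the image as evenly as possible; remainder pixels are folded into the
#' last block along each axis. z and t are untouched, and the global mean is
#' preserved exactly when blocks tile the image evenly.
#'
#' @param v An [volume_series()].
#' @param y_blocks,x_blocks Output extents.
#' @return A downsampled `ipan_volume` (lateral pixel size rescaled).
#' @export
downsample_xy <- function(v, y_blocks = 5L, x_blocks = 10L) {
  d <- dim(v$channels[[1]])
  ny <- d[3]; nx <- d[4]
  if (y_blocks > ny || x_blocks > nx) {
    stop_config("block count exceeds the lateral extent of the volume")
  }
  by <- block_bounds(ny, y_blocks)
  bx <- block_bounds(nx, x_blocks)
  channels <- lapply(v$channels, function(arr) {
    out <- array(0, dim = c(d[1], d[2], y_blocks, x_blocks))
    for (i in seq_len(y_blocks)) {
      for (j in seq_len(x_blocks)) {
        blk <- arr[, , by$starts[i]:by$ends[i], bx$starts[j]:bx$ends[j],
                   drop = FALSE]
        out[, , i, j] <- apply(blk, c(1, 2), mean)
      }
    }
    out
  })
  volume_series(
    channels,
    dz_um = v$dz_um,
    dy_um = v$dy_um * ny / y_blocks, dx_um = v$dx_um * nx / x_blocks,
    dt_min = v$dt_min, t0_label = v$t0_label
  )
}

#' z-profile of mean intensity
#'
#' For each frame, averages every z-slice over (y, x), yielding the
#' intensity-vs-depth profile used for layer-peak detection.
#'
#' @param v An [volume_series()].
#' @param channel Channel to profile (default `"tubulin"`).
#' @return A tibble with columns `frame`, `z` (slice index, 1-based apical
#'   to basal) and `intensity`.
#' @export
z_profile <- function(v, channel = "tubulin") {
  arr <- get_channel(v, channel)
  d <- dim(arr)
  prof <- apply(arr, c(1, 2), mean)  # t x z
  tibble(
    frame = rep(seq_len(d[1]), times = d[2]),
    z = rep(seq_len(d[2]), each = d[1]),
    intensity = as.vector(prof)
  ) |>
    arrange(.data$frame, .data$z)
}

profile_matrix <- function(profiles) {
  nt <- max(profiles$frame)
  nz <- max(profiles$z)
  m <- matrix(NA_real_, nt, nz)
  m[cbind(profiles$frame, profiles$z)] <- profiles$intensity
  m
}

#' Locate the dorsal and ventral layer peaks in a z-profile
#'
#' The dorsal peak `z_d` is the brightest slice among slices
#' `1..3*dallow`; the ventral peak `z_v` is the brightest slice at or below
#' `z_d + h_expected`. Ties are broken toward the lower (more apical) slice.
#' `i_d` and `i_v` are the profile values at those slices.
#'
#' @param profiles A z-profile tibble from [z_profile()].
#' @param params An [ratio_params()] object.
#' @return A tibble with one row per frame: `frame`, `z_d`, `i_d`, `z_v`,
#'   `i_v`.
#' @export
find_layer_peaks <- function(profiles, params = ratio_params()) {
  m <- profile_matrix(profiles)
  nz <- ncol(m)
  if (nz < 3L * params$dallow) {
    stop_geometry(sprintf(
      "profile has %d slices; dorsal search needs at least 3*dallow = %d",
      nz, 3L * params$dallow
    ))
  }
  out <- lapply(seq_len(nrow(m)), function(ti) {
    p <- m[ti, ]
    z_d <- which.max(p[seq_len(3L * params$dallow)])
    v_start <- z_d + params$h_expected
    if (v_start > nz) {
      stop_geometry(sprintf(
        "frame %d: ventral search region [%d, %d] is empty", ti, v_start, nz
      ))
    }
    z_v <- v_start - 1L + which.max(p[v_start:nz])
    tibble(frame = ti, z_d = z_d, i_d = p[z_d], z_v = z_v, i_v = p[z_v])
  })
  bind_rows(out)
}

#' Interepithelial intensity ratio
#'
#' Computes, per frame, the mean interepithelial intensity `i_int` over the
#' inclusive slice window `[z_d + margin, z_v - margin]` and the ratio
#' `r = 2 * i_int / (i_d + i_v)` of the interepithelial level to the average
#' of the two layer-peak levels. The ratio is invariant to rescaling all
#' intensities by a positive constant (but not to adding a constant offset).
#'
#' @param profiles A z-profile tibble from [z_profile()].
#' @param peaks Output of [find_layer_peaks()] for the same profiles.
#' @param params An [ratio_params()] object.
#' @return `peaks` with added columns `i_int` and `ratio`.
#' @export
interepithelial_ratio <- function(profiles, peaks, params = ratio_params()) {
  m <- profile_matrix(profiles)
  res <- lapply(seq_len(nrow(peaks)), function(k) {
    z_d <- peaks$z_d[k]; z_v <- peaks$z_v[k]
    lo <- z_d + params$margin
    hi <- z_v - params$margin
    if (lo > hi) {
      stop_geometry(sprintf(
        "frame %d: interepithelial window [%d, %d] is empty", peaks$frame[k],
        lo, hi
      ))
    }
    i_int <- mean(m[peaks$frame[k], lo:hi])
    denom <- peaks$i_d[k] + peaks$i_v[k]
    if (denom == 0) {
      abort(sprintf("frame %d: i_d + i_v = 0, ratio undefined", peaks$frame[k]),
            class = "ipan_ratio_error")
    }
    c(i_int = i_int, ratio = 2 * i_int / denom)
  })
  res <- do.call(rbind, res)
  peaks$i_int <- unname(res[, "i_int"])
  peaks$ratio <- unname(res[, "ratio"])
  peaks
}

quantize_volume_uint8 <- function(v) {
  channels <- lapply(v$channels, function(arr) {
    arr <- floor(arr)
    arr[arr > 255] <- 255
    arr
  })
  volume_series(channels, dz_um = v$dz_um, dy_um = v$dy_um, dx_um = v$dx_um,
                dt_min = v$dt_min, t0_label = v$t0_label)
}

#' Interepithelial MT ratio time series
#'
#' Full quantification pipeline for one volume: (optional uint8
#' quantization) -> lateral block-mean downsampling -> z-profile -> dual-peak
#' layer detection -> interepithelial ratio, per frame. `total` is the sum
#' of the z-profile over slices (the total-intensity trace).
#'
#' @param v An [volume_series()].
#' @param params An [ratio_params()] object.
#' @param channel Channel to quantify (default `"tubulin"`).
#' @return A tibble with one row per frame and columns `frame`, `t_min`,
#'   `ratio`, `total`, `i_d`, `i_v`, `i_int`, `z_d`, `z_v`.
#' @export
ratio_timeseries <- function(v, params = ratio_params(), channel = "tubulin") {
  if (params$quantize_uint8) v <- quantize_volume_uint8(v)
  ds <- downsample_xy(v, params$downsample_to[1], params$downsample_to[2])
  profiles <- z_profile(ds, channel = channel)
  peaks <- find_layer_peaks(profiles, params)
  peaks <- interepithelial_ratio(profiles, peaks, params)
  totals <- profiles |>
    group_by(.data$frame) |>
    summarise(total = sum(.data$intensity), .groups = "drop")
  peaks |>
    left_join(totals, by = "frame") |>
    mutate(t_min = (.data$frame - 1) * v$dt_min) |>
    select("frame", "t_min", "ratio", "total", "i_d", "i_v", "i_int",
           "z_d", "z_v")
}

#' Least-squares slope of the ratio trace
#'
#' Convenience summary: the slope (per frame) of a straight-line fit to the
#' interepithelial ratio versus frame number.
#'
#' @param ratios Output of [ratio_timeseries()].
#' @return A single number.
#' @export
ratio_slope <- function(ratios) {
  if (nrow(ratios) < 2) return(NA_real_)
  unname(coef(lm(ratio ~ frame, data = ratios))[2])
}
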