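# Automated mitosis detection: pericentriolar-material (cnn) focus
# detection, pairing with spindle confirmation, layer assignment and
# cumulative event linking.

# Local maxima of a 3D array (26-neighbourhood), strict in the forward
# directions so plateaus yield a single (lowest-index) maximum.
local_maxima_3d <- function(a) {
  d <- dim(a)
  if (any(d < 1)) return(matrix(integer(0), 0, 3))
  pad <- array(-Inf, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  is_max <- array(TRUE, dim = d)
  for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
    if (oz == 0 && oy == 0 && ox == 0) next
    shifted <- pad[(2 + oz):(d[1] + 1 + oz),
                   (2 + oy):(d[2] + 1 + oy),
                   (2 + ox):(d[3] + 1 + ox), drop = FALSE]
    strict <- oz > 0 || (oz == 0 && (oy > 0 || (oy == 0 && ox > 0)))
    is_max <- is_max & (if (strict) a > shifted else a >= shifted)
  }
  which(is_max, arr.ind = TRUE)
}

#' Detect pericentriolar-material foci in one frame
#'
#' Multi-scale blob detection (Laplacian-of-Gaussian style scale-space
#' search) on the cnn channel of one frame: the volume is smoothed at each
#' detection scale, local maxima are collected per scale and merged across
#' scales keeping the strongest response within one voxel. The threshold is
#' specified relative to robust background statistics of the smoothed
#' volume (median + `threshold_k` * MAD), so rescaled volumes behave
#' identically; in noise-free volumes (zero MAD) the fallback threshold is
#' the background median plus a fixed fraction of the peak excursion.
#' Returns sub-voxel centroids refined by a background-subtracted local
#' intensity-weighted mean.
#'
#' @param v An [volume_series()].
#' @param frame Frame index.
#' @param channel Channel holding the foci (default `"cnn"`).
#' @param sigmas_um Detection scales (um).
#' @param threshold_k Robust threshold factor.
#' @return A tibble with columns `z`, `y`, `x` (sub-voxel, 1-based),
#'   `z_um`, and `response`.
#' @export
detect_cnn_foci <- function(v, frame, channel = "cnn",
                            sigmas_um = c(0.8, 1.2), threshold_k = 6) {
  arr <- get_channel(v, channel)
  a <- array(arr[frame, , , ], dim = dim(arr)[2:4])
  d0 <- dim(a)
  found <- list()
  for (s_um in sigmas_um) {
    sigma_vox <- s_um / c(v$dz_um, v$dy_um, v$dx_um)
    r <- gaussian_blur_3d(a, sigma_vox)
    bg <- median(r)
    spread <- mad(r)
    # Border voxels see fewer kernel taps (renormalised kernel), so smoothed
    # noise has a higher variance there; scale the threshold excursion by
    # the local-to-interior ratio of the kernel's sum of squared weights.
    w2 <- lapply(1:3, function(ax) {
      rowSums(gaussian_kernel_matrix(d0[ax], sigma_vox[ax])^2)
    })
    w2map <- outer(outer(w2[[1]], w2[[2]]), w2[[3]])
    dim(w2map) <- d0
    s0 <- prod(vapply(w2, min, 0))
    scale_map <- sqrt(w2map / s0)
    if (max(r) <= bg) next
    mx <- local_maxima_3d(r)
    keep <- if (spread > 0) {
      r[mx] > bg + threshold_k * spread * scale_map[mx]
    } else {
      r[mx] > bg + 0.1 * (max(r) - bg)
    }
    mx <- mx[keep, , drop = FALSE]
    if (nrow(mx) == 0) next
    # sub-voxel refinement: background-subtracted intensity-weighted
    # centroid over the 3^3 neighbourhood
    d <- dim(r)
    ref <- t(apply(mx, 1, function(p) {
      zr <- max(1, p[1] - 1):min(d[1], p[1] + 1)
      yr <- max(1, p[2] - 1):min(d[2], p[2] + 1)
      xr <- max(1, p[3] - 1):min(d[3], p[3] + 1)
      w <- r[zr, yr, xr, drop = FALSE]
      w <- pmax(w - min(w), 0)
      tw <- sum(w)
      if (tw == 0) return(as.numeric(p))
      c(sum(slice.index(w, 1) * w) / tw + zr[1] - 1,
        sum(slice.index(w, 2) * w) / tw + yr[1] - 1,
        sum(slice.index(w, 3) * w) / tw + xr[1] - 1)
    }))
    found[[length(found) + 1]] <- tibble(
      z = ref[, 1], y = ref[, 2], x = ref[, 3],
      response = r[mx] - bg, sigma_um = s_um
    )
  }
  if (length(found) == 0) {
    return(tibble(z = numeric(), y = numeric(), x = numeric(),
                  z_um = numeric(), response = numeric()))
  }
  pts <- bind_rows(found) |> arrange(dplyr::desc(.data$response))
  # merge across scales: keep the strongest detection within one voxel
  kept <- pts[0, ]
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (nrow(kept) == 0 ||
        min((kept$z - p$z)^2 + (kept$y - p$y)^2 + (kept$x - p$x)^2) > 1.5^2) {
      kept <- bind_rows(kept, p)
    }
  }
  kept |>
    mutate(z_um = (.data$z - 1) * v$dz_um) |>
    select("z", "y", "x", "z_um", "response")
}

#' Pair foci and confirm mitotic candidates
#'
#' Pairs detected foci by greedy closest-first matching within `d_max_um`
#' (about one spindle length; a mitotic cell shows exactly two
#' pericentriolar foci at the spindle poles). When `confirm` is on, a pair
#' is kept only if the mean tubulin intensity along the inter-focus segment
#' exceeds `confirm_factor` times the local background (median intensity of
#' a surrounding box), i.e. a spindle bar is present. The candidate
#' centroid is the pair midpoint.
#'
#' @param foci Output of [detect_cnn_foci()].
#' @param v The volume (for the tubulin channel).
#' @param frame Frame index.
#' @param d_max_um Maximum focus-pair separation (um).
#' @param confirm Require spindle confirmation (default TRUE).
#' @param confirm_factor Spindle-to-background intensity factor.
#' @param tubulin_channel Channel name for confirmation.
#' @return Tibble of candidates: `z`, `y`, `x` (voxel coords of midpoint),
#'   `z_um`, `sep_um`, `confirmed`.
#' @export
pair_and_confirm <- function(foci, v, frame, d_max_um = 6, confirm = TRUE,
                             confirm_factor = 2, tubulin_channel = "tubulin") {
  empty <- tibble(z = numeric(), y = numeric(), x = numeric(),
                  z_um = numeric(), sep_um = numeric(), confirmed = logical())
  if (nrow(foci) < 2) return(empty)
  sc <- c(v$dz_um, v$dy_um, v$dx_um)
  pos <- as.matrix(foci[, c("z", "y", "x")])
  pos_um <- sweep(pos, 2, sc, "*")
  dmat <- as.matrix(stats::dist(pos_um))
  diag(dmat) <- Inf
  cand_pairs <- which(upper.tri(dmat) & dmat <= d_max_um, arr.ind = TRUE)
  if (nrow(cand_pairs) == 0) return(empty)
  ord <- order(dmat[cand_pairs])
  cand_pairs <- cand_pairs[ord, , drop = FALSE]

  tub <- get_channel(v, tubulin_channel)
  a <- array(tub[frame, , , ], dim = dim(tub)[2:4])
  d <- dim(a)

  used <- rep(FALSE, nrow(foci))
  out <- list()
  for (k in seq_len(nrow(cand_pairs))) {
    i <- cand_pairs[k, 1]; j <- cand_pairs[k, 2]
    if (used[i] || used[j]) next
    ok <- TRUE
    if (confirm) {
      s <- seq(0, 1, length.out = 9)
      seg <- outer(s, pos[i, ]) + outer(1 - s, pos[j, ])
      idx <- cbind(
        pmin(pmax(round(seg[, 1]), 1), d[1]),
        pmin(pmax(round(seg[, 2]), 1), d[2]),
        pmin(pmax(round(seg[, 3]), 1), d[3])
      )
      seg_mean <- mean(a[idx])
      mid <- round((pos[i, ] + pos[j, ]) / 2)
      half_box <- pmax(1, round(5 / sc))
      zr <- max(1, mid[1] - half_box[1]):min(d[1], mid[1] + half_box[1])
      yr <- max(1, mid[2] - half_box[2]):min(d[2], mid[2] + half_box[2])
      xr <- max(1, mid[3] - half_box[3]):min(d[3], mid[3] + half_box[3])
      bg <- median(a[zr, yr, xr])
      ok <- seg_mean > confirm_factor * max(bg, 1e-12)
    }
    if (ok) {
      used[i] <- used[j] <- TRUE
      midp <- unname((pos[i, ] + pos[j, ]) / 2)
      out[[length(out) + 1]] <- tibble(
        z = midp[1], y = midp[2], x = midp[3],
        z_um = (midp[1] - 1) * v$dz_um,
        sep_um = unname(dmat[i, j]), confirmed = TRUE
      )
    }
  }
  if (length(out) == 0) empty else bind_rows(out)
}

#' Assign mitotic candidates to an epithelial layer
#'
#' A candidate is dorsal if its depth falls within the dorsal slab
#' (detected dorsal peak +/- `dorsal_halfwidth_um`, default 2.5, matching
#' the ~5 um optical slice in which dorsal mitoses appear), ventral if it
#' falls within the ventral slab (`ventral_window_um` around the detected
#' ventral peak; the default half-width of 6 um matches the 10-12 um
#' optical slice spanned by the slanted ventral layer). Candidates between
#' slabs are left unassigned (`NA`).
#'
#' @param candidates Tibble with a `z_um` column.
#' @param peaks_frame One row of [find_layer_peaks()] output for the frame.
#' @param dz_um z-step used to convert peak slice indices to depth.
#' @param dorsal_halfwidth_um Dorsal slab half-width (um).
#' @param ventral_window_um Ventral slab window, either a half-width or a
#'   `c(below, above)` pair of extents around the ventral peak (um).
#' @param ventral_band_um Optional explicit ventral depth band
#'   `c(lo, hi)` in um (e.g. from [ventral_band()]), overriding
#'   `ventral_window_um`.
#' @return `candidates` with a `layer` column added.
#' @export
assign_layer <- function(candidates, peaks_frame, dz_um,
                         dorsal_halfwidth_um = 2.5,
                         ventral_window_um = 6,
                         ventral_band_um = NULL) {
  zd_um <- (peaks_frame$z_d - 1) * dz_um
  zv_um <- (peaks_frame$z_v - 1) * dz_um
  if (is.null(ventral_band_um)) {
    if (length(ventral_window_um) == 1) {
      ventral_window_um <- c(ventral_window_um, ventral_window_um)
    }
    ventral_band_um <- c(zv_um - ventral_window_um[1],
                         zv_um + ventral_window_um[2])
  }
  candidates$layer <- dplyr::case_when(
    abs(candidates$z_um - zd_um) <= dorsal_halfwidth_um ~ "dorsal",
    candidates$z_um >= ventral_band_um[1] &
      candidates$z_um <= ventral_band_um[2] ~ "ventral",
    TRUE ~ NA_character_
  )
  candidates
}

#' Estimate the ventral layer depth band from a z-profile
#'
#' The ventral epithelium is slanted, so its mitoses span a thicker optical
#' band than the single ventral peak slice. The band is estimated per frame
#' as the contiguous region of the ventral search range (below
#' `z_d + h_expected`) where the profile is at least `frac` of the ventral
#' peak value, padded by `pad_um`.
#'
#' @param profiles A z-profile tibble from [z_profile()].
#' @param peaks Output of [find_layer_peaks()].
#' @param params An [ratio_params()] object.
#' @param dz_um z-step (um).
#' @param frac Fraction of the ventral peak defining the band.
#' @param pad_um Padding added on both sides (um).
#' @return A tibble with one row per frame: `frame`, `lo_um`, `hi_um`.
#' @export
ventral_band <- function(profiles, peaks, params = ratio_params(),
                         dz_um = 1.0409333, frac = 0.5, pad_um = 2.5) {
  m <- profile_matrix(profiles)
  out <- lapply(seq_len(nrow(peaks)), function(k) {
    p <- m[peaks$frame[k], ]
    vstart <- peaks$z_d[k] + params$h_expected
    idx <- vstart:length(p)
    el <- idx[p[idx] >= frac * peaks$i_v[k]]
    if (length(el) == 0) el <- peaks$z_v[k]
    tibble(
      frame = peaks$frame[k],
      lo_um = (min(el) - 1) * dz_um - pad_um,
      hi_um = (max(el) - 1) * dz_um + pad_um
    )
  })
  bind_rows(out)
}

#' Link per-frame candidates into one-shot mitotic events
#'
#' Candidates within `link_radius_um` of an existing event (in 3D) whose
#' latest detection is at most `max_gap_frames` frames old are merged into
#' it, so a cell mitotic across several frames is counted exactly once; a
#' new event is opened otherwise (mitotic figures are contiguous in time,
#' so a long gap at the same position is a new division of a neighbouring
#' cell, not the same event). Each event is carried
#' into every subsequent frame when counting, so per-layer cumulative
#' counts are monotone and the final-frame count is the total number of
#' mitoses. Events must be seen in at least `min_persist_frames` frames to
#' be kept, except events still visible in the last frame (persistence
#' beyond the acquisition cannot be observed).
#'
#' @param candidates Tibble of per-frame candidates with columns `frame`,
#'   `z_um`, `y`, `x`, `layer`.
#' @param v The volume (for lateral calibration and frame count).
#' @param link_radius_um Linking radius (um).
#' @param min_persist_frames Minimum persistence in frames.
#' @param max_gap_frames Maximum detection gap bridged when linking.
#' @return An event table: `event_id`, `frame`, `t_min`, `layer`, `z_um`,
#'   `y_px`, `x_px`, `cell_id` (NA).
#' @export
cumulate_events <- function(candidates, v, link_radius_um = 5,
                            min_persist_frames = 2L, max_gap_frames = 3L) {
  nf <- n_frames(v)
  ev <- list()  # each: pos (z_um, y_um, x_um), onset, last, n_seen, layers
  if (nrow(candidates) > 0) {
    candidates <- arrange(candidates, .data$frame)
    for (i in seq_len(nrow(candidates))) {
      p <- c(candidates$z_um[i], candidates$y[i] * v$dy_um,
             candidates$x[i] * v$dx_um)
      f <- candidates$frame[i]
      merged <- FALSE
      if (length(ev) > 0) {
        dists <- vapply(ev, function(e) sqrt(sum((e$pos - p)^2)), 0)
        recent <- vapply(ev, function(e) f - e$last <= max_gap_frames, TRUE)
        dists[!recent] <- Inf
        j <- which.min(dists)
        if (dists[j] <= link_radius_um) {
          ev[[j]]$last <- f
          ev[[j]]$n_seen <- ev[[j]]$n_seen + 1L
          ev[[j]]$layers <- c(ev[[j]]$layers, candidates$layer[i])
          merged <- TRUE
        }
      }
      if (!merged) {
        ev[[length(ev) + 1]] <- list(
          pos = p, onset = f, last = f, n_seen = 1L,
          layers = candidates$layer[i],
          y_px = candidates$y[i], x_px = candidates$x[i]
        )
      }
    }
  }
  keep <- vapply(ev, function(e) {
    e$n_seen >= min_persist_frames || e$last >= nf
  }, TRUE)
  ev <- ev[keep]
  if (length(ev) == 0) {
    return(tibble(
      event_id = integer(), frame = integer(), t_min = numeric(),
      layer = character(), z_um = numeric(), y_px = numeric(),
      x_px = numeric(), cell_id = integer()
    ))
  }
  tibble(
    frame = vapply(ev, function(e) as.integer(e$onset), 1L),
    layer = vapply(ev, function(e) {
      ly <- e$layers[!is.na(e$layers)]
      if (length(ly) == 0) NA_character_ else names(sort(table(ly),
                                                         decreasing = TRUE))[1]
    }, ""),
    z_um = vapply(ev, function(e) e$pos[1], 0),
    y_px = vapply(ev, function(e) e$y_px, 0),
    x_px = vapply(ev, function(e) e$x_px, 0)
  ) |>
    arrange(.data$frame, .data$y_px) |>
    mutate(
      event_id = row_number(),
      t_min = (.data$frame - 1) * v$dt_min,
      cell_id = NA_integer_
    ) |>
    select("event_id", "frame", "t_min", "layer", "z_um", "y_px", "x_px",
           "cell_id")
}

#' Detect mitotic events in a volume series
#'
#' Full detection pipeline: per frame, cnn focus detection, closest-first
#' pairing with spindle confirmation, layer assignment from the z-profile
#' layer peaks (the ventral band is estimated per frame with
#' [ventral_band()] to follow the slanted ventral layer), then cross-frame
#' linking into one-shot events. Candidates that cannot be assigned to a
#' layer are dropped.
#'
#' @param v An [volume_series()] with `tubulin` and `cnn` channels.
#' @param params An [ratio_params()] used for layer-peak detection.
#' @param sigmas_um,threshold_k See [detect_cnn_foci()].
#' @param d_max_um,confirm,confirm_factor See [pair_and_confirm()].
#' @param dorsal_halfwidth_um,ventral_window_um See [assign_layer()].
#' @param link_radius_um,min_persist_frames See [cumulate_events()].
#' @return An event table (see [cumulate_events()]).
#' @export
detect_mitoses <- function(v, params = ratio_params(),
                           sigmas_um = c(0.8, 1.2), threshold_k = 6,
                           d_max_um = 6, confirm = TRUE, confirm_factor = 2,
                           dorsal_halfwidth_um = 2.5, ventral_window_um = 6,
                           link_radius_um = 5, min_persist_frames = 2L,
                           max_gap_frames = 3L) {
  profiles <- z_profile(v, channel = "tubulin")
  peaks <- find_layer_peaks(profiles, params)
  vband <- ventral_band(profiles, peaks, params, dz_um = v$dz_um,
                        pad_um = dorsal_halfwidth_um)
  all_cand <- list()
  for (f in seq_len(n_frames(v))) {
    foci <- detect_cnn_foci(v, f, sigmas_um = sigmas_um,
                            threshold_k = threshold_k)
    cand <- pair_and_confirm(foci, v, f, d_max_um = d_max_um,
                             confirm = confirm,
                             confirm_factor = confirm_factor)
    if (nrow(cand) == 0) next
    cand <- assign_layer(cand, peaks[peaks$frame == f, ], v$dz_um,
                         dorsal_halfwidth_um = dorsal_halfwidth_um,
                         ventral_window_um = ventral_window_um,
                         ventral_band_um = c(vband$lo_um[f], vband$hi_um[f]))
    cand$frame <- f
    all_cand[[length(all_cand) + 1]] <- filter(cand, !is.na(.data$layer))
  }
  cand <- if (length(all_cand)) bind_rows(all_cand) else {
    tibble(frame = integer(), z_um = numeric(), y = numeric(), x = numeric(),
           layer = character())
  }
  cumulate_events(cand, v, link_radius_um = link_radius_um,
                  min_persist_frames = min_persist_frames,
                  max_gap_frames = max_gap_frames)
}

#' Count apical microtubule foci per cell
#'
#' 2D blob counting on the max-projected apical slab of the tubulin
#' channel, restricted to a supplied cell label mask (ground truth from the
#' generator, or external). Local maxima of the lightly smoothed projection
#' above a robust threshold are counted per label.
#'
#' @param v An [volume_series()] (typically from [render_apical()]).
#' @param frame Frame index.
#' @param cell_mask Integer matrix of cell labels matching the (y, x)
#'   geometry of `v`; 0 is background.
#' @param slices z slices of the apical slab (default: all slices of `v`).
#' @param channel Channel name.
#' @param smooth_sigma_px Gaussian sigma of the pre-smoothing (pixels).
#' @param threshold_k Robust threshold factor (median + k * MAD; fallback
#'   fraction-of-max in zero-background images).
#' @return Tibble with `cell_id` and `n_foci` for every non-zero label.
#' @export
detect_apical_foci <- function(v, frame = 1L, cell_mask, slices = NULL,
                               channel = "tubulin", smooth_sigma_px = 0.5,
                               threshold_k = 6) {
  arr <- get_channel(v, channel)
  d <- dim(arr)
  slices <- slices %||% seq_len(d[2])
  if (!all(dim(cell_mask) == d[3:4])) {
    stop_format("cell mask geometry does not match the volume")
  }
  slab <- array(arr[frame, slices, , ], dim = c(length(slices), d[3], d[4]))
  proj <- apply(slab, c(2, 3), max)
  if (smooth_sigma_px > 0) {
    a <- array(proj, dim = c(1, d[3], d[4]))
    proj <- gaussian_blur_3d(a, c(0, smooth_sigma_px, smooth_sigma_px))[1, , ]
  }
  theta <- if (mad(proj) > 0) {
    median(proj) + threshold_k * mad(proj)
  } else {
    median(proj) + 0.1 * (max(proj) - median(proj))
  }
  mx <- local_maxima_3d(array(proj, dim = c(1, d[3], d[4])))
  keep <- proj[mx[, 2:3, drop = FALSE]] > theta
  mx <- mx[keep, , drop = FALSE]
  labels <- sort(unique(as.integer(cell_mask[cell_mask > 0])))
  hit_labels <- cell_mask[mx[, 2:3, drop = FALSE]]
  counts <- table(factor(hit_labels[hit_labels > 0], levels = labels))
  tibble(cell_id = labels, n_foci = as.integer(counts))
}

#' Match detected events against ground truth
#'
#' Greedy closest-first matching of detected to true events within
#' `radius_um` (lateral distance) and `frame_tol` frames of onset. Reports
#' recall, precision, F1 and the layer agreement among matched events.
#'
#' @param detected,truth Event tables.
#' @param v The volume (for lateral calibration), or NULL with `dy_um`,
#'   `dx_um` given.
#' @param radius_um Match radius (um).
#' @param frame_tol Onset tolerance (frames).
#' @param dy_um,dx_um Calibration override.
#' @return One-row tibble: `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, `f1`, `layer_agreement`.
#' @export
match_events <- function(detected, truth, v = NULL, radius_um = 5,
                         frame_tol = 2L, dy_um = NULL, dx_um = NULL) {
  dy_um <- dy_um %||% v$dy_um
  dx_um <- dx_um %||% v$dx_um
  n_t <- nrow(truth); n_d <- nrow(detected)
  if (n_t == 0 || n_d == 0) {
    return(tibble(
      n_true = n_t, n_detected = n_d, n_matched = 0L,
      recall = ifelse(n_t == 0, NA_real_, 0),
      precision = ifelse(n_d == 0, NA_real_, 0),
      f1 = ifelse(n_t == 0 && n_d == 0, NA_real_, 0),
      layer_agreement = NA_real_
    ))
  }
  dmat <- outer(detected$y_px * dy_um, truth$y_px * dy_um, "-")^2 +
    outer(detected$x_px * dx_um, truth$x_px * dx_um, "-")^2
  dmat <- sqrt(dmat)
  fdiff <- abs(outer(detected$frame, truth$frame, "-"))
  dmat[fdiff > frame_tol] <- Inf
  dmat[dmat > radius_um] <- Inf
  used_d <- rep(FALSE, n_d); used_t <- rep(FALSE, n_t)
  matches <- 0L; layer_ok <- 0L
  finite_idx <- which(is.finite(dmat), arr.ind = TRUE)
  if (nrow(finite_idx) > 0) {
    ord <- order(dmat[finite_idx])
    finite_idx <- finite_idx[ord, , drop = FALSE]
    for (k in seq_len(nrow(finite_idx))) {
      i <- finite_idx[k, 1]; j <- finite_idx[k, 2]
      if (used_d[i] || used_t[j]) next
      used_d[i] <- used_t[j] <- TRUE
      matches <- matches + 1L
      if (identical(detected$layer[i], truth$layer[j])) {
        layer_ok <- layer_ok + 1L
      }
    }
  }
  recall <- matches / n_t
  precision <- matches / n_d
  tibble(
    n_true = n_t, n_detected = n_d, n_matched = matches,
    recall = recall, precision = precision,
    f1 = ifelse(recall + precision == 0, 0,
                2 * recall * precision / (recall + precision)),
    layer_agreement = ifelse(matches == 0, NA_real_, layer_ok / matches)
  )
}
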