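# Volumetric rendering of simulated tissue with simple confocal optics.

gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    w[i, j[keep]] <- g[keep]
    w[i, ] <- w[i, ] / sum(w[i, ])  # renormalised at the borders
  }
  w
}

# Separable Gaussian blur of a 3D (z, y, x) array; sigma per axis in voxels.
gaussian_blur_3d <- function(a, sigma_vox) {
  d <- dim(a)
  if (sigma_vox[1] > 0) {
    a <- array(gaussian_kernel_matrix(d[1], sigma_vox[1]) %*%
                 matrix(a, d[1], d[2] * d[3]), dim = d)
  }
  if (sigma_vox[2] > 0) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(gaussian_kernel_matrix(d[2], sigma_vox[2]) %*%
                 matrix(a, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    a <- aperm(a, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    a <- aperm(a, c(3, 1, 2))
    a <- array(gaussian_kernel_matrix(d[3], sigma_vox[3]) %*%
                 matrix(a, d[3], d[1] * d[2]), dim = c(d[3], d[1], d[2]))
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

slice_z_um <- function(cfg, k) (k - 1) * cfg$dz_um

slices_in_um_band <- function(cfg, lo_um, hi_um) {
  k <- seq_len(cfg$z_slices)
  k[slice_z_um(cfg, k) >= lo_um & slice_z_um(cfg, k) <= hi_um]
}

#' Render a synthetic two-channel volume series
#'
#' Renders the simulated tissue into a tubulin and a pericentriolar-material
#' (cnn) channel. The tubulin channel holds the flat dorsal slab, the
#' slanted ventral slab, one vertical interepithelial column per cell in
#' contact (removed when the cell's contacts are lost), aggregated apical
#' focus intensity per cell (decaying with state) and a spindle bar for
#' mitotic cells. The cnn channel holds two point foci separated by the
#' spindle length during mitosis only. Optics are applied in order: depth
#' attenuation `exp(-alpha z)` with compensation gain `exp(+beta z)`,
#' isotropic Gaussian blur, then Poisson noise on background-plus-signal
#' counts (per the scenario's noise model).
#'
#' @param truth An [simulate_events()] result.
#' @param seed Seed for the noise substream; defaults to the scenario seed.
#' @param frames Frames to render (default all).
#' @param noise_model Override of the scenario's optics noise model
#'   (`"poisson"` or `"none"`).
#' @return An [volume_series()] with channels `tubulin` and `cnn` covering
#'   the rendered frames (frame `i` of the volume is `frames[i]`).
#' @export
render_volume <- function(truth, seed = truth$cfg$seed, frames = NULL,
                          noise_model = NULL) {
  cfg <- truth$cfg
  cells <- truth$cells
  frames <- frames %||% seq_len(cfg$n_frames)
  noise_model <- noise_model %||% cfg$optics$noise_model
  nz <- cfg$z_slices; ny <- cfg$roi_px[1]; nx <- cfg$roi_px[2]
  hw <- cfg$layer_halfwidth_um
  amp <- cfg$intensity

  # depth gain from attenuation + acquisition compensation, per z slice
  zs_um <- slice_z_um(cfg, seq_len(nz))
  gain <- exp((cfg$optics$compensation_beta - cfg$optics$attenuation_alpha) * zs_um)
  sigma_vox <- cfg$optics$blur_sigma_um / c(cfg$dz_um, cfg$dy_um, cfg$dx_um)
  if (cfg$optics$blur_sigma_um <= 0) sigma_vox <- c(0, 0, 0)

  # static geometry
  vz_x <- ventral_surface_z(cfg, seq_len(nx))
  dorsal_slices <- slices_in_um_band(cfg, cfg$dorsal_z_um - hw, cfg$dorsal_z_um + hw)
  cy <- pmin(pmax(round(cells$y), 1L), ny)
  cx <- pmin(pmax(round(cells$x), 1L), nx)
  cz <- pmin(pmax(round(cells$z_um / cfg$dz_um) + 1L, 1L), nz)
  apical_z <- ifelse(cells$layer == "dorsal",
                     cells$z_um - hw, cells$z_um + hw)
  ca <- pmin(pmax(round(apical_z / cfg$dz_um) + 1L, 1L), nz)

  base <- array(0, dim = c(nz, ny, nx))
  if (nrow(cells) > 0) {
    # the slabs are the epithelial layers themselves; an empty tissue
    # renders as pure background
    base[dorsal_slices, , ] <- amp$layer
    for (xi in seq_len(nx)) {
      vs <- slices_in_um_band(cfg, vz_x[xi] - hw, vz_x[xi] + hw)
      base[vs, , xi] <- base[vs, , xi] + amp$layer
    }
  }

  t_lost <- ifelse(is.na(cells$t_contact_lost_min), Inf, cells$t_contact_lost_min)

  tub <- array(0, dim = c(length(frames), nz, ny, nx))
  cnn <- array(0, dim = c(length(frames), nz, ny, nx))

  for (fi in seq_along(frames)) {
    t <- (frames[fi] - 1) * cfg$dt_min
    st <- state_at(truth, t)
    vol_t <- base
    vol_c <- array(0, dim = c(nz, ny, nx))

    # interepithelial columns for cells still in contact
    in_contact <- which(st == "CONTACT")
    for (i in in_contact) {
      col_z <- slices_in_um_band(cfg, cfg$dorsal_z_um + hw + cfg$dz_um,
                                 vz_x[cx[i]] - hw - cfg$dz_um)
      vol_t[col_z, cy[i], cx[i]] <- vol_t[col_z, cy[i], cx[i]] + amp$column
    }

    # aggregated apical focus intensity
    nf <- foci_count_at(truth, t)
    has_foci <- which(nf > 0)
    for (i in has_foci) {
      vol_t[ca[i], cy[i], cx[i]] <- vol_t[ca[i], cy[i], cx[i]] +
        amp$focus_gain * nf[i]
    }

    # mitotic figures: tubulin spindle bar + two cnn foci
    mit <- which(st == "MITOTIC")
    for (i in mit) {
      half <- cfg$spindle_um / 2
      dy <- sin(cells$spindle_theta[i]); dx <- cos(cells$spindle_theta[i])
      s <- seq(-half, half, length.out = 9)
      py <- pmin(pmax(round(cells$y[i] + s * dy / cfg$dy_um), 1L), ny)
      px <- pmin(pmax(round(cells$x[i] + s * dx / cfg$dx_um), 1L), nx)
      for (k in seq_along(s)) {
        vol_t[cz[i], py[k], px[k]] <- vol_t[cz[i], py[k], px[k]] + amp$spindle
      }
      ends <- c(1L, length(s))
      for (k in ends) {
        vol_c[cz[i], py[k], px[k]] <- vol_c[cz[i], py[k], px[k]] + amp$cnn_focus
      }
    }

    # optics: depth gain, then blur
    vol_t <- vol_t * gain
    vol_c <- vol_c * gain
    if (any(sigma_vox > 0)) {
      vol_t <- gaussian_blur_3d(vol_t, sigma_vox)
      vol_c <- gaussian_blur_3d(vol_c, sigma_vox)
    }
    tub[fi, , , ] <- vol_t
    cnn[fi, , , ] <- vol_c
  }

  tub <- tub + cfg$optics$background
  cnn <- cnn + cfg$optics$background
  if (noise_model == "poisson") {
    with_seed(substream_seed(seed, "noise"), {
      tub <- array(rpois(length(tub), tub), dim = dim(tub))
      cnn <- array(rpois(length(cnn), cnn), dim = dim(cnn))
    })
  }

  volume_series(
    list(tubulin = tub, cnn = cnn),
    dz_um = cfg$dz_um, dy_um = cfg$dy_um, dx_um = cfg$dx_um,
    dt_min = cfg$dt_min, t0_label = "10.5 h APF"
  )
}

#' Render a high-resolution apical plane for focus counting
#'
#' Renders the medioapical microtubule foci of the dorsal layer at
#' sub-micrometre lateral resolution for one frame, together with the
#' ground-truth cell label mask. Each cell's foci are laid out once (dart
#' throwing with a minimum separation inside the apical disk) and decay
#' with cell state, so per-cell counts are non-increasing over frames.
#'
#' @param truth An [simulate_events()] result.
#' @param frame Frame to render.
#' @param px_um Lateral pixel size of the apical render (um).
#' @param blur_sigma_um PSF sigma of the apical render (um).
#' @param cell_radius_um Apical disk radius holding the foci (um).
#' @param min_sep_um Minimum focus separation (um).
#' @param focus_amp Peak-intensity scale of one focus.
#' @param noise_model `"none"` (default) or `"poisson"`.
#' @param seed Seed for focus placement (and noise); defaults to the
#'   scenario seed.
#' @return List with `volume` (single-frame single-slice
#'   [volume_series()], channel `tubulin`), `mask` (integer y-x matrix of
#'   cell ids, 0 = background) and `truth` (tibble: `cell_id`,
#'   `n_foci`).
#' @export
render_apical <- function(truth, frame = 1L, px_um = 0.2,
                          blur_sigma_um = 0.15, cell_radius_um = 2.2,
                          min_sep_um = 0.5, focus_amp = 100,
                          noise_model = "none", seed = truth$cfg$seed) {
  cfg <- truth$cfg
  cells <- filter(truth$cells, .data$layer == "dorsal")
  t <- (frame - 1) * cfg$dt_min
  nf_all <- foci_count_at(truth, t)
  nf <- nf_all[match(cells$cell_id, truth$cells$cell_id)]

  ny <- ceiling(cfg$roi_px[1] * cfg$dy_um / px_um)
  nx <- ceiling(cfg$roi_px[2] * cfg$dx_um / px_um)

  with_seed(substream_seed(seed, "apical"), {
    img <- matrix(0, ny, nx)
    mask <- matrix(0L, ny, nx)
    placed <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      n0 <- cells$foci0[i]
      pts <- matrix(numeric(0), 0, 2)
      attempts <- 0L
      while (nrow(pts) < n0 && attempts < 400L * max(1L, n0)) {
        attempts <- attempts + 1L
        r <- cell_radius_um * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        cand <- c(cells$y[i] * cfg$dy_um + r * sin(th),
                  cells$x[i] * cfg$dx_um + r * cos(th))
        if (nrow(pts) == 0 ||
            min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep_um) {
          pts <- rbind(pts, cand)
        }
      }
      placed[[i]] <- pts
    }
    for (i in seq_len(nrow(cells))) {
      pts <- placed[[i]]
      k <- min(nf[i], nrow(pts))  # state-decayed count; prefix of layout
      if (k > 0) {
        for (j in seq_len(k)) {
          py <- pmin(pmax(round(pts[j, 1] / px_um), 1L), ny)
          px <- pmin(pmax(round(pts[j, 2] / px_um), 1L), nx)
          img[py, px] <- img[py, px] + focus_amp
        }
      }
    }
    # ground-truth mask: disk of each cell (cells are well separated)
    yy <- (seq_len(ny)) * px_um
    xx <- (seq_len(nx)) * px_um
    for (i in seq_len(nrow(cells))) {
      cy_um <- cells$y[i] * cfg$dy_um
      cx_um <- cells$x[i] * cfg$dx_um
      ys <- which(abs(yy - cy_um) <= cell_radius_um + min_sep_um)
      xs <- which(abs(xx - cx_um) <= cell_radius_um + min_sep_um)
      if (length(ys) && length(xs)) {
        sub <- outer(yy[ys] - cy_um, xx[xs] - cx_um,
                     function(a, b) sqrt(a^2 + b^2))
        m <- mask[ys, xs, drop = FALSE]
        m[sub <= cell_radius_um + min_sep_um] <- cells$cell_id[i]
        mask[ys, xs] <- m
      }
    }
    if (blur_sigma_um > 0) {
      a <- array(img, dim = c(1, ny, nx))
      a <- gaussian_blur_3d(a, c(0, blur_sigma_um / px_um, blur_sigma_um / px_um))
      img <- a[1, , ]
    }
    if (noise_model == "poisson") {
      img <- matrix(rpois(length(img), img + cfg$optics$background), ny, nx)
    }
    vol <- volume_series(
      list(tubulin = array(img, dim = c(1, 1, ny, nx))),
      dz_um = cfg$dz_um, dy_um = px_um, dx_um = px_um, dt_min = cfg$dt_min
    )
    list(
      volume = vol, mask = mask,
      truth = tibble(cell_id = cells$cell_id,
                     n_foci = pmin(nf, vapply(placed, nrow, 0L)))
    )
  })
}
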