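# Perturbations that abolish interepithelial contacts outright (severed or
# unformed protrusions), and perturbations that block the G2/M transition
# cell-autonomously. All other perturbations act through the contact-loss
# rate modifier.
PERTURB_ABOLISH <- c("Kat60", "shot")
PERTURB_BLOCK <- c("stg", "polo")
PERTURB_ALL <- c("control", "hTau", "Kat60", "patronin", "shot", "stg", "polo")

#' Scenario configuration for a synthetic wing experiment
#'
#' Defines the geometry, cell-population, kinetic and optical parameters of
#' one reproducible synthetic experiment: two apposed epithelial layers
#' (dorsal flat, ventral slanted away from the objective) connected by
#' vertical interepithelial microtubule columns whose programmed loss gates
#' one-shot mitotic events per cell.
#'
#' The defaults are calibrated to the reference control experiment: 350
#' cells per layer in the region of interest, 48 frames at 5-minute
#' intervals (4 h), dorsal layer at 10 um depth, ventral layer slanting from
#' 62 to 80 um across the ROI (interepithelial gap ~52-70 um), ~30 apical
#' MT foci per cell, and contact-loss kinetics such that the first mitoses
#' appear around 120 min and roughly a third of the cells divide within the
#' 4-hour window.
#'
#' @param name Scenario label.
#' @param n_cells_per_layer Cells per layer in the ROI (>= 0).
#' @param roi_px ROI extent `(y, x)` in pixels.
#' @param dy_um,dx_um Lateral pixel size (um).
#' @param z_slices Number of z slices.
#' @param dz_um z step (um).
#' @param dorsal_z_um Depth of the dorsal layer (um).
#' @param ventral_z_um_range Ventral layer depth `(proximal, distal)` across
#'   the x extent of the ROI (um); encodes the tissue slant. Must exceed
#'   `dorsal_z_um`.
#' @param layer_halfwidth_um Half-thickness of each rendered layer slab (um).
#' @param perturbation_d,perturbation_v Perturbation of each layer; one of
#'   `r paste0('"', PERTURB_ALL, '"', collapse = ", ")`.
#' @param rate_modifiers Named multipliers on the contact-loss hazard per
#'   perturbation (values >= 0). Contact-abolishing and G2/M-blocking
#'   perturbations act through dedicated mechanisms, not this modifier.
#' @param foci_mean Mean apical MT foci per cell (Poisson).
#' @param foci_decay_min Minutes over which apical foci decay to zero after
#'   contact loss.
#' @param hazard List with `lambda0` (per-pair contact-loss rate per minute
#'   once active) and `ramp_start_min` (hazard is zero before this time).
#' @param mitosis_delay List with `shape` and `mean_min` of the Gamma delay
#'   between contact loss and mitotic onset.
#' @param mitosis_duration_min Duration of the rendered mitotic figure.
#' @param n_frames,dt_min Acquisition schedule (frames, minutes/frame).
#' @param grid_jitter Cell-position jitter as a fraction of grid spacing.
#' @param spindle_um Spindle length (um); also the separation of the two
#'   pericentriolar-material foci of a mitotic cell.
#' @param optics List: `blur_sigma_um` (isotropic Gaussian PSF), `
#'   attenuation_alpha` (per um), `compensation_beta` (per um, the depth
#'   gain emulating acquisition z-compensation; must not exceed alpha),
#'   `noise_model` (`"poisson"` or `"none"`), `background` (counts).
#' @param intensity List of rendered signal amplitudes (photon counts):
#'   `layer`, `column`, `focus_gain` (per apical focus), `spindle`,
#'   `cnn_focus`.
#' @param seed Default seed for runs of this scenario.
#' @return An object of class `ipan_scenario`.
#' @export
scenario_config <- function(name = "control",
                            n_cells_per_layer = 350L,
                            roi_px = c(60L, 120L),
                            dy_um = 1, dx_um = 1,
                            z_slices = 85L,
                            dz_um = 1.0409333,
                            dorsal_z_um = 10,
                            ventral_z_um_range = c(62, 80),
                            layer_halfwidth_um = 2.5,
                            perturbation_d = "control",
                            perturbation_v = "control",
                            rate_modifiers = c(
                              control = 1, hTau = 0.25, Kat60 = 1,
                              patronin = 0.5, shot = 1, stg = 1, polo = 1
                            ),
                            foci_mean = 30,
                            foci_decay_min = 30,
                            hazard = list(lambda0 = 0.0035, ramp_start_min = 100),
                            mitosis_delay = list(shape = 2, mean_min = 20),
                            mitosis_duration_min = 15,
                            n_frames = 48L,
                            dt_min = 5,
                            grid_jitter = 0.3,
                            spindle_um = 4,
                            optics = list(
                              blur_sigma_um = 0.8,
                              attenuation_alpha = 0.01,
                              compensation_beta = 0.01,
                              noise_model = "poisson",
                              background = 5
                            ),
                            intensity = list(
                              layer = 60, column = 25, focus_gain = 2,
                              spindle = 120, cnn_focus = 150
                            ),
                            seed = 1L) {
  if (!is_scalar_number(n_cells_per_layer) || n_cells_per_layer < 0) {
    stop_config("`n_cells_per_layer` must be a non-negative integer")
  }
  if (!perturbation_d %in% PERTURB_ALL || !perturbation_v %in% PERTURB_ALL) {
    stop_config(paste0(
      "perturbations must be one of: ", paste(PERTURB_ALL, collapse = ", ")
    ))
  }
  if (any(rate_modifiers < 0)) stop_config("rate modifiers must be >= 0")
  if (min(ventral_z_um_range) <= dorsal_z_um) {
    stop_config("ventral depths must exceed the dorsal depth")
  }
  if (optics$compensation_beta > optics$attenuation_alpha) {
    stop_config("compensation_beta must not exceed attenuation_alpha")
  }
  if (hazard$lambda0 < 0) stop_config("hazard lambda0 must be >= 0")
  max_z_um <- (z_slices - 1) * dz_um
  if (max(ventral_z_um_range) + layer_halfwidth_um > max_z_um) {
    stop_config("z_slices too shallow for the ventral layer depth range")
  }
  structure(
    list(
      name = name,
      n_cells_per_layer = as.integer(n_cells_per_layer),
      roi_px = as.integer(roi_px),
      dy_um = dy_um, dx_um = dx_um,
      z_slices = as.integer(z_slices), dz_um = dz_um,
      dorsal_z_um = dorsal_z_um,
      ventral_z_um_range = as.numeric(ventral_z_um_range),
      layer_halfwidth_um = layer_halfwidth_um,
      perturbation_d = perturbation_d, perturbation_v = perturbation_v,
      rate_modifiers = rate_modifiers,
      foci_mean = foci_mean, foci_decay_min = foci_decay_min,
      hazard = hazard, mitosis_delay = mitosis_delay,
      mitosis_duration_min = mitosis_duration_min,
      n_frames = as.integer(n_frames), dt_min = dt_min,
      grid_jitter = grid_jitter, spindle_um = spindle_um,
      optics = optics, intensity = intensity,
      seed = as.integer(seed)
    ),
    class = "ipan_scenario"
  )
}

#' @export
print.ipan_scenario <- function(x, ...) {
  cat(sprintf(
    "<ipan_scenario> %s: %d cells/layer, %d frames x %g min, D=%s V=%s\n",
    x$name, x$n_cells_per_layer, x$n_frames, x$dt_min,
    x$perturbation_d, x$perturbation_v
  ))
  invisible(x)
}

#' Preset perturbation scenarios
#'
#' Returns the named scenario set mirroring the reference experiment panels:
#' a control, MT stabilization (hTau) in both or only the dorsal layer, MT
#' severing (Kat60) dorsally, minus-end ncMTOC factor knockdowns (patronin
#' both/dorsal, shot dorsal), and cell-autonomous G2/M blocks (stg, polo)
#' dorsally. All presets share the control calibration and differ only in
#' the layer perturbations.
#'
#' @param ... Arguments forwarded to [scenario_config()] (e.g. a reduced
#'   `n_cells_per_layer` for smoke-scale runs).
#' @return Named list of `ipan_scenario` objects.
#' @export
preset_scenarios <- function(...) {
  spec <- list(
    control = c("control", "control"),
    hTau_both = c("hTau", "hTau"),
    hTau_dorsal = c("hTau", "control"),
    kat60_dorsal = c("Kat60", "control"),
    patronin_both = c("patronin", "patronin"),
    patronin_dorsal = c("patronin", "control"),
    shot_dorsal = c("shot", "control"),
    stg_dorsal = c("stg", "control"),
    polo_dorsal = c("polo", "control")
  )
  out <- lapply(names(spec), function(nm) {
    scenario_config(
      name = nm,
      perturbation_d = spec[[nm]][1],
      perturbation_v = spec[[nm]][2],
      ...
    )
  })
  names(out) <- names(spec)
  out
}

#' Read / write scenario configurations as YAML
#'
#' @param cfg An `ipan_scenario`.
#' @param path File path (`.yaml` / `.yml`).
#' @return `path` (write) or an `ipan_scenario` (read).
#' @export
write_scenario <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$rate_modifiers <- unlist(vals$rate_modifiers)
  do.call(scenario_config, vals)
}

# Ventral layer surface depth (um) at lateral position x (pixels, 1-based
# continuous). Linear slant across the x extent of the ROI.
ventral_surface_z <- function(cfg, x_px) {
  nx <- cfg$roi_px[2]
  frac <- if (nx > 1) (x_px - 1) / (nx - 1) else 0
  cfg$ventral_z_um_range[1] +
    frac * (cfg$ventral_z_um_range[2] - cfg$ventral_z_um_range[1])
}
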