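#' Build a two-layer synthetic tissue
#'
#' Places `n_cells_per_layer` cells on a jittered grid in each layer,
#' pairs every cell with its nearest opposite-layer neighbour(s) (the union
#' of nearest-neighbour choices from both sides, so a cell can appear in
#' more than one contact pair - interepithelial contacts are not strictly
#' one-to-one), and forms contacts. A contact pair starts in state
#' `CONTACT` unless either layer carries a contact-abolishing perturbation
#' (`Kat60` or `shot`), in which case every cell of both layers starts as
#' `NEVER_CONTACTED` (the opposed layer cannot form the complexed contact
#' structure on its own).
#'
#' @param cfg An [scenario_config()].
#' @param seed Integer seed; defaults to the scenario's seed.
#' @return An object of class `ipan_tissue`: list with `cells` (tibble:
#'   `cell_id`, `layer`, `y`, `x`, `z_um`, `state0`, `foci0`,
#'   `spindle_theta`), `pairs` (tibble: `pair_id`, `dorsal_id`,
#'   `ventral_id`) and `cfg`.
#' @export
build_tissue <- function(cfg, seed = cfg$seed) {
  n <- cfg$n_cells_per_layer
  ny <- cfg$roi_px[1]; nx <- cfg$roi_px[2]
  if (n > ny * nx) {
    stop_config(sprintf("ROI %dx%d px is too small for %d cells per layer",
                        ny, nx, n))
  }
  abolished <- cfg$perturbation_d %in% PERTURB_ABOLISH ||
    cfg$perturbation_v %in% PERTURB_ABOLISH

  if (n == 0) {
    cells <- tibble(
      cell_id = integer(), layer = character(), y = numeric(), x = numeric(),
      z_um = numeric(), state0 = character(), foci0 = integer(),
      spindle_theta = numeric()
    )
    pairs <- tibble(pair_id = integer(), dorsal_id = integer(),
                    ventral_id = integer())
    return(structure(list(cells = cells, pairs = pairs, cfg = cfg),
                     class = "ipan_tissue"))
  }

  with_seed(substream_seed(seed, "tissue"), {
    layer_positions <- function() {
      ncol_grid <- max(1L, round(sqrt(n * nx / ny)))
      nrow_grid <- ceiling(n / ncol_grid)
      sx <- nx / ncol_grid
      sy <- ny / nrow_grid
      idx <- seq_len(n) - 1L
      gx <- (idx %% ncol_grid + 0.5) * sx
      gy <- (idx %/% ncol_grid + 0.5) * sy
      jit <- cfg$grid_jitter
      tibble(
        y = pmin(pmax(gy + runif(n, -jit, jit) * sy, 0.51), ny + 0.49),
        x = pmin(pmax(gx + runif(n, -jit, jit) * sx, 0.51), nx + 0.49)
      )
    }
    pd <- layer_positions()
    pv <- layer_positions()

    cells <- bind_rows(
      mutate(pd, cell_id = seq_len(n), layer = "dorsal",
             z_um = cfg$dorsal_z_um),
      mutate(pv, cell_id = n + seq_len(n), layer = "ventral",
             z_um = ventral_surface_z(cfg, .data$x))
    )
    cells$foci0 <- rpois(2L * n, cfg$foci_mean)
    cells$spindle_theta <- runif(2L * n, 0, pi)
    cells$state0 <- if (abolished) "NEVER_CONTACTED" else "CONTACT"

    # Contact graph: union of nearest opposite-layer choices from each side,
    # using lateral (y, x) distance in micrometres.
    dmat_y <- outer(pd$y, pv$y, "-") * cfg$dy_um
    dmat_x <- outer(pd$x, pv$x, "-") * cfg$dx_um
    dmat <- sqrt(dmat_y^2 + dmat_x^2)
    nearest_v <- apply(dmat, 1, which.min)
    nearest_d <- apply(dmat, 2, which.min)
    pairs <- unique(rbind(
      cbind(dorsal = seq_len(n), ventral = nearest_v),
      cbind(dorsal = nearest_d, ventral = seq_len(n))
    ))
    pairs <- tibble(
      pair_id = seq_len(nrow(pairs)),
      dorsal_id = as.integer(pairs[, "dorsal"]),
      ventral_id = as.integer(n + pairs[, "ventral"])
    )
    cells <- cells[, c("cell_id", "layer", "y", "x", "z_um", "state0",
                       "foci0", "spindle_theta")]
    structure(list(cells = cells, pairs = pairs, cfg = cfg),
              class = "ipan_tissue")
  })
}

#' @export
print.ipan_tissue <- function(x, ...) {
  cat(sprintf("<ipan_tissue> %d cells (%d pairs), scenario '%s'\n",
              nrow(x$cells), nrow(x$pairs), x$cfg$name))
  invisible(x)
}
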