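#' Simulate contact-loss-gated mitotic events
#'
#' Runs the cell-cycle model on a built tissue. Each `CONTACT` pair carries
#' a contact-loss hazard `lambda(t) = lambda0 * max(m_d, m_v)` for
#' `t > ramp_start_min` (zero before), where `m_d`, `m_v` are the rate
#' modifiers of the two layers' perturbations; taking the maximum encodes
#' rescue of a compromised layer by a wild-type opposite layer. Losses are
#' realised on the acquisition time grid (`dt_min` steps). When a pair is
#' lost, both partner cells leave `CONTACT` (a cell in several pairs loses
#' contact when its first pair does). A lost cell draws a delay
#' `tau ~ Gamma(shape, mean)` and becomes `MITOTIC` at `t_loss + tau` for
#' `mitosis_duration_min` minutes, then `DIVIDED` - each cell divides at
#' most once. Cells whose own layer carries a G2/M-blocking perturbation
#' (`stg`, `polo`) become `G2_BLOCKED` instead of mitotic (the block is
#' cell-autonomous). Mitoses after the last frame are outside the
#' observation window and yield no event.
#'
#' @param tissue An [build_tissue()] result.
#' @param seed Integer seed; defaults to the scenario's seed.
#' @return An object of class `ipan_truth`: list with `cells` (tissue cells
#'   plus `t_contact_lost_min`, `t_mitosis_min`, `final_state`), `events`
#'   (ground-truth event table: `event_id`, `frame`, `t_min`, `layer`,
#'   `z_um`, `y_px`, `x_px`, `cell_id`), `pair_losses` and `cfg`.
#' @export
simulate_events <- function(tissue, seed = tissue$cfg$seed) {
  cfg <- tissue$cfg
  cells <- tissue$cells
  pairs <- tissue$pairs
  t_end <- (cfg$n_frames - 1) * cfg$dt_min

  with_seed(substream_seed(seed, "events"), {
    # Pair loss times. The hazard is piecewise constant (0 before the ramp,
    # lambda0 * max(m_d, m_v) after), so a loss time is an exponential draw
    # shifted by ramp_start, then snapped up to the acquisition grid - the
    # exact law of the discrete-time per-step Bernoulli model.
    m_pair <- max(cfg$rate_modifiers[[cfg$perturbation_d]],
                  cfg$rate_modifiers[[cfg$perturbation_v]])
    rate <- cfg$hazard$lambda0 * m_pair
    n_pairs <- nrow(pairs)
    loss_cont <- if (rate > 0 && n_pairs > 0) {
      cfg$hazard$ramp_start_min + stats::rexp(n_pairs, rate)
    } else {
      rep(Inf, n_pairs)
    }
    loss_grid <- cfg$dt_min * ceiling(loss_cont / cfg$dt_min)
    loss_grid[loss_grid > t_end] <- Inf
    pair_losses <- mutate(pairs, t_loss_min = loss_grid)

    # Contact state never applies to NEVER_CONTACTED tissue.
    contact <- cells$state0 == "CONTACT"
    t_lost <- rep(Inf, nrow(cells))
    if (any(contact) && n_pairs > 0) {
      by_cell <- bind_rows(
        tibble(cell_id = pair_losses$dorsal_id, t = pair_losses$t_loss_min),
        tibble(cell_id = pair_losses$ventral_id, t = pair_losses$t_loss_min)
      ) |>
        group_by(.data$cell_id) |>
        summarise(t_loss = min(.data$t), .groups = "drop")
      idx <- match(cells$cell_id, by_cell$cell_id)
      t_lost_all <- by_cell$t_loss[idx]
      t_lost[contact & !is.na(t_lost_all)] <- t_lost_all[contact & !is.na(t_lost_all)]
    }

    blocked <- (cells$layer == "dorsal" & cfg$perturbation_d %in% PERTURB_BLOCK) |
      (cells$layer == "ventral" & cfg$perturbation_v %in% PERTURB_BLOCK)

    tau <- if (cfg$mitosis_delay$mean_min > 0) {
      rgamma(nrow(cells), shape = cfg$mitosis_delay$shape,
             scale = cfg$mitosis_delay$mean_min / cfg$mitosis_delay$shape)
    } else {
      rep(0, nrow(cells))
    }
    t_mit <- t_lost + tau
    t_mit[blocked] <- Inf
    t_mit[t_mit > t_end] <- Inf

    final_state <- dplyr::case_when(
      cells$state0 == "NEVER_CONTACTED" ~ "NEVER_CONTACTED",
      is.infinite(t_lost) ~ "CONTACT",
      blocked ~ "G2_BLOCKED",
      is.infinite(t_mit) ~ "LOST",
      t_mit + cfg$mitosis_duration_min <= t_end ~ "DIVIDED",
      TRUE ~ "MITOTIC"
    )

    cells$t_contact_lost_min <- ifelse(is.infinite(t_lost), NA_real_, t_lost)
    cells$t_mitosis_min <- ifelse(is.infinite(t_mit), NA_real_, t_mit)
    cells$final_state <- final_state

    mitotic <- which(is.finite(t_mit))
    frame_of <- function(t) {
      # first acquisition frame at or after t (frame i is at (i-1)*dt)
      pmax(1L, as.integer(ceiling(t / cfg$dt_min - 1e-9)) + 1L)
    }
    events <- tibble(
      event_id = seq_along(mitotic),
      frame = frame_of(t_mit[mitotic]),
      layer = cells$layer[mitotic],
      z_um = cells$z_um[mitotic],
      y_px = cells$y[mitotic],
      x_px = cells$x[mitotic],
      cell_id = cells$cell_id[mitotic]
    ) |>
      mutate(t_min = (.data$frame - 1) * cfg$dt_min) |>
      arrange(.data$frame, .data$cell_id) |>
      mutate(event_id = row_number()) |>
      select("event_id", "frame", "t_min", "layer", "z_um", "y_px", "x_px",
             "cell_id")

    structure(
      list(cells = cells, events = events, pair_losses = pair_losses,
           cfg = cfg),
      class = "ipan_truth"
    )
  })
}

#' @export
print.ipan_truth <- function(x, ...) {
  cat(sprintf(
    "<ipan_truth> scenario '%s': %d cells, %d mitotic events (D=%d, V=%d)\n",
    x$cfg$name, nrow(x$cells), nrow(x$events),
    sum(x$events$layer == "dorsal"), sum(x$events$layer == "ventral")
  ))
  invisible(x)
}

#' Per-cell state at a given time
#'
#' @param truth An [simulate_events()] result.
#' @param t_min Time in minutes from the start of the window.
#' @return Character vector of states, one per cell (in `truth$cells`
#'   order): `NEVER_CONTACTED`, `CONTACT`, `LOST`, `MITOTIC`, `G2_BLOCKED`
#'   or `DIVIDED`.
#' @export
state_at <- function(truth, t_min) {
  cfg <- truth$cfg
  cells <- truth$cells
  t_lost <- ifelse(is.na(cells$t_contact_lost_min), Inf, cells$t_contact_lost_min)
  t_mit <- ifelse(is.na(cells$t_mitosis_min), Inf, cells$t_mitosis_min)
  blocked <- cells$final_state == "G2_BLOCKED"
  dplyr::case_when(
    cells$state0 == "NEVER_CONTACTED" ~ "NEVER_CONTACTED",
    t_min < t_lost ~ "CONTACT",
    blocked ~ "G2_BLOCKED",
    t_min < t_mit ~ "LOST",
    t_min < t_mit + cfg$mitosis_duration_min ~ "MITOTIC",
    TRUE ~ "DIVIDED"
  )
}

#' Apical focus count of every cell at a given time
#'
#' The initial Poisson count while the cell is in contact, decaying
#' linearly to zero over `foci_decay_min` after contact loss, and zero from
#' mitotic onset onward (apical minus-end foci disappear as protrusion
#' microtubules are reorganised into the spindle).
#'
#' @param truth An [simulate_events()] result.
#' @param t_min Time in minutes.
#' @return Integer vector, one count per cell (in `truth$cells` order).
#' @export
foci_count_at <- function(truth, t_min) {
  cfg <- truth$cfg
  cells <- truth$cells
  t_lost <- ifelse(is.na(cells$t_contact_lost_min), Inf, cells$t_contact_lost_min)
  t_mit <- ifelse(is.na(cells$t_mitosis_min), Inf, cells$t_mitosis_min)
  frac <- pmax(0, pmin(1, 1 - (t_min - t_lost) / cfg$foci_decay_min))
  frac[t_min < t_lost] <- 1
  frac[t_min >= t_mit] <- 0
  as.integer(round(cells$foci0 * frac))
}

#' Ground-truth cumulative mitosis counts per layer
#'
#' Every event is carried into all subsequent frames, so the per-layer
#' count at the final frame is the total number of mitoses of the window.
#'
#' @param events An event table (ground truth or detected).
#' @param n_frames,dt_min Acquisition schedule.
#' @return A tibble with columns `frame`, `t_min`, `dorsal`, `ventral`.
#' @export
cumulative_counts <- function(events, n_frames = 48L, dt_min = 5) {
  frames <- seq_len(n_frames)
  count_layer <- function(lyr) {
    onset <- events$frame[events$layer == lyr]
    vapply(frames, function(f) sum(onset <= f), 0L)
  }
  tibble(
    frame = frames,
    t_min = (frames - 1) * dt_min,
    dorsal = count_layer("dorsal"),
    ventral = count_layer("ventral")
  )
}
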