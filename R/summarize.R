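#' Summarise one experimental run
#'
#' Collects per-layer cumulative mitosis curves, final counts, divided
#' fractions, onset times, and (when a ratio series is supplied) the
#' interepithelial ratio trace and its least-squares slope.
#'
#' @param events An event table (ground truth or detected).
#' @param ratios Optional output of [ratio_timeseries()].
#' @param n_cells_per_layer Cells per layer observed (for divided
#'   fractions; must be > 0).
#' @param n_frames,dt_min Acquisition schedule.
#' @param scenario,seed Run labels carried into reports.
#' @return An object of class `ipan_run_summary`.
#' @export
summarize_run <- function(events, ratios = NULL, n_cells_per_layer,
                          n_frames = 48L, dt_min = 5,
                          scenario = "control", seed = NA_integer_) {
  if (!is_scalar_number(n_cells_per_layer) || n_cells_per_layer <= 0) {
    stop_config("`n_cells_per_layer` must be > 0 to define divided fractions")
  }
  curves <- cumulative_counts(events, n_frames = n_frames, dt_min = dt_min)
  final <- c(dorsal = dplyr::last(curves$dorsal),
             ventral = dplyr::last(curves$ventral))
  onset_frame <- c(
    dorsal = suppressWarnings(min(events$frame[events$layer == "dorsal"])),
    ventral = suppressWarnings(min(events$frame[events$layer == "ventral"]))
  )
  onset_frame[!is.finite(onset_frame)] <- NA
  structure(
    list(
      scenario = scenario, seed = seed,
      n_cells_per_layer = n_cells_per_layer,
      curves = curves,
      final_counts = final,
      divided_fraction = final / n_cells_per_layer,
      onset_frame = onset_frame,
      onset_min = (onset_frame - 1) * dt_min,
      ratios = ratios,
      ratio_slope = if (is.null(ratios)) NA_real_ else ratio_slope(ratios)
    ),
    class = "ipan_run_summary"
  )
}

#' @export
print.ipan_run_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<ipan_run_summary> %s (seed %s): final D=%d V=%d ",
           "(%.1f%% / %.1f%% divided), onset D=%s V=%s min\n"),
    x$scenario, x$seed, x$final_counts[["dorsal"]],
    x$final_counts[["ventral"]],
    100 * x$divided_fraction[["dorsal"]],
    100 * x$divided_fraction[["ventral"]],
    x$onset_min[["dorsal"]], x$onset_min[["ventral"]]
  ))
  invisible(x)
}

#' Dorsal-ventral coordination of cumulative mitosis curves
#'
#' Two transparent proxies for "tight coordination" of the two layers'
#' cumulative mitosis curves: the maximum absolute dorsal-ventral
#' difference over frames, and the Pearson correlation of the two curves
#' (undefined when either curve is constant). Both are artifact-defined
#' summaries, not field-standard statistics.
#'
#' @param x An `ipan_run_summary` or a curves tibble with `dorsal` and
#'   `ventral` columns.
#' @return One-row tibble: `max_abs_diff`, `pearson_r`.
#' @export
coordination_score <- function(x) {
  curves <- if (inherits(x, "ipan_run_summary")) x$curves else x
  d <- curves$dorsal; v <- curves$ventral
  r <- if (sd(d) == 0 || sd(v) == 0) NA_real_ else cor(d, v)
  tibble(max_abs_diff = max(abs(d - v)), pearson_r = r)
}

run_summary_metrics <- function(s) {
  coord <- coordination_score(s)
  tibble(
    metric = c("final_dorsal", "final_ventral", "frac_dorsal", "frac_ventral",
               "onset_min_dorsal", "onset_min_ventral", "coord_max_abs_diff",
               "coord_pearson_r", "ratio_slope"),
    value = c(s$final_counts[["dorsal"]], s$final_counts[["ventral"]],
              s$divided_fraction[["dorsal"]], s$divided_fraction[["ventral"]],
              s$onset_min[["dorsal"]], s$onset_min[["ventral"]],
              coord$max_abs_diff, coord$pearson_r, s$ratio_slope)
  )
}

#' @export
tidy.ipan_run_summary <- function(x, ...) {
  mutate(run_summary_metrics(x), scenario = x$scenario, seed = x$seed,
         .before = 1)
}

#' @export
glance.ipan_run_summary <- function(x, ...) {
  m <- run_summary_metrics(x)
  out <- as_tibble(as.list(setNames(m$value, m$metric)))
  mutate(out, scenario = x$scenario, seed = x$seed, .before = 1)
}

boot_ci <- function(x, n_boot, probs = c(0.025, 0.975)) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  if (length(x) == 1) return(c(NA_real_, NA_real_))
  means <- vapply(seq_len(n_boot), function(i) {
    mean(sample(x, length(x), replace = TRUE))
  }, 0)
  unname(quantile(means, probs))
}

#' Replicate-level scenario report
#'
#' Summarises replicate runs of one scenario: per-metric mean across seeds,
#' seeded percentile-bootstrap 95% confidence intervals (2000 resamples by
#' default; replicate counts are small and the sampling distributions
#' unknown, so bootstrap percentile intervals are used rather than
#' t-intervals), and deltas against a control scenario when supplied.
#'
#' @param summaries List of `ipan_run_summary` objects (>= 1 seed; CIs
#'   require >= 2).
#' @param control Optional list of control `ipan_run_summary` objects.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return An `ipan_scenario_report`: a tibble with columns `metric`,
#'   `mean`, `ci_lo`, `ci_hi`, `n`, and when control is given
#'   `control_mean` and `delta`.
#' @export
scenario_report <- function(summaries, control = NULL, n_boot = 2000L,
                            seed = 1L) {
  if (length(summaries) == 0) stop_config("need at least one run summary")
  vals <- bind_rows(lapply(summaries, run_summary_metrics), .id = "rep")
  metric_sets <- vals |> group_by(.data$rep) |>
    summarise(sig = paste(.data$metric, collapse = "|"), .groups = "drop")
  if (length(unique(metric_sets$sig)) != 1) {
    stop_config("replicates carry mismatched metric sets")
  }
  if (length(summaries) == 1) {
    warn("single replicate: confidence intervals are undefined")
  }
  report <- with_seed(substream_seed(seed, "bootstrap"), {
    vals |>
      group_by(.data$metric) |>
      summarise(
        mean = mean(.data$value[!is.na(.data$value)]),
        ci_lo = boot_ci(.data$value, n_boot)[1],
        ci_hi = boot_ci(.data$value, n_boot)[2],
        n = sum(!is.na(.data$value)),
        .groups = "drop"
      )
  })
  if (!is.null(control)) {
    cvals <- bind_rows(lapply(control, run_summary_metrics)) |>
      group_by(.data$metric) |>
      summarise(control_mean = mean(.data$value[!is.na(.data$value)]),
                .groups = "drop")
    report <- report |>
      left_join(cvals, by = "metric") |>
      mutate(delta = .data$mean - .data$control_mean)
  }
  structure(report, class = c("ipan_scenario_report", class(report)),
            scenario = summaries[[1]]$scenario, n_reps = length(summaries))
}

#' @export
tidy.ipan_scenario_report <- function(x, ...) as_tibble(x)

#' @export
glance.ipan_scenario_report <- function(x, ...) {
  tibble(
    scenario = attr(x, "scenario"),
    n_reps = attr(x, "n_reps"),
    final_dorsal = x$mean[x$metric == "final_dorsal"],
    final_ventral = x$mean[x$metric == "final_ventral"],
    onset_min = mean(c(x$mean[x$metric == "onset_min_dorsal"],
                       x$mean[x$metric == "onset_min_ventral"]))
  )
}
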