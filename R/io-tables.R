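# Side-table readers/writers: the six-column z-profile table and event CSVs.

profile_table_header <- paste(
  "#frame no, ratio of middle value, total intensity,",
  "dorsal peak val, ventral peak val, middle average value"
)

#' Write a ratio time series as a six-column profile table
#'
#' Writes the tab-delimited table produced by the z-profile quantification:
#' one row per frame with columns frame number, interepithelial ratio, total
#' intensity, dorsal peak value, ventral peak value and mean interepithelial
#' (middle) value, preceded by a `#`-prefixed header line naming exactly
#' those columns.
#'
#' @param ratios A ratio time-series tibble from [ratio_timeseries()] (or any
#'   data frame with columns `frame`, `ratio`, `total`, `i_d`, `i_v`, `i_int`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(ratios, path) {
  need <- c("frame", "ratio", "total", "i_d", "i_v", "i_int")
  if (!all(need %in% names(ratios))) {
    stop_format(paste0(
      "ratio series must have columns: ", paste(need, collapse = ", ")
    ))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(profile_table_header, con)
  if (nrow(ratios) > 0) {
    body <- apply(
      as.matrix(ratios[, need]), 1L,
      function(r) paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
                        collapse = "\t")
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' Read back a six-column profile table
#'
#' @param path Path written by [write_profile_table()].
#' @return A tibble with columns `frame`, `ratio`, `total`, `i_d`, `i_v`,
#'   `i_int`.
#' @export
read_profile_table <- function(path) {
  tab <- utils::read.table(
    path, sep = "\t", comment.char = "#",
    col.names = c("frame", "ratio", "total", "i_d", "i_v", "i_int")
  )
  as_tibble(tab)
}

event_table_columns <- c(
  "event_id", "frame", "t_min", "layer", "z_um", "y_px", "x_px", "cell_id"
)

#' Write / read mitotic event tables
#'
#' Event tables are plain CSV with columns `event_id`, `frame`, `t_min`,
#' `layer`, `z_um`, `y_px`, `x_px`, `cell_id` (NA `cell_id` for detections
#' without a matched ground-truth cell).
#'
#' @param events A tibble of events.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_events <- function(events, path) {
  missing_cols <- setdiff(event_table_columns, names(events))
  for (mc in missing_cols) events[[mc]] <- NA
  readr::write_csv(events[, event_table_columns], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      event_id = readr::col_integer(),
      frame = readr::col_integer(),
      t_min = readr::col_double(),
      layer = readr::col_character(),
      z_um = readr::col_double(),
      y_px = readr::col_double(),
      x_px = readr::col_double(),
      cell_id = readr::col_integer()
    ),
    progress = FALSE
  )
}
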