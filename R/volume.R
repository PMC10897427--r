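#' Multi-channel 4D volume time series
#'
#' A `volume_series` holds one or more fluorescence channels as 4D intensity
#' arrays indexed `(t, z, y, x)`, together with the voxel and time
#' calibration of the acquisition. z index 1 is the most-apical dorsal slice
#' (imaging from the dorsal side); z increases toward the ventral layer. All
#' slab and window arithmetic in the package uses this convention.
#'
#' The default calibration matches the reference acquisition protocol for
#' pupal-wing live imaging: a 1.0409333 um z-step and one 3D frame every
#' 5 minutes (48 frames over 4 h).
#'
#' @param channels Named list of 4D numeric arrays, all of identical
#'   dimension `(t, z, y, x)`, with non-negative finite intensities.
#'   Conventional channel names are `"tubulin"` and `"cnn"`.
#' @param dz_um z step in micrometres (> 0).
#' @param dy_um,dx_um Lateral pixel size in micrometres (> 0).
#' @param dt_min Frame interval in minutes (> 0).
#' @param t0_label Optional nominal start-time label (e.g. `"10.5 h APF"`).
#'
#' @return An object of class `ipan_volume`.
#' @export
volume_series <- function(channels,
                          dz_um = 1.0409333,
                          dy_um = 1,
                          dx_um = 1,
                          dt_min = 5,
                          t0_label = NULL) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop_channel("`channels` must be a non-empty named list of 4D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 4L)) {
    stop_format("every channel must be a 4D array (t, z, y, x)")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop_format("all channels must share the same (t, z, y, x) dimensions")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch) || anyNA(ch) || any(ch < 0)) {
      stop_format(paste0("channel '", nm, "' must be non-negative and finite"))
    }
  }
  assert_scalar_positive(dz_um, "dz_um")
  assert_scalar_positive(dy_um, "dy_um")
  assert_scalar_positive(dx_um, "dx_um")
  assert_scalar_positive(dt_min, "dt_min")
  structure(
    list(
      channels = channels,
      dz_um = dz_um, dy_um = dy_um, dx_um = dx_um, dt_min = dt_min,
      t0_label = t0_label
    ),
    class = "ipan_volume"
  )
}

#' @export
print.ipan_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<ipan_volume> ", paste(names(x$channels), collapse = ", "),
      sprintf("\n  t=%d z=%d y=%d x=%d  dz=%.4f um  dt=%g min\n",
              d[1], d[2], d[3], d[4], x$dz_um, x$dt_min))
  if (!is.null(x$t0_label)) cat("  t0:", x$t0_label, "\n")
  invisible(x)
}

#' @rdname volume_series
#' @param v An `ipan_volume`.
#' @export
n_frames <- function(v) dim(v$channels[[1]])[1]

#' @rdname volume_series
#' @export
n_z_slices <- function(v) dim(v$channels[[1]])[2]

#' @rdname volume_series
#' @param channel Channel name.
#' @export
get_channel <- function(v, channel) {
  if (!channel %in% names(v$channels)) {
    stop_channel(paste0(
      "channel '", channel, "' not present (have: ",
      paste(names(v$channels), collapse = ", "), ")"
    ))
  }
  v$channels[[channel]]
}

#' Frame times of a volume series
#'
#' Frame `i` is acquired at `(i - 1) * dt_min` minutes after the start of the
#' time lapse.
#'
#' @param v An `ipan_volume`.
#' @return Numeric vector of times in minutes, one per frame.
#' @export
frame_times <- function(v) (seq_len(n_frames(v)) - 1) * v$dt_min

# ---------------------------------------------------------------------------
# OME-TIFF writing.
#
# The installed TIFF bindings cannot embed an ImageDescription tag nor store
# raw integer counts, so the writer emits a minimal baseline OME-TIFF itself:
# little-endian, uncompressed uint16, one strip per plane, OME-XML (2016-06
# schema) in the ImageDescription of the first IFD. Plane order follows
# DimensionOrder XYZCT (z fastest, then channel, then time).
# ---------------------------------------------------------------------------

ome_xml <- function(v, size_t, size_z, size_y, size_x) {
  ch <- paste0(
    sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
            seq_along(v$channels) - 1L, names(v$channels)),
    collapse = ""
  )
  desc <- if (is.null(v$t0_label)) "" else {
    sprintf("<Description>t0=%s</Description>", v$t0_label)
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0" Name="ipanr">', desc,
    sprintf(
      paste0(
        '<Pixels ID="Pixels:0" DimensionOrder="XYZCT" Type="uint16" ',
        'SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="%d" ',
        'PhysicalSizeX="%.9g" PhysicalSizeXUnit="&#181;m" ',
        'PhysicalSizeY="%.9g" PhysicalSizeYUnit="&#181;m" ',
        'PhysicalSizeZ="%.9g" PhysicalSizeZUnit="&#181;m" ',
        'TimeIncrement="%.9g" TimeIncrementUnit="min">'
      ),
      size_x, size_y, size_z, length(v$channels), size_t,
      v$dx_um, v$dy_um, v$dz_um, v$dt_min
    ),
    ch, "<TiffData/></Pixels></Image></OME>"
  )
}

write_uint16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
write_uint32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

# One 12-byte IFD entry. type 2=ASCII, 3=SHORT, 4=LONG.
write_ifd_entry <- function(con, tag, type, count, value, is_offset = FALSE) {
  write_uint16(con, tag)
  write_uint16(con, type)
  write_uint32(con, count)
  if (type == 3L && !is_offset) {
    write_uint16(con, value)
    write_uint16(con, 0L)
  } else {
    write_uint32(con, value)
  }
}

#' Write a volume series to OME-TIFF
#'
#' Intensities are stored as unsigned 16-bit counts (values are rounded;
#' values above 65535 are clipped with a warning). Calibration metadata and
#' channel names are stored as OME-XML in the ImageDescription tag, so the
#' file is readable by standard OME-TIFF consumers.
#'
#' @param v An [volume_series()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ipan_volume"))
  d <- dim(v$channels[[1]])
  nt <- d[1]; nz <- d[2]; ny <- d[3]; nx <- d[4]
  nc <- length(v$channels)
  if (any(unlist(lapply(v$channels, max), use.names = FALSE) > 65535)) {
    warn("intensities above 65535 are clipped by the uint16 OME-TIFF writer")
  }

  desc <- ome_xml(v, nt, nz, ny, nx)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  n_planes <- nt * nz * nc
  plane_bytes <- nx * ny * 2L
  data_start <- 8L
  desc_offset <- data_start + n_planes * plane_bytes
  ifd0_offset <- desc_offset + length(desc_raw)
  ifd_size_first <- 2L + 11L * 12L + 4L
  ifd_size_rest <- 2L + 10L * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_uint16(con, 42L)
  write_uint32(con, ifd0_offset)

  # Plane data in XYZCT order: z fastest, then channel, then time.
  for (ti in seq_len(nt)) {
    for (ci in seq_len(nc)) {
      arr <- v$channels[[ci]]
      for (zi in seq_len(nz)) {
        plane <- arr[ti, zi, , ]
        vals <- as.integer(pmin(round(t(plane)), 65535))  # row-major (y rows)
        write_uint16(con, vals)
      }
    }
  }
  writeBin(desc_raw, con)

  for (p in seq_len(n_planes)) {
    first <- p == 1L
    strip_offset <- data_start + (p - 1L) * plane_bytes
    next_ifd <- if (p == n_planes) 0L else {
      ifd0_offset + ifd_size_first + (p - 1L) * ifd_size_rest
    }
    write_uint16(con, if (first) 11L else 10L)
    write_ifd_entry(con, 256L, 4L, 1L, nx)
    write_ifd_entry(con, 257L, 4L, 1L, ny)
    write_ifd_entry(con, 258L, 3L, 1L, 16L)
    write_ifd_entry(con, 259L, 3L, 1L, 1L)
    write_ifd_entry(con, 262L, 3L, 1L, 1L)
    if (first) write_ifd_entry(con, 270L, 2L, length(desc_raw), desc_offset, is_offset = TRUE)
    write_ifd_entry(con, 273L, 4L, 1L, strip_offset)
    write_ifd_entry(con, 277L, 3L, 1L, 1L)
    write_ifd_entry(con, 278L, 4L, 1L, ny)
    write_ifd_entry(con, 279L, 4L, 1L, plane_bytes)
    write_ifd_entry(con, 339L, 3L, 1L, 1L)
    write_uint32(con, next_ifd)
  }
  invisible(path)
}

ome_attr_num <- function(node, attrname) {
  val <- xml2::xml_attr(node, attrname)
  if (is.na(val)) NA_real_ else as.numeric(val)
}

parse_ome_description <- function(desc) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  chn <- xml2::xml_find_all(doc, ".//*[local-name()='Channel']")
  image_desc <- xml2::xml_find_first(doc, ".//*[local-name()='Description']")
  t0 <- if (inherits(image_desc, "xml_missing")) NULL else {
    sub("^t0=", "", xml2::xml_text(image_desc))
  }
  list(
    size_x = ome_attr_num(px, "SizeX"), size_y = ome_attr_num(px, "SizeY"),
    size_z = ome_attr_num(px, "SizeZ"), size_c = ome_attr_num(px, "SizeC"),
    size_t = ome_attr_num(px, "SizeT"),
    dx = ome_attr_num(px, "PhysicalSizeX"), dy = ome_attr_num(px, "PhysicalSizeY"),
    dz = ome_attr_num(px, "PhysicalSizeZ"), dt = ome_attr_num(px, "TimeIncrement"),
    dim_order = xml2::xml_attr(px, "DimensionOrder"),
    channel_names = xml2::xml_attr(chn, "Name"),
    t0_label = t0
  )
}

#' Read an OME-TIFF volume series
#'
#' Reads a multi-page (OME-)TIFF into a [volume_series()]. Axis sizes,
#' calibration and channel names are taken from the OME-XML ImageDescription.
#' When calibration metadata is absent, the documented acquisition defaults
#' (`dz_um = 1.0409333`, `dt_min = 5`, unit lateral pixels) are substituted
#' with a warning so that third-party exports remain usable. A plain TIFF
#' without OME metadata is interpreted as a single-channel, single-frame
#' z-stack (with a warning).
#'
#' @param path Path to the TIFF file.
#' @param require_channels Optional character vector of channel names that
#'   must be present; a channel error is raised otherwise.
#' @return An `ipan_volume`.
#' @export
read_volume <- function(path, require_channels = NULL) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1]], "description")
  meta <- if (is.null(desc)) NULL else parse_ome_description(desc)

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  n_pages <- length(pages)

  if (is.null(meta)) {
    warn("no OME metadata found; assuming a single-channel single-frame z-stack")
    meta <- list(
      size_x = nx, size_y = ny, size_z = n_pages, size_c = 1, size_t = 1,
      dx = NA, dy = NA, dz = NA, dt = NA, dim_order = "XYZCT",
      channel_names = "tubulin", t0_label = NULL
    )
  }
  nz <- as.integer(meta$size_z); nc <- as.integer(meta$size_c)
  nt <- as.integer(meta$size_t)
  if (anyNA(c(nz, nc, nt)) || nz * nc * nt != n_pages) {
    stop_format(sprintf(
      "axes metadata unresolvable: SizeZ*SizeC*SizeT = %s does not match %d pages",
      paste(c(nz, nc, nt), collapse = "*"), n_pages
    ))
  }
  if (!isTRUE(meta$size_x == nx) || !isTRUE(meta$size_y == ny)) {
    stop_format("OME SizeX/SizeY disagree with the TIFF page geometry")
  }
  if (is.na(meta$dz)) {
    warn("PhysicalSizeZ missing; falling back to default dz_um = 1.0409333")
    meta$dz <- 1.0409333
  }
  if (is.na(meta$dt)) {
    warn("TimeIncrement missing; falling back to default dt_min = 5")
    meta$dt <- 5
  }
  if (is.na(meta$dx)) meta$dx <- 1
  if (is.na(meta$dy)) meta$dy <- 1
  ch_names <- meta$channel_names
  if (length(ch_names) != nc || anyNA(ch_names)) {
    ch_names <- if (nc == 2) c("tubulin", "cnn") else paste0("ch", seq_len(nc))
  }

  order <- meta$dim_order %||% "XYZCT"
  axes <- strsplit(sub("^XY", "", order), "")[[1]]
  if (!setequal(axes, c("Z", "C", "T"))) {
    stop_format(paste0("unsupported DimensionOrder: ", order))
  }
  sizes <- c(Z = nz, C = nc, T = nt)

  channels <- lapply(seq_len(nc), function(ci) array(0, dim = c(nt, nz, ny, nx)))
  names(channels) <- ch_names
  for (p in seq_len(n_pages)) {
    idx0 <- p - 1L
    pos <- integer(3)
    rem <- idx0
    for (k in 1:3) {
      pos[k] <- rem %% sizes[[axes[k]]]
      rem <- rem %/% sizes[[axes[k]]]
    }
    names(pos) <- axes
    channels[[pos[["C"]] + 1L]][pos[["T"]] + 1L, pos[["Z"]] + 1L, , ] <- pages[[p]]
  }

  if (!is.null(require_channels)) {
    missing_ch <- setdiff(require_channels, ch_names)
    if (length(missing_ch) > 0) {
      stop_channel(paste0(
        "required channel(s) missing: ", paste(missing_ch, collapse = ", ")
      ))
    }
  }
  volume_series(
    channels,
    dz_um = meta$dz, dy_um = meta$dy, dx_um = meta$dx, dt_min = meta$dt,
    t0_label = meta$t0_label
  )
}
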