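# Readers and writers for the two on-disk formats the pipeline touches:
# TRC-style tab-delimited marker trajectories and per-plate force CSVs.
# All internal computation is SI (meters, newtons); unit conversion happens
# only here.

#' Construct a marker trajectory set
#'
#' @param marker_names Character vector of marker labels (no duplicates).
#' @param positions Array frames x markers x 3, meters, lab frame. Gap frames
#'   carry NA (never silently interpolated).
#' @param rate Sampling rate (Hz).
#' @return Object of class `marker_set`.
#' @export
marker_set <- function(marker_names, positions, rate = 100) {
  if (anyDuplicated(marker_names)) stop("duplicate marker names")
  if (rate <= 0) stop("rate must be positive")
  if (length(dim(positions)) != 3 || dim(positions)[2] != length(marker_names) ||
      dim(positions)[3] != 3) {
    stop("positions must be a frames x markers x 3 array")
  }
  structure(list(marker_names = marker_names, positions = positions,
                 rate = rate, units = "m"),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Marker set:", length(x$marker_names), "markers,",
      dim(x$positions)[1], "frames @", x$rate, "Hz\n")
  invisible(x)
}

#' Write marker trajectories to a TRC-style file
#'
#' Tab-delimited with the customary two-row numeric header (rate, frame and
#' marker counts, units) and X/Y/Z triplets per marker.
#'
#' @param markers A `marker_set`.
#' @param path Output path.
#' @param units `"m"` or `"mm"` for the written coordinates.
#' @export
write_markers <- function(markers, path, units = "m") {
  stopifnot(inherits(markers, "marker_set"))
  fac <- switch(units, m = 1, mm = 1000, stop("units must be 'm' or 'mm'"))
  n <- dim(markers$positions)[1]
  m <- length(markers$marker_names)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType\t4\t(X/Y/Z)", basename(path), sep = "\t"),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    paste(markers$rate, markers$rate, n, m, units, markers$rate, 1, n, sep = "\t"),
    paste0("Frame#\tTime\t", paste(markers$marker_names, collapse = "\t\t\t")),
    paste0("\t\t", paste(paste0(c("X", "Y", "Z"),
                                rep(seq_len(m), each = 3)), collapse = "\t"))
  ), con)
  t <- (seq_len(n) - 1) / markers$rate
  for (f in seq_len(n)) {
    row <- as.vector(t(markers$positions[f, , ])) * fac
    writeLines(paste(c(f, format(t[f], nsmall = 6, trim = TRUE),
                       formatC(row, format = "g", digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read marker trajectories from a TRC-style file
#'
#' Millimeter files are converted to meters on read. When `expected_markers`
#' is given, missing markers are reported in the `missing_markers` attribute
#' and near-miss names trigger a warning with mapping suggestions.
#'
#' @param path Input path.
#' @param expected_markers Optional character vector of required marker names.
#' @return A `marker_set` (meters).
#' @export
read_markers <- function(path, expected_markers = NULL) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed marker file (fewer than 6 lines)")
  hdr <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(hdr[1])
  nframes <- as.integer(hdr[3])
  nmark <- as.integer(hdr[4])
  units <- hdr[5]
  if (is.na(rate) || rate <= 0) stop("marker file header declares no valid rate")
  if (!units %in% c("m", "mm")) stop("marker file header declares unknown units: ", units)
  fac <- if (units == "mm") 1 / 1000 else 1
  names_row <- strsplit(lines[4], "\t")[[1]]
  marker_names <- names_row[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  if (length(marker_names) != nmark) {
    stop("marker file declares ", nmark, " markers but names ", length(marker_names))
  }
  pos <- array(NA_real_, c(nframes, nmark, 3))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nframes) {
    stop("marker file declares ", nframes, " frames but contains ",
         length(data_lines))
  }
  for (f in seq_len(nframes)) {
    vals <- suppressWarnings(as.numeric(strsplit(data_lines[f], "\t")[[1]]))
    if (length(vals) != 2 + 3 * nmark) {
      stop("malformed marker row at line ", f + 5, ": expected ",
           2 + 3 * nmark, " fields, found ", length(vals))
    }
    pos[f, , ] <- matrix(vals[-(1:2)], nmark, 3, byrow = TRUE) * fac
  }
  ms <- marker_set(marker_names, pos, rate)
  if (!is.null(expected_markers)) {
    missing <- setdiff(expected_markers, marker_names)
    unknown <- setdiff(marker_names, expected_markers)
    if (length(unknown) > 0) {
      sugg <- vapply(unknown, function(u) {
        hit <- agrep(u, missing, value = TRUE, max.distance = 0.3)
        if (length(hit) > 0) paste0(u, " -> ", hit[1]) else u
      }, character(1))
      warning("unknown marker names (suggested mapping): ",
              paste(sugg, collapse = "; "))
    }
    attr(ms, "missing_markers") <- missing
  }
  ms
}

#' Construct a force-plate record
#'
#' @param force n x 3 matrix, N, lab frame (Y vertical).
#' @param moment n x 3 matrix, N m, free moment about the COP.
#' @param cop n x 3 matrix, m, lab frame; NA rows where undefined.
#' @param rate Sampling rate (Hz).
#' @param plate_id Integer plate identifier (1-4).
#' @param cop_threshold Vertical force (N) below which the COP is flagged
#'   undefined.
#' @return Object of class `forceplate_record`; `cop_defined` is a logical
#'   per-frame flag.
#' @export
forceplate_record <- function(force, moment, cop, rate = 1000, plate_id = 1L,
                              cop_threshold = 10) {
  force <- as.matrix(force); moment <- as.matrix(moment); cop <- as.matrix(cop)
  stopifnot(ncol(force) == 3, ncol(moment) == 3, ncol(cop) == 3,
            nrow(force) == nrow(moment), nrow(force) == nrow(cop))
  if (rate <= 0) stop("rate must be positive")
  defined <- force[, 2] >= cop_threshold & !is.na(force[, 2])
  cop[!defined, ] <- NA_real_
  structure(list(force = force, moment = moment, cop = cop, rate = rate,
                 plate_id = as.integer(plate_id), cop_defined = defined,
                 cop_threshold = cop_threshold),
            class = "forceplate_record")
}

#' @export
print.forceplate_record <- function(x, ...) {
  cat("Force-plate record: plate", x$plate_id, ",", nrow(x$force),
      "samples @", x$rate, "Hz;", sum(x$cop_defined), "loaded frames\n")
  invisible(x)
}

#' Write a force-plate record to CSV
#'
#' Columns `time, fx, fy, fz, mx, my, mz, copx, copy, copz`, with the plate
#' id and rate in `#`-prefixed header lines.
#'
#' @param fp A `forceplate_record`.
#' @param path Output path.
#' @export
write_forceplate <- function(fp, path) {
  stopifnot(inherits(fp, "forceplate_record"))
  n <- nrow(fp$force)
  df <- data.frame(time = (seq_len(n) - 1) / fp$rate,
                   fx = fp$force[, 1], fy = fp$force[, 2], fz = fp$force[, 3],
                   mx = fp$moment[, 1], my = fp$moment[, 2], mz = fp$moment[, 3],
                   copx = fp$cop[, 1], copy = fp$cop[, 2], copz = fp$cop[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# force plate record",
               paste0("# plate_id: ", fp$plate_id),
               paste0("# rate: ", fp$rate)), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read force-plate records from CSV files
#'
#' @param paths One or more CSV paths written by [write_forceplate()] (or any
#'   file honouring its documented column schema).
#' @return A list of `forceplate_record` objects, one per file.
#' @export
read_forceplates <- function(paths) {
  lapply(paths, function(path) {
    if (!file.exists(path)) stop("force-plate file not found: ", path)
    lines <- readLines(path, n = 20)
    meta <- grep("^#", lines, value = TRUE)
    get_meta <- function(key, default) {
      hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
      if (length(hit) == 0) return(default)
      as.numeric(sub(paste0("^# ", key, ":\\s*"), "", hit[1]))
    }
    plate_id <- get_meta("plate_id", 1)
    rate <- get_meta("rate", 1000)
    df <- utils::read.csv(path, comment.char = "#")
    need <- c("time", "fx", "fy", "fz", "mx", "my", "mz", "copx", "copy", "copz")
    if (!all(need %in% names(df))) {
      stop("force-plate file ", path, " is missing channels: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    forceplate_record(as.matrix(df[, c("fx", "fy", "fz")]),
                      as.matrix(df[, c("mx", "my", "mz")]),
                      as.matrix(df[, c("copx", "copy", "copz")]),
                      rate = rate, plate_id = plate_id)
  })
}

#' Fill short marker gaps by cubic spline interpolation
#'
#' Gap frames (NA) are never filled silently on read; this explicit step
#' fills gaps up to `max_gap` consecutive frames per marker by spline
#' interpolation of each coordinate. Longer gaps are left as NA (the
#' conservative default is to exclude cycles containing them).
#'
#' @param markers A `marker_set`.
#' @param max_gap Longest run of missing frames to fill (default 5).
#' @return A `marker_set` with short gaps filled; attribute `filled_frames`
#'   counts interpolated frames per marker.
#' @export
fill_marker_gaps <- function(markers, max_gap = 5) {
  pos <- markers$positions
  filled <- integer(length(markers$marker_names))
  for (i in seq_along(markers$marker_names)) {
    slab <- matrix(pos[, i, ], ncol = 3)
    miss <- rowSums(is.na(slab)) > 0
    if (!any(miss) || all(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      if (r$lengths[k] > max_gap) next
      if (starts[k] == 1 || ends[k] == nrow(slab)) next  # no extrapolation
      idx <- starts[k]:ends[k]
      ok <- which(!miss)
      for (d in 1:3) {
        slab[idx, d] <- stats::spline(ok, slab[ok, d], xout = idx)$y
      }
      filled[i] <- filled[i] + length(idx)
    }
    pos[, i, ] <- slab
  }
  out <- marker_set(markers$marker_names, pos, markers$rate)
  attr(out, "filled_frames") <- stats::setNames(filled, markers$marker_names)
  out
}

#' Resample a force-plate record onto the marker clock
#'
#' Anti-alias low-pass filters the force and moment channels (zero-lag
#' Butterworth), then decimates to the target rate, which must divide the
#' source rate. COP samples are decimated without filtering so undefined
#' (swing) gaps stay sharp.
#'
#' @param fp A `forceplate_record`.
#' @param rate Target rate (Hz).
#' @param cutoff Anti-alias cutoff (Hz); default 20.
#' @return A `forceplate_record` at the target rate.
#' @export
resample_to_marker_clock <- function(fp, rate, cutoff = 20) {
  if (fp$rate %% rate != 0) {
    stop("target rate ", rate, " does not divide the plate rate ", fp$rate)
  }
  factor <- fp$rate / rate
  if (factor == 1) return(fp)
  idx <- seq(1, nrow(fp$force), by = factor)
  force <- filter_signal(fp$force, fp$rate, cutoff)[idx, , drop = FALSE]
  moment <- filter_signal(fp$moment, fp$rate, cutoff)[idx, , drop = FALSE]
  cop <- fp$cop[idx, , drop = FALSE]
  forceplate_record(force, moment, cop, rate = rate, plate_id = fp$plate_id,
                    cop_threshold = fp$cop_threshold)
}
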