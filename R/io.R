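#' Motion-capture text formats
#'
#' Minimal, strict readers and writers for the two headered TSV dialects
#' used by optical motion capture pipelines: TRC (marker trajectories)
#' and STO/MOT (time-series tables of coordinates, forces or solution
#' states). Internal units are SI and radians; unit conversion (mm to m,
#' degrees to radians) happens here and only here. Readers reject
#' malformed or ambiguous headers with the offending line number rather
#' than guessing.
#'
#' @name motion_io
NULL

#' Time-series table
#'
#' @param time time column, s (strictly increasing).
#' @param data numeric matrix (rows = samples), unique column labels.
#' @param units free-form units note.
#' @param rate nominal sampling rate, Hz.
#' @return a `timeseries_table`.
#' @export
timeseries_table <- function(time, data, units = "SI", rate = NA_real_) {
  if (any(diff(time) <= 0)) stopf("time column must strictly increase")
  data <- as.matrix(data)
  if (nrow(data) != length(time)) stopf("data rows must match time")
  if (anyDuplicated(colnames(data))) stopf("column labels must be unique")
  structure(list(time = time, data = data, units = units, rate = rate),
            class = "timeseries_table")
}

#' Read / write TRC marker files
#'
#' Standard TRC layout: a 3-line preamble (`PathFileType`, header keys,
#' header values), marker-name row, axis row, then `Frame# Time X1 Y1 Z1
#' ...` data. Positions are converted to meters according to the
#' `Units` header field.
#'
#' @param path TRC file path.
#' @param trial a [marker_trial()] (two markers written as `exo_r`,
#'   `exo_l` unless named via `marker_names`).
#' @param marker_names names for the two markers on write.
#' @return `read_trc` returns a [marker_trial()] (first two markers);
#'   `write_trc` returns `path` invisibly.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stopf("TRC parse error at line 1: truncated file")
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  if (length(vals) < length(keys)) {
    stopf("TRC parse error at line 3: %d header values for %d keys",
          length(vals), length(keys))
  }
  hdr <- stats::setNames(as.list(vals), keys)
  rate <- suppressWarnings(as.numeric(hdr[["DataRate"]]))
  n_markers <- suppressWarnings(as.integer(hdr[["NumMarkers"]]))
  units <- hdr[["Units"]]
  if (is.na(rate) || is.na(n_markers) || is.null(units)) {
    stopf("TRC parse error at line 2-3: need DataRate, NumMarkers, Units")
  }
  scale <- switch(units, mm = 1e-3, m = 1, cm = 1e-2,
                  stopf("TRC parse error at line 3: unknown units '%s'",
                        units))
  mk <- strsplit(lines[4], "\t")[[1]]
  marker_names <- mk[seq(3, by = 3, length.out = n_markers)]
  first_data <- 6
  while (first_data <= length(lines) &&
         !grepl("^[0-9]", trimws(lines[first_data]))) {
    first_data <- first_data + 1
  }
  raw <- utils::read.table(text = lines[first_data:length(lines)],
                           sep = "\t", header = FALSE,
                           fill = TRUE, na.strings = c("", "NA"))
  need <- 2 + 3 * n_markers
  if (ncol(raw) < need) {
    stopf("TRC parse error at line %d: %d columns, expected %d",
          first_data, ncol(raw), need)
  }
  time <- raw[[2]]
  get_marker <- function(i) {
    as.matrix(raw[, 2 + (i - 1) * 3 + (1:3)]) * scale
  }
  if (n_markers < 2) stopf("TRC parse error: need at least 2 markers")
  out <- marker_trial(time, get_marker(1), get_marker(2), rate)
  attr(out, "marker_names") <- marker_names
  out
}

#' @rdname read_trc
#' @export
write_trc <- function(trial, path, marker_names = c("exo_r", "exo_l")) {
  n <- length(trial$time)
  hdr <- c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t2\tm\t%g\t1\t%d", trial$rate, trial$rate, n,
            trial$rate, n),
    paste(c("Frame#", "Time",
            as.vector(rbind(marker_names, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), 2),
                           rep(1:2, each = 3))), collapse = "\t"),
    "")
  body <- cbind(seq_len(n), trial$time, trial$p1, trial$p2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' Read / write STO and MOT time-series tables
#'
#' Header of `key=value` lines (`nRows`, `nColumns`, optional
#' `inDegrees`) terminated by `endheader`, then a tab-separated label
#' row starting with `time` and the data. With `inDegrees=yes`,
#' rotational columns (all except those ending in `_tx`/`_ty`/`_tz`)
#' are converted to radians on read.
#'
#' @param path file path.
#' @param table a [timeseries_table()].
#' @param name table name written to the first header line.
#' @param in_degrees write angles in degrees (the internal radian data
#'   are converted on write).
#' @return `read_sto_mot` returns a [timeseries_table()] (radians/SI);
#'   the writer returns `path` invisibly.
#' @export
read_sto_mot <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (length(end) != 1) {
    stopf("STO parse error: expected exactly one endheader line")
  }
  hdr <- lines[seq_len(end - 1)]
  getkey <- function(key) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(hit) != 1) return(NA_character_)
    sub(paste0("^", key, "="), "", hit)
  }
  n_rows <- suppressWarnings(as.integer(getkey("nRows")))
  n_cols <- suppressWarnings(as.integer(getkey("nColumns")))
  in_deg <- tolower(getkey("inDegrees"))
  labels <- strsplit(trimws(lines[end + 1]), "\t")[[1]]
  if (labels[1] != "time") {
    stopf("STO parse error at line %d: first column must be 'time'",
          end + 1)
  }
  raw <- utils::read.table(text = lines[(end + 2):length(lines)],
                           sep = "\t", header = FALSE)
  if (!is.na(n_rows) && nrow(raw) != n_rows) {
    stopf("STO parse error: header says nRows=%d but found %d data rows",
          n_rows, nrow(raw))
  }
  if (!is.na(n_cols) && ncol(raw) != n_cols) {
    stopf("STO parse error: header says nColumns=%d but found %d",
          n_cols, ncol(raw))
  }
  data <- as.matrix(raw[, -1, drop = FALSE])
  colnames(data) <- labels[-1]
  if (identical(in_deg, "yes")) {
    rot <- !grepl("_(tx|ty|tz)$", colnames(data))
    data[, rot] <- data[, rot] * pi / 180
  }
  timeseries_table(raw[[1]], data, units = "SI")
}

#' @rdname read_sto_mot
#' @export
write_sto_mot <- function(table, path, name = "table",
                          in_degrees = FALSE) {
  data <- table$data
  if (in_degrees) {
    rot <- !grepl("_(tx|ty|tz)$", colnames(data))
    data[, rot] <- data[, rot] * 180 / pi
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               sprintf("nRows=%d", nrow(data)),
               sprintf("nColumns=%d", ncol(data) + 1L),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(c("time", colnames(data)), collapse = "\t")), con)
  utils::write.table(cbind(table$time, data), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a reference gait as coordinate + GRF tables
#'
#' @param ref a [reference_data()].
#' @param coord_path STO path for the coordinates.
#' @param grf_path MOT path for the per-foot GRFs (columns
#'   `grf_r_x, grf_r_y, grf_l_x, grf_l_y`).
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, coord_path, grf_path) {
  write_sto_mot(timeseries_table(ref$time, ref$coords), coord_path,
                name = "coordinates")
  G <- cbind(grf_r_x = ref$grf_r[, 1], grf_r_y = ref$grf_r[, 2],
             grf_l_x = ref$grf_l[, 1], grf_l_y = ref$grf_l[, 2])
  write_sto_mot(timeseries_table(ref$time, G), grf_path, name = "grf")
  invisible(c(coord_path, grf_path))
}

#' Read a reference gait from coordinate + GRF tables
#'
#' @param coord_path,grf_path files written by [write_reference()].
#' @param speed,mass metadata not carried by the table formats.
#' @return a [reference_data()] (stride duration = table time span).
#' @export
read_reference <- function(coord_path, grf_path, speed, mass) {
  ct <- read_sto_mot(coord_path)
  gt <- read_sto_mot(grf_path)
  reference_data(ct$time, ct$data,
                 gt$data[, c("grf_r_x", "grf_r_y")],
                 gt$data[, c("grf_l_x", "grf_l_y")],
                 speed, ct$time[length(ct$time)] - ct$time[1], mass)
}

#' Write a run manifest
#'
#' Records what produced a results directory: a label, the seed, the
#' configuration (hashed and in full) and package/R versions.
#'
#' @param path output JSON path.
#' @param label free-form stage label.
#' @param seed integer seed used.
#' @param config any serializable configuration list.
#' @return `path` invisibly.
#' @export
write_manifest <- function(path, label, seed, config = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  jsonlite::write_json(list(
    label = label, seed = seed,
    config_hash = sum(utf8ToInt(as.character(cfg_json))),
    config = config,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("exotendon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
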