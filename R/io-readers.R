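# Vendor export dialects.
#
# Real vendor exports vary by software version; this package documents one
# simplified text dialect per hardware family and parses strictly against
# it, failing loudly on anything else.  The canonical format
# (write_canonical/read_canonical) is the supported archival path.
#
#   emed (.lst)      header lines, then one rectangular grid block per frame
#   pedar (.asc)     sensor-major: one column per insole sensor, one row per
#                    frame; geometry from a bundled/registered layout
#   pliance (.asc)   same dialect as pedar (mat layouts)
#   tekscan (.asf)   "Frame n" separated comma-delimited grid blocks;
#                    calibrated pressures only (raw exports are rejected)
#   footscan (.xls-style)  tab-delimited spreadsheet export: one grid table
#                    per frame, blank-line separated
#
# Declared N/cm2 values are scaled by exactly 10 into kPa; kPa passes
# through unchanged.  Decimal commas are accepted whenever the delimiter is
# not a comma.

UNIT_FACTORS <- c("kPa" = 1, "N/cm2" = 10)

unit_factor <- function(u) {
  if (!u %in% names(UNIT_FACTORS)) stop("unsupported unit: ", u)
  UNIT_FACTORS[[u]]
}

parse_values <- function(line, delim) {
  if (delim == ",") {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
  } else {
    line <- gsub(",", ".", line, fixed = TRUE)  # decimal commas
    parts <- strsplit(trimws(line), delim)[[1]]
  }
  as.numeric(parts[nzchar(parts)])
}

header_value <- function(lines, key, required = TRUE) {
  pat <- paste0("^", key, "\\s*:\\s*")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) {
    if (required) stop("missing header field: ", key)
    return(NULL)
  }
  trimws(sub(pat, "", hit[1]))
}

# ---- insole layout registry -------------------------------------------------

.layouts <- new.env(parent = emptyenv())

#' Register an insole sensor layout
#'
#' Sensor-major exports (pedar/pliance) carry no geometry; layouts supply
#' it.  A layout is a trimmed [sensor_grid] plus the sensor-number to
#' (row, col) map.  The bundled `"pedar99"` (99-sensor insole) and
#' `"pliance256"` (16 x 16 mat) layouts are pre-registered; synthetic
#' layouts may be added for testing.
#'
#' @param name layout name.
#' @param grid a [sensor_grid] whose active cells are the sensors.
#' @param sensor_cells n_sensors x 2 (row, col) matrix, in sensor order.
#' @export
register_insole_layout <- function(name, grid, sensor_cells) {
  stopifnot(nrow(sensor_cells) == sum(grid$active))
  assign(name, list(grid = grid, sensor_cells = sensor_cells),
         envir = .layouts)
  invisible(name)
}

builtin_layouts <- function() {
  if (!exists("pedar99", envir = .layouts)) {
    g <- pedar_layout_99()
    register_insole_layout("pedar99", g, pedar_sensor_cells())
    gm <- sensor_grid(16L, 16L, dx = 10, dy = 10)
    cells <- which(gm$active, arr.ind = TRUE)[, c(1, 2)]
    register_insole_layout("pliance256", gm, unname(cells))
  }
  invisible()
}

lookup_layout <- function(n_sensors) {
  builtin_layouts()
  for (nm in ls(.layouts)) {
    lay <- get(nm, envir = .layouts)
    if (nrow(lay$sensor_cells) == n_sensors) return(c(lay, name = nm))
  }
  stop("no registered insole layout with ", n_sensors, " sensors (known: ",
       paste(sort(ls(.layouts)), collapse = ", "), ")")
}

#' The bundled 99-sensor insole layout
#'
#' A 15 x 7 trimmed grid (corner cells of the toe and heel rows inactive)
#' of 11.4 x 16 mm capacitive cells, approximating a standard insole.
#'
#' @return A [sensor_grid] with 99 active cells.
#' @export
pedar_layout_99 <- function() {
  n_rows <- 15L; n_cols <- 7L
  active <- matrix(TRUE, n_rows, n_cols)
  active[1, c(1, 7)] <- FALSE
  active[2, c(1, 7)] <- FALSE
  active[15, c(1, 7)] <- FALSE
  sensor_grid(n_rows, n_cols, dx = 11.4, dy = 16, active = active)
}

# Sensor numbering: 1 at the medial heel, increasing medial-to-lateral then
# heel-to-toe (row 15 first).
pedar_sensor_cells <- function() {
  g <- pedar_layout_99()
  out <- NULL
  for (r in rev(seq_len(g$n_rows)))
    for (c in seq_len(g$n_cols))
      if (g$active[r, c]) out <- rbind(out, c(r, c))
  colnames(out) <- c("row", "col")
  out
}

# ---- emed -------------------------------------------------------------------

#' Load an emed-style platform export
#'
#' Parses the documented `.lst`-style dialect: header fields (`units`,
#' `sampling_rate[Hz]`, `rows`, `columns`, `cell_size[mm]`) followed by one
#' `frame: t` grid block per time point.
#'
#' @param path file path.
#' @return A [pressure_recording] with `system = "emed"`, pressures in kPa.
#' @export
load_emed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^frame\\s*:", lines)
  if (!length(fstart)) stop("no frame blocks found")
  hdr <- lines[seq_len(fstart[1] - 1L)]
  fac <- unit_factor(header_value(hdr, "units"))
  sr <- as.numeric(header_value(hdr, "sampling_rate\\[Hz\\]"))
  n_rows <- as.integer(header_value(hdr, "rows"))
  n_cols <- as.integer(header_value(hdr, "columns"))
  cs <- parse_values(header_value(hdr, "cell_size\\[mm\\]"), "\\s+")
  frames <- read_grid_blocks(lines, fstart, n_rows, n_cols, "\\s+")
  grid <- sensor_grid(n_rows, n_cols, dx = cs[1], dy = cs[2])
  rec <- pressure_recording(frames * fac, sr, grid, system = "emed")
  stop_if_invalid(rec)
  rec
}

read_grid_blocks <- function(lines, fstart, n_rows, n_cols, delim) {
  T <- length(fstart)
  frames <- array(0, c(T, n_rows, n_cols))
  for (t in seq_len(T)) {
    i <- fstart[t]
    if (i + n_rows > length(lines) + 1L &&
        !(i + n_rows <= length(lines) + 1L))
      stop("truncated frame block ", t)
    if (i + n_rows > length(lines))
      stop("truncated frame block ", t)
    block <- lines[(i + 1L):(i + n_rows)]
    vals <- lapply(block, parse_values, delim = delim)
    if (any(lengths(vals) != n_cols) || anyNA(unlist(vals)))
      stop("frame ", t, ": expected ", n_rows, " x ", n_cols, " numeric block")
    frames[t, , ] <- do.call(rbind, vals)
  }
  frames
}

# ---- pedar / pliance --------------------------------------------------------

load_sensor_major <- function(path, system) {
  lines <- readLines(path, warn = FALSE)
  dstart <- grep("^data\\s*:\\s*$", lines)
  if (length(dstart) != 1L) stop("missing 'data:' marker")
  hdr <- lines[seq_len(dstart - 1L)]
  fac <- unit_factor(header_value(hdr, "units"))
  sr <- as.numeric(header_value(hdr, "sampling_rate\\[Hz\\]"))
  n_sens <- as.integer(header_value(hdr, "sensors"))
  lay <- lookup_layout(n_sens)
  body <- lines[(dstart + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vals <- lapply(body, parse_values, delim = "\\s+")
  if (any(lengths(vals) != n_sens))
    stop("frame ", which(lengths(vals) != n_sens)[1],
         ": expected ", n_sens, " sensor values")
  mat <- do.call(rbind, vals) * fac
  g <- lay$grid
  T <- nrow(mat)
  frames <- array(0, c(T, g$n_rows, g$n_cols))
  for (s in seq_len(n_sens))
    frames[, lay$sensor_cells[s, 1], lay$sensor_cells[s, 2]] <- mat[, s]
  rec <- pressure_recording(frames, sr, g, system = system)
  stop_if_invalid(rec)
  rec
}

#' Load a pedar-style in-shoe export
#'
#' Parses the documented `.asc`-style sensor-major dialect (one column per
#' insole sensor, one line per frame after a `data:` marker); geometry
#' comes from the registered layout matching the sensor count.  Multi-step
#' series are kept in full; events stay empty until [select_steps()].
#'
#' @param path file path.
#' @return A [pressure_recording] with `system = "pedar"`.
#' @export
load_pedar <- function(path) load_sensor_major(path, "pedar")

#' Load a pliance-style mat export
#'
#' Same dialect as [load_pedar()]; `system = "pliance"`.
#'
#' @param path file path.
#' @return A [pressure_recording].
#' @export
load_pliance <- function(path) load_sensor_major(path, "pliance")

# ---- tekscan ----------------------------------------------------------------

#' Load a Tekscan-style export
#'
#' Parses the documented `.asf`/`.csv`-style dialect: uppercase header
#' fields, then comma-delimited grid blocks separated by `Frame n` lines.
#' Only calibrated pressure exports are supported; `UNITS RAW` is rejected.
#'
#' @param path file path.
#' @return A [pressure_recording] with `system = "tekscan"`.
#' @export
load_tekscan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^Frame\\b", lines)
  if (!length(fstart)) stop("missing Frame separator")
  hdr <- lines[seq_len(fstart[1] - 1L)]
  get <- function(key, required = TRUE) {
    hit <- grep(paste0("^", key, "\\b"), hdr, value = TRUE)
    if (!length(hit)) {
      if (required) stop("missing header field: ", key)
      return(NULL)
    }
    trimws(sub(paste0("^", key, "\\s+"), "", hit[1]))
  }
  u <- get("UNITS")
  if (toupper(u) == "RAW")
    stop("uncalibrated raw-unit Tekscan export; only calibrated pressures are supported")
  fac <- unit_factor(u)
  sr <- as.numeric(get("SAMPLING_RATE"))
  n_rows <- as.integer(get("ROWS"))
  n_cols <- as.integer(get("COLS"))
  rs <- as.numeric(get("ROW_SPACING"))
  cs <- as.numeric(get("COL_SPACING"))
  frames <- read_grid_blocks(lines, fstart, n_rows, n_cols, ",")
  grid <- sensor_grid(n_rows, n_cols, dx = cs, dy = rs)
  rec <- pressure_recording(frames * fac, sr, grid, system = "tekscan")
  stop_if_invalid(rec)
  rec
}

# ---- footscan ---------------------------------------------------------------

#' Load a footscan-style spreadsheet export
#'
#' Parses the documented tab-delimited spreadsheet dialect: header fields,
#' then one rectangular frame table per time point, separated by
#' `frame<TAB>t` lines.  Binary `.xls` containers are out of scope; export
#' the sheet as text.
#'
#' @param path file path.
#' @return A [pressure_recording] with `system = "footscan"`.
#' @export
load_footscan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^frame\t", lines)
  if (!length(fstart)) stop("empty sheet: no frame tables found")
  hdr <- lines[seq_len(fstart[1] - 1L)]
  fac <- unit_factor(header_value(hdr, "units"))
  sr <- as.numeric(header_value(hdr, "sampling_rate\\[Hz\\]"))
  n_rows <- as.integer(header_value(hdr, "rows"))
  n_cols <- as.integer(header_value(hdr, "columns"))
  cs <- parse_values(header_value(hdr, "cell_size\\[mm\\]"), "\\s+")
  frames <- array(0, c(length(fstart), n_rows, n_cols))
  for (t in seq_along(fstart)) {
    i <- fstart[t]
    if (i + n_rows > length(lines)) stop("truncated frame table ", t)
    block <- lines[(i + 1L):(i + n_rows)]
    vals <- lapply(block, function(s)
      suppressWarnings(as.numeric(strsplit(s, "\t", fixed = TRUE)[[1]])))
    if (any(lengths(vals) != n_cols)) stop("frame ", t, ": wrong column count")
    if (anyNA(unlist(vals))) stop("frame ", t, ": non-numeric cell")
    frames[t, , ] <- do.call(rbind, vals)
  }
  grid <- sensor_grid(n_rows, n_cols, dx = cs[1], dy = cs[2])
  rec <- pressure_recording(frames * fac, sr, grid, system = "footscan")
  stop_if_invalid(rec)
  rec
}

# ---- fixture writer ---------------------------------------------------------

fmt_fix <- function(x) sprintf("%.8g", x)

#' Write a recording as a vendor-dialect fixture file
#'
#' Emits a file in one of the five documented dialects such that the
#' matching loader parses it back to an equal recording (up to the 8
#' significant digits of the float text).  Used as the round-trip oracle
#' for the loaders and by the `simulate` CLI subcommand.
#'
#' @param rec a valid [pressure_recording].
#' @param system target dialect: `"emed"`, `"pedar"`, `"pliance"`,
#'   `"tekscan"` or `"footscan"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(rec, system = c("emed", "pedar", "pliance",
                                          "tekscan", "footscan"), path) {
  system <- match.arg(system)
  stop_if_invalid(rec)
  g <- rec$grid; T <- n_frames(rec)
  full_grid_needed <- system %in% c("emed", "tekscan", "footscan")
  if (full_grid_needed && any(!g$active))
    stop("the ", system, " dialect cannot represent a trimmed grid")
  lines <- switch(system,
    emed = {
      out <- c("EMED pressure export",
               "units: kPa",
               paste0("sampling_rate[Hz]: ", fmt_fix(rec$sampling_rate)),
               paste0("rows: ", g$n_rows),
               paste0("columns: ", g$n_cols),
               paste0("cell_size[mm]: ", fmt_fix(g$dx), " ", fmt_fix(g$dy)))
      for (t in seq_len(T)) {
        out <- c(out, paste0("frame: ", t),
                 apply(rec$frames[t, , , drop = FALSE], 2, function(r)
                   paste(fmt_fix(r), collapse = " ")))
      }
      out
    },
    tekscan = {
      out <- c("TEKSCAN pressure export",
               "UNITS kPa",
               paste("SAMPLING_RATE", fmt_fix(rec$sampling_rate)),
               paste("ROWS", g$n_rows),
               paste("COLS", g$n_cols),
               paste("ROW_SPACING", fmt_fix(g$dy)),
               paste("COL_SPACING", fmt_fix(g$dx)))
      for (t in seq_len(T)) {
        out <- c(out, paste("Frame", t),
                 apply(rec$frames[t, , , drop = FALSE], 2, function(r)
                   paste(fmt_fix(r), collapse = ",")))
      }
      out
    },
    footscan = {
      out <- c("footscan pressure export",
               "units: kPa",
               paste0("sampling_rate[Hz]: ", fmt_fix(rec$sampling_rate)),
               paste0("rows: ", g$n_rows),
               paste0("columns: ", g$n_cols),
               paste0("cell_size[mm]: ", fmt_fix(g$dx), " ", fmt_fix(g$dy)))
      for (t in seq_len(T)) {
        out <- c(out, paste0("frame\t", t),
                 apply(rec$frames[t, , , drop = FALSE], 2, function(r)
                   paste(fmt_fix(r), collapse = "\t")))
      }
      out
    },
    {  # pedar / pliance: sensor-major
      builtin_layouts()
      lay <- NULL
      for (nm in ls(.layouts)) {
        cand <- get(nm, envir = .layouts)
        if (identical(dim(cand$grid$active), dim(g$active)) &&
            identical(unname(cand$grid$active), unname(g$active))) {
          lay <- cand
          break
        }
      }
      if (is.null(lay))
        stop("recording geometry matches no registered insole layout")
      sc <- lay$sensor_cells
      out <- c(paste(system, "pressure export"),
               "units: kPa",
               paste0("sampling_rate[Hz]: ", fmt_fix(rec$sampling_rate)),
               paste0("sensors: ", nrow(sc)),
               "data:")
      for (t in seq_len(T)) {
        v <- rec$frames[t, , ][sc]
        out <- c(out, paste(fmt_fix(v), collapse = " "))
      }
      out
    })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Load a pressure file, dispatching on system
#'
#' @param path file path.
#' @param system one of the five dialects, or `"auto"` to guess from the
#'   first line of the file.
#' @return A [pressure_recording].
#' @export
load_pressure <- function(path, system = "auto") {
  if (system == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    system <- if (grepl("^EMED", first)) "emed"
      else if (grepl("^TEKSCAN", first)) "tekscan"
      else if (grepl("^pedar", first)) "pedar"
      else if (grepl("^pliance", first)) "pliance"
      else if (grepl("^footscan", first)) "footscan"
      else if (grepl("^PEDOBAR", first)) "canonical"
      else stop("cannot auto-detect system from file header")
  }
  switch(system,
         emed = load_emed(path), pedar = load_pedar(path),
         pliance = load_pliance(path), tekscan = load_tekscan(path),
         footscan = load_footscan(path), canonical = read_canonical(path),
         stop("unknown system: ", system))
}
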