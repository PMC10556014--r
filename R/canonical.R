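# Versioned plain-text archive format for pressure recordings.
#
# Layout (all ASCII, LF line endings, '.' decimal separator):
#   PEDOBAR 1
#   key: value header lines (system, side, sampling_rate_hz, n_rows, n_cols,
#                            pressure_unit, area_unit, length_unit)
#   GEOMETRY <n_cells>      one line per cell, row-major:
#     row col x y area active nv v1x v1y ... vnx vny
#   FRAMES <T> / FRAME <t>  n_rows lines of n_cols pressures each
#   EVENTS <n>              start end
#   MASKS <n>               MASK <name> polygon|sensors <k> <rule> <fraction>
#                           followed by k "x y" or "row col" lines
#   END
#
# Pressures and geometry are written with 17 significant digits so doubles
# round-trip bit-faithfully.

CANONICAL_MAGIC <- "PEDOBAR"
CANONICAL_VERSION <- 1L

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a recording to the canonical interchange format
#'
#' Serializes every field of a [pressure_recording] (frames, geometry,
#' metadata, events, masks) to a self-describing versioned text file.
#' Writing the same recording twice produces byte-identical files, and
#' [read_canonical()] restores the object exactly.
#'
#' @param rec a valid [pressure_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_canonical <- function(rec, path) {
  stop_if_invalid(rec)
  g <- rec$grid; T <- n_frames(rec)
  lines <- c(
    paste(CANONICAL_MAGIC, CANONICAL_VERSION),
    paste0("system: ", rec$system),
    paste0("side: ", rec$side),
    paste0("sampling_rate_hz: ", fmt_num(rec$sampling_rate)),
    paste0("n_rows: ", g$n_rows),
    paste0("n_cols: ", g$n_cols),
    "pressure_unit: kPa",
    "area_unit: cm2",
    "length_unit: mm")
  geo <- character(g$n_rows * g$n_cols)
  k <- 0L
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    p <- g$polygons[[cell_index(r, c, g$n_cols)]]
    k <- k + 1L
    geo[k] <- paste(r, c, fmt_num(g$centers$x[r, c]), fmt_num(g$centers$y[r, c]),
                    fmt_num(g$area[r, c]), as.integer(g$active[r, c]), nrow(p),
                    paste(fmt_num(t(p)), collapse = " "))
  }
  lines <- c(lines, paste("GEOMETRY", g$n_rows * g$n_cols), geo,
             paste("FRAMES", T))
  fr <- character(T * (g$n_rows + 1L))
  k <- 0L
  for (t in seq_len(T)) {
    k <- k + 1L; fr[k] <- paste("FRAME", t)
    m <- matrix(fmt_num(t(rec$frames[t, , ])), g$n_cols, g$n_rows)
    for (r in seq_len(g$n_rows)) {
      k <- k + 1L
      fr[k] <- paste(m[, r], collapse = " ")
    }
  }
  lines <- c(lines, fr, paste("EVENTS", n_events(rec$events)))
  if (n_events(rec$events))
    lines <- c(lines, paste(rec$events[, "start"], rec$events[, "end"]))
  lines <- c(lines, paste("MASKS", length(rec$masks)))
  for (m in rec$masks) {
    if (grepl("\\s", m$name)) stop("mask names may not contain whitespace")
    if (m$type == "polygon") {
      lines <- c(lines, paste("MASK", m$name, "polygon", nrow(m$vertices),
                              m$coverage_rule, fmt_num(m$fraction)),
                 paste(fmt_num(m$vertices[, 1]), fmt_num(m$vertices[, 2])))
    } else {
      lines <- c(lines, paste("MASK", m$name, "sensors", nrow(m$cells),
                              m$coverage_rule, fmt_num(m$fraction)),
                 if (nrow(m$cells)) paste(m$cells[, 1], m$cells[, 2]))
    }
  }
  lines <- c(lines, "END")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a recording from the canonical interchange format
#'
#' @param path file written by [write_canonical()].
#' @return A [pressure_recording] that passes [validate_recording()].
#' @export
read_canonical <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty canonical file")
  magic <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(magic) != 2L || magic[1] != CANONICAL_MAGIC)
    stop("not a canonical pressure file (bad magic line)")
  if (as.integer(magic[2]) != CANONICAL_VERSION)
    stop("unsupported canonical format version: ", magic[2])
  i <- 2L
  hdr <- list()
  while (i <= length(lines) && grepl("^[a-z_]+: ", lines[i])) {
    kv <- sub("^([a-z_]+): (.*)$", "\\1\x01\\2", lines[i])
    kv <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  if (!identical(hdr$pressure_unit, "kPa") ||
      !identical(hdr$area_unit, "cm2") ||
      !identical(hdr$length_unit, "mm"))
    stop("unsupported unit in canonical header")
  n_rows <- as.integer(hdr$n_rows); n_cols <- as.integer(hdr$n_cols)
  sr <- as.numeric(hdr$sampling_rate_hz)
  expect_section <- function(name) {
    if (i > length(lines)) stop("truncated file: missing ", name, " section")
    tok <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (tok[1] != name) stop("expected ", name, " section at line ", i)
    i <<- i + 1L
    as.integer(tok[2])
  }
  nc <- expect_section("GEOMETRY")
  if (nc != n_rows * n_cols) stop("geometry cell count mismatch")
  cx <- matrix(0, n_rows, n_cols); cy <- matrix(0, n_rows, n_cols)
  area <- matrix(0, n_rows, n_cols); active <- matrix(TRUE, n_rows, n_cols)
  polys <- vector("list", nc)
  for (k in seq_len(nc)) {
    v <- as.numeric(strsplit(lines[i], " ", fixed = TRUE)[[1]])
    r <- as.integer(v[1]); c <- as.integer(v[2])
    cx[r, c] <- v[3]; cy[r, c] <- v[4]; area[r, c] <- v[5]
    active[r, c] <- v[6] == 1
    nv <- as.integer(v[7])
    polys[[cell_index(r, c, n_cols)]] <-
      matrix(v[8:(7 + 2 * nv)], ncol = 2, byrow = TRUE,
             dimnames = list(NULL, c("x", "y")))
    i <- i + 1L
  }
  T <- expect_section("FRAMES")
  frames <- array(0, c(T, n_rows, n_cols))
  for (t in seq_len(T)) {
    if (i > length(lines) || !identical(lines[i], paste("FRAME", t)))
      stop("truncated or corrupted file at frame ", t)
    i <- i + 1L
    if (i + n_rows - 1L > length(lines))
      stop("truncated file: incomplete frame ", t)
    block <- lines[i:(i + n_rows - 1L)]
    vals <- lapply(block, function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]]))
    if (any(lengths(vals) != n_cols)) stop("corrupted frame ", t, ": wrong column count")
    frames[t, , ] <- do.call(rbind, vals)
    i <- i + n_rows
  }
  ne <- expect_section("EVENTS")
  ev <- event_list()
  if (ne > 0L) {
    m <- do.call(rbind, lapply(lines[i:(i + ne - 1L)], function(s)
      as.integer(strsplit(s, " ", fixed = TRUE)[[1]])))
    ev <- event_list(m[, 1], m[, 2])
    i <- i + ne
  }
  nm <- expect_section("MASKS")
  masks <- list()
  for (k in seq_len(nm)) {
    tok <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (tok[1] != "MASK") stop("expected MASK header at line ", i)
    name <- tok[2]; type <- tok[3]; kk <- as.integer(tok[4])
    rule <- tok[5]; frac <- as.numeric(tok[6])
    i <- i + 1L
    body <- matrix(numeric(0), 0, 2)
    if (kk > 0L) {
      if (i + kk - 1L > length(lines)) stop("truncated mask '", name, "'")
      body <- do.call(rbind, lapply(lines[i:(i + kk - 1L)], function(s)
        as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])))
      i <- i + kk
    }
    masks[[name]] <- if (type == "polygon")
      pressure_mask(name, vertices = body, coverage_rule = rule, fraction = frac)
    else
      pressure_mask(name, cells = body, coverage_rule = rule, fraction = frac)
  }
  if (i > length(lines) || lines[i] != "END")
    stop("truncated file: missing END marker")
  grid <- sensor_grid(n_rows, n_cols,
                      dx = if (n_cols > 1) abs(cx[1, 2] - cx[1, 1]) else 5,
                      dy = if (n_rows > 1) abs(cy[1, 1] - cy[2, 1]) else 5,
                      centers = list(x = cx, y = cy), polygons = polys,
                      area = area, active = active)
  rec <- pressure_recording(frames, sr, grid, system = hdr$system,
                            side = hdr$side, events = ev, masks = masks)
  stop_if_invalid(rec)
  rec
}
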