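#' @keywords internal
"_PACKAGE"

# Conventions used throughout the package
# ---------------------------------------
# Pressures are kPa, lengths mm, sensor areas cm^2, forces N
# (1 kPa acting on 1 cm^2 is 0.1 N).  The frame array is indexed
# [frame, row, col] with frames 1-indexed; event intervals are inclusive on
# both ends.  Cell (row r, col c) has center x = (c-1)*dx, y = (n_rows-r)*dy
# for a regular grid: the origin sits at the bottom-left cell center, x grows
# with column index and y grows towards the top row, which after alignment
# points towards the toes.

cell_index <- function(r, c, n_cols) (r - 1L) * n_cols + c

#' Construct a sensor grid
#'
#' Describes the geometry of a pressure sensor array: per-cell center
#' coordinates, polygon outlines, areas and an active-cell map (inactive
#' cells model trimmed insole layouts and never carry pressure).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param dx,dy cell pitch in mm (used when `centers` is `NULL`).
#' @param centers optional list with matrices `x` and `y` (`n_rows` x
#'   `n_cols`, mm) of cell centers.
#' @param polygons optional list of length `n_rows * n_cols` (row-major) of
#'   m x 2 vertex matrices in mm; defaults to axis-aligned `dx` x `dy`
#'   rectangles around each center.
#' @param area optional matrix of per-cell sensor areas in cm^2; defaults to
#'   `dx * dy / 100`.
#' @param active optional logical matrix; defaults to all `TRUE`.
#' @return An object of class `sensor_grid`.
#' @export
sensor_grid <- function(n_rows, n_cols, dx = 5, dy = 5,
                        centers = NULL, polygons = NULL,
                        area = NULL, active = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, dx > 0, dy > 0)
  if (is.null(centers)) {
    cx <- matrix(rep((seq_len(n_cols) - 1) * dx, each = n_rows), n_rows, n_cols)
    cy <- matrix(rep((n_rows - seq_len(n_rows)) * dy, times = n_cols), n_rows, n_cols)
    centers <- list(x = cx, y = cy)
  }
  if (is.null(polygons)) {
    polygons <- vector("list", n_rows * n_cols)
    hx <- dx / 2; hy <- dy / 2
    for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
      x0 <- centers$x[r, c]; y0 <- centers$y[r, c]
      polygons[[cell_index(r, c, n_cols)]] <- cbind(
        x = x0 + c(-hx, hx, hx, -hx), y = y0 + c(-hy, -hy, hy, hy))
    }
  }
  if (is.null(area)) area <- matrix(dx * dy / 100, n_rows, n_cols)
  if (is.null(active)) active <- matrix(TRUE, n_rows, n_cols)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 centers = centers, polygons = polygons,
                 area = area, active = active, dx = dx, dy = dy),
            class = "sensor_grid")
}

#' Construct an event list
#'
#' Events mark steps (or other cycles) as inclusive `[start, end]` frame
#' intervals, sorted and non-overlapping.
#'
#' @param start,end integer vectors of equal length (1-indexed frames).
#' @return An object of class `event_list` (a 2-column integer matrix).
#' @export
event_list <- function(start = integer(0), end = integer(0)) {
  stopifnot(length(start) == length(end))
  m <- cbind(start = as.integer(start), end = as.integer(end))
  structure(m, class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat("<event_list> ", nrow(x), " interval(s)\n", sep = "")
  if (nrow(x)) print(unclass(x))
  invisible(x)
}

n_events <- function(ev) if (is.null(ev)) 0L else nrow(ev)

#' Construct a regional mask
#'
#' A mask names an anatomical region, defined either by a polygon in grid
#' coordinates (mm) or by an explicit set of sensor cells.  Polygon masks
#' carry a coverage rule deciding how partially covered sensors are treated:
#' `"center_in"` keeps a cell whose center lies inside (or on the boundary
#' of) the polygon; `"fraction_ge"` keeps a cell whose overlap fraction with
#' the polygon is at least `fraction`.
#'
#' @param name unique region label.
#' @param vertices m x 2 matrix of polygon vertices (mm), or `NULL`.
#' @param cells k x 2 matrix of (row, col) sensor indices, or `NULL`.
#'   Exactly one of `vertices`/`cells` must be given.
#' @param coverage_rule `"center_in"` or `"fraction_ge"`.
#' @param fraction threshold in `[0, 1]` for `"fraction_ge"`.
#' @return An object of class `pressure_mask`.
#' @export
pressure_mask <- function(name, vertices = NULL, cells = NULL,
                          coverage_rule = c("center_in", "fraction_ge"),
                          fraction = 0.5) {
  coverage_rule <- match.arg(coverage_rule)
  if (is.null(vertices) == is.null(cells))
    stop("give exactly one of `vertices` or `cells`")
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    if (nrow(unique(vertices)) < 3L)
      stop("polygon mask '", name, "' needs >= 3 distinct vertices")
    if (polygon_area_signed(vertices) == 0)
      stop("polygon mask '", name, "' has collinear vertices")
    type <- "polygon"
  } else {
    cells <- matrix(as.integer(as.matrix(cells)), ncol = 2)
    colnames(cells) <- c("row", "col")
    type <- "sensors"
  }
  stopifnot(fraction >= 0, fraction <= 1)
  structure(list(name = as.character(name), type = type,
                 vertices = vertices, cells = cells,
                 coverage_rule = coverage_rule, fraction = fraction),
            class = "pressure_mask")
}

PRESSURE_SYSTEMS <- c("emed", "pedar", "pliance", "tekscan", "footscan",
                      "synthetic")

#' Construct a standardized pressure recording
#'
#' The central container of the package: a frame series on a sensor grid
#' plus acquisition metadata, step events and regional masks.  All loaders
#' and the synthetic generator produce this object; all processing and
#' analysis functions consume it.
#'
#' @param frames numeric array `T x n_rows x n_cols` of pressures in kPa.
#' @param sampling_rate sampling frequency in Hz.
#' @param grid a [sensor_grid].
#' @param system hardware family label, one of
#'   `r paste0('"', PRESSURE_SYSTEMS, '"', collapse = ", ")`.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @param events an [event_list] (may be empty).
#' @param masks named list of [pressure_mask] objects.
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(frames, sampling_rate, grid,
                               system = "synthetic", side = "unknown",
                               events = event_list(), masks = list()) {
  if (length(dim(frames)) == 2L)
    frames <- array(frames, c(1L, dim(frames)))
  stopifnot(length(dim(frames)) == 3L)
  system <- match.arg(system, PRESSURE_SYSTEMS)
  side <- match.arg(side, c("left", "right", "unknown"))
  rec <- structure(list(frames = frames, sampling_rate = sampling_rate,
                        grid = grid, system = system, side = side,
                        events = events, masks = masks),
                   class = "pressure_recording")
  rec
}

n_frames <- function(rec) dim(rec$frames)[1L]

#' @export
print.pressure_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat("<pressure_recording> ", x$system, ", side ", x$side, "\n",
      "  ", d[1L], " frames @ ", x$sampling_rate, " Hz on a ",
      d[2L], " x ", d[3L], " grid (", sum(x$grid$active),
      " active cells)\n", sep = "")
  if (n_events(x$events))
    cat("  events: ", n_events(x$events), "\n", sep = "")
  if (length(x$masks))
    cat("  masks: ", paste(names(x$masks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pressure_recording <- function(object, ...) {
  f <- whole_pressure_curve(object, "force")
  cat("Duration: ", (n_frames(object) - 1) / object$sampling_rate, " s\n",
      "Peak force: ", round(max(f$values), 1), " N\n",
      "Peak pressure: ", round(max(object$frames), 1), " kPa\n", sep = "")
  print(object)
}

#' Validate a pressure recording
#'
#' Checks every structural invariant of the data model (finite non-negative
#' pressures, positive areas on active cells, silent inactive cells, sane
#' events and masks) and reports all violations found.  Never modifies the
#' recording.
#'
#' @param rec a [pressure_recording].
#' @return An object of class `recording_validation` with elements `ok`
#'   (logical) and `issues` (character vector of violations).
#' @export
validate_recording <- function(rec) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!inherits(rec, "pressure_recording")) {
    add("not a pressure_recording")
    return(structure(list(ok = FALSE, issues = issues),
                     class = "recording_validation"))
  }
  d <- dim(rec$frames); T <- d[1L]; g <- rec$grid
  if (d[2L] != g$n_rows || d[3L] != g$n_cols)
    add(sprintf("frame dims %dx%d do not match grid %dx%d",
                d[2L], d[3L], g$n_rows, g$n_cols))
  if (T < 1L) add("recording has no frames")
  if (!is.finite(rec$sampling_rate) || rec$sampling_rate <= 0)
    add("sampling_rate must be > 0")
  bad <- which(!is.finite(rec$frames) | rec$frames < 0, arr.ind = TRUE)
  if (nrow(bad))
    add(sprintf("negative or non-finite pressure at (t=%d, r=%d, c=%d)",
                bad[1, 1], bad[1, 2], bad[1, 3]))
  if (any(!is.finite(g$area[g$active]) | g$area[g$active] <= 0))
    add("active cell with non-positive or non-finite area")
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    p <- g$polygons[[cell_index(r, c, g$n_cols)]]
    if (!point_in_polygon(g$centers$x[r, c], g$centers$y[r, c], p))
      add(sprintf("center of cell (%d,%d) outside its polygon", r, c))
    if (!polygon_is_simple(p))
      add(sprintf("self-intersecting polygon at cell (%d,%d)", r, c))
  }
  if (any(!g$active)) {
    inact <- which(!g$active, arr.ind = TRUE)
    for (i in seq_len(nrow(inact))) {
      if (any(rec$frames[, inact[i, 1], inact[i, 2]] > 0)) {
        add(sprintf("inactive cell (%d,%d) carries pressure",
                    inact[i, 1], inact[i, 2]))
        break
      }
    }
  }
  ev <- rec$events
  if (n_events(ev)) {
    if (any(ev[, "start"] > ev[, "end"])) add("event start > end")
    if (any(ev[, "start"] < 1L) || any(ev[, "end"] > T))
      add(sprintf("event outside frame range [1, %d]", T))
    if (nrow(ev) > 1L) {
      if (is.unsorted(ev[, "start"])) add("events not sorted")
      if (any(ev[-1L, "start"] <= ev[-nrow(ev), "end"]))
        add("overlapping events")
    }
  }
  if (length(rec$masks)) {
    nm <- vapply(rec$masks, `[[`, "", "name")
    if (anyDuplicated(nm)) add("duplicate mask names")
    for (m in rec$masks) {
      if (m$type == "sensors" && nrow(m$cells) &&
          (any(m$cells[, 1] < 1L | m$cells[, 1] > g$n_rows) ||
           any(m$cells[, 2] < 1L | m$cells[, 2] > g$n_cols)))
        add(sprintf("mask '%s' references out-of-grid cells", m$name))
    }
  }
  structure(list(ok = length(issues) == 0L, issues = issues),
            class = "recording_validation")
}

#' @export
print.recording_validation <- function(x, ...) {
  if (x$ok) cat("recording OK\n")
  else cat("recording INVALID:\n", paste0("  - ", x$issues, "\n"), sep = "")
  invisible(x)
}

stop_if_invalid <- function(rec) {
  v <- validate_recording(rec)
  if (!v$ok) stop("invalid recording: ", paste(v$issues, collapse = "; "))
  invisible(rec)
}
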