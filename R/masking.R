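# Regional masks: manual polygons/sensor sets, sensor assignment with
# partial-coverage rules, template insole schemes, and the automatic
# 10-region barefoot algorithm.

#' Masking scheme geometry for the automatic barefoot algorithm
#'
#' Longitudinal split fractions of measured foot length (heel, midfoot,
#' forefoot, toes) and mediolateral width fractions (medial to lateral)
#' inside the forefoot and toe bands.  Each group must sum to 1.  The
#' defaults follow literature-typical foot proportions and are fully
#' overridable.
#'
#' @param long_fracs named fractions of foot length for heel, midfoot,
#'   forefoot and toes.
#' @param forefoot_fracs width fractions, medial to lateral, for MTH1-5.
#' @param toe_fracs width fractions for hallux, toe2 and toes3-5.
#' @return An object of class `masking_scheme`.
#' @export
masking_scheme <- function(long_fracs = c(heel = 0.30, midfoot = 0.25,
                                          forefoot = 0.27, toes = 0.18),
                           forefoot_fracs = c(MTH1 = 0.30, MTH2 = 0.20,
                                              MTH3 = 0.175, MTH4 = 0.175,
                                              MTH5 = 0.15),
                           toe_fracs = c(hallux = 0.35, toe2 = 0.20,
                                         toes3_5 = 0.45)) {
  for (fr in list(long_fracs, forefoot_fracs, toe_fracs))
    if (abs(sum(fr) - 1) > 1e-9) stop("split fractions must sum to 1")
  structure(list(long_fracs = long_fracs, forefoot_fracs = forefoot_fracs,
                 toe_fracs = toe_fracs), class = "masking_scheme")
}

#' Assign sensors to a mask
#'
#' Resolves a mask to the set of active sensor cells it covers.  For
#' sensor-set masks this is the stored set (restricted to active cells).
#' For polygon masks the coverage rule decides how partially covered cells
#' are treated: `"center_in"` includes a cell iff its center lies inside or
#' on the boundary of the polygon; `"fraction_ge"` includes a cell iff the
#' fraction of its own polygon overlapped by the mask polygon is at least
#' the mask's `fraction` (exact polygon clipping, no sampling).
#'
#' @param mask a [pressure_mask].
#' @param grid a [sensor_grid].
#' @param coverage_rule optional override of the mask's own rule.
#' @param fraction optional override of the mask's threshold.
#' @return A list with `cells` (k x 2 row/col matrix) and `coverage`
#'   (overlap fraction per assigned cell; 1 for center_in/sensor sets).
#' @export
assign_sensors <- function(mask, grid, coverage_rule = NULL, fraction = NULL) {
  rule <- coverage_rule %||% mask$coverage_rule
  frac <- fraction %||% mask$fraction
  if (mask$type == "sensors") {
    keep <- grid$active[mask$cells]
    return(list(cells = mask$cells[keep, , drop = FALSE],
                coverage = rep(1, sum(keep))))
  }
  idx <- which(grid$active)
  if (rule == "center_in") {
    inside <- points_in_polygon(grid$centers$x[idx], grid$centers$y[idx],
                                mask$vertices)
    cells <- arrayInd(idx[inside], dim(grid$active))
    colnames(cells) <- c("row", "col")
    return(list(cells = cells, coverage = rep(1, sum(inside))))
  }
  cov <- vapply(idx, function(i) {
    rc <- arrayInd(i, dim(grid$active))
    cell_coverage_fraction(mask$vertices,
                           grid$polygons[[cell_index(rc[1], rc[2], grid$n_cols)]])
  }, numeric(1))
  keep <- cov >= frac & cov > 0
  cells <- arrayInd(idx[keep], dim(grid$active))
  colnames(cells) <- c("row", "col")
  list(cells = cells, coverage = cov[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add manually defined masks to a recording
#'
#' The programmatic equivalent of outlining regions on a plot: each
#' definition is either an ordered vertex matrix (mm) or an explicit
#' (row, col) sensor set.
#'
#' @param rec a [pressure_recording].
#' @param definitions list of m x 2 matrices: polygon vertices when
#'   `definition = "by_vertices"`, sensor (row, col) indices when
#'   `"by_sensors"`.
#' @param names one unique name per definition.
#' @param definition `"by_vertices"` or `"by_sensors"`.
#' @param coverage_rule,fraction partial-coverage rule for polygon masks,
#'   see [assign_sensors()].
#' @return The recording with the new masks appended.
#' @export
create_mask_manual <- function(rec, definitions, names,
                               definition = c("by_vertices", "by_sensors"),
                               coverage_rule = "center_in", fraction = 0.5) {
  definition <- match.arg(definition)
  stopifnot(length(definitions) == length(names))
  if (anyDuplicated(c(names, vapply(rec$masks, `[[`, "", "name"))))
    stop("duplicate mask name")
  for (i in seq_along(definitions)) {
    m <- if (definition == "by_vertices")
      pressure_mask(names[i], vertices = definitions[[i]],
                    coverage_rule = coverage_rule, fraction = fraction)
    else
      pressure_mask(names[i], cells = definitions[[i]],
                    coverage_rule = coverage_rule, fraction = fraction)
    rec$masks[[m$name]] <- m
  }
  rec
}

#' Edit the vertices of a polygon mask
#'
#' Moves selected vertices of an existing polygon mask to new positions,
#' the programmatic equivalent of dragging vertices on a plot.  Old
#' vertices are matched to the mask's vertices within `snap_tol` mm.
#'
#' @param rec a [pressure_recording].
#' @param mask_name name of a polygon-defined mask.
#' @param old_vertices,new_vertices k x 2 matrices: each old vertex is
#'   replaced by the corresponding new one.
#' @param snap_tol matching tolerance in mm.
#' @return The recording with the edited mask.
#' @export
edit_mask <- function(rec, mask_name, old_vertices, new_vertices,
                      snap_tol = 5) {
  m <- rec$masks[[mask_name]]
  if (is.null(m)) stop("mask not found: ", mask_name)
  if (m$type != "polygon") stop("mask '", mask_name, "' is not polygon-defined")
  old_vertices <- matrix(old_vertices, ncol = 2)
  new_vertices <- matrix(new_vertices, ncol = 2)
  stopifnot(nrow(old_vertices) == nrow(new_vertices))
  v <- m$vertices
  for (i in seq_len(nrow(old_vertices))) {
    d <- sqrt((v[, 1] - old_vertices[i, 1])^2 + (v[, 2] - old_vertices[i, 2])^2)
    j <- which.min(d)
    if (d[j] > snap_tol)
      stop("no vertex of '", mask_name, "' within ", snap_tol, " mm of (",
           old_vertices[i, 1], ", ", old_vertices[i, 2], ")")
    v[j, ] <- new_vertices[i, ]
  }
  rec$masks[[mask_name]] <- pressure_mask(mask_name, vertices = v,
                                          coverage_rule = m$coverage_rule,
                                          fraction = m$fraction)
  rec
}

#' Automatic regional masks
#'
#' For barefoot platform data (`scheme = "automask_novel"`) the footprint
#' (cells whose max-over-time pressure exceeds `threshold`) is aligned to
#' its principal axis and oriented by COP travel; the measured foot length
#' is split longitudinally into heel / midfoot / forefoot / toes, the
#' forefoot band mediolaterally into MTH1-MTH5 and the toe band into
#' hallux / toe2 / toes3-5, producing exactly 10 sensor-set masks that
#' partition the footprint.  Cells on a split line go to the more
#' posterior / more medial region.  For in-shoe data the three bundled
#' pedar template schemes assign the 99 insole sensors to 3, 9 or 10
#' regions from editable tables under `inst/extdata` (approximations of
#' published schemes).
#'
#' @param rec a [pressure_recording].
#' @param scheme `"automask_novel"`, `"pedar_mask1"`, `"pedar_mask2"` or
#'   `"pedar_mask3"`.
#' @param foot_side `"left"`, `"right"` or `"auto"` (uses
#'   [auto_detect_side()], falling back to the recording's stored side).
#' @param threshold footprint activity threshold in kPa.
#' @param config a [masking_scheme] with the split fractions.
#' @return The recording with the scheme's masks appended.
#' @export
create_mask_auto <- function(rec, scheme = c("automask_novel", "pedar_mask1",
                                             "pedar_mask2", "pedar_mask3"),
                             foot_side = "auto", threshold = 5,
                             config = masking_scheme()) {
  scheme <- match.arg(scheme)
  if (scheme != "automask_novel")
    return(apply_pedar_template(rec, scheme, foot_side))
  al <- align_footprint(rec, threshold)  # errors when no footprint
  side <- resolve_side(rec, foot_side)
  f <- al$s / al$L                       # longitudinal fraction from heel
  lf <- cumsum(config$long_fracs)        # band upper edges
  # boundary cells go posterior: band k is (lf[k-1], lf[k]]
  band <- findInterval(f, c(lf[1], lf[2], lf[3]), left.open = TRUE) + 1L
  medial_frac <- function(sel) {
    m <- al$m[sel]
    rng <- range(m)
    if (diff(rng) == 0) return(rep(0, sum(sel)))
    if (side == "right") (m - rng[1]) / diff(rng) else (rng[2] - m) / diff(rng)
  }
  region <- character(length(f))
  region[band == 1L] <- "heel"
  region[band == 2L] <- "midfoot"
  ff <- band == 3L
  if (any(ff)) {
    edges <- cumsum(config$forefoot_fracs)
    g <- medial_frac(ff)
    k <- findInterval(g, edges[-length(edges)], left.open = TRUE) + 1L
    region[ff] <- names(config$forefoot_fracs)[k]
  }
  tb <- band == 4L
  if (any(tb)) {
    edges <- cumsum(config$toe_fracs)
    g <- medial_frac(tb)
    k <- findInterval(g, edges[-length(edges)], left.open = TRUE) + 1L
    region[tb] <- names(config$toe_fracs)[k]
  }
  labels <- c("heel", "midfoot", names(config$forefoot_fracs),
              names(config$toe_fracs))
  dims <- dim(rec$grid$active)
  for (lab in labels) {
    cells <- arrayInd(al$cells[region == lab], dims)
    colnames(cells) <- c("row", "col")
    rec$masks[[lab]] <- pressure_mask(lab, cells = cells)
  }
  rec$side <- side
  rec
}

resolve_side <- function(rec, foot_side) {
  if (foot_side %in% c("left", "right")) return(foot_side)
  if (foot_side != "auto") stop("unknown foot_side: ", foot_side)
  if (rec$side %in% c("left", "right")) return(rec$side)
  side <- auto_detect_side(rec)
  if (side == "unknown")
    stop("could not determine foot side: ", attr(side, "reason"))
  as.character(side)
}

apply_pedar_template <- function(rec, scheme, foot_side) {
  g <- rec$grid
  layout <- pedar_layout_99()
  if (g$n_rows != layout$n_rows || g$n_cols != layout$n_cols ||
      !identical(unname(g$active), unname(layout$active)))
    stop(scheme, " requires the 99-sensor insole layout")
  side <- if (foot_side %in% c("left", "right")) foot_side
    else if (rec$side %in% c("left", "right")) rec$side
    else stop("insole template schemes need an explicit foot_side")
  path <- system.file("extdata", paste0(scheme, ".csv"), package = "pedobaR",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cells <- pedar_sensor_cells()
  for (lab in unique(tab$region)) {
    cc <- cells[tab$sensor[tab$region == lab], , drop = FALSE]
    if (side == "left") cc[, 2] <- g$n_cols + 1L - cc[, 2]
    rec$masks[[lab]] <- pressure_mask(lab, cells = cc)
  }
  rec$side <- side
  rec
}

# All mask assignments of a recording, as a named list.
mask_assignments <- function(rec) {
  lapply(rec$masks, assign_sensors, grid = rec$grid)
}
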