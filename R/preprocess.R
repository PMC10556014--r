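# Whole-recording curves, step events, temporal interpolation, side
# detection and center of pressure.

# Regional force in N at every frame: 0.1 * sum(p * a) over the given cells
# (logical matrix or index matrix), since 1 kPa on 1 cm^2 is 0.1 N.
force_series <- function(rec, cells = NULL) {
  g <- rec$grid; T <- n_frames(rec)
  w <- g$area * g$active
  if (!is.null(cells)) {
    sel <- matrix(FALSE, g$n_rows, g$n_cols)
    if (is.logical(cells)) sel <- cells else sel[cells] <- TRUE
    w <- w * sel
  }
  0.1 * vapply(seq_len(T), function(t) sum(rec$frames[t, , ] * w), numeric(1))
}

#' Whole-foot summary curve
#'
#' Collapses every frame to a single number: total force (N), spatial peak
#' pressure (kPa), or loaded contact area (cm^2, cells with pressure
#' strictly above `area_threshold`).
#'
#' @param rec a [pressure_recording].
#' @param variable `"force"`, `"peak_pressure"` or `"contact_area"`.
#' @param area_threshold kPa threshold for the contact-area variable.
#' @return An object of class `whole_curve`: list with `variable`, `values`
#'   (length-T series), `units` and `sampling_rate`.
#' @export
whole_pressure_curve <- function(rec, variable = c("force", "peak_pressure",
                                                   "contact_area"),
                                 area_threshold = 5) {
  variable <- match.arg(variable)
  g <- rec$grid; T <- n_frames(rec)
  act <- g$active
  values <- switch(variable,
    force = force_series(rec),
    peak_pressure = vapply(seq_len(T), function(t)
      max(rec$frames[t, , ][act], 0), numeric(1)),
    contact_area = vapply(seq_len(T), function(t)
      sum(g$area[act & rec$frames[t, , ] > area_threshold]), numeric(1)))
  units <- c(force = "N", peak_pressure = "kPa", contact_area = "cm2")[[variable]]
  structure(list(variable = variable, values = values, units = units,
                 sampling_rate = rec$sampling_rate),
            class = "whole_curve")
}

#' @export
print.whole_curve <- function(x, ...) {
  cat("<whole_curve> ", x$variable, " [", x$units, "], ",
      length(x$values), " frames, max ", round(max(x$values), 2), "\n", sep = "")
  invisible(x)
}

#' Interpolate a recording to a fixed number of frames
#'
#' Linearly interpolates every sensor's time series onto a uniform
#' parameter over `[0, 1]`, so that steps can be expressed in percent of
#' stance (the conventional choice is 101 frames = 0..100%).  The first and
#' last frames are preserved exactly and the sampling rate is rescaled so
#' the recording duration is unchanged.  Event frames are rescaled
#' proportionally.
#'
#' @param rec a [pressure_recording] with at least 2 frames.
#' @param interp_to target frame count (>= 2), default 101.
#' @return The interpolated [pressure_recording].
#' @export
pressure_interp <- function(rec, interp_to = 101) {
  T <- n_frames(rec)
  if (interp_to < 2) stop("interp_to must be >= 2")
  if (T < 2) stop("cannot interpolate a single-frame recording")
  s_old <- seq(0, 1, length.out = T)
  s_new <- seq(0, 1, length.out = interp_to)
  d <- dim(rec$frames)
  old <- matrix(rec$frames, T, d[2] * d[3])
  new <- apply(old, 2, function(y) stats::approx(s_old, y, xout = s_new)$y)
  frames <- array(new, c(interp_to, d[2], d[3]))
  duration <- (T - 1) / rec$sampling_rate
  ev <- rec$events
  if (n_events(ev)) {
    scale <- (interp_to - 1) / (T - 1)
    ev <- event_list(round((ev[, "start"] - 1L) * scale) + 1L,
                     round((ev[, "end"] - 1L) * scale) + 1L)
  }
  pressure_recording(frames, (interp_to - 1) / duration, rec$grid,
                     system = rec$system, side = rec$side, events = ev,
                     masks = rec$masks)
}

#' Detect steps from the force curve
#'
#' Identifies steps as maximal runs of frames whose total force is at or
#' above `force_threshold` (hysteresis of one frame: a run is entered at
#' the first frame >= threshold and left at the first frame below it).
#' Runs shorter than `min_duration` are dropped, then the first
#' `discard_first` runs (typically gait initiation), then an optional
#' `keep` index list replaces the interactive keep/discard prompt.
#'
#' @param rec a [pressure_recording].
#' @param force_threshold N, default 10.
#' @param min_duration minimum step duration in s, default 0.15.
#' @param discard_first number of leading steps to drop.
#' @param keep optional integer vector selecting among the remaining steps.
#' @return An [event_list] of inclusive frame intervals.  Assign it to
#'   `rec$events` to store it on the recording.  If the threshold exceeds
#'   the global force maximum an empty list is returned with a warning.
#' @export
select_steps <- function(rec, force_threshold = 10, min_duration = 0.15,
                         discard_first = 0, keep = NULL) {
  stopifnot(force_threshold > 0)
  f <- force_series(rec)
  if (max(f) < force_threshold) {
    warning("force never reaches threshold; no steps detected")
    return(event_list())
  }
  above <- f >= force_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  starts <- starts[sel]; ends <- ends[sel]
  dur <- (ends - starts) / rec$sampling_rate
  long <- dur >= min_duration
  starts <- starts[long]; ends <- ends[long]
  if (discard_first > 0 && length(starts)) {
    idx <- seq_along(starts) > discard_first
    starts <- starts[idx]; ends <- ends[idx]
  }
  if (!is.null(keep)) {
    starts <- starts[keep]; ends <- ends[keep]
  }
  event_list(starts, ends)
}

# Footprint alignment shared by side detection, automask and CPEI.
# Footprint cells are those whose max-over-time pressure exceeds
# `threshold` kPa.  The principal axis of the (pressure-weighted) cell
# cloud gives the long axis; it is oriented toe-ward using the direction of
# COP travel from the first to the last valid frame.  Returns per-footprint
# cell longitudinal (s, mm from heel end) and mediolateral (m, mm) aligned
# coordinates plus the transform.
align_footprint <- function(rec, threshold = 5) {
  g <- rec$grid
  pmax_cell <- apply(rec$frames, c(2, 3), max)
  fp <- g$active & pmax_cell > threshold
  if (!any(fp)) stop("no footprint detected above ", threshold, " kPa")
  idx <- which(fp)
  x <- g$centers$x[idx]; y <- g$centers$y[idx]; w <- pmax_cell[idx]
  pa <- principal_axis(x, y, w)
  axis <- pa$axis
  f <- force_series(rec)
  tr <- cop(rec, force_threshold = 0.05 * max(f))  # ignore noise-only frames
  v <- which(tr$valid)
  if (length(v) >= 2) {
    travel <- tr$points[v[length(v)], ] - tr$points[v[1], ]
    if (sum(travel * axis) < 0) axis <- -axis
  } else if (axis[2] < 0) axis <- -axis  # static trial: assume toes up
  perp <- c(axis[2], -axis[1])  # points to the viewer's right of the axis
  s <- (x - pa$center[1]) * axis[1] + (y - pa$center[2]) * axis[2]
  m <- (x - pa$center[1]) * perp[1] + (y - pa$center[2]) * perp[2]
  s0 <- min(s)
  list(cells = idx, fp = fp, s = s - s0, m = m, L = max(s) - s0,
       center = pa$center, axis = axis, perp = perp, s0 = s0,
       weight = w)
}

#' Detect whether a barefoot recording is a left or right foot
#'
#' Aligns the footprint to its principal axis (toe direction resolved by
#' the travel of the center of pressure) and classifies by the signed
#' mediolateral offset of the anterior-third pressure centroid: the bulk of
#' forefoot load (MTH1, hallux) lies medially.  When the offset is smaller
#' than `margin` times the footprint width the result is `"unknown"` with
#' a diagnostic attribute rather than a guess.
#'
#' @param rec a barefoot single-step [pressure_recording].
#' @param threshold footprint activity threshold in kPa.
#' @param margin confidence margin as a fraction of footprint width.
#' @return `"left"`, `"right"` or `"unknown"` (with attribute `reason`).
#' @export
auto_detect_side <- function(rec, threshold = 5, margin = 0.05) {
  al <- align_footprint(rec, threshold)
  width <- diff(range(al$m))
  ant <- al$s > 2 / 3 * al$L
  if (!any(ant)) {
    return(structure("unknown", reason = "no anterior-third footprint"))
  }
  m_mid <- mean(range(al$m))
  offset <- sum(al$weight[ant] * al$m[ant]) / sum(al$weight[ant]) - m_mid
  if (abs(offset) < margin * width) {
    return(structure("unknown",
                     reason = sprintf(
                       "anterior centroid offset %.2f mm below confidence margin %.2f mm",
                       offset, margin * width)))
  }
  # viewed from above with toes pointing away, the medial (hallux) side of a
  # right foot lies to the viewer's left, i.e. at negative m
  if (offset < 0) "right" else "left"
}

#' Center of pressure trajectory
#'
#' The per-frame force-weighted centroid of the pressure distribution.
#' Frames whose total force is below `force_threshold` (or with no load at
#' all) are marked invalid.
#'
#' @param rec a [pressure_recording].
#' @param force_threshold N; frames below it get no COP point.
#' @return An object of class `cop_trajectory`: list with `points` (T x 2
#'   matrix of x, y in mm, `NA` where invalid) and `valid` (logical).
#' @export
cop <- function(rec, force_threshold = 0) {
  g <- rec$grid; T <- n_frames(rec)
  wa <- g$area * g$active
  pts <- matrix(NA_real_, T, 2, dimnames = list(NULL, c("x", "y")))
  valid <- logical(T)
  for (t in seq_len(T)) {
    w <- rec$frames[t, , ] * wa
    tot <- sum(w)
    if (tot > 0 && 0.1 * tot >= force_threshold) {
      pts[t, ] <- c(sum(w * g$centers$x), sum(w * g$centers$y)) / tot
      valid[t] <- TRUE
    }
  }
  structure(list(points = pts, valid = valid), class = "cop_trajectory")
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat("<cop_trajectory> ", sum(x$valid), "/", length(x$valid),
      " valid frames\n", sep = "")
  invisible(x)
}
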