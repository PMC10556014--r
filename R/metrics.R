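# Regional and whole-foot pressure variables.
#
# Conventions (documented, overridable):
#   peak pressure (sensor)  max over assigned cells and frames, kPa
#   FTI                     trapezoidal integral of regional force, N*s
#   PTI (Melai)             FTI / A, with A the region's peak contact area
#   PTI (spatial-peak)      trapezoidal integral of the regional spatial
#                           peak pressure series, kPa*s
#   contact time            time with regional force > 0 (sum of dt between
#                           consecutive loaded frames), s
#   peak pressure (mean)    temporal mean of the spatial peak over contact
#                           frames (named unambiguously: the mean is
#                           temporal, the peak spatial)

MASK_VARIABLES <- c("press_peak_sensor", "press_peak_mean", "force_max",
                    "contact_area_peak", "contact_time", "fti", "pti_melai",
                    "pti_peak")

METRIC_UNITS <- c(press_peak_sensor = "kPa", press_peak_mean = "kPa",
                  force_max = "N", contact_area_peak = "cm2",
                  contact_time = "s", fti = "N*s", pti_melai = "N*s/cm2",
                  pti_peak = "kPa*s")

trapz <- function(y, dt) if (length(y) < 2) 0 else dt * (sum(y) - (y[1] + y[length(y)]) / 2)

# Per-region series needed by all metrics.
region_series <- function(rec, cells) {
  k <- nrow(cells)
  T <- n_frames(rec)
  mat <- matrix(0, T, k)
  for (j in seq_len(k)) mat[, j] <- rec$frames[, cells[j, 1], cells[j, 2]]
  a <- rec$grid$area[cells]
  list(p = mat, a = a,
       force = 0.1 * as.vector(mat %*% a),
       spatial_peak = apply(mat, 1, max))
}

#' Regional pressure variables
#'
#' Computes pressure, force and contact metrics for every mask on the
#' recording.  See the package vignette for the exact definition of each
#' variable; in particular the two pressure-time integrals are exposed
#' under distinct names (`pti_melai` = FTI / peak regional contact area;
#' `pti_peak` = time integral of the regional spatial peak pressure) since
#' the literature uses both under the one name "PTI".
#'
#' @param rec a [pressure_recording] with at least one mask.
#' @param variable one or more of
#'   `r paste0('"', MASK_VARIABLES, '"', collapse = ", ")`.
#' @param area_threshold kPa threshold above which a cell counts as in
#'   contact (contact area, contact frames).
#' @return A `region_table` data frame with columns region, metric, value,
#'   units.
#' @export
mask_analysis <- function(rec, variable = "press_peak_sensor",
                          area_threshold = 0) {
  variable <- match.arg(variable, MASK_VARIABLES, several.ok = TRUE)
  if (!length(rec$masks)) stop("recording has no masks")
  dt <- 1 / rec$sampling_rate
  out <- list()
  for (m in rec$masks) {
    asg <- assign_sensors(m, rec$grid)
    if (nrow(asg$cells) == 0L)
      stop("mask '", m$name, "' has zero assigned cells")
    rs <- region_series(rec, asg$cells)
    contact <- rs$force > 0
    ca <- as.vector((rs$p > area_threshold) %*% rs$a)
    vals <- vapply(variable, function(v) switch(v,
      press_peak_sensor = max(rs$p),
      press_peak_mean = if (any(contact)) mean(rs$spatial_peak[contact]) else 0,
      force_max = max(rs$force),
      contact_area_peak = max(ca),
      contact_time = sum(contact[-1] & contact[-length(contact)]) * dt,
      fti = trapz(rs$force, dt),
      pti_melai = trapz(rs$force, dt) / max(ca),
      pti_peak = trapz(rs$spatial_peak, dt)), numeric(1))
    out[[m$name]] <- data.frame(region = m$name, metric = variable,
                                value = unname(vals),
                                units = unname(METRIC_UNITS[variable]),
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("region_table", "data.frame")
  res
}

#' @export
print.region_table <- function(x, ...) {
  cat("Regional pressure variables\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Geometric core of the CPEI: works on COP points expressed in aligned
# foot coordinates (s: mm from heel end along the foot axis; m_med: mm,
# positive towards the medial border).  The construction line joins the
# first COP point to either the most medial COP point of the anterior
# third of the foot ("tangent", the medial-border tangent) or the last COP
# point ("chord").  The deviation is the perpendicular distance from that
# line to the COP path where it crosses the anterior trisection boundary
# (s = 2/3 L), signed positive for lateral deviation, and the CPEI is
# 100 * deviation / forefoot width.
cpei_from_aligned <- function(s, m_med, L, forefoot_width,
                              construction = c("tangent", "chord")) {
  construction <- match.arg(construction)
  if (forefoot_width <= 0) stop("degenerate forefoot width")
  n <- length(s)
  if (n < 3) stop("need at least 3 COP points")
  p0 <- c(s[1], m_med[1])
  if (construction == "chord") {
    p1 <- c(s[n], m_med[n])
  } else {
    ant <- which(s > 2 / 3 * L)
    if (!length(ant)) stop("no COP points in the anterior third")
    j <- ant[which.max(m_med[ant])]
    p1 <- c(s[j], m_med[j])
  }
  if (all(p1 == p0)) stop("degenerate construction line")
  s_star <- 2 / 3 * L
  cross <- which(s[-n] <= s_star & s[-1] > s_star)
  if (!length(cross)) {
    # path never crosses the boundary going forward; use the closest point
    i <- which.min(abs(s - s_star))
    q <- c(s[i], m_med[i])
  } else {
    i <- cross[1]
    f <- (s_star - s[i]) / (s[i + 1] - s[i])
    q <- c(s_star, m_med[i] + f * (m_med[i + 1] - m_med[i]))
  }
  d <- point_line_signed_distance(q[1], q[2], p0, p1)
  # orient the sign so that lateral (negative m_med side of the line) is
  # positive regardless of the line direction
  ref <- point_line_signed_distance(q[1], q[2] - 1, p0, p1) -
    point_line_signed_distance(q[1], q[2], p0, p1)
  deviation <- d * sign(ref)
  list(cpei = 100 * deviation / forefoot_width, deviation = deviation,
       trisection_point = q, line = rbind(p0, p1),
       forefoot_width = forefoot_width)
}

#' Center of pressure excursion index
#'
#' Quantifies how far the COP path bows away from the medial border of the
#' foot: the footprint is aligned to its principal axis, a construction
#' line is drawn from the first COP point to the most medial COP point of
#' the anterior third of the foot (its medial-border tangent; a
#' first-to-last chord variant is available), and the perpendicular
#' distance from this line to the COP path at the anterior trisection
#' boundary is expressed as a percentage of the forefoot width.  Positive
#' values mean lateral deviation.
#'
#' @param rec a barefoot single-step [pressure_recording] with at least 3
#'   COP frames.
#' @param force_threshold N; frames below it contribute no COP point.
#' @param threshold footprint activity threshold (kPa).
#' @param construction `"tangent"` (default) or `"chord"`.
#' @param side `"left"`/`"right"`; defaults to the recording's stored side
#'   or, failing that, [auto_detect_side()].
#' @return An object of class `cpei_result`: list with `cpei` (percent),
#'   `deviation` (mm), `forefoot_width` (mm), `cop_points` (plate mm),
#'   `construction_line` (2 x 2, plate mm), `side`.
#' @export
cpei <- function(rec, force_threshold = 0, threshold = 5,
                 construction = c("tangent", "chord"), side = NULL) {
  construction <- match.arg(construction)
  tr <- cop(rec, force_threshold)
  v <- which(tr$valid)
  if (length(v) < 3) stop("COP computable on fewer than 3 frames")
  al <- align_footprint(rec, threshold)
  if (is.null(side)) {
    side <- if (rec$side %in% c("left", "right")) rec$side
      else auto_detect_side(rec, threshold)
    if (side == "unknown")
      stop("foot side undeterminable: ", attr(side, "reason"))
  }
  pts <- tr$points[v, , drop = FALSE]
  rel_x <- pts[, 1] - al$center[1]; rel_y <- pts[, 2] - al$center[2]
  s <- rel_x * al$axis[1] + rel_y * al$axis[2] - al$s0
  m <- rel_x * al$perp[1] + rel_y * al$perp[2]
  m_med <- if (side == "right") -m else m
  ff <- al$s / al$L > 0.55 & al$s / al$L <= 0.82
  if (!any(ff)) stop("no footprint cells in the forefoot band")
  w <- diff(range(al$m[ff]))
  res <- cpei_from_aligned(s, m_med, al$L, w, construction)
  to_plate <- function(sm) {
    mm <- if (side == "right") -sm[2] else sm[2]
    al$center + al$axis * (sm[1] + al$s0) + al$perp * mm
  }
  structure(list(cpei = res$cpei, deviation = res$deviation,
                 forefoot_width = w, cop_points = pts,
                 construction_line = rbind(to_plate(res$line[1, ]),
                                           to_plate(res$line[2, ])),
                 trisection_point = to_plate(res$trisection_point),
                 side = side, construction = construction),
            class = "cpei_result")
}

#' @export
print.cpei_result <- function(x, ...) {
  cat(sprintf("CPEI: %.2f%% (%s foot, deviation %.2f mm / forefoot width %.2f mm)\n",
              x$cpei, x$side, x$deviation, x$forefoot_width))
  invisible(x)
}

#' Dynamic plantar loading index
#'
#' A dimensionless measure of how well a peak-pressure-versus-time series
#' follows a normal (Gaussian) shape: a scaled Gaussian
#' `a * exp(-(t - mu)^2 / (2 * sigma^2))` is least-squares fitted
#' (Levenberg-Marquardt, moment initialisation) and the DPLI is `1 - R^2`
#' of the fit, clipped to `[0, 1]`.  0 means a perfectly normal loading
#' curve; larger values mean increasingly irregular loading.
#'
#' @param curve non-negative numeric series (length >= 5) with a positive
#'   maximum, or a `whole_curve`.
#' @return DPLI in `[0, 1]`.
#' @export
dpli <- function(curve) {
  y <- if (inherits(curve, "whole_curve")) curve$values else as.numeric(curve)
  if (length(y) < 5) stop("need at least 5 frames")
  if (any(y < 0)) stop("series must be non-negative")
  if (max(y) == 0) stop("all-zero series")
  t <- seq_along(y)
  a0 <- max(y); mu0 <- t[which.max(y)]
  half <- which(y >= a0 / 2)
  w <- max(1L, diff(range(half)))
  s0 <- max(w / (2 * sqrt(2 * log(2))), 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(t - mu)^2 / (2 * sg^2)),
                      start = list(a = a0, mu = mu0, sg = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ss_res <- if (is.null(fit)) {
    # degenerate series (e.g. flat curves) can defeat Levenberg-Marquardt;
    # fall back to direct simplex minimisation of the same least squares
    sse <- function(p) sum((y - p[1] * exp(-(t - p[2])^2 / (2 * p[3]^2)))^2)
    stats::optim(c(a0, mu0, s0), sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$value
  } else sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  # a constant series is the infinite-sigma limit of the Gaussian: R^2 is
  # degenerate there and the loading curve is perfectly smooth, so score 0
  if (ss_tot < 1e-12 * max(y)^2) return(0)
  min(1, max(0, ss_res / ss_tot))
}
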