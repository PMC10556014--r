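# Synthetic gait generator: physiologically plausible pressure recordings
# with known ground truth (site cell sets, side, contact windows), so that
# step detection, side detection, masking and the regional metrics can be
# validated without external data.

# Default anatomical sites for a right foot, in foot-frame mm: x runs
# medial (0) to lateral, y runs heel (0) to toes.  Loads are isotropic
# Gaussian patches truncated at 2.2 sd (compact contact patches), each with
# a raised-cosine on/peak/off activation expressed as a fraction of stance.
# Positions and patch sizes are chosen so that each site's core sits inside
# the anatomical region a standard 10-region barefoot scheme assigns to it;
# peak magnitudes are typical adult barefoot values.
default_sites <- function() {
  data.frame(
    name   = c("heel", "arch", "MTH1", "MTH2", "MTH3", "MTH4", "MTH5",
               "hallux", "toe2", "toes3_5"),
    x      = c(47.5, 62, 15.4, 40, 58.75, 76.25, 89, 19.3, 36.5, 60.7),
    y      = c(35, 115, 170, 174, 175, 174, 171, 228, 226, 224),
    sd     = c(14, 11, 7, 6, 6, 6, 5, 6.5, 5, 6.5),
    peak   = c(400, 60, 450, 380, 330, 280, 220, 350, 150, 120),
    onset  = c(0.00, 0.15, 0.25, 0.25, 0.26, 0.27, 0.27, 0.45, 0.48, 0.48),
    peak_t = c(0.22, 0.45, 0.72, 0.70, 0.70, 0.70, 0.68, 0.85, 0.82, 0.80),
    offset = c(0.58, 0.78, 0.97, 0.97, 0.96, 0.96, 0.95, 1.00, 1.00, 1.00),
    region = c("heel", "midfoot", "MTH1", "MTH2", "MTH3", "MTH4", "MTH5",
               "hallux", "toe2", "toes3_5"),
    stringsAsFactors = FALSE)
}

#' Define a synthetic foot model
#'
#' Describes the anatomy and loading pattern of a simulated foot: ten
#' anatomical sites (heel, arch, MTH1-5, hallux, toe2, toes3-5), each a
#' compact Gaussian pressure patch with its own peak pressure and
#' activation window, plus sensor noise and seeded trial-to-trial jitter.
#' The `"inshoe"` preset spreads the patches and lowers the peaks, as an
#' insole between foot and sensor does.
#'
#' @param preset `"barefoot"` (platform trial) or `"inshoe"`.
#' @param side `"left"` or `"right"`.
#' @param foot_length,foot_width nominal foot dimensions in mm.
#' @param sites optional data frame replacing the default site table
#'   (columns name, x, y, sd, peak, onset, peak_t, offset, region).
#' @param noise_sd sensor noise standard deviation in kPa (additive,
#'   truncated at zero).
#' @param rotation_deg mean foot axis rotation on the plate (toe-out).
#' @param jitter if `TRUE`, seeded per-trial jitter is applied to rotation
#'   (+-4 deg), position (+-3 mm) and site peaks (5%).
#' @param seed integer seed driving all randomness.
#' @return An object of class `foot_model`.
#' @export
foot_model <- function(preset = c("barefoot", "inshoe"), side = "right",
                       foot_length = 250, foot_width = 100, sites = NULL,
                       noise_sd = 0.5, rotation_deg = 7, jitter = TRUE,
                       seed = 1L) {
  preset <- match.arg(preset)
  side <- match.arg(side, c("left", "right"))
  if (is.null(sites)) sites <- default_sites()
  if (preset == "inshoe") {
    sites$sd <- sites$sd * 1.6
    sites$peak <- sites$peak * 0.6
  }
  stopifnot(all(sites$peak > 0), all(sites$sd > 0),
            all(sites$onset < sites$peak_t),
            all(sites$peak_t < sites$offset))
  structure(list(preset = preset, side = side, foot_length = foot_length,
                 foot_width = foot_width, sites = sites, noise_sd = noise_sd,
                 rotation_deg = rotation_deg, jitter = jitter,
                 seed = as.integer(seed)),
            class = "foot_model")
}

# Raised-cosine activation: 0 outside [onset, offset], 1 at peak_t.
activation_profile <- function(s, onset, peak_t, offset) {
  g <- numeric(length(s))
  r <- s >= onset & s <= peak_t
  g[r] <- 0.5 - 0.5 * cos(pi * (s[r] - onset) / (peak_t - onset))
  f <- s > peak_t & s <= offset
  g[f] <- 0.5 + 0.5 * cos(pi * (s[f] - peak_t) / (offset - peak_t))
  g
}

TRUNCATION_SD <- 2.2  # contact patch support radius in units of site sd

# Site centers in plate-frame mm after mirroring (left feet), rotation and
# translation.  Returns a matrix with one row per site.
place_sites <- function(model, rot_deg, shift) {
  s <- model$sites
  x <- s$x; y <- s$y
  if (model$side == "left") x <- model$foot_width - x
  th <- rot_deg * pi / 180
  ctr <- c(model$foot_width / 2, model$foot_length / 2)
  xr <- ctr[1] + cos(th) * (x - ctr[1]) - sin(th) * (y - ctr[2]) + shift[1]
  yr <- ctr[2] + sin(th) * (x - ctr[1]) + cos(th) * (y - ctr[2]) + shift[2]
  cbind(x = xr, y = yr)
}

#' Generate a synthetic barefoot platform trial
#'
#' Simulates a single barefoot step on a pressure platform from a
#' [foot_model]: per-cell pressure is the sum of the site patches times
#' their activation profiles, plus truncated-at-zero Gaussian sensor noise.
#' Returns the recording together with its ground truth, which downstream
#' tests use as the oracle.
#'
#' @param model a [foot_model].
#' @param dx,dy sensor pitch in mm.  An error is raised when the grid is
#'   too coarse to resolve the smallest site (fewer than 2 cells per sd).
#' @param sampling_rate Hz.
#' @param stance_duration stance time in s.
#' @param margin plate margin around the footprint in mm.
#' @return A list with elements `rec` (a [pressure_recording], side set
#'   from the model) and `truth` (side, per-site core cell sets and the
#'   region each belongs to, site centers in plate mm, contact frame
#'   window).
#' @export
generate_footprint <- function(model, dx = 2.5, dy = 2.5,
                               sampling_rate = 100, stance_duration = 0.7,
                               margin = 15) {
  stopifnot(inherits(model, "foot_model"))
  if (min(model$sites$sd) < 2 * max(dx, dy))
    stop("grid too coarse to resolve sites: fewer than 2 cells per site sd")
  set.seed(model$seed)
  rot <- model$rotation_deg
  shift <- c(0, 0)
  amp <- rep(1, nrow(model$sites))
  if (model$jitter) {
    rot <- rot + stats::runif(1, -4, 4)
    shift <- stats::runif(2, -3, 3)
    amp <- 1 + stats::rnorm(nrow(model$sites), 0, 0.05)
  }
  ctr <- place_sites(model, rot, shift)
  rad <- TRUNCATION_SD * model$sites$sd
  x0 <- min(ctr[, 1] - rad) - margin; x1 <- max(ctr[, 1] + rad) + margin
  y0 <- min(ctr[, 2] - rad) - margin; y1 <- max(ctr[, 2] + rad) + margin
  n_cols <- ceiling((x1 - x0) / dx) + 1L
  n_rows <- ceiling((y1 - y0) / dy) + 1L
  grid <- sensor_grid(n_rows, n_cols, dx = dx, dy = dy)
  # shift site centers into grid coordinates (origin bottom-left cell center)
  ctr[, 1] <- ctr[, 1] - x0; ctr[, 2] <- ctr[, 2] - y0
  T <- round(stance_duration * sampling_rate) + 1L
  s <- seq(0, 1, length.out = T)
  cx <- as.vector(grid$centers$x); cy <- as.vector(grid$centers$y)
  frames <- matrix(0, T, n_rows * n_cols)
  site_cells <- vector("list", nrow(ctr))
  act_any <- numeric(T)
  for (i in seq_len(nrow(ctr))) {
    d2 <- (cx - ctr[i, 1])^2 + (cy - ctr[i, 2])^2
    map <- amp[i] * model$sites$peak[i] * exp(-d2 / (2 * model$sites$sd[i]^2))
    map[d2 > rad[i]^2] <- 0
    g <- activation_profile(s, model$sites$onset[i], model$sites$peak_t[i],
                            model$sites$offset[i])
    frames <- frames + outer(g, map)
    act_any <- act_any + g
    core <- which(d2 <= (0.75 * model$sites$sd[i])^2)
    site_cells[[i]] <- cbind(row = (core - 1L) %% n_rows + 1L,
                             col = (core - 1L) %/% n_rows + 1L)
  }
  if (model$noise_sd > 0)
    frames[] <- pmax(0, frames + stats::rnorm(length(frames), 0, model$noise_sd))
  arr <- array(0, c(T, n_rows, n_cols))
  for (t in seq_len(T)) arr[t, , ] <- matrix(frames[t, ], n_rows, n_cols)
  rec <- pressure_recording(arr, sampling_rate, grid, system = "synthetic",
                            side = model$side)
  names(site_cells) <- model$sites$name
  contact <- range(which(act_any > 0))
  truth <- list(side = model$side, site_cells = site_cells,
                site_region = stats::setNames(model$sites$region,
                                              model$sites$name),
                centers_mm = ctr, contact = contact)
  list(rec = rec, truth = truth)
}

#' Generate a synthetic multi-step in-shoe trial
#'
#' Concatenates several stance phases separated by swing phases (zero load
#' apart from sensor noise) on the bundled 99-sensor insole layout,
#' mimicking a pedar-style in-shoe trial.  The ground-truth contact windows
#' are returned for validating step detection.
#'
#' @param model a [foot_model]; the `"inshoe"` preset is the natural choice.
#' @param n_steps number of steps (>= 1).
#' @param sampling_rate Hz.
#' @param stance_duration stance time per step in s.
#' @param swing_fraction fraction of each gait cycle spent in swing,
#'   strictly inside (0, 1).
#' @return A list with elements `rec` (a [pressure_recording] on the
#'   trimmed insole grid) and `truth` (an [event_list] of ground-truth
#'   contact windows).
#' @export
generate_multistep <- function(model, n_steps = 3, sampling_rate = 50,
                               stance_duration = 0.6, swing_fraction = 0.35) {
  stopifnot(inherits(model, "foot_model"), n_steps >= 1)
  if (swing_fraction <= 0 || swing_fraction >= 1)
    stop("swing_fraction must be strictly between 0 and 1")
  set.seed(model$seed)
  grid <- pedar_layout_99()
  # map the foot frame onto the insole extent
  ins_w <- max(grid$centers$x) ; ins_l <- max(grid$centers$y)
  sc_x <- (ins_w * 0.9) / model$foot_width
  sc_y <- (ins_l * 0.95) / model$foot_length
  sx <- model$sites$x; if (model$side == "left") sx <- model$foot_width - sx
  ctr <- cbind(x = sx * sc_x + ins_w * 0.05, y = model$sites$y * sc_y + ins_l * 0.02)
  rad <- TRUNCATION_SD * model$sites$sd * mean(c(sc_x, sc_y))
  sdm <- model$sites$sd * mean(c(sc_x, sc_y))
  T_st <- round(stance_duration * sampling_rate) + 1L
  T_sw <- max(2L, round(stance_duration * swing_fraction /
                          (1 - swing_fraction) * sampling_rate))
  T <- n_steps * T_st + (n_steps + 1L) * T_sw
  s <- seq(0, 1, length.out = T_st)
  nc <- grid$n_rows * grid$n_cols
  cx <- as.vector(grid$centers$x); cy <- as.vector(grid$centers$y)
  stance <- matrix(0, T_st, nc)
  act_any <- numeric(T_st)
  for (i in seq_len(nrow(ctr))) {
    d2 <- (cx - ctr[i, 1])^2 + (cy - ctr[i, 2])^2
    map <- model$sites$peak[i] * exp(-d2 / (2 * sdm[i]^2))
    map[d2 > rad[i]^2] <- 0
    g <- activation_profile(s, model$sites$onset[i], model$sites$peak_t[i],
                            model$sites$offset[i])
    stance <- stance + outer(g, map)
    act_any <- act_any + g
  }
  stance[, !as.vector(grid$active)] <- 0
  frames <- matrix(0, T, nc)
  starts <- integer(n_steps)
  for (k in seq_len(n_steps)) {
    t0 <- T_sw + (k - 1L) * (T_st + T_sw)
    frames[t0 + seq_len(T_st), ] <- stance
    starts[k] <- t0 + 1L
  }
  if (model$noise_sd > 0) {
    act <- as.vector(grid$active)
    noise <- matrix(0, T, nc)
    noise[, act] <- stats::rnorm(T * sum(act), 0, model$noise_sd)
    frames[] <- pmax(0, frames + noise)
  }
  arr <- array(0, c(T, grid$n_rows, grid$n_cols))
  for (t in seq_len(T)) arr[t, , ] <- matrix(frames[t, ], grid$n_rows, grid$n_cols)
  rec <- pressure_recording(arr, sampling_rate, grid, system = "synthetic",
                            side = model$side)
  contact_local <- range(which(act_any > 0))
  truth_ev <- event_list(starts + contact_local[1] - 1L,
                         starts + contact_local[2] - 1L)
  list(rec = rec, truth = list(events = truth_ev, side = model$side))
}

#' Mirror a recording about its vertical axis
#'
#' Flips the recording left-to-right (columns reversed, geometry mirrored),
#' turning a right-foot recording into the corresponding left-foot one.
#' The stored side label is flipped accordingly.
#'
#' @param rec a [pressure_recording].
#' @return The mirrored [pressure_recording].
#' @export
mirror_recording <- function(rec) {
  g <- rec$grid
  rev_cols <- rev(seq_len(g$n_cols))
  xmax <- max(g$centers$x)
  cx <- xmax - g$centers$x[, rev_cols, drop = FALSE]
  cy <- g$centers$y[, rev_cols, drop = FALSE]
  polys <- vector("list", g$n_rows * g$n_cols)
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    p <- g$polygons[[cell_index(r, rev_cols[c], g$n_cols)]]
    pm <- cbind(x = xmax - p[, 1], y = p[, 2])
    polys[[cell_index(r, c, g$n_cols)]] <- pm[rev(seq_len(nrow(pm))), , drop = FALSE]
  }
  grid <- sensor_grid(g$n_rows, g$n_cols, dx = g$dx, dy = g$dy,
                      centers = list(x = cx, y = cy), polygons = polys,
                      area = g$area[, rev_cols, drop = FALSE],
                      active = g$active[, rev_cols, drop = FALSE])
  masks <- lapply(rec$masks, function(m) {
    if (m$type == "polygon") {
      v <- cbind(xmax - m$vertices[, 1], m$vertices[, 2])
      pressure_mask(m$name, vertices = v[rev(seq_len(nrow(v))), ],
                    coverage_rule = m$coverage_rule, fraction = m$fraction)
    } else {
      cells <- cbind(m$cells[, 1], g$n_cols + 1L - m$cells[, 2])
      pressure_mask(m$name, cells = cells, coverage_rule = m$coverage_rule,
                    fraction = m$fraction)
    }
  })
  side <- c(left = "right", right = "left", unknown = "unknown")[[rec$side]]
  pressure_recording(rec$frames[, , rev_cols, drop = FALSE],
                     rec$sampling_rate, grid, system = rec$system,
                     side = side, events = rec$events, masks = masks)
}
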