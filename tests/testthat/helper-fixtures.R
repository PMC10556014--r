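# Shared fixture builders and independent oracles.  Everything here is
# deliberately written as directly as possible (double loops, exhaustive
# scans, grid searches) so it stays independent of the implementation it
# checks.

# A tiny recording built by hand: frames is T x R x C (or a matrix for a
# single frame); every cell active with the given area (cm^2).
tiny_rec <- function(frames, sampling_rate = 100, dx = 5, dy = 5,
                     area = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(1, dim(frames)))
  g <- sensor_grid(dim(frames)[2], dim(frames)[3], dx = dx, dy = dy)
  if (!is.null(area)) g$area[] <- area
  pressure_recording(frames, sampling_rate, g)
}

# A quick low-resolution synthetic foot (coarse grid allowed by scaling the
# model down is not possible -> use the default grid but fewer frames).
quick_foot <- function(seed = 1, side = "right", stance_duration = 0.4) {
  generate_footprint(foot_model(side = side, seed = seed),
                     stance_duration = stance_duration)
}

# Exhaustive-force oracle: plain double loop over cells.
force_oracle <- function(rec) {
  g <- rec$grid
  out <- numeric(dim(rec$frames)[1])
  for (t in seq_along(out)) {
    acc <- 0
    for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols))
      if (g$active[r, c]) acc <- acc + rec$frames[t, r, c] * g$area[r, c]
    out[t] <- 0.1 * acc
  }
  out
}

# Exhaustive spatial/temporal max over a cell subset.
peak_oracle <- function(rec, cells) {
  best <- -Inf
  for (t in seq_len(dim(rec$frames)[1]))
    for (j in seq_len(nrow(cells)))
      best <- max(best, rec$frames[t, cells[j, 1], cells[j, 2]])
  best
}

# Brute-force weighted centroid for one frame.
cop_oracle <- function(rec, t) {
  g <- rec$grid
  sx <- sy <- sw <- 0
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    if (!g$active[r, c]) next
    w <- rec$frames[t, r, c] * g$area[r, c]
    sx <- sx + w * g$centers$x[r, c]
    sy <- sy + w * g$centers$y[r, c]
    sw <- sw + w
  }
  c(sx, sy) / sw
}

# Independent point-in-polygon via dense ray casting on a slightly jittered
# point (used only where boundary cases are not at stake).
pip_oracle <- function(px, py, v) {
  n <- nrow(v); cross <- 0
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > py) != (v[j, 2] > py)) {
      xint <- v[i, 1] + (py - v[i, 2]) / (v[j, 2] - v[i, 2]) * (v[j, 1] - v[i, 1])
      if (px < xint) cross <- cross + 1
    }
    j <- i
  }
  cross %% 2 == 1
}

# Coarse-to-fine grid-search Gaussian fit: independent oracle for dpli().
dpli_oracle <- function(y) {
  t <- seq_along(y); n <- length(y)
  best <- c(a = max(y), mu = which.max(y), sg = n / 4)
  ranges <- list(a = max(y) * c(0.3, 2), mu = c(1 - n / 4, n + n / 4),
                 sg = c(0.3, 1.5 * n))
  sse <- function(p) sum((y - p[1] * exp(-(t - p[2])^2 / (2 * p[3]^2)))^2)
  for (stage in 1:4) {
    grid_a <- seq(ranges$a[1], ranges$a[2], length.out = 15)
    grid_mu <- seq(ranges$mu[1], ranges$mu[2], length.out = 15)
    grid_sg <- seq(ranges$sg[1], ranges$sg[2], length.out = 15)
    best_sse <- Inf
    for (a in grid_a) for (mu in grid_mu) for (sg in grid_sg) {
      s <- sse(c(a, mu, sg))
      if (s < best_sse) { best_sse <- s; best <- c(a, mu, sg) }
    }
    shrink <- function(rng, ctr) {
      w <- diff(rng) / 4
      c(ctr - w, ctr + w)
    }
    ranges <- list(a = shrink(ranges$a, best[1]),
                   mu = shrink(ranges$mu, best[2]),
                   sg = pmax(1e-3, shrink(ranges$sg, best[3])))
  }
  # local polish of the grid optimum (Nelder-Mead; independent of the
  # Levenberg-Marquardt path used by the implementation)
  pol <- stats::optim(best, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  ss_res <- min(sse(best), pol$value)
  ss_tot <- sum((y - mean(y))^2)
  # shared degenerate-case convention: constant series score 0
  if (ss_tot < 1e-12 * max(y)^2) return(0)
  min(1, max(0, ss_res / ss_tot))
}

# Minimal GIF structure parser (independent of the encoder): returns the
# number of image descriptors and the per-frame delays in 1/100 s.
parse_gif <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  stopifnot(rawToChar(b[1:6]) %in% c("GIF87a", "GIF89a"))
  packed <- as.integer(b[11])
  i <- 14L
  if (bitwAnd(packed, 0x80L) > 0)
    i <- i + 3L * 2L^(bitwAnd(packed, 7L) + 1L)
  frames <- 0L; delays <- integer(0)
  skip_subblocks <- function(i) {
    repeat {
      len <- as.integer(b[i])
      i <- i + 1L + len
      if (len == 0L) return(i)
    }
  }
  while (i <= length(b)) {
    tag <- as.integer(b[i])
    if (tag == 0x3B) break
    if (tag == 0x21) {
      label <- as.integer(b[i + 1L])
      if (label == 0xF9)
        delays <- c(delays, as.integer(b[i + 4L]) + 256L * as.integer(b[i + 5L]))
      i <- skip_subblocks(i + 2L)
    } else if (tag == 0x2C) {
      frames <- frames + 1L
      pk <- as.integer(b[i + 9L])
      i <- i + 10L
      if (bitwAnd(pk, 0x80L) > 0) i <- i + 3L * 2L^(bitwAnd(pk, 7L) + 1L)
      i <- skip_subblocks(i + 1L)
    } else stop("unexpected GIF block tag: ", tag)
  }
  list(frames = frames, delays = delays)
}

read_bytes <- function(path) readBin(path, "raw", file.size(path))
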