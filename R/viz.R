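# Footprint plots and GIF animation.
#
# Rendering is done into an explicit palette-indexed pixel raster (one
# cell_px x cell_px block per sensor cell) so that output bytes are fully
# deterministic: identical recording + spec give identical files.

# Default 8-bin scale approximating the conventional pressure-plot palette;
# breaks in kPa.  Both are documented, overridable defaults.
DEFAULT_BREAKS <- c(15, 40, 60, 100, 150, 220, 300)
DEFAULT_COLORS <- c("#C8E4F8", "#7FB8E6", "#3C8DD0", "#53C978",
                    "#F5E663", "#F5A742", "#E8503A", "#F272B4")

NAMED_PLOT_COLORS <- c(light_blue = "#ADD8E6", light_green = "#90EE90",
                       yellow = "#FFFF00", pink = "#FFC0CB",
                       red = "#FF0000", orange = "#FFA500",
                       blue = "#0000FF", green = "#008000",
                       white = "#FFFFFF", black = "#000000")

resolve_color <- function(x) {
  x <- ifelse(x %in% names(NAMED_PLOT_COLORS), NAMED_PLOT_COLORS[x], x)
  grDevices::col2rgb(x)  # 3 x n, 0..255
}

#' Plot specification for pressure images
#'
#' @param variable `"max"` (max over time per cell), `"mean"` (mean over
#'   time) or `"frame"` (a single frame, give `frame`).
#' @param frame frame index for `variable = "frame"`.
#' @param plot_colors `"default"` or `"custom"`.
#' @param break_values strictly ascending pressure bin edges in kPa
#'   (custom mode).
#' @param break_colors one more color than break values; values at or
#'   below the first break get the first color, values above the last
#'   break the last color.
#' @param plot_COP overlay the center-of-pressure path.
#' @param plot_outline overlay the convex hull outline of the footprint.
#' @param sensor_outline draw individual sensor cell outlines.
#' @param legend draw a color legend strip.
#' @param cell_px rendered pixels per sensor cell.
#' @param outline_threshold kPa; cells above it count as footprint for the
#'   hull outline.
#' @return An object of class `plot_spec`.
#' @export
plot_spec <- function(variable = c("max", "mean", "frame"), frame = NULL,
                      plot_colors = c("default", "custom"),
                      break_values = DEFAULT_BREAKS,
                      break_colors = DEFAULT_COLORS,
                      plot_COP = FALSE, plot_outline = FALSE,
                      sensor_outline = TRUE, legend = TRUE, cell_px = 6,
                      outline_threshold = 5) {
  variable <- match.arg(variable)
  plot_colors <- match.arg(plot_colors)
  if (plot_colors == "default") {
    break_values <- DEFAULT_BREAKS
    break_colors <- DEFAULT_COLORS
  }
  if (is.unsorted(break_values, strictly = TRUE))
    stop("break_values must be strictly ascending")
  if (length(break_colors) != length(break_values) + 1L)
    stop("need exactly one more color than break values")
  structure(list(variable = variable, frame = frame,
                 break_values = break_values, break_colors = break_colors,
                 plot_COP = plot_COP, plot_outline = plot_outline,
                 sensor_outline = sensor_outline, legend = legend,
                 cell_px = as.integer(cell_px),
                 outline_threshold = outline_threshold),
            class = "plot_spec")
}

#' Map pressure values to color bins
#'
#' Bin boundaries are inclusive on the lower color: with breaks
#' `(100, 200, 300)`, a value of 100 maps to the first color, 101 to the
#' second, and anything above 300 to the last.  Values of 0 (and below)
#' map to the first bin.
#'
#' @param value numeric pressures in kPa.
#' @param spec a [plot_spec], or a numeric vector of ascending breaks.
#' @return Integer bin indices in `1 .. length(breaks) + 1`, indexing the
#'   spec's `break_colors`.
#' @export
color_bin <- function(value, spec = plot_spec()) {
  breaks <- if (inherits(spec, "plot_spec")) spec$break_values else spec
  if (is.unsorted(breaks, strictly = TRUE))
    stop("break_values must be strictly ascending")
  findInterval(value, breaks, left.open = TRUE) + 1L
}

# mm -> pixel center transforms for a regular grid raster.
raster_transform <- function(grid, cell_px) {
  x0 <- min(grid$centers$x); ymax <- max(grid$centers$y)
  list(
    px = function(x) (x - x0) / grid$dx * cell_px + cell_px / 2,
    py = function(y) (ymax - y) / grid$dy * cell_px + cell_px / 2)
}

draw_line_idx <- function(idx, x0, y0, x1, y1, code) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  keep <- xs >= 1 & xs <= ncol(idx) & ys >= 1 & ys <= nrow(idx)
  idx[cbind(ys[keep], xs[keep])] <- code
  idx
}

# Render a palette-indexed raster.  Returns list(index, palette, layers):
# index is an H x W integer matrix of 1-based palette entries; palette a
# K x 3 matrix of 0..255 RGB rows.  Palette order: white background, the
# bin colors, then black (outline), COP green, sensor-outline gray.
render_pressure_raster <- function(rec, spec) {
  g <- rec$grid; p <- spec$cell_px
  T <- n_frames(rec)
  V <- switch(spec$variable,
    max = apply(rec$frames, c(2, 3), max),
    mean = apply(rec$frames, c(2, 3), mean),
    frame = {
      if (is.null(spec$frame) || spec$frame < 1 || spec$frame > T)
        stop("frame index out of range [1, ", T, "]")
      rec$frames[spec$frame, , ]
    })
  nb <- length(spec$break_colors)
  pal <- rbind(c(255, 255, 255), t(resolve_color(spec$break_colors)),
               c(0, 0, 0), c(0, 100, 0), c(90, 90, 90))
  BG <- 1L; BIN0 <- 1L  # bins occupy entries 2 .. nb + 1
  OUTLINE <- nb + 2L; COP <- nb + 3L; SENS <- nb + 4L
  legend_w <- if (spec$legend) 4L * p else 0L
  H <- g$n_rows * p; W <- g$n_cols * p + legend_w
  idx <- matrix(BG, H, W)
  bins <- matrix(color_bin(V, spec), g$n_rows, g$n_cols)
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    if (!g$active[r, c]) next
    rows <- ((r - 1L) * p + 1L):(r * p)
    cols <- ((c - 1L) * p + 1L):(c * p)
    idx[rows, cols] <- BIN0 + bins[r, c]
    if (spec$sensor_outline) {
      idx[rows[1], cols] <- SENS; idx[rows[p], cols] <- SENS
      idx[rows, cols[1]] <- SENS; idx[rows, cols[p]] <- SENS
    }
  }
  layers <- "cells"
  if (spec$sensor_outline) layers <- c(layers, "sensor_outline")
  tf <- raster_transform(g, p)
  if (spec$plot_outline) {
    loaded <- which(g$active & V > spec$outline_threshold)
    if (length(loaded)) {
      vx <- vy <- numeric(0)
      for (i in loaded) {
        poly <- g$polygons[[{
          rc <- arrayInd(i, dim(g$active))
          cell_index(rc[1], rc[2], g$n_cols)
        }]]
        vx <- c(vx, poly[, 1]); vy <- c(vy, poly[, 2])
      }
      hull <- convex_hull(vx, vy)
      nh <- nrow(hull)
      for (k in seq_len(nh)) {
        a <- hull[k, ]; b <- hull[(k %% nh) + 1L, ]
        idx <- draw_line_idx(idx, tf$px(a[1]), tf$py(a[2]),
                             tf$px(b[1]), tf$py(b[2]), OUTLINE)
      }
      layers <- c(layers, "outline")
    }
  }
  if (spec$plot_COP) {
    tr <- cop(rec)
    v <- which(tr$valid)
    if (length(v) >= 2) {
      for (k in seq_len(length(v) - 1L)) {
        a <- tr$points[v[k], ]; b <- tr$points[v[k + 1L], ]
        idx <- draw_line_idx(idx, tf$px(a[1]), tf$py(a[2]),
                             tf$px(b[1]), tf$py(b[2]), COP)
      }
      layers <- c(layers, "cop")
    }
  }
  if (spec$legend) {
    sw_h <- max(1L, H %/% (nb + 2L))
    for (b in seq_len(nb)) {
      rows <- (H - b * sw_h + 1L):(H - (b - 1L) * sw_h)
      cols <- (g$n_cols * p + p):(g$n_cols * p + 3L * p)
      idx[rows, cols] <- BIN0 + b
    }
    layers <- c(layers, "legend")
  }
  list(index = idx, palette = pal, layers = layers)
}

#' Plot a pressure footprint to a PNG file
#'
#' Renders the per-cell maximum, mean or single-frame pressures as a
#' color-binned footprint image with optional COP path, footprint convex
#' hull outline, sensor outlines and legend.  Rendering is deterministic:
#' the same recording and spec always produce identical bytes.
#'
#' @param rec a [pressure_recording].
#' @param spec a [plot_spec].
#' @param path output PNG path.
#' @return Invisibly, a manifest list: `width`, `height`, active `layers`,
#'   and the palette `index` raster.
#' @export
plot_pressure <- function(rec, spec = plot_spec(), path) {
  ras <- render_pressure_raster(rec, spec)
  h <- nrow(ras$index); w <- ncol(ras$index)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(ras$palette[ras$index, ch] / 255, h, w)
  png::writePNG(img, path)
  invisible(list(width = w, height = h, layers = ras$layers,
                 index = ras$index, path = path))
}

#' Export a GIF animation of the pressure data
#'
#' Renders every frame with the given spec (any `variable` setting is
#' overridden per frame) and writes an animated GIF with one image per
#' recording frame at the requested frame rate.
#'
#' @param rec a [pressure_recording] with at least 2 frames.
#' @param spec a [plot_spec]; `legend`/overlay settings apply per frame.
#' @param fps frames per second (GIF delays are in 1/100 s; fps is rounded
#'   to the nearest representable delay).
#' @param path output GIF path.
#' @param keep_frames if `TRUE`, the per-frame index rasters are included
#'   in the returned manifest.
#' @return Invisibly, a manifest: `n_frames`, `delay_cs`, `width`,
#'   `height`, and optionally `frames`.
#' @export
animate_pressure <- function(rec, spec = plot_spec(), fps = 25, path,
                             keep_frames = FALSE) {
  T <- n_frames(rec)
  if (T < 2) stop("animation needs at least 2 frames")
  frames <- vector("list", T)
  pal <- NULL
  for (t in seq_len(T)) {
    sp <- spec; sp$variable <- "frame"; sp$frame <- t
    ras <- render_pressure_raster(rec, sp)
    frames[[t]] <- ras$index - 1L  # 0-based palette indices
    pal <- ras$palette
  }
  delay_cs <- max(1L, round(100 / fps))
  write_gif(frames, pal, delay_cs, path)
  out <- list(n_frames = T, delay_cs = delay_cs,
              width = ncol(frames[[1]]), height = nrow(frames[[1]]),
              path = path)
  if (keep_frames) out$frames <- frames
  invisible(out)
}

# ---- minimal GIF89a encoder -------------------------------------------------
# LZW output uses literal codes at fixed width with periodic clear codes
# (the standard uncompressed-GIF technique), which keeps the encoder simple
# and the bit packing fully vectorized.

u16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

write_gif <- function(frames, palette, delay_cs, path, loop = TRUE) {
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  ncol_pal <- nrow(palette)
  m <- max(2L, ceiling(log2(ncol_pal)))
  gct <- matrix(0L, 2L^m, 3L)
  gct[seq_len(ncol_pal), ] <- round(palette)
  out <- c(charToRaw("GIF89a"), u16(w), u16(h),
           as.raw(bitwOr(0xF0L, m - 1L)), as.raw(0), as.raw(0),
           as.raw(as.integer(t(gct))))
  if (loop)
    out <- c(out, as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01, 0x00, 0x00, 0x00)))
  for (f in frames) {
    out <- c(out,
             as.raw(c(0x21, 0xF9, 0x04, 0x00)), u16(delay_cs),
             as.raw(c(0x00, 0x00)),
             as.raw(0x2C), u16(0L), u16(0L), u16(w), u16(h), as.raw(0x00),
             as.raw(m), lzw_literal(as.integer(t(f)), m))
    }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(out, as.raw(0x3B)), con)
  invisible(path)
}

# Encode pixel stream as fixed-width literal LZW codes with clears.
lzw_literal <- function(pix, min_code_size) {
  clear <- 2L^min_code_size
  eoi <- clear + 1L
  width <- min_code_size + 1L
  run <- 2L^min_code_size - 3L  # literals between clears: table never grows
  n <- length(pix)
  n_chunks <- ceiling(n / run)
  codes <- integer(n + n_chunks + 2L)
  pos <- 1L
  codes[pos] <- clear; pos <- pos + 1L
  for (k in seq_len(n_chunks)) {
    seg <- pix[((k - 1L) * run + 1L):min(k * run, n)]
    codes[pos:(pos + length(seg) - 1L)] <- seg
    pos <- pos + length(seg)
    if (k < n_chunks) {
      codes[pos] <- clear; pos <- pos + 1L
    }
  }
  codes[pos] <- eoi
  codes <- codes[seq_len(pos)]
  bits <- matrix(0L, width, length(codes))
  for (b in seq_len(width))
    bits[b, ] <- bitwAnd(bitwShiftR(codes, b - 1L), 1L)
  bv <- as.logical(as.vector(bits))
  pad <- (-length(bv)) %% 8L
  if (pad) bv <- c(bv, rep(FALSE, pad))
  bytes <- packBits(bv, type = "raw")
  # chunk into <= 255-byte sub-blocks, terminated by a zero block
  nb <- length(bytes)
  starts <- seq(1L, nb, by = 255L)
  blocks <- lapply(starts, function(s) {
    seg <- bytes[s:min(s + 254L, nb)]
    c(as.raw(length(seg)), seg)
  })
  c(do.call(c, blocks), as.raw(0))
}
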