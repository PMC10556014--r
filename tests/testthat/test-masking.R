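test_that("manual polygon masks assign exactly the covered sensor centers", {
  rec <- tiny_rec(array(10, c(1, 5, 5)))  # centers at 0,5,..,20 in x and y
  sq <- cbind(c(2, 13, 13, 2), c(2, 2, 13, 13))  # covers centers 5 and 10
  rec <- create_mask_manual(rec, list(sq), "sq")
  asg <- assign_sensors(rec$masks$sq, rec$grid)
  expect_identical(nrow(asg$cells), 4L)
  # brute-force point-in-polygon over every cell
  g <- rec$grid
  expected <- 0L
  for (r in 1:5) for (c in 1:5)
    if (pip_oracle(g$centers$x[r, c], g$centers$y[r, c], sq))
      expected <- expected + 1L
  expect_identical(nrow(asg$cells), expected)

  expect_error(create_mask_manual(rec, list(sq), "sq"), "duplicate")
  expect_error(create_mask_manual(rec, list(cbind(c(0, 1), c(0, 1))), "bad"),
               "vertices")
})

test_that("explicit sensor-set masks are assigned verbatim", {
  rec <- tiny_rec(array(1, c(1, 3, 3)))
  cells <- cbind(c(1, 1), c(1, 2))
  rec <- create_mask_manual(rec, list(cells), "pair",
                            definition = "by_sensors")
  asg <- assign_sensors(rec$masks$pair, rec$grid)
  expect_equal(unname(asg$cells), unname(cells))
})

test_that("fraction_ge uses exact overlap areas and center_in counts boundaries", {
  rec <- tiny_rec(array(1, c(1, 3, 3)))  # cells 5x5 mm
  g <- rec$grid
  cellpoly <- g$polygons[[pedobaR:::cell_index(2, 2, 3)]]

  # the cell's own polygon covers it fully
  m <- pressure_mask("full", vertices = cellpoly,
                     coverage_rule = "fraction_ge", fraction = 1.0)
  asg <- assign_sensors(m, g)
  expect_equal(unname(asg$cells), cbind(2L, 2L))
  expect_equal(asg$coverage, 1, tolerance = 1e-9)

  # left half of that cell: exact coverage 0.5
  half <- cellpoly
  half[half[, 1] == max(half[, 1]), 1] <- mean(range(cellpoly[, 1]))
  m5 <- pressure_mask("half", vertices = half, coverage_rule = "fraction_ge",
                      fraction = 0.4)
  asg <- assign_sensors(m5, g)
  expect_true(any(asg$cells[, 1] == 2 & asg$cells[, 2] == 2))
  m6 <- pressure_mask("half2", vertices = half, coverage_rule = "fraction_ge",
                      fraction = 0.6)
  asg <- assign_sensors(m6, g)
  expect_false(any(asg$cells[, 1] == 2 & asg$cells[, 2] == 2))

  # polygon edge passing through a center: boundary counts as inside
  x0 <- g$centers$x[2, 2]; y0 <- g$centers$y[2, 2]
  tri <- cbind(c(x0, x0 + 30, x0 + 30), c(y0, y0 - 20, y0 + 20))
  mc <- pressure_mask("tri", vertices = tri, coverage_rule = "center_in")
  asg <- assign_sensors(mc, g)
  expect_true(any(asg$cells[, 1] == 2 & asg$cells[, 2] == 2))
})

test_that("fraction_ge assignments shrink monotonically with the threshold", {
  rec <- tiny_rec(array(1, c(1, 6, 6)))
  poly <- cbind(c(3, 22, 26, 8), c(2, 6, 21, 24))
  prev <- Inf
  for (f in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    m <- pressure_mask("m", vertices = poly, coverage_rule = "fraction_ge",
                       fraction = f)
    n <- nrow(assign_sensors(m, rec$grid)$cells)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the barefoot automask returns 10 regions partitioning the footprint", {
  gen <- quick_foot(seed = 6)
  rec <- create_mask_auto(gen$rec, "automask_novel")
  expect_setequal(names(rec$masks),
                  c("heel", "midfoot", "MTH1", "MTH2", "MTH3", "MTH4", "MTH5",
                    "hallux", "toe2", "toes3_5"))
  expect_length(rec$masks, 10L)
  asg <- lapply(rec$masks, assign_sensors, grid = rec$grid)
  keys <- unlist(lapply(asg, function(a) paste(a$cells[, 1], a$cells[, 2])))
  expect_identical(anyDuplicated(keys), 0L)  # pairwise disjoint
  pmax_cell <- apply(rec$frames, c(2, 3), max)
  fp <- which(rec$grid$active & pmax_cell > 5)
  fp_keys <- paste(arrayInd(fp, dim(rec$grid$active))[, 1],
                   arrayInd(fp, dim(rec$grid$active))[, 2])
  expect_setequal(keys, fp_keys)  # union = active footprint
})

test_that("automask fails loudly without a footprint", {
  rec <- tiny_rec(array(0, c(3, 8, 8)))
  expect_error(create_mask_auto(rec, "automask_novel", foot_side = "right"),
               "no footprint")
})

test_that("mirroring the recording mirrors the masks label-for-label", {
  gen <- quick_foot(seed = 9, side = "right")
  rec <- create_mask_auto(gen$rec, "automask_novel", foot_side = "right")
  mrec <- create_mask_auto(mirror_recording(gen$rec), "automask_novel",
                           foot_side = "left")
  nc <- gen$rec$grid$n_cols
  for (lab in names(rec$masks)) {
    a <- assign_sensors(rec$masks[[lab]], rec$grid)$cells
    b <- assign_sensors(mrec$masks[[lab]], mrec$grid)$cells
    mirrored <- cbind(a[, 1], nc + 1L - a[, 2])
    expect_setequal(paste(b[, 1], b[, 2]),
                    paste(mirrored[, 1], mirrored[, 2]))
  }
})

test_that("assignments are invariant under rigid motion of grid and polygon", {
  poly <- cbind(c(2, 16, 17, 3), c(3, 2, 18, 17))
  base <- sensor_grid(5, 5, dx = 5, dy = 5)
  ref <- assign_sensors(pressure_mask("m", vertices = poly), base)

  transform <- function(th, tx, ty) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    cx <- as.vector(base$centers$x); cy <- as.vector(base$centers$y)
    pts <- cbind(cx, cy) %*% t(R)
    g2 <- base
    g2$centers <- list(x = matrix(pts[, 1] + tx, 5, 5),
                       y = matrix(pts[, 2] + ty, 5, 5))
    g2$polygons <- lapply(base$polygons, function(p) {
      q <- p %*% t(R); q[, 1] <- q[, 1] + tx; q[, 2] <- q[, 2] + ty; q
    })
    p2 <- poly %*% t(R); p2[, 1] <- p2[, 1] + tx; p2[, 2] <- p2[, 2] + ty
    list(grid = g2, poly = p2)
  }
  for (case in list(c(0, 11, -7), c(pi / 7, 0, 0), c(pi / 3, 4, 9))) {
    tr <- transform(case[1], case[2], case[3])
    got <- assign_sensors(pressure_mask("m", vertices = tr$poly,
                                        coverage_rule = "fraction_ge",
                                        fraction = 0.5), tr$grid)
    ref_f <- assign_sensors(pressure_mask("m", vertices = poly,
                                          coverage_rule = "fraction_ge",
                                          fraction = 0.5), base)
    expect_identical(unname(got$cells), unname(ref_f$cells))
  }
  expect_gt(nrow(ref$cells), 0)
})

test_that("mask edits snap, recompute assignments, and refuse bad input", {
  rec <- tiny_rec(array(10, c(1, 6, 6)))
  sq <- cbind(c(2, 13, 13, 2), c(2, 2, 13, 13))
  rec <- create_mask_manual(rec, list(sq), "region")
  before <- assign_sensors(rec$masks$region, rec$grid)

  # move a vertex and move it back: assignment unchanged
  r1 <- edit_mask(rec, "region", c(13, 13), c(24, 24))
  r2 <- edit_mask(r1, "region", c(24, 24), c(13, 13))
  after <- assign_sensors(r2$masks$region, r2$grid)
  expect_identical(unname(after$cells), unname(before$cells))

  # enlarging to include one more center gains exactly that cell
  r3 <- edit_mask(rec, "region", c(13, 13), c(18, 13))
  gained <- assign_sensors(r3$masks$region, r3$grid)
  new_keys <- setdiff(paste(gained$cells[, 1], gained$cells[, 2]),
                      paste(before$cells[, 1], before$cells[, 2]))
  got_poly <- r3$masks$region$vertices
  g <- rec$grid
  oracle_new <- character(0)
  for (r in 1:6) for (c in 1:6) {
    inside_new <- pip_oracle(g$centers$x[r, c] - 1e-9,
                             g$centers$y[r, c] - 1e-9, got_poly)
    inside_old <- pip_oracle(g$centers$x[r, c] - 1e-9,
                             g$centers$y[r, c] - 1e-9, sq)
    if (inside_new && !inside_old) oracle_new <- c(oracle_new, paste(r, c))
  }
  expect_setequal(new_keys, oracle_new)

  rec_s <- create_mask_manual(rec, list(cbind(1L, 1L)), "cells",
                              definition = "by_sensors")
  expect_error(edit_mask(rec_s, "cells", c(0, 0), c(1, 1)),
               "not polygon-defined")
  expect_error(edit_mask(rec, "nope", c(0, 0), c(1, 1)), "not found")
  expect_error(edit_mask(rec, "region", c(100, 100), c(1, 1)), "within")
})

test_that("insole template schemes produce their documented region counts", {
  gen <- generate_multistep(foot_model(preset = "inshoe", seed = 3),
                            n_steps = 1)
  counts <- c(pedar_mask1 = 3L, pedar_mask2 = 9L, pedar_mask3 = 10L)
  for (scheme in names(counts)) {
    rec <- create_mask_auto(gen$rec, scheme, foot_side = "right")
    expect_length(rec$masks, counts[[scheme]])
    asg <- lapply(rec$masks, assign_sensors, grid = rec$grid)
    keys <- unlist(lapply(asg, function(a) paste(a$cells[, 1], a$cells[, 2])))
    expect_identical(length(keys), 99L)  # all sensors, exactly once
    expect_identical(anyDuplicated(keys), 0L)
  }
  anon <- gen$rec
  anon$side <- "unknown"
  expect_error(create_mask_auto(anon, "pedar_mask1"), "foot_side")
})

test_that("masking schemes validate their split fractions", {
  expect_error(masking_scheme(long_fracs = c(heel = 0.5, midfoot = 0.2,
                                             forefoot = 0.2, toes = 0.2)),
               "sum to 1")
  expect_silent(masking_scheme())
})
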