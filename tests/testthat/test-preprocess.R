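test_that("force, peak pressure and contact area follow their closed forms", {
  # 10 sensors of 0.5 cm^2 at a uniform 100 kPa: force = 0.1*100*0.5*10 = 50 N
  rec <- tiny_rec(array(100, c(3, 2, 5)), area = 0.5)
  f <- whole_pressure_curve(rec, "force")
  expect_equal(f$values, rep(50, 3))

  # single loaded sensor: peak pressure curve is the sensor's own series
  fr <- array(0, c(3, 2, 2)); fr[, 1, 2] <- c(0, 80, 40)
  rec <- tiny_rec(fr)
  expect_equal(whole_pressure_curve(rec, "peak_pressure")$values, c(0, 80, 40))

  # contact area with threshold 0: 0.25 cm^2 per loaded cell
  fr <- array(0, c(2, 4, 4))
  fr[1, 1, 1:3] <- 50; fr[2, 2, 1:2] <- 10
  rec <- tiny_rec(fr)  # dx = dy = 5 mm -> 0.25 cm^2
  ca <- whole_pressure_curve(rec, "contact_area", area_threshold = 0)
  expect_equal(ca$values, c(0.75, 0.5))
  # exhaustive scan oracle
  for (t in 1:2) {
    n_loaded <- sum(rec$frames[t, , ] > 0)
    expect_equal(ca$values[t], 0.25 * n_loaded)
  }
})

test_that("the force curve matches the exhaustive double-loop oracle", {
  set.seed(99)
  rec <- tiny_rec(array(runif(4 * 6 * 5, 0, 400), c(4, 6, 5)))
  rec$grid$area[] <- runif(30, 0.2, 0.6)
  rec$grid$active[2, 3] <- FALSE
  rec$frames[, 2, 3] <- 0
  expect_equal(whole_pressure_curve(rec, "force")$values, force_oracle(rec))
})

test_that("interpolation hits 101 frames with endpoints preserved", {
  gen <- quick_foot(seed = 2)
  out <- pressure_interp(gen$rec)
  expect_identical(dim(out$frames)[1], 101L)
  expect_equal(out$frames[1, , ], gen$rec$frames[1, , ])
  expect_equal(out$frames[101, , ],
               gen$rec$frames[dim(gen$rec$frames)[1], , ])
  # duration preserved through the rescaled sampling rate
  expect_equal((101 - 1) / out$sampling_rate,
               (dim(gen$rec$frames)[1] - 1) / gen$rec$sampling_rate)
})

test_that("interpolation is exact on constants, lines and the identity", {
  rec <- tiny_rec(array(rep(c(10, 10, 10, 10), each = 1), c(4, 1, 1)))
  out <- pressure_interp(rec, 7)
  expect_equal(as.vector(out$frames), rep(10, 7))

  # single-cell ramp 0 -> 100 over T = 5; closed-form line at 9 points
  rec <- tiny_rec(array(seq(0, 100, length.out = 5), c(5, 1, 1)))
  out <- pressure_interp(rec, 9)
  expect_equal(as.vector(out$frames), seq(0, 100, length.out = 9))

  # interpolating back to the original frame count returns the original
  set.seed(1)
  rec <- tiny_rec(array(runif(6 * 2 * 2, 0, 50), c(6, 2, 2)))
  out <- pressure_interp(rec, 6)
  expect_equal(out$frames, rec$frames)

  expect_error(pressure_interp(rec, 1), ">= 2")
})

test_that("step detection recovers the generator's contact windows", {
  for (seed in 1:3) {
    gen <- generate_multistep(foot_model(preset = "inshoe", seed = seed),
                              n_steps = 3)
    ev <- select_steps(gen$rec, force_threshold = 10)
    expect_identical(nrow(ev), 3L)
    expect_lte(max(abs(unclass(ev) - unclass(gen$truth$events))), 1)
    # intervals sorted and disjoint
    expect_true(all(diff(ev[, "start"]) > 0))
    expect_true(all(ev[-1, "start"] > ev[-nrow(ev), "end"]))

    ev2 <- select_steps(gen$rec, force_threshold = 10, discard_first = 1)
    expect_identical(nrow(ev2), 2L)
    expect_identical(unclass(ev2), unclass(ev)[-1, , drop = FALSE])
  }
})

test_that("step detection handles silence and is monotone in min_duration", {
  rec <- tiny_rec(array(0, c(20, 3, 3)))
  expect_warning(ev <- select_steps(rec), "threshold")
  expect_identical(nrow(ev), 0L)

  gen <- generate_multistep(foot_model(preset = "inshoe", seed = 4),
                            n_steps = 3)
  strict <- select_steps(gen$rec, min_duration = 0.4)
  loose <- select_steps(gen$rec, min_duration = 0.05)
  strict_keys <- paste(strict[, 1], strict[, 2])
  loose_keys <- paste(loose[, 1], loose[, 2])
  expect_true(all(strict_keys %in% loose_keys))
})

test_that("COP matches its closed forms and the exhaustive oracle", {
  # single loaded sensor: COP at that sensor's center
  fr <- array(0, c(1, 3, 3)); fr[1, 2, 3] <- 120
  rec <- tiny_rec(fr)
  tr <- cop(rec)
  expect_equal(unname(tr$points[1, ]),
               c(rec$grid$centers$x[2, 3], rec$grid$centers$y[2, 3]))

  # two equal sensors: midpoint of their centers
  fr <- array(0, c(1, 3, 3)); fr[1, 1, 1] <- 80; fr[1, 3, 3] <- 80
  rec <- tiny_rec(fr)
  tr <- cop(rec)
  mid <- c(mean(c(rec$grid$centers$x[1, 1], rec$grid$centers$x[3, 3])),
           mean(c(rec$grid$centers$y[1, 1], rec$grid$centers$y[3, 3])))
  expect_equal(unname(tr$points[1, ]), mid)

  # arbitrary frame vs brute-force centroid
  set.seed(7)
  rec <- tiny_rec(array(runif(2 * 5 * 4, 0, 200), c(2, 5, 4)))
  rec$grid$area[] <- runif(20, 0.2, 0.5)
  tr <- cop(rec)
  for (t in 1:2) expect_equal(unname(tr$points[t, ]), cop_oracle(rec, t))
})

test_that("valid COP points stay inside the hull of loaded sensor centers", {
  gen <- quick_foot(seed = 8)
  rec <- gen$rec
  tr <- cop(rec, force_threshold = 5)
  g <- rec$grid
  for (t in which(tr$valid)) {
    loaded <- which(g$active & rec$frames[t, , ] > 0)
    hull <- pedobaR:::convex_hull(g$centers$x[loaded], g$centers$y[loaded])
    expect_true(pedobaR:::in_convex_hull(tr$points[t, 1], tr$points[t, 2],
                                         hull, tol = 1e-6))
  }
})

test_that("side detection recovers ground truth and is mirror-antisymmetric", {
  for (seed in 1:4) {
    side <- if (seed %% 2) "right" else "left"
    gen <- quick_foot(seed = seed, side = side)
    det <- auto_detect_side(gen$rec)
    expect_identical(as.character(det), side)
    det_m <- auto_detect_side(mirror_recording(gen$rec))
    expect_identical(as.character(det_m), setdiff(c("left", "right"), side))
  }
})

test_that("a symmetric pressure blob yields 'unknown', never a guess", {
  n <- 21
  fr <- array(0, c(3, n, n))
  cx <- (n + 1) / 2
  for (r in 1:n) for (c in 1:n) {
    d2 <- (r - cx)^2 + (c - cx)^2
    fr[, r, c] <- 200 * exp(-d2 / 18)
  }
  fr[2, , ] <- fr[2, , ] * 1.5  # temporal structure, spatially symmetric
  rec <- tiny_rec(fr)
  det <- auto_detect_side(rec)
  expect_identical(as.character(det), "unknown")
  expect_false(is.null(attr(det, "reason")))
})
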