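test_that("FTI and Melai PTI follow their defining identities", {
  # constant regional force of 20 N over 0.5 s: FTI = 10 N*s
  # 1 cell of 1 cm^2 at 200 kPa -> 0.1 * 200 * 1 = 20 N; T = 51 @ 100 Hz
  fr <- array(0, c(51, 3, 3)); fr[, 2, 2] <- 200
  rec <- tiny_rec(fr, sampling_rate = 100, area = 1)
  rec <- create_mask_manual(rec, list(cbind(2L, 2L)), "region",
                            definition = "by_sensors")
  tab <- mask_analysis(rec, c("fti", "force_max", "contact_time"))
  expect_equal(tab$value[tab$metric == "fti"], 10)
  expect_equal(tab$value[tab$metric == "force_max"], 20)
  expect_equal(tab$value[tab$metric == "contact_time"], 0.5)

  # same force over a region of A = 4 cm^2: PTI_melai = 10 / 4 = 2.5
  fr <- array(0, c(51, 3, 3)); fr[, 2, 2:3] <- 25; fr[, 3, 2:3] <- 25
  rec <- tiny_rec(fr, sampling_rate = 100, area = 1)
  rec <- create_mask_manual(rec, list(cbind(c(2, 2, 3, 3), c(2, 3, 2, 3))),
                            "region", definition = "by_sensors")
  tab <- mask_analysis(rec, c("fti", "pti_melai", "contact_area_peak"))
  expect_equal(tab$value[tab$metric == "contact_area_peak"], 4)
  expect_equal(tab$value[tab$metric == "pti_melai"],
               tab$value[tab$metric == "fti"] / 4)

  # identity PTI * A = FTI holds exactly on arbitrary data
  set.seed(12)
  fr <- array(runif(30 * 4 * 4, 0, 300), c(30, 4, 4))
  rec <- tiny_rec(fr)
  rec <- create_mask_manual(rec, list(cbind(c(1, 2, 3), c(2, 2, 4))), "r",
                            definition = "by_sensors")
  tab <- mask_analysis(rec, c("fti", "pti_melai", "contact_area_peak"))
  expect_identical(tab$value[tab$metric == "pti_melai"] *
                     tab$value[tab$metric == "contact_area_peak"],
                   tab$value[tab$metric == "fti"])
})

test_that("peak pressure metrics reduce to exhaustive maxima", {
  fr <- array(0, c(3, 2, 2))
  fr[, 1, 1] <- c(120, 340, 95)
  rec <- tiny_rec(fr)
  rec <- create_mask_manual(rec, list(cbind(1L, 1L)), "r",
                            definition = "by_sensors")
  tab <- mask_analysis(rec, "press_peak_sensor")
  expect_equal(tab$value, 340)

  set.seed(3)
  fr <- array(runif(10 * 5 * 5, 0, 500), c(10, 5, 5))
  rec <- tiny_rec(fr)
  cells <- cbind(c(1, 2, 4, 5), c(3, 1, 4, 2))
  rec <- create_mask_manual(rec, list(cells), "r", definition = "by_sensors")
  tab <- mask_analysis(rec, "press_peak_sensor")
  expect_equal(tab$value, peak_oracle(rec, cells))
})

test_that("trapezoidal FTI is exact for piecewise-linear force", {
  # triangular ramp 0 -> F -> 0 with knots on frames: integral F*T/2
  up <- seq(0, 100, length.out = 6)
  series <- c(up, rev(up)[-1])          # 11 frames, peak 100 kPa
  fr <- array(0, c(11, 2, 2)); fr[, 1, 1] <- series
  rec <- tiny_rec(fr, sampling_rate = 10, area = 1)  # force = 10 kPa*cm2*0.1
  rec <- create_mask_manual(rec, list(cbind(1L, 1L)), "r",
                            definition = "by_sensors")
  tab <- mask_analysis(rec, "fti")
  # force peaks at 10 N, duration 1 s, triangle area = 10 * 1 / 2
  expect_equal(tab$value, 5)
})

test_that("press_peak_mean is the temporal mean of the spatial peak", {
  fr <- array(0, c(4, 2, 2))
  fr[, 1, 1] <- c(0, 100, 200, 0)
  fr[, 2, 2] <- c(0, 150, 50, 0)
  rec <- tiny_rec(fr)
  rec <- create_mask_manual(rec, list(cbind(c(1, 2), c(1, 2))), "r",
                            definition = "by_sensors")
  tab <- mask_analysis(rec, "press_peak_mean")
  # contact frames are 2 and 3; spatial peaks there are 150 and 200
  expect_equal(tab$value, mean(c(150, 200)))
})

test_that("whole-foot peak equals the max over a partitioning automask", {
  gen <- quick_foot(seed = 10)
  rec <- create_mask_auto(gen$rec, "automask_novel")
  tab <- mask_analysis(rec, "press_peak_sensor")
  whole <- max(whole_pressure_curve(rec, "peak_pressure")$values)
  expect_equal(max(tab$value), whole)
})

test_that("mask analysis rejects unknown variables and empty masks", {
  rec <- tiny_rec(array(1, c(2, 3, 3)))
  rec <- create_mask_manual(rec, list(cbind(1L, 1L)), "r",
                            definition = "by_sensors")
  expect_error(mask_analysis(rec, "nope"))
  rec$grid$active[1, 1] <- FALSE
  rec$frames[, 1, 1] <- 0
  expect_error(mask_analysis(rec, "fti"), "zero assigned cells")
  expect_error(mask_analysis(tiny_rec(array(1, c(1, 2, 2)))), "no masks")
})

test_that("the CPEI geometric construction reproduces planted deviations", {
  # COP exactly on its own construction line: CPEI = 0
  L <- 240
  s <- seq(5, 230, length.out = 40)
  res <- pedobaR:::cpei_from_aligned(s, rep(1.5, 40), L, 90)
  expect_equal(res$cpei, 0, tolerance = 1e-12)

  # plant a deviation d at the trisection, forefoot width w
  for (case in list(c(d = 7.5, w = 80), c(d = 12, w = 95),
                    c(d = 0.31, w = 60.5))) {
    d <- case[["d"]]; w <- case[["w"]]
    s_star <- 2 / 3 * L
    s <- c(0, s_star - 30, s_star, s_star + 1e-9, s_star + 40, 0.95 * L)
    m <- c(0, -d, -d, -d, 0, 0)   # medial coordinate; negative = lateral
    res <- pedobaR:::cpei_from_aligned(s, m, L, w)
    expect_equal(res$cpei, 100 * d / w, tolerance = 1e-6)
  }
})

test_that("CPEI is mirror-consistent and invariant to scale and rotation", {
  gen <- quick_foot(seed = 7)
  a <- cpei(gen$rec)
  b <- cpei(mirror_recording(gen$rec))
  expect_equal(b$cpei, a$cpei, tolerance = 1e-9)
  expect_equal(abs(b$deviation), abs(a$deviation), tolerance = 1e-9)

  # uniform spatial scaling: double every length (areas x4)
  rec <- gen$rec
  g <- rec$grid
  scaled <- sensor_grid(g$n_rows, g$n_cols, dx = 2 * g$dx, dy = 2 * g$dy,
                        area = g$area * 4, active = g$active)
  rec2 <- pressure_recording(rec$frames, rec$sampling_rate, scaled,
                             side = rec$side)
  cs <- cpei(rec2)
  expect_equal(cs$cpei, a$cpei, tolerance = 1e-6)

  # rigid rotation of the foot on the plate (re-rasterized, so a small
  # discretization tolerance applies)
  rot0 <- generate_footprint(foot_model(seed = 20, rotation_deg = 0,
                                        jitter = FALSE, noise_sd = 0))
  rot25 <- generate_footprint(foot_model(seed = 20, rotation_deg = 25,
                                         jitter = FALSE, noise_sd = 0))
  c0 <- cpei(rot0$rec); c25 <- cpei(rot25$rec)
  expect_equal(c25$cpei, c0$cpei, tolerance = 0.08)
})

test_that("DPLI is zero for Gaussian curves and bounded in [0, 1]", {
  t <- 1:60
  y <- 320 * exp(-(t - 27)^2 / (2 * 9^2))
  expect_lt(dpli(y), 1e-6)

  set.seed(5)
  for (i in 1:5) {
    y <- pmax(0, 200 * exp(-(t - 30)^2 / 80) + rnorm(60, 0, 40))
    v <- dpli(y)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(dpli(rep(0, 10)), "all-zero")
  expect_error(dpli(c(1, 2, 3)), "at least 5")
  expect_error(dpli(c(-1, 2, 3, 4, 5)), "non-negative")
})

test_that("DPLI agrees with an independent grid-search fit", {
  t <- 1:40
  set.seed(8)
  # flat nonzero series
  expect_lt(abs(dpli(rep(3, 40)) - dpli_oracle(rep(3, 40))), 1e-3)
  for (i in 1:6) {
    y <- pmax(0, 250 * exp(-(t - 18)^2 / (2 * 6^2)) + rnorm(40, 0, 25 * i / 3))
    expect_lt(abs(dpli(y) - dpli_oracle(y)), 1e-3)
  }
})

test_that("DPLI grows with noise amplitude in expectation", {
  t <- 1:50
  mean_dpli <- function(noise_sd) {
    vals <- vapply(1:8, function(s) {
      set.seed(1000 + s)
      dpli(pmax(0, 300 * exp(-(t - 25)^2 / (2 * 8^2)) + rnorm(50, 0, noise_sd)))
    }, numeric(1))
    mean(vals)
  }
  expect_lt(mean_dpli(5), mean_dpli(60))
})
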