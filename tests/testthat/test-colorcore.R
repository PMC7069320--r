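test_that("linearization is a fixed-endpoint power law and rejects bad input", {
  expect_identical(linearize(1, 2.2), 1)
  expect_identical(linearize(0, 2.2), 0)
  expect_equal(linearize(0.5, 2.2), 0.5^2.2, tolerance = 1e-15)
  # monotone over a grid
  v <- seq(0, 1, by = 0.05)
  expect_true(all(diff(linearize(v, 2.2)) > 0))
  expect_error(linearize(1.2), "outside")
  expect_error(linearize(-0.1), "outside")
  expect_error(linearize(0.5, gamma = 0), "gamma")
})

test_that("equalization maps the gray card to its own reflectance and scales per channel", {
  g <- c(0.36, 0.45, 0.30)
  expect_equal(unname(equalize(g, g)[1:3]), rep(0.18, 3), tolerance = 1e-15)
  out <- equalize(c(0.72, 0.45, 0.15), g)
  expect_equal(unname(out[1:3]), c(0.36, 0.18, 0.09), tolerance = 1e-15)
  expect_equal(unname(out["V"]), 0.21, tolerance = 1e-15)
  expect_error(equalize(c(0.3, 0.3, 0.3), c(0.36, 0, 0.30)), "calibration")
  # gray fixed point holds for arbitrary positive observations
  for (seed in 1:20) {
    set.seed(seed)
    g2 <- runif(3, 0.05, 0.95)
    expect_equal(unname(equalize(g2, g2)[1:3]), rep(0.18, 3), tolerance = 1e-12)
  }
})

test_that("chromaticity, saturation, and hue match their definitions", {
  expect_equal(unname(chromaticity(c(0.3, 0.3, 0.3))), c(0, 0))
  expect_equal(unname(chromaticity(c(1, 0, 0))), c(1, 0))
  expect_equal(unname(chromaticity(c(0, 1, 0))), c(-1, 1))
  expect_error(chromaticity(c(0, 0, 0)), "undefined")
  expect_identical(saturation(0, 0), 0)
  expect_identical(saturation(1, 0), 1)
  expect_equal(saturation(-1, 1), sqrt(2), tolerance = 1e-15)
  expect_identical(hue(1, 0), 0)
  expect_equal(hue(0, 1), pi / 2, tolerance = 1e-15)
  expect_equal(hue(-1, 0), pi, tolerance = 1e-15)  # full-quadrant convention
  expect_error(hue(0, 0), "achromatic")
  expect_equal(brightness(c(0.1, 0.2, 0.3)), 0.2, tolerance = 1e-15)
  expect_identical(brightness(c(0, 0, 0)), 0)
})

test_that("chromaticity, saturation, hue are brightness-scale invariant; S = 0 iff gray", {
  set.seed(11)
  for (i in 1:50) {
    rgb <- runif(3, 0.01, 1)
    k <- runif(1, 0.1, 10)
    xy1 <- chromaticity(rgb)
    xy2 <- chromaticity(k * rgb)
    expect_equal(xy1, xy2, tolerance = 1e-12)
    expect_equal(saturation(xy1[1], xy1[2]), saturation(xy2[1], xy2[2]),
                 tolerance = 1e-12)
    if (any(xy1 != 0)) {
      expect_equal(hue(xy1[1], xy1[2]), hue(xy2[1], xy2[2]), tolerance = 1e-12)
    }
    s <- saturation(xy1[1], xy1[2])
    if (abs(rgb[1] - rgb[2]) < 1e-14 && abs(rgb[2] - rgb[3]) < 1e-14) {
      expect_equal(s, 0)
    } else {
      expect_gt(s, 0)
    }
  }
})

test_that("calibration round-trips a synthetic camera encode to true reflectance", {
  gains <- c(1.2, 1.0, 0.8)
  gamma <- 2.2
  set.seed(4)
  for (i in 1:25) {
    truth <- runif(3, 0.05, 0.7)
    raw <- camera_encode(truth, gains, gamma)
    gray_raw <- camera_encode(rep(0.18, 3), gains, gamma)
    rec <- calibrate_color(raw, gray_raw, gamma = gamma)
    expect_equal(unname(rec[1:3]), truth, tolerance = 1e-10)
  }
})

test_that("calibrate_table appends the eight derived columns rowwise", {
  tbl <- data.frame(
    R_raw = c(0.5, 0.3), G_raw = c(0.5, 0.5), B_raw = c(0.5, 0.2),
    R_gray = c(0.5, 0.5), G_gray = c(0.5, 0.5), B_gray = c(0.5, 0.5)
  )
  out <- calibrate_table(tbl, gamma = 1)
  expect_true(all(c("R", "G", "B", "V", "x", "y", "S", "H") %in% names(out)))
  # row 1 is the gray card itself: achromatic, hue undefined (NA)
  expect_equal(out$R[1], 0.18, tolerance = 1e-12)
  expect_equal(out$S[1], 0)
  expect_true(is.na(out$H[1]))
  # row 2 checked against the scalar operations
  cal <- calibrate_color(c(0.3, 0.5, 0.2), c(0.5, 0.5, 0.5), gamma = 1)
  xy <- chromaticity(cal)
  expect_equal(out$x[2], unname(xy[1]), tolerance = 1e-12)
  expect_equal(out$H[2], unname(hue(xy[1], xy[2])), tolerance = 1e-12)
  expect_error(calibrate_table(tbl[1:3]), "missing columns")
})
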