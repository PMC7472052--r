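test_that("system matrix matches the closed-form elements and has unit determinant", {
  cfg <- proto_cfg()
  cases <- expand.grid(x1 = c(41.8, 45, 48.2, 52), x2 = c(15, 18, 18.5, 25))
  for (i in seq_len(nrow(cases))) {
    m <- system_matrix(cfg, cases$x1[i], cases$x2[i])
    cf <- abcd_closed(cfg, cases$x1[i], cases$x2[i])
    expect_equal(m$A, cf$A, tolerance = 1e-9)
    expect_equal(m$B, cf$B, tolerance = 1e-9)
    expect_equal(m$C, cf$C, tolerance = 1e-9)
    expect_equal(m$D, cf$D, tolerance = 1e-9)
    expect_equal(m$A * m$D - m$B * m$C, 1, tolerance = 1e-12)
  }
  # non-telecentric configuration too
  cfg2 <- proto_cfg(d_mm = 150)
  m <- system_matrix(cfg2, 46.3, 21.7)
  cf <- abcd_closed(cfg2, 46.3, 21.7)
  expect_equal(m$B, cf$B, tolerance = 1e-9)
  expect_equal(m$A * m$D - m$B * m$C, 1, tolerance = 1e-12)
})

test_that("image distance zeroes the B element (imaging condition)", {
  for (d in c(63, 100, 150)) {
    cfg <- proto_cfg(d_mm = d)
    for (x1 in c(41.8, 45, 48.2)) {
      x2 <- image_distance(cfg, x1)
      m <- system_matrix(cfg, x1, x2)
      scale <- max(abs(x1), abs(x2), cfg$d)
      expect_lt(abs(m$B), 1e-9 * scale)
      # agrees with an independent numerical root of B
      expect_equal(x2, image_distance_by_root(cfg, x1), tolerance = 1e-8)
    }
  }
})

test_that("telecentric image distance follows the affine reduction", {
  cfg <- proto_cfg()  # d = F1 + F2
  # x2 = F2 + F2^2/F1 - (F2/F1)^2 * x1
  affine <- function(x1) 18 + 324 / 45 - (18 / 45)^2 * x1
  expect_equal(image_distance(cfg, 45), 18)
  expect_equal(image_distance(cfg, 41.8), affine(41.8), tolerance = 1e-12)
  expect_equal(image_distance(cfg, 41.8), 18.512, tolerance = 1e-12)
  # degenerate configuration: denominator pole
  cfg2 <- proto_cfg(d_mm = 100)   # pole at x1 = 3690/37
  expect_error(image_distance(cfg2, 3690 / 37), "degenerate")
})

test_that("magnification is -F2/F1 and x1-independent at the telecentric separation", {
  cfg <- proto_cfg()
  for (x1 in c(42, 45, 48))
    expect_equal(magnification(cfg, x1), -18 / 45, tolerance = 1e-12)
  # away from it, magnification varies with specimen position
  cfg2 <- proto_cfg(d_mm = 150)
  expect_gt(abs(magnification(cfg2, 46) - magnification(cfg2, 45)), 1e-3)
})

test_that("stripe column hits the sensor centre and the documented endpoints", {
  cfg <- proto_cfg()
  expect_equal(stripe_column(cfg, 45), 640)
  expect_equal(specimen_from_column(cfg, 640), 45)
  # endpoints of the visible range, printed to one decimal as 41.8 / 48.2
  expect_equal(round(specimen_from_column(cfg, 1280), 1), 41.8)
  expect_equal(round(specimen_from_column(cfg, 0), 1), 48.2)
  # off-sensor columns are returned unchanged, not clamped
  expect_gt(stripe_column(cfg, 41.5), 1280)
  expect_lt(stripe_column(cfg, 48.5), 0)
})

test_that("stripe column is affine in x1 and strictly decreasing at d = F1 + F2", {
  cfg <- proto_cfg()
  grid <- seq(41.8, 48.2, length.out = 1000)
  cc <- vapply(grid, stripe_column, numeric(1), cfg = cfg)
  fit <- lm(cc ~ grid)
  expect_lt(max(abs(resid(fit))) / diff(range(cc)), 1e-6)
  expect_true(all(diff(cc) < 0))
  mm <- vapply(grid, magnification, numeric(1), cfg = cfg)
  expect_lt(diff(range(mm)), 1e-12)
  ss <- vapply(grid, sensitivity, numeric(1), cfg = cfg)
  expect_lt(diff(range(ss)), 1e-9 * abs(ss[1]))
})

test_that("analytic sensitivity matches central finite differences", {
  for (d in c(63, 100, 150)) {
    cfg <- proto_cfg(d_mm = d)
    for (x1 in c(42.5, 45, 47.5)) {
      an <- sensitivity(cfg, x1)
      fd <- sensitivity(cfg, x1, method = "fd", h_mm = 1e-5)
      expect_equal(an, fd, tolerance = 1e-3)
    }
  }
})

test_that("prototype sensitivity is about -201 per mm and scales inversely with sensor width", {
  cfg <- proto_cfg()
  s <- sensitivity(cfg, 45)
  expect_equal(s, -(18 / 45)^2 * 1280 / 1.44 / cospi(0.25), tolerance = 1e-12)
  expect_equal(round(s), -201)
  cfg_w2 <- proto_cfg(sensor_width_mm = 2 * 1.44)
  expect_equal(sensitivity(cfg_w2, 45), s / 2, tolerance = 1e-12)
  # non-telecentric sensitivity varies with x1
  cfg2 <- proto_cfg(d_mm = 100)
  expect_gt(abs(sensitivity(cfg2, 43) - sensitivity(cfg2, 47)), 1)
})

test_that("column inversion round-trips over the visible range", {
  cfg <- proto_cfg()
  set.seed(11)
  for (x1 in runif(100, 41.9, 48.1)) {
    cc <- stripe_column(cfg, x1)
    expect_equal(stripe_column(cfg, specimen_from_column(cfg, cc)), cc,
                 tolerance = 1e-6)
    expect_equal(specimen_from_column(cfg, cc), x1, tolerance = 1e-9)
  }
  # also for a non-telecentric geometry (Moebius inverse)
  cfg2 <- proto_cfg(d_mm = 100)
  for (x1 in c(43, 45, 47)) {
    cc <- stripe_column(cfg2, x1)
    expect_equal(specimen_from_column(cfg2, cc), x1, tolerance = 1e-9)
  }
})

test_that("model sweep reproduces range and resolution of the prototype", {
  cfg <- proto_cfg()
  lo <- specimen_from_column(cfg, 1280)
  hi <- specimen_from_column(cfg, 0)
  sw <- optics_sweep(cfg, seq(lo, hi, length.out = 101))
  expect_equal(max(sw$column_px) - min(sw$column_px), 1280, tolerance = 1e-9)
  span <- max(sw$x1_mm) - min(sw$x1_mm)
  expect_equal(round(span, 1), 6.4)
  expect_equal(round(span / cfg$nc, 3), 0.005)
  expect_false(any(sw$off_sensor))
  # single-point grid matches the scalar operations
  sw1 <- optics_sweep(cfg, 45)
  expect_equal(nrow(sw1), 1L)
  expect_equal(sw1$x2_mm, image_distance(cfg, 45))
  expect_equal(sw1$column_px, stripe_column(cfg, 45))
  expect_equal(sw1$magnification, magnification(cfg, 45))
  # degenerate points are flagged NA, not fatal
  cfg2 <- proto_cfg(d_mm = 100)
  sw2 <- optics_sweep(cfg2, c(45, 3690 / 37))
  expect_true(is.na(sw2$column_px[2]) && !is.na(sw2$column_px[1]))
})

test_that("invalid configurations are rejected", {
  expect_error(optical_config(f1_mm = -1), "f1_mm")
  expect_error(optical_config(n_columns = 1), "n_columns")
  expect_error(optical_config(tilt_deg = 90), "tilt_deg")
})
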