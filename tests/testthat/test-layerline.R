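test_that("average power spectrum concentrates power as expected", {
  # constant image: all power at the origin
  stack <- structure(list(data = array(1, dim = c(32, 32, 1)),
                          pixel_size_ang = 1), class = "image_stack")
  ps <- average_power_spectrum(stack)
  off_origin <- ps$data
  off_origin[ps$origin["row"], ps$origin["col"]] <- 0
  expect_true(all(off_origin == 0))
  expect_gt(ps$data[ps$origin["row"], ps$origin["col"]], 0)

  # vertical stripes of period 10 px: equatorial peaks at +/- 1/10 px^-1
  img <- matrix(rep(sin(2 * pi * (1:40) / 10), each = 40), 40, 40)
  ps2 <- average_power_spectrum(structure(
    list(data = array(img, dim = c(40, 40, 1)), pixel_size_ang = 1),
    class = "image_stack"))
  peaks <- which(ps2$data > max(ps2$data) / 2, arr.ind = TRUE)
  expect_true(all(peaks[, "row"] == ps2$origin["row"]))
  r_freq <- (peaks[, "col"] - ps2$origin["col"]) * ps2$radial_sampling
  expect_equal(sort(r_freq), c(-0.1, 0.1), tolerance = 1e-9)

  expect_error(average_power_spectrum(structure(
    list(data = array(0, dim = c(8, 8, 0)), pixel_size_ang = 1),
    class = "image_stack")), "empty")
})

test_that("computed spectra obey Friedel symmetry", {
  fil <- make_filament(data.frame(r = c(20, 12), phi = c(0, 100), z = c(0, 1)),
                       helical_symmetry(-101.124, 4.848), 120)
  ps <- average_power_spectrum(project_filament(fil, 1.21, 128))
  d <- ps$data
  o <- ps$origin
  sub <- d[2:nrow(d), 2:ncol(d)]
  mate <- d[nrow(d):2, ncol(d):2]
  expect_lt(max(abs(sub - mate)) / max(d), 1e-6)
})

test_that("layer lines are detected at their true heights", {
  # pure noise: nothing above a high threshold
  set.seed(2)
  noise <- matrix(abs(rnorm(64 * 64)), 64, 64)
  ps_noise <- power_spectrum(noise, 0.01, 0.01)
  expect_length(detect_layer_lines(ps_noise, min_snr = 30), 0)

  # constructed spectrum with lines at 1/17.3 and 1/4.87
  nr <- 128
  d <- matrix(1e-6, nr, nr)
  samp <- 1 / (128 * 1.21)
  o <- nr %/% 2 + 1
  for (h in c(1 / 17.3, 1 / 4.87)) {
    row <- o + round(h / samp)
    d[row, ] <- 5
    d[2 * o - row, ] <- 5
  }
  ps <- power_spectrum(d, samp, samp)
  got <- as.numeric(detect_layer_lines(ps, min_snr = 8))
  expect_length(got, 2)
  expect_lt(abs(got[1] - 1 / 17.3), samp)
  expect_lt(abs(got[2] - 1 / 4.87), samp)

  # synthetic stack at the studied symmetry: a line within one Fourier
  # pixel of 1/4.848 (the meridional rise reflection) and rows at
  # multiples of ~1/155 are present
  fil <- make_filament(data.frame(r = 25, phi = 0, z = 0),
                       helical_symmetry(-101.124, 4.848), 280)
  stack <- project_filament(fil, 1.21, 256, n_images = 8, blob_sigma_px = 1)
  psf <- average_power_spectrum(stack)
  hh <- as.numeric(detect_layer_lines(psf, min_snr = 5))
  expect_true(any(abs(hh - 1 / 4.848) <= psf$axial_sampling))
  c_true <- 32 * 4.848
  l_near <- hh * c_true
  expect_true(all(abs(l_near - round(l_near)) < c_true * psf$axial_sampling))
})

test_that("repeat fitting indexes heights as l/c", {
  fit <- fit_repeat(c(1 / 10, 2 / 10, 3 / 10), max_l = 10)
  expect_equal(fit$c_ang, 10, tolerance = 1e-12)
  expect_identical(fit$l, c(1L, 2L, 3L))

  fit2 <- fit_repeat(c(9 / 155.8, 32 / 155.8), max_l = 40)
  expect_equal(fit2$c_ang, 155.8, tolerance = 1e-9)
  expect_identical(fit2$l, c(9L, 32L))

  # ~1% jitter: c recovered within 2% (modulo the gcd of the drawn indices,
  # which defines the true minimal repeat)
  set.seed(31)
  for (i in 1:20) {
    c_true <- runif(1, 50, 300)
    ls <- sort(sample(1:12, 6))
    g <- Reduce(helifil:::.gcd, ls)
    h <- ls / c_true * (1 + rnorm(6, 0, 0.005))
    fit3 <- fit_repeat(h, max_l = 15, rel_tol = 0.03)
    expect_lt(abs(fit3$c_ang - c_true / g) / (c_true / g), 0.02)
  }

  expect_error(fit_repeat(c(0.1), max_l = 10), "at least two")
  expect_error(fit_repeat(c(0.1, 0.1234567), max_l = 2, rel_tol = 1e-4),
               "no consistent")
})

test_that("repeat fitting is scale-consistent", {
  h <- c(3, 7, 12) / 120
  f1 <- fit_repeat(h, 20)
  for (k in c(0.5, 2, 5)) {
    fk <- fit_repeat(h * k, 20)
    expect_equal(fk$c_ang, f1$c_ang / k, tolerance = 1e-9)
    expect_identical(fk$l, f1$l)
  }
})

test_that("Bessel orders follow the first-maximum heuristic", {
  expect_identical(assign_bessel_order(0, 25)$n, 0L)

  # J1 first maximum near x = 1.8412 (located by numeric scan)
  xs <- seq(0.1, 5, by = 1e-4)
  x1 <- xs[which.max(besselJ(xs, 1))]
  expect_equal(x1, 1.8412, tolerance = 1e-3)
  got <- assign_bessel_order(x1 / (2 * pi * 25), 25)
  expect_identical(got$n, 1L)
  expect_false(got$low_confidence)

  # far beyond the n_max prediction: capped with a low-confidence flag
  capped <- assign_bessel_order(3, 25, n_max = 4)
  expect_identical(capped$n, 4L)
  expect_true(capped$low_confidence)
})

test_that("indexing solves the symmetry from c and the key lines", {
  idx <- index_symmetry(155.8, 32, 9)
  expect_equal(round(idx$rise_ang, 2), 4.87)
  expect_equal(round(idx$pitch_ang, 1), 17.3)
  expect_equal(round(idx$repeat_$units_per_turn, 2), 3.56)
  expect_identical(idx$symmetry$handedness, "left")

  idx2 <- index_symmetry(20, 4, 1)
  expect_equal(idx2$rise_ang, 5)
  expect_equal(idx2$pitch_ang, 20)
  expect_equal(idx2$repeat_$units_per_turn, 4)

  expect_warning(idx3 <- index_symmetry(100, 30, 9), "reducing")
  expect_identical(c(idx3$repeat_$u, idx3$repeat_$t), c(10L, 3L))
  expect_error(index_symmetry(100, 9, 9), "l_meridional > l_pitch")
})

test_that("indexing round-trips random (u, t, rise) exactly", {
  set.seed(77)
  for (i in 1:200) {
    t <- sample(1:9, 1)
    u <- t + sample(1:40, 1)
    while (helifil:::.gcd(u, t) != 1) u <- u + 1
    rise <- runif(1, 2, 8)
    cc <- u * rise
    idx <- index_symmetry(cc, u, t)
    expect_equal(idx$rise_ang, rise, tolerance = 1e-12)
    expect_equal(idx$repeat_$units_per_turn, u / t, tolerance = 1e-12)
    expect_equal(abs(idx$symmetry$twist_deg), 360 * t / u, tolerance = 1e-9)
  }
})
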