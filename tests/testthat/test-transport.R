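test_that("Stokes-Einstein scaling hits the GFP anchor and exact half-value", {
  expect_identical(stokes_einstein_diffusivity(27), 24)
  ## 216 kDa = 8 x 27 kDa, cube root of 1/8 is exactly 1/2
  expect_equal(stokes_einstein_diffusivity(216), 12, tolerance = 1e-12)
  ## independent closed form at the apoptosome mass
  expect_equal(stokes_einstein_diffusivity(700), 24 * (27 / 700)^(1 / 3),
               tolerance = 1e-12)
  expect_error(stokes_einstein_diffusivity(0), "positive")
  expect_error(stokes_einstein_diffusivity(-5), "positive")
})

test_that("diffusivity decreases strictly with mass", {
  set.seed(7)
  masses <- sort(stats::runif(20, 5, 2000))
  D <- stokes_einstein_diffusivity(masses)
  expect_true(all(diff(D) < 0))
})

test_that("MOMP onset times are linear with the stated end-to-end delay", {
  inp <- wave_input("smac", 0.35, 0.007, wave_velocity_um_s = 0.1)
  expect_equal(momp_onset_time(0, inp), 0)
  expect_equal(momp_onset_time(30, inp), 300)
  expect_equal(momp_onset_time(15, inp), 150)
  expect_error(momp_onset_time(-1, inp), "domain")
  expect_error(momp_onset_time(31, inp, length_um = 30), "domain")
  ## synchronous limit
  sync <- wave_input("smac", 0.35, 0.007, wave_velocity_um_s = Inf)
  expect_equal(momp_onset_time(c(0, 15, 30), sync), c(0, 0, 0))
})

test_that("wave input saturates with first-order kinetics", {
  inp <- wave_input("smac", amplitude_uM = 0.4, saturation_rate_per_s = 0.01,
                    wave_velocity_um_s = 0.1, onset_smoothing_s = 0)
  x <- 10  # onset at 100 s
  expect_equal(wave_input_value(x, 99, inp), 0)
  expect_equal(wave_input_value(x, 100, inp), 0)
  expect_equal(wave_input_value(x, 100 + 1 / 0.01, inp),
               0.4 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(wave_input_value(x, 1e6, inp), 0.4, tolerance = 1e-9)
  ## monotone non-decreasing and bounded
  tt <- seq(0, 2000, by = 7)
  v <- wave_input_value(x, tt, inp)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 0.4 + 1e-12))
})

test_that("onset smoothing only perturbs a narrow window around onset", {
  sharp <- wave_input("smac", 0.4, 0.01, 0.1, onset_smoothing_s = 0)
  smooth <- wave_input("smac", 0.4, 0.01, 0.1, onset_smoothing_s = 1)
  tt <- seq(0, 600, by = 0.5)
  dv <- abs(wave_input_value(10, tt, smooth) - wave_input_value(10, tt, sharp))
  expect_lt(max(dv), 0.4 * 0.01 * 1)   # bounded by Cmax * k * tau
  expect_lt(max(dv[tt < 95 | tt > 110]), 1e-4)
  ## the rate is the time derivative of the cumulative value
  ts <- seq(1, 600, by = 0.5)
  mid <- wave_input_value(10, ts + 1e-3, smooth) - wave_input_value(10, ts - 1e-3, smooth)
  expect_equal(wave_input_rate(10, ts, smooth), mid / 2e-3, tolerance = 1e-5)
})

test_that("input invariant: Smac saturates slower than apoptosome formation", {
  net <- build_reference_network()
  inputs <- default_wave_inputs(net)
  labs <- vapply(net$inputs, `[[`, "", "label")
  ks <- vapply(inputs, `[[`, 0, "saturation_rate_per_s")
  expect_lt(ks[labs == "smac"], ks[labs == "apoptosome"])
})

test_that("diffusion operator is conservative and annihilates uniform fields", {
  g <- spatial_grid(30, 75)
  expect_equal(diffusion_operator(rep(2.5, 75), 10, g), rep(0, 75))
  set.seed(11)
  for (i in 1:5) {
    f <- stats::runif(75)
    r <- diffusion_operator(f, 7.3, g)
    expect_lt(abs(sum(r)), 1e-12)          # exact discrete mass conservation
  }
  expect_error(diffusion_operator(rep(1, 10), 1, g), "match")
})

test_that("diffusion operator is symmetric under mirroring", {
  g <- spatial_grid(20, 64)
  set.seed(3)
  f <- stats::runif(64)
  expect_equal(rev(diffusion_operator(rev(f), 5, g)),
               diffusion_operator(f, 5, g))
})

test_that("cosine eigenmode is an approximate eigenfunction of the operator", {
  n <- 201
  g <- spatial_grid(30, n)
  D <- 24
  f <- cos(pi * g$x / g$length_um)
  r <- diffusion_operator(f, D, g)
  lam <- D * (pi / g$length_um)^2
  ## interior nodes: second-order accurate eigenrelation; the flux-form
  ## boundary closure concentrates its truncation error in the two
  ## boundary nodes (conservation is exact there instead)
  idx <- 4:(n - 3)
  err201 <- max(abs(r[idx] + lam * f[idx]))
  expect_lt(err201, lam * 1e-3)
  ## halving the spacing cuts the interior error ~4x
  g2 <- spatial_grid(30, 2 * n - 1)
  f2 <- cos(pi * g2$x / g2$length_um)
  r2 <- diffusion_operator(f2, D, g2)
  idx2 <- 7:(2 * n - 7)
  err401 <- max(abs(r2[idx2] + lam * f2[idx2]))
  expect_lt(err401, err201 / 3)
})

test_that("grid construction validates its invariants", {
  g <- spatial_grid(30, 300)
  expect_equal(range(g$x), c(0, 30))
  expect_true(all(diff(g$x) > 0))
  expect_equal(g$dx, 30 / 299)
  expect_error(spatial_grid(0, 300), "length_um")
  expect_error(spatial_grid(30, 2), "n_nodes")
})
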