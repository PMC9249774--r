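test_that("forward model reaches the static and high-frequency limits", {
  p <- cole_cole_params(5, 0, 1e-6, 0, 70, 8e-12, 0)
  s <- cole_cole_forward(p, c(1e3, 1e4))
  expect_equal(s$eps_real[1], 75, tolerance = 1e-6) # eps_s = eps_inf + sum(delta)
  expect_equal(p$eps_static, 75)
  expect_equal(p$eps_intermediate, 75)
  s_hi <- cole_cole_forward(p, c(1e14, 2e14))
  expect_lt(abs(s_hi$eps_real[2] - 5), 1e-3)
})

test_that("single Debye pole peaks at omega*tau = 1 with loss delta_eps/2", {
  tau <- 8e-12
  f_peak <- 1 / (2 * pi * tau)
  p <- cole_cole_params(5, 0, 1e-6, 0, 70, tau, 0)
  s <- cole_cole_forward(p, c(f_peak, 2 * f_peak))
  expect_equal(s$eps_imag[1], 35, tolerance = 1e-12)
})

test_that("peak loss matches the closed form (delta/2) tan(pi(1-alpha)/4)", {
  # oracle: at omega*tau = 1 a single Cole-Cole pole has loss
  # (delta_eps/2) * tan(pi (1 - alpha) / 4); also the grid maximum
  delta <- 70; tau <- 8e-12
  f_peak <- 1 / (2 * pi * tau)
  for (alpha in c(0, 0.06, 0.16, 0.4)) {
    closed <- (delta / 2) * tan(pi * (1 - alpha) / 4)
    p <- cole_cole_params(5, 0, 1e-6, 0, delta, tau, alpha)
    s <- cole_cole_forward(p, c(f_peak, 2 * f_peak))
    expect_lt(abs(s$eps_imag[1] - closed), 1e-9)
    dense <- cole_cole_forward(p, exp(seq(log(f_peak / 100),
                                          log(f_peak * 100), length.out = 4001)))
    expect_lte(max(dense$eps_imag), closed + 1e-9)
  }
  # spec'd spot value: delta = 70, alpha = 0.16
  expect_equal((70 / 2) * tan(pi * 0.84 / 4), 27.15, tolerance = 1e-3)
})

test_that("eps' is monotone non-increasing and bounded; eps'' non-negative", {
  set.seed(42)
  grid <- drs_grid(1e6, 1e12, n = 300, spacing = "log")
  for (i in 1:20) {
    p <- random_liver_params(cv = 0.2)
    s <- cole_cole_forward(p, grid)
    expect_true(all(diff(s$eps_real) <= 1e-12))
    expect_true(all(s$eps_real <= p$eps_static + 1e-9))
    expect_true(all(s$eps_real >= p$eps_inf - 1e-9))
    expect_true(all(s$eps_imag >= 0))
  }
})

test_that("dispersion separation is exactly additive and pole-attributed", {
  grid <- drs_grid(n = 50)
  p <- liver_params()
  total <- cole_cole_forward(p, grid)
  comp <- separate_dispersions(p, grid)
  expect_equal(comp$pole1$eps_imag + comp$pole2$eps_imag, total$eps_imag,
               tolerance = 1e-12)
  # degenerate strengths zero out the corresponding pole
  p1 <- cole_cole_params(4, 0, 0.8e-9, 0.06, 37.6, 7e-12, 0.16)
  c1 <- separate_dispersions(p1, grid)
  expect_true(all(c1$pole1$eps_imag == 0))
  expect_equal(c1$pole2$eps_imag, cole_cole_forward(p1, grid)$eps_imag,
               tolerance = 1e-12)
  p2 <- cole_cole_params(4, 15, 0.8e-9, 0.06, 0, 7e-12, 0.16)
  expect_true(all(separate_dispersions(p2, grid)$pole2$eps_imag == 0))
})

test_that("loss/conductivity conversions are exact inverses", {
  # sigma = 2 pi f eps0 eps'': at the 8 ps Debye peak with eps'' = 35,
  # sigma = 35 * eps0 / 8e-12 = 38.73707 S/m (recomputed arithmetic)
  f_peak <- 1 / (2 * pi * 8e-12)
  s <- permittivity_spectrum(c(f_peak, 2 * f_peak), c(40, 30), c(35, 20))
  cond <- loss_to_conductivity(s)
  expect_equal(cond$sigma[1], 35 * 8.8541878128e-12 / 8e-12,
               tolerance = 1e-12)
  expect_equal(cond$sigma[1], 38.737, tolerance = 1e-4)
  back <- conductivity_to_loss(cond)
  expect_equal(back$eps_imag, s$eps_imag, tolerance = 1e-15)
  zero <- permittivity_spectrum(c(1e9, 2e9), c(10, 10), c(0, 0))
  expect_equal(loss_to_conductivity(zero)$sigma, c(0, 0))
})

test_that("debye water model reduces to the single-pole forward model", {
  grid <- drs_grid(n = 30)
  d <- water_debye_default()
  s1 <- debye_water_model(d$eps_s, d$eps_inf, d$tau, grid)
  p <- cole_cole_params(d$eps_inf, 0, d$tau * 1e3, 0, d$eps_s - d$eps_inf,
                        d$tau, 0)
  s2 <- cole_cole_forward(p, grid)
  expect_identical(s1$eps_real, s2$eps_real)
  expect_identical(s1$eps_imag, s2$eps_imag)
  f_peak <- 1 / (2 * pi * d$tau)
  peak <- debye_water_model(d$eps_s, d$eps_inf, d$tau, c(f_peak, 2 * f_peak))
  expect_equal(peak$eps_imag[1], (d$eps_s - d$eps_inf) / 2, tolerance = 1e-12)
  expect_error(debye_water_model(5, 10, 1e-12, grid), "eps_s > eps_inf")
})

test_that("reference comparison reports the maximum relative deviation", {
  grid <- drs_grid(n = 20)
  ref <- cole_cole_forward(liver_params(), grid)
  expect_equal(compare_to_reference(ref, ref), 0)
  scaled <- permittivity_spectrum(grid, ref$eps_real * 1.02,
                                  ref$eps_imag * 1.02)
  expect_equal(compare_to_reference(scaled, ref), 2, tolerance = 1e-9)
  # the saline acceptance criterion: within-2% spectra pass
  expect_lte(compare_to_reference(scaled, ref), 2 + 1e-9)
  other <- cole_cole_forward(liver_params(), drs_grid(n = 21))
  expect_error(compare_to_reference(other, ref), "identical frequency grid")
})

test_that("type validators reject unphysical inputs", {
  expect_error(permittivity_spectrum(c(2e9, 1e9), c(10, 10), c(1, 1)),
               "strictly increasing")
  expect_error(permittivity_spectrum(c(-1e9, 1e9), c(10, 10), c(1, 1)),
               "positive")
  expect_error(permittivity_spectrum(c(1e9, 2e9), c(10, 10), c(-1, 1)),
               "non-negative")
  expect_error(permittivity_spectrum(1e9, 10, 1), "at least 2")
  expect_error(cole_cole_params(5, 10, 1e-12, 0, 40, 1e-9, 0), "tau_1")
  expect_error(cole_cole_params(5, 10, 1e-9, 1.2, 40, 1e-12, 0), "alpha")
  expect_error(cole_cole_params(5, -1, 1e-9, 0, 40, 1e-12, 0), ">= 0")
  expect_error(cole_cole_forward(liver_params(), c(-1, 1e9)), "positive")
})

test_that("default grid spans 200 MHz-14 GHz; log spacing available", {
  g <- drs_grid()
  expect_length(g, 167)
  expect_equal(g[1], 200e6)
  expect_equal(g[167], 14e9)
  gl <- drs_grid(spacing = "log")
  expect_length(gl, 167)
  expect_equal(range(gl), c(200e6, 14e9))
  expect_true(all(diff(diff(log(gl))) < 1e-9))
})
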