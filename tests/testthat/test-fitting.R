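test_that("noise-free spectra are recovered to 0.1% with R^2 ~ 1", {
  grid <- drs_grid()
  truth <- liver_params()
  fit <- fit_cole_cole(cole_cole_forward(truth, grid))
  expect_true(fit$converged)
  expect_gte(fit$r_squared, 1 - 1e-10)
  nm <- c("eps_inf", "delta_eps_1", "tau_1", "alpha_1",
          "delta_eps_2", "tau_2", "alpha_2")
  for (k in nm)
    expect_lt(abs(fit$params[[k]] - truth[[k]]) / truth[[k]], 1e-3)
})

test_that("initialization converges for the documented start example", {
  truth <- cole_cole_params(5, 10, 1e-9, 0.06, 70, 8e-12, 0.16)
  spec <- cole_cole_forward(truth, drs_grid())
  init <- initialize_parameters(spec)
  expect_s3_class(init, "cole_cole_params")
  expect_equal(init$alpha_1, 0.06)
  expect_equal(init$alpha_2, 0.16)
  expect_equal(init$tau_2, 8e-12)
  fit <- fit_cole_cole(spec, init = init)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$delta_eps_2 - 70) / 70, 1e-3)
  expect_lt(abs(fit$params$tau_2 - 8e-12) / 8e-12, 1e-3)
  narrow <- cole_cole_forward(truth, seq(1e9, 2e9, length.out = 20))
  expect_error(initialize_parameters(narrow), "decade")
})

test_that("a pure Debye spectrum yields a near-zero dominant alpha", {
  truth <- cole_cole_params(5, 0, 1e-6, 0, 70, 8e-12, 0)
  fit <- fit_cole_cole(cole_cole_forward(truth, drs_grid()))
  expect_true(fit$converged)
  dominant_alpha <- if (fit$params$delta_eps_1 > fit$params$delta_eps_2)
    fit$params$alpha_1 else fit$params$alpha_2
  expect_lte(dominant_alpha, 0.01)
})

test_that("parameter recovery holds over random liver-like draws", {
  set.seed(7)
  grid <- drs_grid()
  for (i in 1:50) {
    truth <- random_liver_params()
    fit <- fit_cole_cole(cole_cole_forward(truth, grid))
    expect_true(fit$converged)
    for (k in c("eps_inf", "delta_eps_1", "tau_1", "alpha_1",
                "delta_eps_2", "tau_2", "alpha_2"))
      expect_lt(abs(fit$params[[k]] - truth[[k]]) / max(truth[[k]], 1e-12),
                1e-3)
  }
})

test_that("with measurement noise the water pole is recovered within 10%
           and the low-frequency pole within 25%", {
  set.seed(11)
  for (i in 1:50) {
    truth <- random_liver_params()
    fit <- fit_cole_cole(noisy_liver_spectrum(truth))
    expect_true(fit$converged)
    expect_lt(abs(fit$params$delta_eps_2 - truth$delta_eps_2) /
                truth$delta_eps_2, 0.10)
    expect_lt(abs(fit$params$tau_2 - truth$tau_2) / truth$tau_2, 0.10)
    expect_lt(abs(fit$params$delta_eps_1 - truth$delta_eps_1) /
                truth$delta_eps_1, 0.25)
    expect_lt(abs(fit$params$tau_1 - truth$tau_1) / truth$tau_1, 0.25)
  }
})

test_that("confidence intervals bracket the estimates and poles are ordered", {
  set.seed(3)
  fit <- fit_cole_cole(noisy_liver_spectrum())
  est <- unlist(fit$params[rownames(fit$ci95)])
  expect_true(all(fit$ci95[, "lower"] <= est + 1e-12))
  expect_true(all(fit$ci95[, "upper"] >= est - 1e-12))
  expect_gt(fit$params$tau_1, fit$params$tau_2)
})

test_that("fit is stable under factor-2 grid subsampling, within CI widths", {
  set.seed(5)
  grid <- drs_grid()
  truth <- liver_params()
  spec <- noisy_liver_spectrum(truth, grid)
  fit_full <- fit_cole_cole(spec)
  idx <- seq(1, length(grid), by = 2)
  spec_half <- permittivity_spectrum(grid[idx], spec$eps_real[idx],
                                     spec$eps_imag[idx])
  fit_half <- fit_cole_cole(spec_half)
  width <- fit_full$ci95[, "upper"] - fit_full$ci95[, "lower"]
  est_full <- unlist(fit_full$params[rownames(fit_full$ci95)])
  est_half <- unlist(fit_half$params[rownames(fit_half$ci95)])
  expect_true(all(abs(est_full - est_half) <= width))
})

test_that("R^2 follows its definition on the stacked vector", {
  expect_equal(compute_r_squared(c(0, 1, 2, 3), c(0, 1, 2, 2)), 0.8)
  expect_equal(compute_r_squared(c(1, 2, 5), c(1, 2, 5)), 1)
  obs <- c(3, 1, 4, 1, 5)
  expect_equal(compute_r_squared(obs, rep(mean(obs), 5)), 0)
  expect_error(compute_r_squared(c(2, 2, 2), c(2, 2, 1)), "zero variance")
  # invariant under joint reordering of the stacked entries
  set.seed(1)
  fitd <- obs + rnorm(5, 0, 0.1)
  perm <- sample(5)
  expect_equal(compute_r_squared(obs, fitd),
               compute_r_squared(obs[perm], fitd[perm]))
})

test_that("bad inputs and non-convergence are surfaced, never silent", {
  grid <- drs_grid()
  spec <- cole_cole_forward(liver_params(), grid)
  bad <- spec
  bad$eps_real[5] <- NaN
  expect_error(fit_cole_cole(bad), "NA/NaN")
  short <- cole_cole_forward(liver_params(), drs_grid(n = 8))
  expect_error(fit_cole_cole(short), "at least 10")
  # starved optimizer must flag itself
  stunted <- fit_cole_cole(spec, maxiter = 1)
  expect_false(stunted$converged)
})

test_that("a flat spectrum is flagged degenerate", {
  grid <- drs_grid(n = 20)
  flat <- permittivity_spectrum(grid, rep(10, 20), rep(10, 20))
  expect_warning(fit <- fit_cole_cole(flat, init = liver_params()),
                 "degenerate")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$r_squared))
})
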