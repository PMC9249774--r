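# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

liver_params <- function() {
  cole_cole_params(4, 15, 0.8e-9, 0.06, 37.614, 7e-12, 0.16)
}

# Liver-level spectrum: per-replicate multiplicative noise averaged over
# n_rep replicates, the way measured livers are summarized before fitting.
noisy_liver_spectrum <- function(params = liver_params(), grid = drs_grid(),
                                 noise_sd = 0.01, n_rep = 20) {
  s <- cole_cole_forward(params, grid)
  nf <- length(grid)
  er <- s$eps_real * colMeans(matrix(rnorm(nf * n_rep, 1, noise_sd), n_rep))
  ei <- s$eps_imag * colMeans(matrix(rnorm(nf * n_rep, 1, noise_sd), n_rep))
  permittivity_spectrum(grid, pmax(er, 1), pmax(ei, 0))
}

# Random liver-like parameter draw around the baseline (lognormal scale
# multipliers, additive alpha jitter), mirroring inter-liver variability.
random_liver_params <- function(cv = 0.05) {
  b <- liver_params()
  sdlog <- sqrt(log(1 + cv^2))
  m <- exp(rnorm(4, -sdlog^2 / 2, sdlog))
  cole_cole_params(b$eps_inf,
                   b$delta_eps_1 * m[1], b$tau_1 * m[2],
                   min(max(b$alpha_1 + rnorm(1, 0, 0.005), 0), 0.3),
                   b$delta_eps_2 * m[3], b$tau_2 * m[4],
                   min(max(b$alpha_2 + rnorm(1, 0, 0.005), 0), 0.3))
}

# Minimal long-format study: one group, `hours` timepoints, `n` livers,
# one site/replicate, a 2-point grid, conductivity-flat spectra whose
# eps'' values are supplied per (liver, hour) by `value_fn(liver, hour)`.
tiny_study <- function(n = 7, hours = 1:4, group = "CON",
                       value_fn = function(liver, hour) 10) {
  grid <- c(1e9, 2e9)
  rows <- list()
  for (h in hours) for (l in seq_len(n)) {
    v <- value_fn(l, h)
    rows[[length(rows) + 1]] <- data.frame(
      liver_id = paste0(group, "-", l), group = group, phase = "invivo",
      hour = h, site = 1L, replicate = 1L, frequency_hz = grid,
      eps_real = 50, eps_imag = v)
  }
  drs_study(do.call(rbind, rows))
}
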