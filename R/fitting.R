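# Internal parameter vector used by the optimizer:
# (eps_inf, delta_eps_1, log10_tau_1, alpha_1, delta_eps_2, log10_tau_2, alpha_2)
# Relaxation times are fitted on a log10 scale: they span picoseconds to
# microseconds and the log transform keeps the Jacobian well conditioned.
.par_names <- c("eps_inf", "delta_eps_1", "tau_1", "alpha_1",
                "delta_eps_2", "tau_2", "alpha_2")

.theta_from_params <- function(p) {
  c(p$eps_inf, p$delta_eps_1, log10(p$tau_1), p$alpha_1,
    p$delta_eps_2, log10(p$tau_2), p$alpha_2)
}

.params_from_theta <- function(th) {
  list(eps_inf = th[1], delta_eps_1 = th[2], tau_1 = 10^th[3], alpha_1 = th[4],
       delta_eps_2 = th[5], tau_2 = 10^th[6], alpha_2 = th[7])
}

.cc_model_stacked <- function(th, frequencies) {
  p <- .params_from_theta(th)
  eps <- p$eps_inf +
    .cc_pole(p$delta_eps_1, p$tau_1, p$alpha_1, frequencies) +
    .cc_pole(p$delta_eps_2, p$tau_2, p$alpha_2, frequencies)
  c(Re(eps), -Im(eps))
}

#' Default fitting bounds
#'
#' Box constraints for [fit_cole_cole()]: relaxation strengths
#' non-negative, relaxation times between 0.1 ps and 1 us, broadening
#' parameters in \[0, 0.5\], and the high-frequency limit in \[1, 20\].
#'
#' @return A list with numeric vectors `lower` and `upper` named by
#'   parameter.
#' @export
default_fit_bounds <- function() {
  list(
    lower = c(eps_inf = 1, delta_eps_1 = 0, tau_1 = 1e-13, alpha_1 = 0,
              delta_eps_2 = 0, tau_2 = 1e-13, alpha_2 = 0),
    upper = c(eps_inf = 20, delta_eps_1 = 1e4, tau_1 = 1e-6, alpha_1 = 0.5,
              delta_eps_2 = 1e4, tau_2 = 1e-6, alpha_2 = 0.5)
  )
}

.bounds_to_theta <- function(bounds) {
  list(
    lower = c(bounds$lower[["eps_inf"]], bounds$lower[["delta_eps_1"]],
              log10(bounds$lower[["tau_1"]]), bounds$lower[["alpha_1"]],
              bounds$lower[["delta_eps_2"]], log10(bounds$lower[["tau_2"]]),
              bounds$lower[["alpha_2"]]),
    upper = c(bounds$upper[["eps_inf"]], bounds$upper[["delta_eps_1"]],
              log10(bounds$upper[["tau_1"]]), bounds$upper[["alpha_1"]],
              bounds$upper[["delta_eps_2"]], log10(bounds$upper[["tau_2"]]),
              bounds$upper[["alpha_2"]])
  )
}

#' Heuristic starting parameters for a liver-like spectrum
#'
#' Seeds the two-pole fit. The water pole is assumed to have the
#' characteristic liver values tau = 8 ps and alpha = 0.16; with those
#' fixed, eps_inf and delta_eps_2 follow from a two-point linear solve of
#' the real-permittivity model at ~2 GHz (where pole 1 has fully relaxed)
#' and at the top of the band. The low-frequency pole is then seeded from
#' the static-limit estimate (delta_eps_1 = eps'(f_min) - eps_inf -
#' delta_eps_2, floored at 1), tau_1 = 1 ns, alpha_1 = 0.06.
#'
#' A plain "eps_inf = min eps'" start is not used: at 14 GHz the band
#' still sits below the water relaxation peak, so min eps' overestimates
#' eps_inf severely and strands the optimizer in a wrong basin.
#'
#' @param spectrum A [permittivity_spectrum()] covering at least one
#'   decade of frequency.
#' @return A [cole_cole_params()] starting point.
#' @export
initialize_parameters <- function(spectrum) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  f <- spectrum$frequencies
  if (length(f) < 4 || max(f) / min(f) < 10)
    stop("spectrum must cover at least one decade of frequency")
  if (all(is.na(spectrum$eps_real)))
    stop("initialization needs the real permittivity")
  er <- spectrum$eps_real
  tau2 <- 8e-12; alpha2 <- 0.16
  relax <- function(fq) Re(1 / (1 + (1i * 2 * pi * fq * tau2)^(1 - alpha2)))
  i_mid <- which.min(abs(f - 2e9))
  i_top <- length(f)
  c_mid <- relax(f[i_mid]); c_top <- relax(f[i_top])
  if (abs(c_mid - c_top) < 1e-9) { # degenerate band: fall back to min eps'
    eps_inf <- min(er); d2 <- max(er[i_mid] - eps_inf, 0)
  } else {
    d2 <- (er[i_mid] - er[i_top]) / (c_mid - c_top)
    eps_inf <- er[i_top] - d2 * c_top
  }
  b <- default_fit_bounds()
  eps_inf <- min(max(eps_inf, b$lower[["eps_inf"]]), b$upper[["eps_inf"]])
  d2 <- max(d2, 0)
  d1 <- max(er[1] - eps_inf - d2, 1)
  cole_cole_params(eps_inf, d1, 1e-9, 0.06, d2, tau2, alpha2)
}

#' Coefficient of determination on a stacked observation vector
#'
#' \eqn{R^2 = 1 - SS_{res} / SS_{tot}} with the total sum of squares
#' taken about the mean of the stacked observed vector. For the complex
#' permittivity fit the stacked vector is
#' \eqn{(\varepsilon'_1, \ldots, \varepsilon'_n, \varepsilon''_1, \ldots,
#' \varepsilon''_n)}.
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @return A single number <= 1; exactly 1 when residuals are all zero.
#' @export
#' @examples
#' compute_r_squared(c(0, 1, 2, 3), c(0, 1, 2, 2)) # 0.8
compute_r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("observed and fitted must have equal length")
  if (anyNA(observed) || anyNA(fitted)) stop("NA values not allowed")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance; R^2 undefined")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Fit the two-pole Cole-Cole model to a measured spectrum
#'
#' Minimizes the unweighted stacked residual
#' \eqn{[\varepsilon'_{model} - \varepsilon'_{data};\;
#' \varepsilon''_{model} - \varepsilon''_{data}]} over the seven model
#' parameters with the bounded Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]). Relaxation times are optimized on a log10
#' scale. 95% confidence intervals are t-quantile times the standard
#' errors from \eqn{(J^T J)^{-1} s^2} at the optimum; intervals for the
#' relaxation times are computed on the log scale and back-transformed.
#' After fitting, poles are relabeled so that `tau_1 > tau_2` (tie-break:
#' the pole with larger relaxation strength becomes pole 2, the water
#' pole).
#'
#' @param spectrum A [permittivity_spectrum()] with at least 10 grid
#'   points and no missing values.
#' @param init Optional [cole_cole_params()] starting point; default
#'   [initialize_parameters()].
#' @param bounds Optional list with named vectors `lower`/`upper` as in
#'   [default_fit_bounds()].
#' @param scale Residual scale to fit on: `"stacked"` (default) fits
#'   \eqn{\varepsilon'} and \eqn{\varepsilon''} jointly; `"loss"` fits
#'   \eqn{\varepsilon''} alone.
#' @param maxiter Maximum number of Levenberg-Marquardt iterations.
#' @return An object of class `drs_fit`: a list with elements `params`
#'   ([cole_cole_params()]), `ci95` (7 x 2 matrix of lower/upper bounds),
#'   `r_squared`, `residual_norm`, `n_iterations`, `converged`,
#'   `degenerate`, `df_residual` and `message`.
#' @export
fit_cole_cole <- function(spectrum, init = NULL, bounds = NULL,
                          scale = c("stacked", "loss"), maxiter = 500) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  scale <- match.arg(scale)
  f <- spectrum$frequencies
  if (length(f) < 10) stop("fit needs at least 10 grid points")
  if (anyNA(spectrum$eps_imag) ||
      (scale == "stacked" && anyNA(spectrum$eps_real)))
    stop("NA/NaN values in the spectrum; clean the input first")
  if (is.null(init)) init <- initialize_parameters(spectrum)
  stopifnot(inherits(init, "cole_cole_params"))
  if (is.null(bounds)) bounds <- default_fit_bounds()
  bt <- .bounds_to_theta(bounds)

  observed <- switch(scale,
    stacked = c(spectrum$eps_real, spectrum$eps_imag),
    loss = spectrum$eps_imag
  )
  resid_fn <- function(th, frequencies, observed, scale) {
    m <- .cc_model_stacked(th, frequencies)
    if (scale == "loss") m <- m[-seq_along(frequencies)]
    m - observed
  }
  th0 <- pmin(pmax(.theta_from_params(init), bt$lower), bt$upper)
  # non-convergence is reported through the `converged` flag, not as a
  # condition, so the optimizer's own iteration-limit warning is muted
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = th0, lower = bt$lower, upper = bt$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxfev = 2000, maxiter = maxiter),
    frequencies = f, observed = observed, scale = scale
  ))
  converged <- fit$info %in% 1:4
  th <- fit$par
  n <- length(observed); p <- length(th)
  df_res <- n - p

  # covariance on the internal (log-tau) scale; fall back to a
  # pseudo-inverse when a parameter sits on an active bound
  sigma2 <- fit$deviance / df_res
  covar <- tryCatch(solve(fit$hessian), error = function(e) MASS::ginv(fit$hessian))
  se <- sqrt(pmax(diag(covar), 0) * sigma2)
  tq <- qt(0.975, df_res)
  ci_lo <- th - tq * se
  ci_hi <- th + tq * se

  # back-transform to natural scale (tau CIs exponentiated)
  nat <- function(v) c(v[1], v[2], 10^v[3], v[4], v[5], 10^v[6], v[7])
  est <- nat(th); lo <- nat(ci_lo); hi <- nat(ci_hi)

  # relabel poles so tau_1 > tau_2
  i1 <- 2:4; i2 <- 5:7
  swap <- est[3] < est[6] ||
    (est[3] == est[6] && est[2] > est[5]) # tie: larger strength -> pole 2
  if (swap) {
    est[c(i1, i2)] <- est[c(i2, i1)]
    lo[c(i1, i2)] <- lo[c(i2, i1)]
    hi[c(i1, i2)] <- hi[c(i2, i1)]
  }
  ci95 <- cbind(lower = lo, upper = hi)
  rownames(ci95) <- .par_names

  ss_tot <- sum((observed - mean(observed))^2)
  degenerate <- ss_tot == 0
  if (degenerate) {
    warning("observed spectrum has zero variance; fit is degenerate")
    r2 <- NA_real_
  } else {
    r2 <- 1 - fit$deviance / ss_tot
  }

  params <- cole_cole_params(est[1], est[2], est[3], est[4],
                             est[5], est[6], est[7])
  structure(
    list(params = params, ci95 = ci95, r_squared = r2,
         residual_norm = sqrt(fit$deviance), n_iterations = fit$niter,
         converged = converged, degenerate = degenerate,
         df_residual = df_res, scale = scale, message = fit$message),
    class = "drs_fit"
  )
}

#' @export
print.drs_fit <- function(x, ...) {
  cat(sprintf("<drs_fit> %s after %d iterations (R^2 = %s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations,
              if (is.na(x$r_squared)) "NA" else sprintf("%.6f", x$r_squared)))
  est <- unlist(x$params[.par_names])
  tab <- cbind(estimate = est, x$ci95)
  print(signif(tab, 5))
  invisible(x)
}
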