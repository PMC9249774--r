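#' Measurement frequency grid
#'
#' Default grid used throughout: 167 points spanning 200 MHz to 14 GHz,
#' the combined working range of a DAK 3.5 coaxial probe and an R140
#' vector network analyzer. Linear spacing is the default; logarithmic
#' spacing is available since the instrument sweep mode is configurable.
#'
#' @param f_min,f_max Band edges in Hz.
#' @param n Number of grid points.
#' @param spacing `"linear"` or `"log"`.
#' @return Numeric vector of strictly increasing frequencies in Hz.
#' @export
#' @examples
#' f <- drs_grid()
#' length(f) # 167
drs_grid <- function(f_min = 200e6, f_max = 14e9, n = 167,
                     spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 || f_max <= f_min)
    stop("need 0 < f_min < f_max")
  if (n < 2) stop("grid needs at least 2 points")
  switch(spacing,
    linear = seq(f_min, f_max, length.out = n),
    log    = exp(seq(log(f_min), log(f_max), length.out = n))
  )
}

#' Complex permittivity spectrum
#'
#' One measurement: a frequency grid with the real permittivity
#' \eqn{\varepsilon'} (energy storage) and the dielectric loss
#' \eqn{\varepsilon''} (energy dissipation), both dimensionless relative
#' permittivities. The sign convention is
#' \eqn{\varepsilon^* = \varepsilon' - j\varepsilon''} with
#' \eqn{\varepsilon'' \ge 0} stored positive.
#'
#' `eps_real` may be `NA` throughout for loss-only spectra (e.g. the
#' output of [conductivity_to_loss()] or [separate_dispersions()]).
#'
#' @param frequencies Strictly increasing positive frequencies, Hz.
#' @param eps_real Real permittivity, all values >= 1 (or all `NA`).
#' @param eps_imag Dielectric loss, all values >= 0.
#' @param temperature Sample temperature in deg C; metadata only.
#' @return An object of class `permittivity_spectrum`.
#' @export
permittivity_spectrum <- function(frequencies, eps_real, eps_imag,
                                  temperature = 37.5) {
  frequencies <- as.numeric(frequencies)
  eps_real <- as.numeric(eps_real)
  eps_imag <- as.numeric(eps_imag)
  n <- length(frequencies)
  if (n < 2) stop("a spectrum needs at least 2 grid points")
  if (length(eps_real) != n || length(eps_imag) != n)
    stop("frequencies, eps_real and eps_imag must have equal length")
  if (anyNA(frequencies) || any(frequencies <= 0))
    stop("all frequencies must be positive")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing (first violation at row ",
         which(diff(frequencies) <= 0)[1] + 1, ")")
  if (anyNA(eps_real)) {
    if (!all(is.na(eps_real)))
      stop("eps_real must be fully specified or all NA (loss-only spectrum)")
  } else if (any(eps_real < 1 - 1e-9)) {
    stop("eps_real must be >= 1 for a physical relative permittivity")
  }
  if (anyNA(eps_imag) || any(eps_imag < -1e-12))
    stop("eps_imag must be non-negative for a physical spectrum")
  structure(
    list(frequencies = frequencies, eps_real = eps_real,
         eps_imag = pmax(eps_imag, 0), temperature = temperature),
    class = "permittivity_spectrum"
  )
}

#' @export
print.permittivity_spectrum <- function(x, ...) {
  cat(sprintf("<permittivity_spectrum> %d points, %.3g-%.3g Hz, %.1f degC\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$temperature))
  if (all(is.na(x$eps_real))) {
    cat(sprintf("  loss-only; eps'' in [%.3g, %.3g]\n",
                min(x$eps_imag), max(x$eps_imag)))
  } else {
    cat(sprintf("  eps' in [%.3g, %.3g]; eps'' in [%.3g, %.3g]\n",
                min(x$eps_real), max(x$eps_real),
                min(x$eps_imag), max(x$eps_imag)))
  }
  invisible(x)
}

#' Conductivity spectrum
#'
#' Dielectric conductivity \eqn{\sigma = 2\pi f \varepsilon_0
#' \varepsilon''} in S/m on a frequency grid. This is the energy-loss
#' expression of the dielectric loss, not a static (ionic) conductivity.
#'
#' @param frequencies Strictly increasing positive frequencies, Hz.
#' @param sigma Non-negative conductivities, S/m.
#' @return An object of class `conductivity_spectrum`.
#' @export
conductivity_spectrum <- function(frequencies, sigma) {
  frequencies <- as.numeric(frequencies)
  sigma <- as.numeric(sigma)
  if (length(frequencies) < 2) stop("a spectrum needs at least 2 grid points")
  if (length(sigma) != length(frequencies))
    stop("frequencies and sigma must have equal length")
  if (anyNA(frequencies) || any(frequencies <= 0))
    stop("all frequencies must be positive")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  if (anyNA(sigma) || any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(frequencies = frequencies, sigma = sigma),
            class = "conductivity_spectrum")
}

#' Two-pole Cole-Cole parameter set
#'
#' Parameters of the relaxation model
#' \deqn{\varepsilon^*(\omega) = \varepsilon_\infty +
#'   \frac{\Delta\varepsilon_1}{1 + (j\omega\tau_1)^{1-\alpha_1}} +
#'   \frac{\Delta\varepsilon_2}{1 + (j\omega\tau_2)^{1-\alpha_2}}}
#' with \eqn{\omega = 2\pi f}. Pole 1 is the low-frequency process
#' (molecules larger than water, beta-dispersion region) and pole 2 the
#' high-frequency water process (gamma region), so \eqn{\tau_1 > \tau_2}
#' is enforced. \eqn{\alpha \in [0, 1)} broadens the relaxation-time
#' distribution; \eqn{\alpha = 0} is the Debye model.
#'
#' Derived quantities: static permittivity
#' \eqn{\varepsilon_s = \varepsilon_\infty + \Delta\varepsilon_1 +
#' \Delta\varepsilon_2} and intermediate permittivity
#' \eqn{\varepsilon_1 = \varepsilon_\infty + \Delta\varepsilon_2}.
#'
#' @param eps_inf High-frequency permittivity limit, > 0.
#' @param delta_eps_1 Relaxation strength of pole 1, >= 0.
#' @param tau_1 Relaxation time of pole 1, seconds, > 0.
#' @param alpha_1 Broadening of pole 1, in \[0, 1).
#' @param delta_eps_2 Relaxation strength of pole 2 (water), >= 0.
#' @param tau_2 Relaxation time of pole 2, seconds; must satisfy
#'   `tau_2 < tau_1`.
#' @param alpha_2 Broadening of pole 2, in \[0, 1).
#' @return An object of class `cole_cole_params` with fields as above plus
#'   derived `eps_static` and `eps_intermediate`.
#' @export
#' @examples
#' p <- cole_cole_params(4, 15, 0.8e-9, 0.06, 37.6, 7e-12, 0.16)
#' p$eps_static
cole_cole_params <- function(eps_inf, delta_eps_1, tau_1, alpha_1,
                             delta_eps_2, tau_2, alpha_2) {
  stopifnot(is.numeric(eps_inf), is.numeric(delta_eps_1), is.numeric(tau_1),
            is.numeric(alpha_1), is.numeric(delta_eps_2), is.numeric(tau_2),
            is.numeric(alpha_2))
  if (eps_inf <= 0) stop("eps_inf must be > 0")
  if (delta_eps_1 < 0 || delta_eps_2 < 0) stop("relaxation strengths must be >= 0")
  if (tau_1 <= 0 || tau_2 <= 0) stop("relaxation times must be > 0")
  if (alpha_1 < 0 || alpha_1 >= 1 || alpha_2 < 0 || alpha_2 >= 1)
    stop("alpha must lie in [0, 1)")
  if (tau_1 <= tau_2)
    stop("tau_1 must exceed tau_2 (pole 1 is the low-frequency process)")
  structure(
    list(eps_inf = eps_inf,
         delta_eps_1 = delta_eps_1, tau_1 = tau_1, alpha_1 = alpha_1,
         delta_eps_2 = delta_eps_2, tau_2 = tau_2, alpha_2 = alpha_2,
         eps_static = eps_inf + delta_eps_1 + delta_eps_2,
         eps_intermediate = eps_inf + delta_eps_2),
    class = "cole_cole_params"
  )
}

#' @export
print.cole_cole_params <- function(x, ...) {
  cat("<cole_cole_params>\n")
  cat(sprintf("  eps_inf = %.4g, eps_static = %.4g\n", x$eps_inf, x$eps_static))
  cat(sprintf("  pole 1: delta_eps = %.4g, tau = %.4g s, alpha = %.4g\n",
              x$delta_eps_1, x$tau_1, x$alpha_1))
  cat(sprintf("  pole 2: delta_eps = %.4g, tau = %.4g s, alpha = %.4g\n",
              x$delta_eps_2, x$tau_2, x$alpha_2))
  invisible(x)
}

# Complex permittivity of one Cole-Cole pole; principal branch of the
# complex power, (j w tau)^(1-a) = (w tau)^(1-a) exp(j pi (1-a) / 2).
.cc_pole <- function(delta_eps, tau, alpha, frequencies) {
  delta_eps / (1 + (1i * 2 * pi * frequencies * tau)^(1 - alpha))
}

#' Evaluate the two-pole Cole-Cole model
#'
#' Forward model: returns \eqn{\varepsilon'(f) = \mathrm{Re}\,
#' \varepsilon^*} and \eqn{\varepsilon''(f) = -\mathrm{Im}\,
#' \varepsilon^*} on the given grid.
#'
#' @param params A [cole_cole_params()] object.
#' @param frequencies Positive frequencies in Hz (strictly increasing).
#' @param temperature Metadata passed to the returned spectrum.
#' @return A [permittivity_spectrum()].
#' @export
#' @examples
#' p <- cole_cole_params(5, 0, 1e-9, 0, 70, 8e-12, 0)
#' s <- cole_cole_forward(p, drs_grid())
cole_cole_forward <- function(params, frequencies, temperature = 37.5) {
  stopifnot(inherits(params, "cole_cole_params"))
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  eps <- params$eps_inf +
    .cc_pole(params$delta_eps_1, params$tau_1, params$alpha_1, frequencies) +
    .cc_pole(params$delta_eps_2, params$tau_2, params$alpha_2, frequencies)
  permittivity_spectrum(frequencies, Re(eps), -Im(eps),
                        temperature = temperature)
}

#' Separate the two dispersion processes
#'
#' Splits the total dielectric loss into the additive contributions of
#' pole 1 (low-frequency, large molecules) and pole 2 (high-frequency,
#' water). The two loss curves sum exactly to the total loss of
#' [cole_cole_forward()] at every frequency.
#'
#' @inheritParams cole_cole_forward
#' @return A list with loss-only spectra `pole1` and `pole2`.
#' @export
separate_dispersions <- function(params, frequencies, temperature = 37.5) {
  stopifnot(inherits(params, "cole_cole_params"))
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  e1 <- .cc_pole(params$delta_eps_1, params$tau_1, params$alpha_1, frequencies)
  e2 <- .cc_pole(params$delta_eps_2, params$tau_2, params$alpha_2, frequencies)
  na <- rep(NA_real_, length(frequencies))
  list(
    pole1 = permittivity_spectrum(frequencies, na, -Im(e1), temperature),
    pole2 = permittivity_spectrum(frequencies, na, -Im(e2), temperature)
  )
}

#' Single-pole Debye model for water
#'
#' Convenience wrapper for a pure Debye relaxation (Cole-Cole with
#' \eqn{\alpha = 0}), the standard model for deionized water in the
#' microwave band. Evaluates via [cole_cole_forward()] with the water
#' process placed in pole 2.
#'
#' @param eps_s Static permittivity, must exceed `eps_inf`.
#' @param eps_inf High-frequency permittivity limit, > 0.
#' @param tau Relaxation time, seconds.
#' @param frequencies Positive frequencies, Hz.
#' @param temperature Metadata, deg C.
#' @return A [permittivity_spectrum()].
#' @export
debye_water_model <- function(eps_s, eps_inf, tau, frequencies,
                              temperature = 37.5) {
  if (!(eps_s > eps_inf && eps_inf > 0)) stop("need eps_s > eps_inf > 0")
  if (tau <= 0) stop("tau must be > 0")
  params <- cole_cole_params(eps_inf, 0, tau * 1e3, 0, eps_s - eps_inf, tau, 0)
  cole_cole_forward(params, frequencies, temperature = temperature)
}

#' Convert dielectric loss to conductivity
#'
#' \eqn{\sigma(f) = 2\pi f \varepsilon_0 \varepsilon''(f)}, the exact
#' inverse of [conductivity_to_loss()].
#'
#' @param spectrum A [permittivity_spectrum()].
#' @return A [conductivity_spectrum()].
#' @export
loss_to_conductivity <- function(spectrum) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  conductivity_spectrum(spectrum$frequencies,
                        2 * pi * spectrum$frequencies * .eps0 * spectrum$eps_imag)
}

#' Convert conductivity to dielectric loss
#'
#' \eqn{\varepsilon''(f) = \sigma(f) / (2\pi f \varepsilon_0)}. Returns a
#' loss-only spectrum (`eps_real` is `NA`).
#'
#' @param spectrum A [conductivity_spectrum()].
#' @param temperature Metadata, deg C.
#' @return A loss-only [permittivity_spectrum()].
#' @export
conductivity_to_loss <- function(spectrum, temperature = 37.5) {
  stopifnot(inherits(spectrum, "conductivity_spectrum"))
  permittivity_spectrum(
    spectrum$frequencies,
    rep(NA_real_, length(spectrum$frequencies)),
    spectrum$sigma / (2 * pi * spectrum$frequencies * .eps0),
    temperature = temperature
  )
}

#' Maximum relative deviation from a reference spectrum
#'
#' Probe-calibration verification: the maximum over the grid and over
#' both components (\eqn{\varepsilon'}, \eqn{\varepsilon''}) of
#' \eqn{|measured - reference| / |reference| \times 100}. Measurements on
#' a verification liquid (0.1 mol/L saline) are accepted when the
#' deviation stays within 2%.
#'
#' @param measured,reference [permittivity_spectrum()] objects on the
#'   identical frequency grid.
#' @return Maximum relative deviation in percent (a single number).
#' @export
compare_to_reference <- function(measured, reference) {
  stopifnot(inherits(measured, "permittivity_spectrum"),
            inherits(reference, "permittivity_spectrum"))
  if (length(measured$frequencies) != length(reference$frequencies) ||
      any(measured$frequencies != reference$frequencies))
    stop("measured and reference must share an identical frequency grid")
  dev <- numeric(0)
  if (!all(is.na(measured$eps_real)) && !all(is.na(reference$eps_real)))
    dev <- c(dev, abs(measured$eps_real - reference$eps_real) /
                   abs(reference$eps_real))
  dev <- c(dev, abs(measured$eps_imag - reference$eps_imag) /
                 abs(reference$eps_imag))
  max(dev) * 100
}
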