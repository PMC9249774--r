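#' Default Debye parameters for deionized water at 37.5 degC
#'
#' Literature-typical single-Debye description of pure water near body
#' temperature: static permittivity 74.0, high-frequency limit 5.2,
#' relaxation time 6.2 ps. These are configuration values; replace them
#' with a measured water spectrum via [water_reference()] when one is
#' available.
#'
#' @return A list with `eps_s`, `eps_inf`, `tau` (seconds) and
#'   `temperature` (deg C).
#' @export
water_debye_default <- function() {
  list(eps_s = 74.0, eps_inf = 5.2, tau = 6.2e-12, temperature = 37.5)
}

#' Deionized-water reference spectrum
#'
#' Returns the dielectric loss curve of deionized water on the given
#' grid, either generated from single-pole Debye parameters (default) or
#' loaded from a measured spectrum file. File input is never regridded:
#' its frequency grid must match `grid` exactly.
#'
#' @param grid Frequency grid in Hz.
#' @param debye List with `eps_s`, `eps_inf`, `tau` (and optionally
#'   `temperature`), as returned by [water_debye_default()].
#' @param file Optional path to a spectrum CSV (see
#'   [read_spectrum_csv()]); overrides `debye`.
#' @return A [permittivity_spectrum()].
#' @export
water_reference <- function(grid, debye = water_debye_default(), file = NULL) {
  if (!is.null(file)) {
    ref <- read_spectrum_csv(file)
    if (length(ref$frequencies) != length(grid) ||
        any(ref$frequencies != grid))
      stop("water reference file grid does not match the requested grid; ",
           "regridding is not supported")
    return(ref)
  }
  temp <- if (is.null(debye$temperature)) 37.5 else debye$temperature
  debye_water_model(debye$eps_s, debye$eps_inf, debye$tau, grid,
                    temperature = temp)
}

#' Estimate tissue water content from the separated water dispersion
#'
#' Water content in percent is the ratio of the summed dielectric loss of
#' the liver's high-frequency (water) dispersion to the summed dielectric
#' loss of deionized water on the same grid:
#' \deqn{\mathrm{water\ content}\,[\%] =
#'   \frac{\sum \varepsilon''_{water\ pole\ in\ liver}}
#'        {\sum \varepsilon''_{deionized\ water}} \times 100}
#' The numerator is the pole-2 loss from [separate_dispersions()]. Both
#' sums run over the identical grid. The plain sum is the default; with a
#' linear grid it is proportional to a trapezoidal integral, and an
#' explicit trapezoid mode is available.
#'
#' The method systematically underestimates absolute (gravimetric) water
#' content because tissue water is partially bound and relaxes more
#' slowly than free water; no bound-water correction is applied.
#'
#' @param fit A converged [fit_cole_cole()] result, or a
#'   [cole_cole_params()] object.
#' @param reference Deionized-water [permittivity_spectrum()] from
#'   [water_reference()]; its grid defines the summation window.
#' @param method `"sum"` (default, the literal definition) or
#'   `"trapezoid"`.
#' @return An object of class `water_content_estimate`: list with
#'   `percent`, `numerator_sum`, `denominator_sum`, `grid_id`.
#' @export
estimate_water_content <- function(fit, reference,
                                   method = c("sum", "trapezoid")) {
  method <- match.arg(method)
  if (inherits(fit, "drs_fit")) {
    if (!isTRUE(fit$converged))
      stop("fit did not converge; refusing to estimate water content")
    params <- fit$params
  } else if (inherits(fit, "cole_cole_params")) {
    params <- fit
  } else {
    stop("fit must be a drs_fit or cole_cole_params object")
  }
  stopifnot(inherits(reference, "permittivity_spectrum"))
  grid <- reference$frequencies
  pole2 <- separate_dispersions(params, grid)$pole2
  acc <- switch(method,
    sum = function(y) sum(y),
    trapezoid = function(y) sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
  )
  num <- acc(pole2$eps_imag)
  den <- acc(reference$eps_imag)
  if (den == 0) stop("reference loss sums to zero; cannot form the ratio")
  structure(
    list(percent = num / den * 100,
         numerator_sum = num, denominator_sum = den,
         grid_id = sprintf("%g-%g Hz, %d points", min(grid), max(grid),
                           length(grid))),
    class = "water_content_estimate"
  )
}

#' @export
print.water_content_estimate <- function(x, ...) {
  cat(sprintf("<water_content_estimate> %.2f%% (grid %s)\n",
              x$percent, x$grid_id))
  invisible(x)
}
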