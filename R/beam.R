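# Physical constants (CODATA 2018).
.const <- list(
  me_c2_keV = 510.99895,     # electron rest energy
  hc_keV_pm = 1239.8419844,  # h*c
  a0_A      = 0.52917721067, # Bohr radius
  amu       = 1.66053907     # atomic mass unit, 1e-24 g
)

#' Relativistic beam parameters
#'
#' Derives the quantities that govern electron-specimen interaction at a given
#' accelerating voltage: the Lorentz factor, the relativistic de Broglie
#' wavelength, the wavevector and the interaction constant sigma that converts
#' projected potential (in volts) to phase shift.
#'
#' @param energy_keV Accelerating voltage in keV (scalar, > 0).
#' @return An object of class `em_beam` with fields `energy` (keV), `gamma`
#'   (dimensionless Lorentz factor), `wavelength` (pm), `wavevector`
#'   (2*pi/wavelength, 1/pm) and `sigma` (rad per volt per Angstrom).
#' @examples
#' b <- beam_parameters(200)
#' b$wavelength  # ~2.508 pm
#' @export
beam_parameters <- function(energy_keV) {
  if (!is.numeric(energy_keV) || length(energy_keV) != 1L ||
      !is.finite(energy_keV) || energy_keV <= 0) {
    stop("`energy_keV` must be a single positive number", call. = FALSE)
  }
  E <- as.numeric(energy_keV)
  mc2 <- .const$me_c2_keV
  lambda_pm <- .const$hc_keV_pm / sqrt(E * (E + 2 * mc2))
  gamma <- 1 + E / mc2
  lambda_A <- lambda_pm * 1e-2
  # interaction constant, rad / (V * Angstrom)
  sigma <- 2 * pi / (lambda_A * E * 1e3) * (mc2 + E) / (2 * mc2 + E)
  structure(
    list(energy = E, gamma = gamma, wavelength = lambda_pm,
         wavevector = 2 * pi / lambda_pm, sigma = sigma),
    class = "em_beam"
  )
}

#' @export
print.em_beam <- function(x, ...) {
  cat(sprintf("<em_beam> %g keV: lambda = %.4f pm, gamma = %.4f, sigma = %.4g rad/(V.A)\n",
              x$energy, x$wavelength, x$gamma, x$sigma))
  invisible(x)
}

.as_beam <- function(beam) {
  if (inherits(beam, "em_beam")) beam else beam_parameters(beam)
}

.lambda_nm <- function(beam) beam$wavelength * 1e-3
.lambda_A  <- function(beam) beam$wavelength * 1e-2

#' Product lambda * gamma and its square
#'
#' `lambda_gamma_product()` returns the product of the relativistic wavelength
#' and the Lorentz factor, the quantity that scales the Fourier coefficients of
#' the scattering potential.  It decreases monotonically with accelerating
#' voltage and saturates at the Compton wavelength (~2.43 pm), which is why
#' MeV voltages buy little extra weak-phase validity.
#' `lambda_gamma_sq_ratio()` gives the factor by which incoherent mean free
#' paths grow relative to a reference voltage (mfp proportional to
#' 1/(lambda*gamma)^2).
#'
#' @param energy_keV Accelerating voltage(s) in keV.
#' @param ref_energy_keV Reference voltage for the mean-free-path scaling.
#' @return `lambda_gamma_product()`: lambda*gamma in pm.
#'   `lambda_gamma_sq_ratio()`: dimensionless scaling
#'   (lambda*gamma)^2_ref / (lambda*gamma)^2_E.
#' @export
lambda_gamma_product <- function(energy_keV) {
  vapply(energy_keV, function(E) {
    b <- beam_parameters(E)
    b$wavelength * b$gamma
  }, numeric(1))
}

#' @rdname lambda_gamma_product
#' @export
lambda_gamma_sq_ratio <- function(energy_keV, ref_energy_keV = 200) {
  (lambda_gamma_product(ref_energy_keV) / lambda_gamma_product(energy_keV))^2
}
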