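# Parameterised elastic electron scattering factors (Born approximation),
# 5-Gaussian fits f(s) = sum_i a_i exp(-b_i s^2) with s = sin(theta/2)/lambda
# in 1/Angstrom, after Peng et al.'s neutral-atom tables.  Only the elements
# occurring in vitreous ice, protein and nucleic acid are shipped.
.peng <- list(
  H = list(Z = 1,  A = 1.008,
           a = c(0.0349, 0.1201, 0.1970, 0.0573, 0.1195),
           b = c(0.5347, 3.5867, 12.3471, 18.9525, 38.6269)),
  C = list(Z = 6,  A = 12.011,
           a = c(0.0893, 0.2563, 0.7570, 1.0487, 0.3575),
           b = c(0.2465, 1.7100, 6.4094, 18.6113, 50.2523)),
  N = list(Z = 7,  A = 14.007,
           a = c(0.1022, 0.3219, 0.7982, 0.8197, 0.1715),
           b = c(0.2451, 1.7481, 6.1925, 17.3894, 48.1431)),
  O = list(Z = 8,  A = 15.999,
           a = c(0.0974, 0.2921, 0.6910, 0.6990, 0.2039),
           b = c(0.2067, 1.3815, 4.6943, 12.7105, 32.4726)),
  P = list(Z = 15, A = 30.974,
           a = c(0.2548, 0.6106, 1.4541, 2.3204, 0.8477),
           b = c(0.2908, 1.8740, 8.5176, 24.3434, 63.2996)),
  S = list(Z = 16, A = 32.06,
           a = c(0.2497, 0.5628, 1.3899, 2.1865, 0.7715),
           b = c(0.2681, 1.6711, 7.0267, 19.5377, 68.1647))
)

.known_elements <- function() names(.peng)

#' Elastic electron scattering factor
#'
#' Evaluates the parameterised elastic scattering factor f_el(theta) (in
#' Angstrom) for a single element at the given scattering angle(s) and beam
#' energy.  The momentum-transfer variable is s = sin(theta/2)/lambda.
#'
#' @param element Element symbol, one of `"H","C","N","O","P","S"`.
#' @param theta Scattering angle(s) in rad (>= 0).
#' @param beam An `em_beam` or an energy in keV.
#' @return f_el in Angstrom, same length as `theta`.  Monotone non-increasing
#'   in `theta`.
#' @export
scattering_factor <- function(element, theta, beam) {
  p <- .peng[[element]]
  if (is.null(p)) {
    stop(sprintf("unknown element '%s' (no scattering factor shipped)", element),
         call. = FALSE)
  }
  beam <- .as_beam(beam)
  s <- sin(theta / 2) / .lambda_A(beam)
  vapply(s, function(si) sum(p$a * exp(-p$b * si^2)), numeric(1))
}

.atomic_mass <- function(element) .peng[[element]]$A
.atomic_number <- function(element) .peng[[element]]$Z
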