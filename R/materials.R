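#' Define a material
#'
#' A material is a set of elemental number fractions plus a mass density.
#' Optionally the averaged low-angle scattering factor `avg_f0`, the
#' absorption coefficient `mu_abs` used in the multislice phase gratings, and
#' measured elastic/inelastic mean free paths can be supplied as overrides;
#' when absent they are derived from the shipped scattering-factor table.
#' Overridden mean free paths and `mu_abs` refer to `mfp_energy_keV` and are
#' rescaled to other voltages with the (lambda*gamma)^2 law.
#'
#' @param name Label.
#' @param fractions Named numeric vector of number fractions (must sum to 1).
#' @param density Mass density in g/cc (>= 0; 0 encodes vacuum).
#' @param avg_f0 Optional composition-averaged elastic scattering factor
#'   (Angstrom); when given it is used, angle-independently, in place of the
#'   parameterised table in Eq.-of-phase evaluations.
#' @param mu_abs Optional absorption coefficient (1/Angstrom) representing
#'   scattering beyond the multislice acceptance window.
#' @param elastic_mfp,inelastic_mfp Optional mean free paths in nm.
#' @param mfp_energy_keV Voltage at which the overrides were stated.
#' @return An object of class `em_material`.
#' @export
material <- function(name, fractions, density,
                     avg_f0 = NULL, mu_abs = NULL,
                     elastic_mfp = NULL, inelastic_mfp = NULL,
                     mfp_energy_keV = 200) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("`fractions` must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(names(fractions), .known_elements())
  if (length(unknown)) {
    stop(sprintf("unknown element(s) in composition: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  fractions <- fractions[fractions > 0]
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1L || density < 0) {
    stop("`density` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(name = name, fractions = fractions, density = density,
         avg_f0 = avg_f0, mu_abs = mu_abs,
         elastic_mfp = elastic_mfp, inelastic_mfp = inelastic_mfp,
         mfp_energy_keV = mfp_energy_keV),
    class = "em_material"
  )
}

#' @export
print.em_material <- function(x, ...) {
  cat(sprintf("<em_material> %s: rho = %g g/cc, {%s}\n", x$name, x$density,
              paste(sprintf("%s %.4g", names(x$fractions), x$fractions),
                    collapse = ", ")))
  invisible(x)
}

#' Default material set
#'
#' Reads the shipped materials file (vitreous ice, protein, DNA/RNA and
#' vacuum) with their compositions, densities, averaged scattering factors,
#' multislice absorption coefficients and measured mean free paths at 200 keV.
#'
#' @param path Optional path to a JSON materials file with the same schema.
#' @return Named list of `em_material`.
#' @export
default_materials <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.json", package = "thickEM",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw$materials, function(m) {
    material(name = m$name,
             fractions = unlist(m$fractions),
             density = m$density,
             avg_f0 = m$avg_f0,
             mu_abs = m$mu_abs,
             elastic_mfp = m$elastic_mfp,
             inelastic_mfp = m$inelastic_mfp,
             mfp_energy_keV = if (!is.null(raw$mfp_energy_keV)) raw$mfp_energy_keV else 200)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

# Composition-averaged scattering factor at angle theta (Angstrom).
# An avg_f0 override is treated as angle-independent (the low-angle regime the
# mean-inner-potential treatment assumes).
.avg_f <- function(mat, theta, beam) {
  if (!is.null(mat$avg_f0)) return(rep(mat$avg_f0, length(theta)))
  fs <- vapply(names(mat$fractions),
               function(el) scattering_factor(el, theta, beam),
               numeric(length(theta)))
  if (length(theta) == 1L) sum(fs * mat$fractions)
  else as.numeric(matrix(fs, nrow = length(theta)) %*% mat$fractions)
}

.mean_mass <- function(mat) sum(mat$fractions * vapply(names(mat$fractions),
                                                       .atomic_mass, numeric(1)))

# Atoms per cubic Angstrom.
.number_density <- function(mat) {
  if (mat$density == 0) return(0)
  mat$density / (.const$amu * .mean_mass(mat))
}

#' Phase shift per unit thickness
#'
#' The mean-inner-potential phase accumulated by the beam per Angstrom of
#' material: lambda * rho * gamma * sum(f_j(0) n_j) / (1.66 * sum(n_j A_j)),
#' with lambda in Angstrom and rho in g/cc.
#'
#' @param mat An `em_material`.
#' @param beam An `em_beam` or energy in keV.
#' @return Phase in rad per Angstrom.
#' @export
phase_per_thickness <- function(mat, beam) {
  beam <- .as_beam(beam)
  if (mat$density == 0) return(0)
  .lambda_A(beam) * beam$gamma * .avg_f(mat, 0, beam) * .number_density(mat)
}

#' Thickness giving a 1 radian phase difference between two materials
#'
#' The inverse of the difference in phase per unit thickness, the conventional
#' yardstick for the validity of the weak-phase-object approximation.
#' The constants entering the evaluation (per-material phase per Angstrom and
#' the averaged scattering factors used) are attached as attributes so the
#' convention behind any published value can be inspected.
#'
#' @param mat_a,mat_b Two `em_material` objects.
#' @param beam An `em_beam` or energy in keV.
#' @return Thickness in nm, with attributes `phase_per_A_a`, `phase_per_A_b`.
#' @export
one_radian_thickness <- function(mat_a, mat_b, beam) {
  beam <- .as_beam(beam)
  pa <- phase_per_thickness(mat_a, beam)
  pb <- phase_per_thickness(mat_b, beam)
  if (abs(pa - pb) < 1e-15) {
    stop("materials have identical phase per thickness: 1-radian thickness undefined",
         call. = FALSE)
  }
  t_nm <- 1 / abs(pa - pb) / 10
  structure(t_nm, phase_per_A_a = pa, phase_per_A_b = pb)
}

#' Absorption coefficient from scattering outside an angular window
#'
#' Solid-angle integral of the composition-summed squared elastic scattering
#' factors over [theta_min, theta_max], scaled by gamma^2 and the atomic
#' number density: electrons deflected into this window are treated as lost
#' ("absorbed") from the coherent wave.  Integrated over (0, pi) it equals the
#' reciprocal elastic mean free path.
#'
#' @param mat An `em_material`.
#' @param beam An `em_beam` or energy in keV.
#' @param theta_min,theta_max Angular window in rad, 0 <= min < max <= pi.
#' @return mu in 1/Angstrom.
#' @export
absorption_coefficient <- function(mat, beam, theta_min, theta_max) {
  beam <- .as_beam(beam)
  if (!is.numeric(theta_min) || !is.numeric(theta_max) ||
      theta_min < 0 || theta_max > pi + 1e-12 || theta_min > theta_max) {
    stop("need 0 <= theta_min <= theta_max <= pi", call. = FALSE)
  }
  if (theta_min == theta_max || mat$density == 0) return(0)
  els <- names(mat$fractions)
  fr <- mat$fractions
  integrand <- function(th) {
    acc <- 0
    for (i in seq_along(els)) {
      acc <- acc + fr[[i]] * scattering_factor(els[i], th, beam)^2
    }
    acc * 2 * pi * sin(th)
  }
  # integrand is sharply peaked near 0: split the window at a few decades
  brk <- unique(pmin(pmax(c(theta_min, 1e-3, 1e-2, 1e-1, theta_max), theta_min),
                     theta_max))
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    total <- total + stats::integrate(integrand, brk[i], brk[i + 1L],
                                      rel.tol = 1e-9, abs.tol = 0,
                                      subdivisions = 400L)$value
  }
  beam$gamma^2 * .number_density(mat) * total
}

#' Elastic and inelastic mean free paths
#'
#' Uses a material's measured override when present (rescaled from its stated
#' voltage with the (lambda*gamma)^2 law), otherwise derives the elastic mean
#' free path from the total elastic cross-section of the shipped scattering
#' factors; the inelastic mean free path defaults to 0.27 times the elastic
#' one, the measured ratio for vitreous ice.
#'
#' @param mat An `em_material`.
#' @param beam An `em_beam` or energy in keV.
#' @return Mean free path in nm.
#' @export
elastic_mfp <- function(mat, beam) {
  beam <- .as_beam(beam)
  if (!is.null(mat$elastic_mfp)) {
    return(mat$elastic_mfp * lambda_gamma_sq_ratio(beam$energy, mat$mfp_energy_keV))
  }
  mu <- absorption_coefficient(mat, beam, 0, pi)  # 1/A
  if (mu == 0) return(Inf)
  1 / mu / 10
}

#' @rdname elastic_mfp
#' @export
inelastic_mfp <- function(mat, beam) {
  beam <- .as_beam(beam)
  if (!is.null(mat$inelastic_mfp)) {
    return(mat$inelastic_mfp * lambda_gamma_sq_ratio(beam$energy, mat$mfp_energy_keV))
  }
  0.27 * elastic_mfp(mat, beam)
}

#' Bundle of optical constants for a material at a beam setting
#'
#' @param mat An `em_material`.
#' @param beam An `em_beam` or energy in keV.
#' @param theta_min,theta_max Angular window used for the absorption
#'   coefficient (defaults: the 6 mrad multislice acceptance to pi).
#' @return List with `phase_per_A` (rad/Angstrom), `mu` (1/Angstrom),
#'   `elastic_mfp` (nm), `inelastic_mfp` (nm).
#' @export
optical_constants <- function(mat, beam, theta_min = 6e-3, theta_max = pi) {
  beam <- .as_beam(beam)
  mu <- .grating_mu(mat, beam, theta_min)
  list(phase_per_A = phase_per_thickness(mat, beam),
       mu = mu,
       elastic_mfp = elastic_mfp(mat, beam),
       inelastic_mfp = inelastic_mfp(mat, beam))
}

# mu (1/A) used by the phase gratings for a given acceptance angle: the
# material override (rescaled in energy) when present, else Eq.-(4) style
# integral from absorb_beyond to pi.
.grating_mu <- function(mat, beam, absorb_beyond) {
  beam <- .as_beam(beam)
  if (!is.null(mat$mu_abs)) {
    return(mat$mu_abs / lambda_gamma_sq_ratio(beam$energy, mat$mfp_energy_keV))
  }
  absorption_coefficient(mat, beam, absorb_beyond, pi)
}

#' Beam attenuation over a thickness
#'
#' exp(-mu * t), or exp(-t/mfp).  Used both for the coherent-wave absorption
#' budget and for zero-loss fluence budgeting with the inelastic mean free
#' path.
#'
#' @param thickness_nm Thickness in nm (>= 0).
#' @param mu Absorption coefficient in 1/Angstrom (exclusive with `mfp_nm`).
#' @param mfp_nm Mean free path in nm.
#' @return Transmitted fraction in [0, 1].
#' @export
attenuation <- function(thickness_nm, mu = NULL, mfp_nm = NULL) {
  if (any(thickness_nm < 0)) stop("negative thickness", call. = FALSE)
  if (is.null(mu) == is.null(mfp_nm)) {
    stop("supply exactly one of `mu` (1/Angstrom) or `mfp_nm`", call. = FALSE)
  }
  rate_per_nm <- if (!is.null(mu)) mu * 10 else 1 / mfp_nm
  exp(-rate_per_nm * thickness_nm)
}
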