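#' Wave fields
#'
#' A complex N x N amplitude grid on a square field of width `L` nm.
#' `plane_wave()` gives the unit-amplitude incident wave.
#'
#' @param values Complex matrix.
#' @param L Field width, nm.
#' @param beam An `em_beam` or energy in keV.
#' @return An `em_wave`.
#' @export
wave_field <- function(values, L, beam) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("wave field contains non-finite entries", call. = FALSE)
  }
  structure(list(values = values, N = nrow(values), L = L, beam = .as_beam(beam)),
            class = "em_wave")
}

#' @rdname wave_field
#' @param N Grid size.
#' @export
plane_wave <- function(N, L, beam) {
  wave_field(matrix(as.complex(1), N, N), L, beam)
}

#' @export
print.em_wave <- function(x, ...) {
  cat(sprintf("<em_wave> %dx%d, L = %g nm, %g keV, total intensity %.6g\n",
              x$N, x$N, x$L, x$beam$energy, sum(Mod(x$values)^2)))
  invisible(x)
}

# spatial-frequency grids (cycles/nm), unshifted FFT ordering
.kgrid <- function(N, L) {
  k1 <- c(0:(ceiling(N / 2) - 1L), -(floor(N / 2)):-1L) / L
  list(kx = k1, ky = k1,
       k2 = outer(k1^2, k1^2, `+`),
       kmax = N / (2 * L))
}

#' Total intensity of a wave
#' @param wave An `em_wave`.
#' @return Sum of squared moduli.
#' @export
wave_intensity <- function(wave) sum(Mod(wave$values)^2)

#' Build complex phase gratings from material maps
#'
#' Per slice and voxel the transmission is exp(i phi - mu dt / 2), with phi
#' the mean-inner-potential phase of the voxel material over one slice and mu
#' the absorption coefficient representing elastic scattering beyond
#' `absorb_beyond` (the multislice acceptance): making the potential complex
#' with imaginary part mu/2.
#'
#' @param maps An `em_matmaps` from [rasterize()].
#' @param beam An `em_beam` or energy in keV.
#' @param absorb_beyond Acceptance semi-angle in rad beyond which scattering
#'   is treated as absorbed (default 6 mrad, in (0, pi)).
#' @return An `em_slicestack`.
#' @export
phase_gratings <- function(maps, beam, absorb_beyond = 6e-3) {
  stopifnot(inherits(maps, "em_matmaps"))
  beam <- .as_beam(beam)
  if (!(absorb_beyond > 0 && absorb_beyond < pi)) {
    stop("`absorb_beyond` must lie in (0, pi)", call. = FALSE)
  }
  dt_A <- maps$delta_t * 10
  trans <- vapply(maps$palette, function(nm) {
    mat <- maps$materials[[nm]]
    if (is.null(mat)) stop("material '", nm, "' missing from palette", call. = FALSE)
    phi <- phase_per_thickness(mat, beam) * dt_A
    mu <- .grating_mu(mat, beam, absorb_beyond)
    exp(complex(imaginary = phi)) * exp(-mu * dt_A / 2)
  }, complex(1))
  structure(
    list(kind = "maps", maps = maps, trans = trans,
         delta_t = maps$delta_t, L = maps$L, N = maps$N, beam = beam,
         n_slices = length(maps$maps)),
    class = "em_slicestack"
  )
}

#' Low-level slice stack from explicit transmission grids
#'
#' For synthetic specimens (tests, weak-phase objects): `trans` is a list of
#' complex N x N matrices, each with |t| <= 1.
#'
#' @param trans List of complex matrices.
#' @param delta_t Slice thickness, nm.
#' @param L Field width, nm.
#' @param beam An `em_beam` or energy in keV.
#' @return An `em_slicestack`.
#' @export
slice_stack <- function(trans, delta_t, L, beam) {
  stopifnot(is.list(trans), length(trans) >= 1L)
  N <- nrow(trans[[1L]])
  for (tr in trans) {
    stopifnot(is.matrix(tr), nrow(tr) == N, ncol(tr) == N)
    if (max(Mod(tr)) > 1 + 1e-9) {
      stop("slice transmission exceeds unit modulus (gain is unphysical)",
           call. = FALSE)
    }
  }
  structure(list(kind = "explicit", slices = trans, trans = NULL,
                 delta_t = delta_t, L = L, N = N, beam = .as_beam(beam),
                 n_slices = length(trans)),
            class = "em_slicestack")
}

#' Transmission grid of one slice
#' @param stack An `em_slicestack`.
#' @param i Slice index.
#' @return Complex N x N matrix.
#' @export
slice_transmission <- function(stack, i) {
  if (stack$kind == "explicit") return(stack$slices[[i]])
  m <- stack$maps$maps[[i]]
  matrix(stack$trans[m], stack$N, stack$N)
}

#' @export
print.em_slicestack <- function(x, ...) {
  cat(sprintf("<em_slicestack> %d slices, %dx%d, dt = %g nm, L = %g nm\n",
              x$n_slices, x$N, x$N, x$delta_t, x$L))
  invisible(x)
}

#' Fresnel free-space propagation
#'
#' Fourier-space multiplication by exp(-i pi lambda d k^2) (sign convention:
#' a positive distance advances the wave towards the exit surface).  Unitary:
#' the total intensity is conserved to machine precision.
#'
#' @param wave An `em_wave`.
#' @param distance Propagation distance in nm (>= 0).
#' @return The propagated `em_wave`.
#' @export
propagate <- function(wave, distance) {
  stopifnot(inherits(wave, "em_wave"))
  if (distance < 0) stop("negative propagation distance", call. = FALSE)
  if (distance == 0) return(wave)
  kg <- .kgrid(wave$N, wave$L)
  P <- exp(complex(imaginary = -pi * .lambda_nm(wave$beam) * distance * kg$k2))
  wave$values <- stats::fft(P * stats::fft(wave$values), inverse = TRUE) /
    length(wave$values)
  wave
}

# circular band-limit mask in FFT ordering (fraction of the Nyquist radius)
.band_mask <- function(N, L, fraction = 2 / 3) {
  kg <- .kgrid(N, L)
  kg$k2 <= (fraction * kg$kmax)^2
}

#' Exit wave through a slice stack
#'
#' Symmetric (Strang) split-step multislice: half-slice propagation, then
#' alternate phase-grating multiplication and full-slice propagation, closing
#' with a half slice, so each grating acts at its slice centre.  A circular
#' band-limit mask (default 2/3 of Nyquist) is applied in the Fourier domain
#' at every propagation to prevent aliasing of high-angle scattering.
#'
#' @param stack An `em_slicestack`.
#' @param incident An `em_wave` (default: unit plane wave).
#' @param bandlimit Fraction of the Nyquist radius kept (set to 1 to disable).
#' @return The exit `em_wave`.
#' @export
exit_wave <- function(stack, incident = NULL, bandlimit = 2 / 3) {
  stopifnot(inherits(stack, "em_slicestack"), stack$n_slices >= 1L)
  if (is.null(incident)) incident <- plane_wave(stack$N, stack$L, stack$beam)
  if (incident$N != stack$N || abs(incident$L - stack$L) > 1e-9) {
    stop("wave and stack disagree in N or L", call. = FALSE)
  }
  N <- stack$N; L <- stack$L
  lam <- .lambda_nm(stack$beam)
  kg <- .kgrid(N, L)
  mask <- if (bandlimit >= 1) 1 else .band_mask(N, L, bandlimit)
  kern <- function(d) mask * exp(complex(imaginary = -pi * lam * d * kg$k2))
  P_half <- kern(stack$delta_t / 2)
  P_full <- kern(stack$delta_t)
  psi <- incident$values
  psi <- stats::fft(P_half * stats::fft(psi), inverse = TRUE) / length(psi)
  for (i in seq_len(stack$n_slices)) {
    psi <- psi * slice_transmission(stack, i)
    P <- if (i == stack$n_slices) P_half else P_full
    psi <- stats::fft(P * stats::fft(psi), inverse = TRUE) / length(psi)
  }
  wave_field(psi, L, stack$beam)
}

#' Maximum sampled scattering angle of a multislice cell
#'
#' theta_M = lambda N / (2 L): the angle mapped to the edge (Nyquist) of the
#' sampled reciprocal grid along the cell side.
#'
#' @param N Grid size.
#' @param L Field width, nm.
#' @param beam An `em_beam` or energy in keV.
#' @return Angle in rad.
#' @export
max_sampled_angle <- function(N, L, beam) {
  stopifnot(N > 0, L > 0)
  beam <- .as_beam(beam)
  .lambda_nm(beam) * N / (2 * L)
}

#' Multislice slice-thickness error budget
#'
#' Per-slice splitting error estimated as half the product of the grating
#' phase accumulated over one slice (evaluated with the scattering factor at
#' the largest sampled angle theta_M) and the propagator dephasing at theta_M
#' over half a slice, pi theta_M^2 dt / (2 lambda) -- the half slice because
#' the symmetric splitting applies gratings at slice centres.  The overall
#' error is the per-slice error times the number of slices and therefore
#' scales linearly with the slice thickness.
#'
#' @param mat An `em_material`.
#' @param beam An `em_beam` or energy in keV.
#' @param delta_t Slice thickness, nm.
#' @param theta_M Largest sampled angle, rad (see [max_sampled_angle()]).
#' @param total_thickness Specimen thickness, nm (must be a multiple of
#'   `delta_t`).
#' @return Overall error as a fraction, with attribute `per_slice`.
#' @export
slice_error <- function(mat, beam, delta_t, theta_M, total_thickness) {
  beam <- .as_beam(beam)
  n <- round(total_thickness / delta_t)
  if (abs(n * delta_t - total_thickness) > 1e-9) {
    stop("delta_t must divide total_thickness", call. = FALSE)
  }
  dt_A <- delta_t * 10
  lam_A <- .lambda_A(beam)
  phi_per_A <- .lambda_A(beam) * beam$gamma * .avg_f(mat, theta_M, beam) *
    .number_density(mat)
  per_slice <- 0.5 * (phi_per_A * dt_A) * (pi * theta_M^2 * dt_A / (2 * lam_A))
  structure(per_slice * n, per_slice = per_slice)
}
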