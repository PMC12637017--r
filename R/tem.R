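#' Simulated electron-count image container
#'
#' @param counts Non-negative matrix (electrons per pixel, or noiseless
#'   intensity when `fluence` is NA).
#' @param pixel_size Pixel size, nm.
#' @param fluence Incident fluence used, e-/A^2 (NA for noiseless intensity).
#' @param seed RNG seed used (NA when noiseless).
#' @param meta Optional provenance list.
#' @return An `em_image`.
#' @export
sim_image <- function(counts, pixel_size, fluence = NA_real_,
                      seed = NA_integer_, meta = list()) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  structure(list(counts = counts, pixel_size = pixel_size, fluence = fluence,
                 seed = seed, meta = meta),
            class = "em_image")
}

#' @export
print.em_image <- function(x, ...) {
  cat(sprintf("<em_image> %dx%d, pixel %g nm, fluence %s, counts [%.3g, %.3g]\n",
              nrow(x$counts), ncol(x$counts), x$pixel_size,
              if (is.na(x$fluence)) "n/a" else sprintf("%g e-/A^2", x$fluence),
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Aberrated bright-field image from an exit wave
#'
#' Multiplies the exit wave in the Fourier domain by the coherent transfer
#' exp(i chi) masked by the objective aperture and damped by the temporal and
#' spatial coherence envelopes, inverse transforms, and takes the modulus
#' squared.  Intensity 1 corresponds to the incident plane-wave flux.
#'
#' @param wave An `em_wave` (exit wave).
#' @param optics An `em_optics`.
#' @param beam An `em_beam` or energy in keV (default: the wave's beam).
#' @return Real intensity matrix.
#' @export
image_from_exit_wave <- function(wave, optics, beam = wave$beam) {
  stopifnot(inherits(wave, "em_wave"))
  beam <- .as_beam(beam)
  kg <- .kgrid(wave$N, wave$L)
  kk <- sqrt(kg$k2)
  theta <- .lambda_nm(beam) * kk
  H <- exp(complex(imaginary = -chi(theta, optics, beam))) *
    temporal_envelope(kk, optics$focal_spread, beam) *
    spatial_envelope(kk, optics, beam)
  if (!is.null(optics$aperture)) H <- H * (theta <= optics$aperture)
  psi <- stats::fft(H * stats::fft(wave$values), inverse = TRUE) /
    length(wave$values)
  Mod(psi)^2
}

#' Zero-loss fluence budget
#'
#' The fluence surviving an energy filter set on the zero-loss peak:
#' fluence * exp(-t / lambda_inelastic).
#'
#' @param fluence_in Incident fluence, e-/A^2.
#' @param ice_thickness_nm Specimen thickness, nm.
#' @param inelastic_mfp_nm Inelastic mean free path, nm (157 for vitreous ice
#'   at 200 keV).
#' @return Transmitted (zero-loss) fluence, e-/A^2.
#' @export
zero_loss_fluence <- function(fluence_in, ice_thickness_nm,
                              inelastic_mfp_nm = 157) {
  stopifnot(fluence_in > 0, ice_thickness_nm >= 0, inelastic_mfp_nm > 0)
  fluence_in * exp(-ice_thickness_nm / inelastic_mfp_nm)
}

#' Poisson shot noise
#'
#' Per-pixel independent Poisson draws with mean intensity * fluence * pixel
#' area.  Deterministic under a fixed seed.
#'
#' @param intensity Non-negative intensity matrix (1 = incident flux).
#' @param fluence Fluence reaching the detector, e-/A^2 (> 0).
#' @param pixel_size Pixel size, nm.
#' @param seed Integer RNG seed.
#' @return An `em_image` of integer counts.
#' @export
add_shot_noise <- function(intensity, fluence, pixel_size, seed = 1L) {
  stopifnot(is.matrix(intensity), all(intensity >= 0), fluence > 0)
  mean_counts <- intensity * fluence * (pixel_size * 10)^2
  counts <- .with_seed(seed, {
    matrix(stats::rpois(length(mean_counts), mean_counts),
           nrow(mean_counts), ncol(mean_counts))
  })
  sim_image(counts, pixel_size, fluence = fluence, seed = seed)
}

# evaluate expr under a temporary RNG state (restores the caller's stream)
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' End-to-end bright-field TEM simulation
#'
#' Composes rasterisation, phase gratings, the multislice exit wave, the
#' aberrated image, the zero-loss fluence budget and Poisson shot noise.
#'
#' @param model An embedded `em_specimen`.
#' @param beam An `em_beam` or energy in keV.
#' @param optics An `em_optics`.
#' @param fluence Incident fluence, e-/A^2.
#' @param seed RNG seed for the shot noise.
#' @param N,L,delta_t Sampling: grid size, field width (nm), slice thickness
#'   (nm).
#' @param absorb_beyond Multislice acceptance semi-angle, rad.
#' @param energy_filter `"zero-loss"` (fluence reduced by exp(-t/imfp)) or
#'   `"none"`.
#' @param noise If `FALSE`, return the noiseless intensity (fluence budget
#'   still reported in `meta`).
#' @return An `em_image`; `meta` records the stage parameters.
#' @export
simulate_tem <- function(model, beam, optics, fluence = 4, seed = 1L,
                         N = 512, L = 128, delta_t = 2,
                         absorb_beyond = 6e-3,
                         energy_filter = c("zero-loss", "none"),
                         noise = TRUE) {
  beam <- .as_beam(beam)
  energy_filter <- match.arg(energy_filter)
  maps <- rasterize(model, N = N, L = L, delta_t = delta_t)
  stack <- phase_gratings(maps, beam, absorb_beyond = absorb_beyond)
  wave <- exit_wave(stack)
  img <- image_from_exit_wave(wave, optics, beam)
  t_nm <- model$bounds[["thickness"]]
  imfp <- inelastic_mfp(model$materials[["ice"]], beam)
  fl <- if (energy_filter == "zero-loss") {
    zero_loss_fluence(fluence, t_nm, imfp)
  } else fluence
  meta <- list(beam = beam$energy, optics = unclass(optics), N = N, L = L,
               delta_t = delta_t, absorb_beyond = absorb_beyond,
               thickness = t_nm, fluence_in = fluence, fluence_used = fl,
               energy_filter = energy_filter,
               orientation = model$orientation_name)
  if (!noise) {
    out <- sim_image(img, pixel_size = L / N, meta = meta)
    return(out)
  }
  out <- add_shot_noise(img, fl, pixel_size = L / N, seed = seed)
  out$meta <- meta
  out
}
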