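#' Segmented annular detector geometry
#'
#' Rings are given by inner/outer semi-angles (gaps allowed), each divided
#' into equal azimuthal segments.  Bin order: ring-major, segment-minor.
#'
#' @param edges Either a strictly increasing vector of semi-angle edges in rad
#'   (consecutive pairs become rings), or a two-column matrix/data.frame of
#'   (inner, outer) per ring for geometries with gaps.
#' @param segments Azimuthal segments per ring (>= 1).
#' @return An `em_detector` with data.frame `rings`, `segments`, `n_bins` and
#'   a matrix `centers` of bin-centre angle vectors (omega_x, omega_y) in rad.
#' @export
detector_geometry <- function(edges, segments = 1L) {
  if (is.matrix(edges) || is.data.frame(edges)) {
    rings <- data.frame(inner = edges[, 1], outer = edges[, 2])
  } else {
    stopifnot(length(edges) >= 2L)
    rings <- data.frame(inner = edges[-length(edges)], outer = edges[-1L])
  }
  if (any(rings$outer <= rings$inner) || any(diff(rings$inner) <= 0) ||
      any(rings$inner < 0)) {
    stop("ring edges must be non-negative and strictly increasing", call. = FALSE)
  }
  segments <- as.integer(segments)
  stopifnot(segments >= 1L)
  nr <- nrow(rings)
  n_bins <- nr * segments
  ring_of <- rep(seq_len(nr), each = segments)
  seg_of <- rep(seq_len(segments), times = nr)
  om <- (rings$inner[ring_of] + rings$outer[ring_of]) / 2
  az <- (seg_of - 0.5) * 2 * pi / segments
  structure(list(rings = rings, segments = segments, n_bins = n_bins,
                 ring_of = ring_of, seg_of = seg_of,
                 centers = cbind(om * cos(az), om * sin(az))),
            class = "em_detector")
}

#' @export
print.em_detector <- function(x, ...) {
  cat(sprintf("<em_detector> %d rings x %d segments (%g-%g mrad)\n",
              nrow(x$rings), x$segments, 1e3 * min(x$rings$inner),
              1e3 * max(x$rings$outer)))
  invisible(x)
}

#' Stock detector geometries
#'
#' `tcbf_detector()`: the pixelated bright-field detector used for
#' tilt-corrected bright-field STEM -- 20 annular rings covering 0-4 mrad
#' with 90 azimuthal segments.  `opal_detector()`: the fixed segmented
#' annular rings used for incoherent STEM -- 0-7 (bright field), 10-20,
#' 20-30 and 30-44 mrad at 200 keV, scaled by the electron wavelength ratio
#' at other voltages (0-2.43/3.5-7.0/7.0-10.4/10.4-15.3 mrad at 1 MeV).
#'
#' @param max_angle Outer semi-angle, rad.
#' @param rings,segments Ring/segment counts.
#' @param energy_keV Accelerating voltage for the angle scaling.
#' @return An `em_detector`.
#' @export
tcbf_detector <- function(max_angle = 4e-3, rings = 20L, segments = 90L) {
  detector_geometry(seq(0, max_angle, length.out = rings + 1L), segments)
}

#' @rdname tcbf_detector
#' @export
opal_detector <- function(energy_keV = 200) {
  base <- rbind(c(0, 7), c(10, 20), c(20, 30), c(30, 44)) * 1e-3
  scale <- beam_parameters(energy_keV)$wavelength /
    beam_parameters(200)$wavelength
  detector_geometry(base * scale, segments = 1L)
}

#' Aberrated convergent probe wave
#'
#' Aperture-limited (semi-angle = convergence), aberrated probe centred at
#' `position`, normalised to unit total intensity.
#'
#' @param position c(x, y) probe centre in nm.
#' @param convergence Probe-forming semi-angle, rad; must not exceed the
#'   sampled angular range.
#' @param optics An `em_optics` (Cs, defocus).
#' @param beam An `em_beam` or energy in keV.
#' @param N,L Grid size and field width (nm).
#' @return An `em_wave`.
#' @export
probe_wave <- function(position, convergence, optics, beam, N, L) {
  beam <- .as_beam(beam)
  if (convergence > max_sampled_angle(N, L, beam)) {
    stop("convergence exceeds the sampled angular range lambda*N/(2L)",
         call. = FALSE)
  }
  A <- .probe_fourier(convergence, optics, beam, N, L)
  kg <- .kgrid(N, L)
  ramp <- outer(exp(complex(imaginary = -2 * pi * kg$kx * position[1])),
                exp(complex(imaginary = -2 * pi * kg$ky * position[2])))
  psi <- stats::fft(A * ramp, inverse = TRUE) / (N * N)
  psi <- psi / sqrt(sum(Mod(psi)^2))
  wave_field(psi, L, beam)
}

# Fourier-space probe-forming amplitude (no position ramp)
.probe_fourier <- function(convergence, optics, beam, N, L) {
  kg <- .kgrid(N, L)
  kk <- sqrt(kg$k2)
  theta <- .lambda_nm(beam) * kk
  mask <- theta <= convergence
  mask * exp(complex(imaginary = -chi(theta, optics, beam)))
}

#' Scan grid for STEM
#'
#' `n x n` probe positions with pitch `step`, centred on the field of width
#' `L` so scan pixels coincide with image pixels of the same pitch.
#'
#' @param n Positions per side.
#' @param step Scan step, nm (default 0.25).
#' @param L Field width the scan is centred on, nm.
#' @param offset Position of the first scan row/column, nm (default: centred;
#'   pass e.g. a pixel-centre coordinate to align the scan with an image
#'   raster).
#' @return List with position vectors `x`, `y` (nm), `n`, `step`.
#' @export
scan_grid <- function(n, step = 0.25, L, offset = NULL) {
  if (is.null(offset)) offset <- (L - n * step) / 2 + step / 2
  if (offset < 0 || offset + (n - 1) * step > L) {
    stop("scan grid larger than the field", call. = FALSE)
  }
  list(x = offset + (seq_len(n) - 1L) * step,
       y = offset + (seq_len(n) - 1L) * step, n = n, step = step)
}

# per-pixel detector bin index (0 = not on any bin) for an N/L grid
.detector_bin_map <- function(detector, beam, N, L) {
  kg <- .kgrid(N, L)
  kx <- matrix(kg$kx, N, N)
  ky <- matrix(kg$ky, N, N, byrow = TRUE)
  theta <- .lambda_nm(beam) * sqrt(kg$k2)
  az <- atan2(ky, kx) %% (2 * pi)
  seg <- pmin(detector$segments,
              1L + floor(az / (2 * pi / detector$segments)))
  bin <- matrix(0L, N, N)
  for (r in seq_len(nrow(detector$rings))) {
    inr <- detector$rings$inner[r]; out <- detector$rings$outer[r]
    sel <- if (inr == 0) theta <= out else theta > inr & theta <= out
    bin[sel] <- (r - 1L) * detector$segments + seg[sel]
  }
  bin
}

#' Record a 4D-STEM dataset
#'
#' For every probe position: multislice exit wave of the aberrated probe,
#' far-field intensity, binned onto the segmented detector.  Intensities are
#' fractions of the incident probe current; per position the binned total
#' plus `beyond` (outside all bins) plus `absorbed` equals 1.
#'
#' @param x An embedded `em_specimen` or a prebuilt `em_slicestack`.
#' @param beam An `em_beam` or energy in keV.
#' @param optics An `em_optics`; `optics$convergence` sets the probe-forming
#'   aperture.
#' @param detector An `em_detector`.
#' @param scan A [scan_grid()].
#' @param N,L,delta_t Sampling (ignored when `x` is already a slice stack).
#' @param bandlimit Multislice anti-aliasing band (see [exit_wave()]).
#' @return An `em_4d`: `data` array (scan_x, scan_y, bin), matrices
#'   `beyond` and `absorbed`, plus geometry metadata.
#' @export
record_4d <- function(x, beam, optics, detector, scan,
                      N = 256, L = 128, delta_t = 2, bandlimit = 2 / 3) {
  beam <- .as_beam(beam)
  stack <- if (inherits(x, "em_slicestack")) x else {
    phase_gratings(rasterize(x, N = N, L = L, delta_t = delta_t), beam)
  }
  N <- stack$N; L <- stack$L
  conv <- optics$convergence
  if (conv <= 0) stop("optics$convergence must be set for STEM", call. = FALSE)
  if (conv > bandlimit * max_sampled_angle(N, L, beam)) {
    stop(sprintf(
      "probe convergence %.2f mrad exceeds the anti-aliased angular range %.2f mrad (lambda*N/2L * bandlimit); increase N or reduce L",
      1e3 * conv, 1e3 * bandlimit * max_sampled_angle(N, L, beam)),
      call. = FALSE)
  }
  if (max(scan$x) > L || max(scan$y) > L || min(scan$x) < 0 || min(scan$y) < 0) {
    stop("scan grid extends outside the field", call. = FALSE)
  }
  A0 <- .probe_fourier(conv, optics, beam, N, L)
  kg <- .kgrid(N, L)
  binmap <- .detector_bin_map(detector, beam, N, L)
  binvec <- as.integer(binmap) + 1L  # 1 = none, 2.. = bins
  nb <- detector$n_bins
  lam <- .lambda_nm(beam)
  mask <- if (bandlimit >= 1) 1 else .band_mask(N, L, bandlimit)
  P_half <- mask * exp(complex(imaginary = -pi * lam * (stack$delta_t / 2) * kg$k2))
  P_full <- mask * exp(complex(imaginary = -pi * lam * stack$delta_t * kg$k2))
  n_sl <- stack$n_slices
  trans <- lapply(seq_len(n_sl), function(i) slice_transmission(stack, i))
  rampx <- lapply(scan$x, function(x0)
    exp(complex(imaginary = -2 * pi * kg$kx * x0)))
  rampy <- lapply(scan$y, function(y0)
    exp(complex(imaginary = -2 * pi * kg$ky * y0)))
  data <- array(0, dim = c(scan$n, scan$n, nb))
  absorbed <- matrix(0, scan$n, scan$n)
  beyond <- matrix(0, scan$n, scan$n)
  npix <- N * N
  # unit-current probe in the Fourier domain, entry half-step folded in
  A0n <- A0 / sqrt(sum(Mod(A0)^2) / npix)
  A0h <- A0n * P_half
  on_det <- which(binvec > 1L)
  det_fac <- factor(binvec[on_det], levels = 2L:(nb + 1L))
  mask_only <- if (bandlimit >= 1) 1 else .band_mask(N, L, bandlimit)
  for (iy in seq_len(scan$n)) {
    ry <- rampy[[iy]]
    for (ix in seq_len(scan$n)) {
      # all propagation kept in the Fourier domain; the exit half-step is a
      # pure phase and cannot change far-field intensities, so only its
      # band-limit mask is applied
      Psi <- A0h * outer(rampx[[ix]], ry)
      for (i in seq_len(n_sl)) {
        psi <- stats::fft(Psi, inverse = TRUE) / npix
        Psi <- stats::fft(psi * trans[[i]])
        Psi <- if (i == n_sl) Psi * mask_only else Psi * P_full
      }
      far <- Mod(Psi)^2 / npix
      tot <- sum(far)
      binned <- tapply(far[on_det], det_fac, sum, default = 0)
      data[ix, iy, ] <- binned
      beyond[ix, iy] <- tot - sum(binned)
      absorbed[ix, iy] <- 1 - tot
    }
  }
  structure(list(data = data, beyond = beyond, absorbed = absorbed,
                 scan = scan, detector = detector, optics = optics,
                 beam = beam, N = N, L = L, delta_t = stack$delta_t),
            class = "em_4d")
}

#' @export
print.em_4d <- function(x, ...) {
  cat(sprintf("<em_4d> %dx%d scan (step %g nm) x %d bins\n",
              x$scan$n, x$scan$n, x$scan$step, x$detector$n_bins))
  invisible(x)
}

#' Parallax image shift for a detector (tilt) angle
#'
#' The image displacement (Cs omega^2 - defocus) * omega associated with the
#' tilt omega of a bright-field detector pixel; it vanishes at omega = 0 and
#' at the defocus Cs omega^2.
#'
#' @param omega n x 2 matrix (or length-2 vector) of tilt angle components,
#'   rad.
#' @param optics An `em_optics`.
#' @return n x 2 matrix of displacements in nm.
#' @export
parallax_shift <- function(omega, optics) {
  if (is.null(dim(omega))) omega <- matrix(omega, ncol = 2L)
  om2 <- omega[, 1]^2 + omega[, 2]^2
  (optics$Cs_nm * om2 - optics$defocus) * omega
}

#' Tilt-corrected bright-field image from a 4D record
#'
#' Each detector bin inside the bright-field disc yields a scan image; the
#' bin's parallax shift is undone by a Fourier phase ramp (exact for
#' band-limited images) and the corrected images are summed.  Bins outside
#' the bright-field disc are excluded with a warning.  Since no energy
#' selection is involved the full incident fluence applies when noise is
#' requested.
#'
#' @param record An `em_4d`.
#' @param optics Optics used for the parallax correction (default: the ones
#'   stored in the record).
#' @param ring_average If `TRUE`, average bins within a ring before shifting
#'   (single shift magnitude per ring is not possible for segments -- this
#'   option shifts by each segment's centre but uses the ring-mean image),
#'   kept for comparison; default is per-segment shifting.
#' @param fluence,seed,noise Optional Poisson counting at `fluence` e-/A^2
#'   on the scan-step pixel.
#' @return An `em_image` (intensity as fraction of incident current unless
#'   noise is applied).
#' @export
tilt_corrected_bf <- function(record, optics = record$optics,
                              ring_average = FALSE,
                              fluence = NA_real_, seed = 1L, noise = FALSE) {
  stopifnot(inherits(record, "em_4d"))
  det <- record$detector
  conv <- record$optics$convergence
  outer_r <- det$rings$outer[det$ring_of]
  use <- outer_r <= conv + 1e-12
  if (!any(use)) stop("no detector bin lies inside the bright-field disc",
                      call. = FALSE)
  if (any(!use)) {
    warning(sprintf("%d detector bins outside the bright-field disc excluded",
                    sum(!use)))
  }
  n <- record$scan$n; step <- record$scan$step
  # undo the apparent displacement of the bin's scan image: the image formed
  # via a detector pixel at tilt omega appears displaced by -(Cs w^2 - df) w,
  # so the correction translates it by +parallax_shift(omega)
  shifts <- parallax_shift(det$centers, optics)
  k1 <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L) / (n * step)
  data <- record$data
  if (noise) {
    if (is.na(fluence)) stop("fluence required for noise", call. = FALSE)
    area_A2 <- (step * 10)^2
    data <- .with_seed(seed, {
      d <- array(stats::rpois(length(data), data * fluence * area_A2),
                 dim = dim(data))
      d / (fluence * area_A2)
    })
  }
  if (ring_average) {
    for (r in unique(det$ring_of)) {
      idx <- which(det$ring_of == r)
      m <- apply(data[, , idx, drop = FALSE], c(1, 2), mean)
      for (b in idx) data[, , b] <- m
    }
  }
  acc <- matrix(as.complex(0), n, n)
  for (b in which(use)) {
    img <- data[, , b]
    if (all(img == 0)) next
    # image indexed [ix, iy]; shift components (x, y) in nm
    ramp <- outer(exp(complex(imaginary = -2 * pi * k1 * shifts[b, 1])),
                  exp(complex(imaginary = -2 * pi * k1 * shifts[b, 2])))
    acc <- acc + stats::fft(img) * ramp
  }
  out <- Re(stats::fft(acc, inverse = TRUE)) / (n * n)
  out[out < 0] <- 0
  counts <- if (noise) out * fluence * (step * 10)^2 else out
  sim_image(counts, pixel_size = step,
            fluence = if (noise) fluence else NA_real_,
            seed = if (noise) seed else NA_integer_,
            meta = list(bins_used = sum(use), convergence = conv))
}

#' End-to-end tilt-corrected bright-field STEM simulation
#'
#' @inheritParams simulate_tem
#' @param detector An `em_detector` (default [tcbf_detector()]).
#' @param scan_n,scan_step Scan size and step (nm).
#' @return An `em_image`.
#' @export
simulate_tcbf <- function(model, beam, optics, detector = tcbf_detector(),
                          fluence = 4, seed = 1L, scan_n = 64,
                          scan_step = 0.25, N = 256, L = 128, delta_t = 2,
                          noise = TRUE) {
  beam <- .as_beam(beam)
  sg <- scan_grid(scan_n, scan_step, L)
  rec <- record_4d(model, beam, optics, detector, sg,
                   N = N, L = L, delta_t = delta_t)
  tilt_corrected_bf(rec, fluence = fluence, seed = seed, noise = noise)
}
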