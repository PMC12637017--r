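#' Low-loss EELS spectrum container
#'
#' @param energy Energy-loss axis in eV, uniformly spaced, strictly
#'   increasing (channel centres; the elastic peak sits at 0 eV).
#' @param counts Non-negative counts per channel.
#' @param collection_mrad Optional collection semi-angle metadata.
#' @param meta Optional provenance list.
#' @return An `em_eels`.
#' @export
eels_spectrum <- function(energy, counts, collection_mrad = NA_real_,
                          meta = list()) {
  stopifnot(length(energy) == length(counts), all(diff(energy) > 0))
  d <- diff(energy)
  if (max(abs(d - d[1])) > 1e-9 * d[1]) {
    stop("energy axis must be uniformly spaced", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  structure(list(energy = energy, counts = counts,
                 collection_mrad = collection_mrad, meta = meta),
            class = "em_eels")
}

#' @export
print.em_eels <- function(x, ...) {
  cat(sprintf("<em_eels> %d channels, %g-%g eV (%g eV/ch), total %.4g counts\n",
              length(x$energy), min(x$energy), max(x$energy),
              x$energy[2] - x$energy[1], sum(x$counts)))
  invisible(x)
}

# Drude-type single-scattering plasmon profile on a channel axis (eV),
# zero at E <= 0, unit sum.
.plasmon_profile <- function(energy, peak_eV, width_eV) {
  p <- ifelse(energy > 0,
              energy * width_eV * peak_eV^2 /
                ((energy^2 - peak_eV^2)^2 + (energy * width_eV)^2),
              0)
  p / sum(p)
}

#' Synthesize a thick-specimen low-loss spectrum
#'
#' Poisson multiple scattering: the n-fold scattering order carries weight
#' P(n) = exp(-t/lambda) (t/lambda)^n / n! and the n-fold self-convolution of
#' a Drude-like single plasmon profile (peak ~20 eV, half-width ~10 eV); the
#' zero order is the elastic (zero-loss) line.  The aggregate is evaluated in
#' closed form via the exponential of the profile's Fourier transform on a
#' padded axis.  With increasing t/lambda the spectral weight climbs through
#' the plasmon towards a skewed high-loss (Landau-like) peak.  Optional
#' Poisson count noise.
#'
#' @param t_over_lambda Thickness in inelastic mean free paths (>= 0).
#' @param plasmon_energy Plasmon peak energy, eV.
#' @param plasmon_width Plasmon half-width (FWHM), eV.
#' @param n_channels Number of channels.
#' @param dE Channel width, eV (axis starts at 0).
#' @param total_counts Expected total counts.
#' @param seed Integer seed for Poisson count noise, or `NULL` for the
#'   noiseless expectation.
#' @param collection_mrad Metadata.
#' @return An `em_eels`.
#' @export
synthesize_spectrum <- function(t_over_lambda, plasmon_energy = 20,
                                plasmon_width = 10, n_channels = 1024L,
                                dE = 0.5, total_counts = 1e6, seed = NULL,
                                collection_mrad = 17) {
  stopifnot(t_over_lambda >= 0, plasmon_energy > 0, plasmon_width > 0)
  n_pad <- 4L * stats::nextn(n_channels, 2L)
  e_pad <- (seq_len(n_pad) - 1L) * dE
  p1 <- .plasmon_profile(e_pad, plasmon_energy, plasmon_width)
  Fp <- stats::fft(p1)
  Fs <- exp(t_over_lambda * (Fp - 1))
  s <- Re(stats::fft(Fs, inverse = TRUE)) / n_pad
  s[s < 0] <- 0
  s <- s[seq_len(n_channels)]
  # the axis is taken to record all transmitted electrons: the (tiny)
  # multiple-scattering tail beyond the last channel is renormalised into the
  # inelastic part so that the zero-loss fraction is exactly exp(-t/lambda)
  p0 <- exp(-t_over_lambda)
  inel <- s[-1L]
  if (sum(inel) > 0) inel <- inel * (1 - p0) / sum(inel)
  s <- c(p0, inel)
  counts <- s * total_counts
  if (!is.null(seed)) {
    counts <- .with_seed(seed, stats::rpois(length(counts), counts))
  }
  eels_spectrum((seq_len(n_channels) - 1L) * dE, counts,
                collection_mrad = collection_mrad,
                meta = list(t_over_lambda = t_over_lambda,
                            plasmon_energy = plasmon_energy,
                            plasmon_width = plasmon_width, seed = seed))
}

#' Log-ratio thickness from a low-loss spectrum
#'
#' t / lambda_inelastic = ln(I_total / I_zero_loss), with the zero-loss
#' intensity integrated over `zero_loss_window`.
#'
#' @param spec An `em_eels`.
#' @param zero_loss_window c(lo, hi) energy bounds in eV containing the
#'   elastic peak.
#' @param inelastic_mfp_nm Optional mean free path to also report an absolute
#'   thickness.
#' @return t/lambda (dimensionless); when `inelastic_mfp_nm` is given, the
#'   attribute `thickness_nm` carries t.
#' @export
thickness_from_spectrum <- function(spec, zero_loss_window = c(-2, 2),
                                    inelastic_mfp_nm = NULL) {
  stopifnot(inherits(spec, "em_eels"))
  sel <- spec$energy >= zero_loss_window[1] & spec$energy <= zero_loss_window[2]
  I0 <- sum(spec$counts[sel])
  IT <- sum(spec$counts)
  if (I0 <= 0 || IT <= 0) {
    stop("non-positive integral: zero-loss window misses the elastic peak?",
         call. = FALSE)
  }
  t_over_lambda <- log(IT / I0)
  if (!is.null(inelastic_mfp_nm)) {
    attr(t_over_lambda, "thickness_nm") <- t_over_lambda * inelastic_mfp_nm
  }
  t_over_lambda
}

#' Fraction of electrons in an energy window
#'
#' Windowed integral divided by the total integral.
#'
#' @param spec An `em_eels`.
#' @param window c(lo, hi) in eV (channels with lo <= E <= hi).
#' @return Fraction in [0, 1] (0 with a warning for an empty window).
#' @export
window_fraction <- function(spec, window) {
  stopifnot(inherits(spec, "em_eels"))
  sel <- spec$energy >= window[1] & spec$energy <= window[2]
  if (!any(sel)) {
    warning("window contains no channels")
    return(0)
  }
  sum(spec$counts[sel]) / sum(spec$counts)
}

#' Energy window of given width maximising the collected fraction
#'
#' Exhaustive scan over channel offsets.
#'
#' @param spec An `em_eels`.
#' @param width Window width in eV (> 0).
#' @return c(lo, hi) bounds in eV; attribute `fraction` holds the fraction
#'   collected.
#' @export
optimal_window <- function(spec, width) {
  stopifnot(inherits(spec, "em_eels"), width > 0)
  dE <- spec$energy[2] - spec$energy[1]
  w_ch <- max(1L, round(width / dE))
  cs <- cumsum(spec$counts)
  n <- length(cs)
  if (w_ch >= n) {
    out <- c(spec$energy[1], spec$energy[n])
    attr(out, "fraction") <- 1
    return(out)
  }
  windowed <- cs[w_ch:n] - c(0, cs[seq_len(n - w_ch)])
  i <- which.max(windowed)           # window covers channels i .. i+w_ch-1
  lo <- spec$energy[i] - dE / 2
  hi <- spec$energy[i + w_ch - 1L] + dE / 2
  out <- c(lo, hi)
  attr(out, "fraction") <- windowed[i] / cs[n]
  out
}

#' Read/write EELS spectra as two-column text or MSA
#'
#' `write_spectrum()` / `read_spectrum()` use plain two-column text
#' (energy eV, counts) or the EMSA/MAS exchange format when the file ends in
#' `.msa`.
#'
#' @param spec An `em_eels`.
#' @param path File path.
#' @return `read_spectrum()` returns an `em_eels`.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "em_eels"))
  if (grepl("\\.msa$", path, ignore.case = TRUE)) {
    hdr <- c("#FORMAT      : EMSA/MAS Spectral Data File",
             "#VERSION     : 1.0",
             "#TITLE       : thickEM synthetic low-loss spectrum",
             sprintf("#NPOINTS     : %d", length(spec$energy)),
             "#XUNITS      : eV",
             "#YUNITS      : counts",
             sprintf("#XPERCHAN    : %g", spec$energy[2] - spec$energy[1]),
             sprintf("#OFFSET      : %g", spec$energy[1]),
             "#SPECTRUM    :")
    body <- sprintf("%g, %g", spec$energy, spec$counts)
    writeLines(c(hdr, body, "#ENDOFDATA   :"), path)
  } else {
    utils::write.table(data.frame(energy_eV = spec$energy, counts = spec$counts),
                       path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (grepl("\\.msa$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    dat <- lines[!grepl("^#", lines)]
    parts <- do.call(rbind, strsplit(trimws(dat), "\\s*,\\s*"))
    eels_spectrum(as.numeric(parts[, 1]), as.numeric(parts[, 2]))
  } else {
    d <- utils::read.table(path)
    eels_spectrum(d[[1]], d[[2]])
  }
}
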