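#' Monte Carlo configuration
#'
#' Defaults follow the incoherent-STEM simulation conditions: 10,000
#' electrons per 1 nm pixel (100 e-/A^2) stepped over a 110 x 110 grid, with
#' the four-ring segmented annular detector.
#'
#' @param electrons_per_pixel Electrons incident per scan pixel (> 0).
#' @param scan_n Scan positions per side.
#' @param scan_step Scan pitch, nm.
#' @param seed Base RNG seed.
#' @param energy_keV Accelerating voltage (200 or 1000 in the stock setups).
#' @param detector An `em_detector` (default [opal_detector()] at
#'   `energy_keV`).
#' @param chunk_size Electrons simulated per reproducibility chunk; partial
#'   runs partitioned at chunk granularity sum exactly to a full run.
#' @param voxel_nm Lateral voxel size for the material lookup.
#' @param delta_z Axial voxel (slice) size, nm.
#' @param margin_nm Ice margin added laterally around the scanned field.
#' @param max_events Safety cap on scattering events per electron.
#' @return An `em_mc_config`.
#' @export
mc_config <- function(electrons_per_pixel = 10000L, scan_n = 110L,
                      scan_step = 1, seed = 1L, energy_keV = 200,
                      detector = opal_detector(energy_keV),
                      chunk_size = 1000L, voxel_nm = 1, delta_z = 2,
                      margin_nm = 24, max_events = 10000L) {
  stopifnot(electrons_per_pixel > 0, scan_n > 0, chunk_size > 0)
  structure(list(electrons_per_pixel = as.integer(electrons_per_pixel),
                 scan_n = as.integer(scan_n), scan_step = scan_step,
                 seed = as.integer(seed), energy_keV = energy_keV,
                 detector = detector, chunk_size = as.integer(chunk_size),
                 voxel_nm = voxel_nm, delta_z = delta_z,
                 margin_nm = margin_nm, max_events = as.integer(max_events)),
            class = "em_mc_config")
}

#' Sample free path lengths and event types
#'
#' Exponential path lengths with the total mean free path
#' 1/(1/lambda_el + 1/lambda_in); the event type is inelastic with
#' probability lambda_tot / lambda_in.  Draws from the current RNG stream.
#'
#' @param mat An `em_material`.
#' @param beam An `em_beam` or energy in keV.
#' @param n Number of samples.
#' @return List with `length` (nm; `Inf` for vacuum) and `type`
#'   (`"elastic"`/`"inelastic"`).
#' @export
sample_free_path <- function(mat, beam, n) {
  beam <- .as_beam(beam)
  l_el <- elastic_mfp(mat, beam)
  l_in <- inelastic_mfp(mat, beam)
  rate <- 1 / l_el + 1 / l_in
  if (!is.finite(rate) || rate <= 0) {
    return(list(length = rep(Inf, n), type = rep(NA_character_, n)))
  }
  len <- stats::rexp(n, rate)
  p_in <- (1 / l_in) / rate
  type <- ifelse(stats::runif(n) < p_in, "inelastic", "elastic")
  list(length = len, type = type)
}

# Thomas-Fermi screened-Rutherford screening parameter eta for one element:
# theta_0 = lambda / (2 pi a_s), a_s = 0.885 a_0 Z^(-1/3), eta = theta_0^2/4.
.screening_eta <- function(Z, beam) {
  a_s <- 0.885 * .const$a0_A * Z^(-1 / 3)
  theta0 <- .lambda_A(beam) / (2 * pi * a_s)
  theta0^2 / 4
}

#' Sample elastic scattering deflections
#'
#' Screened-Rutherford polar angle by inverse-CDF sampling,
#' cos(theta) = 1 - 2 eta u / (1 + eta - u), with the Thomas-Fermi screening
#' parameter eta = (lambda Z^(1/3) / (2 pi 0.885 a0))^2 / 4 of an element
#' drawn with probability proportional to n_j Z_j^(4/3) (the screened
#' total-cross-section weighting); uniform azimuth.
#'
#' @param mat An `em_material`.
#' @param beam An `em_beam` or energy in keV.
#' @param n Number of samples.
#' @return List with `theta` and `phi` in rad.
#' @export
sample_elastic_angle <- function(mat, beam, n) {
  beam <- .as_beam(beam)
  els <- names(mat$fractions)
  Z <- vapply(els, .atomic_number, numeric(1))
  w <- mat$fractions * Z^(4 / 3)
  j <- sample.int(length(els), n, replace = TRUE, prob = w)
  eta <- .screening_eta(Z, beam)[j]
  u <- stats::runif(n)
  ct <- 1 - 2 * eta * u / (1 + eta - u)
  ct <- pmin(1, pmax(-1, ct))
  list(theta = acos(ct), phi = stats::runif(n, 0, 2 * pi))
}

# inverse-CDF sampler for the Drude single-loss profile (eV)
.loss_sampler <- function(peak_eV = 20, width_eV = 10, emax = 200, de = 0.25) {
  e <- seq(de, emax, by = de)
  p <- .plasmon_profile(e, peak_eV, width_eV)
  cdf <- cumsum(p) / sum(p)
  function(n) {
    u <- stats::runif(n)
    e[findInterval(u, cdf) + 1L]
  }
}

# Lorentzian dipole angular deflection with Bethe-ridge cutoff
.sample_inelastic_angle <- function(loss_eV, beam) {
  thE <- characteristic_angle(loss_eV, beam)
  thC2 <- 2 * thE                      # cutoff^2 = 2 theta_E (Bethe ridge)
  u <- stats::runif(length(thE))
  theta <- thE * sqrt((1 + thC2 / thE^2)^u - 1)
  list(theta = theta, phi = stats::runif(length(thE), 0, 2 * pi))
}

# rotate unit directions d (n x 3) by polar angle theta about the direction,
# azimuth phi; vectorised
.deflect <- function(d, theta, phi) {
  hx <- ifelse(abs(d[, 3]) < 0.99, 0, 1)
  hz <- 1 - hx
  # e1 = normalize(cross(d, h))
  e1x <- d[, 2] * hz - d[, 3] * 0
  e1y <- d[, 3] * hx - d[, 1] * hz
  e1z <- -d[, 2] * hx
  nrm <- sqrt(e1x^2 + e1y^2 + e1z^2)
  e1x <- e1x / nrm; e1y <- e1y / nrm; e1z <- e1z / nrm
  # e2 = cross(d, e1)
  e2x <- d[, 2] * e1z - d[, 3] * e1y
  e2y <- d[, 3] * e1x - d[, 1] * e1z
  e2z <- d[, 1] * e1y - d[, 2] * e1x
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi); sp <- sin(phi)
  cbind(ct * d[, 1] + st * (cp * e1x + sp * e2x),
        ct * d[, 2] + st * (cp * e1y + sp * e2y),
        ct * d[, 3] + st * (cp * e1z + sp * e2z))
}

.derive_seed <- function(base, i) {
  v <- ((as.numeric(base) %% 100000) * 97561 +
          (as.numeric(i) %% 268435399) * 7919) %% 2147483629
  as.integer(v)
}

#' Run the incoherent-STEM Monte Carlo
#'
#' Trajectories are stepped through the voxelised specimen by Woodcock
#' (delta) tracking against the densest material's total scattering rate;
#' real events are elastic (screened Rutherford) or inelastic (Lorentzian
#' dipole deflection, Drude energy loss -- tallied but not fed back into the
#' kinematics).  Electrons laterally outside the voxel grid see background
#' ice.  Exit polar angles are binned onto the detector; backscattered
#' electrons and angles missing every bin are tallied as out-of-range.
#' Reproducible: per (scan position, chunk) derived seeds.
#'
#' @param model An embedded `em_specimen`.
#' @param config An `em_mc_config`.
#' @param chunk_offset Offset added to the chunk index in the seed
#'   derivation, enabling exact electron-count partitioning across runs.
#' @return An `em_mc`: `counts` (scan_x, scan_y, bin), `out_of_range`,
#'   `unscattered`, `mean_loss_eV` matrices, plus configuration.
#' @export
run_mc <- function(model, config = mc_config(), chunk_offset = 0L) {
  stopifnot(inherits(model, "em_specimen"), inherits(config, "em_mc_config"))
  if (is.null(model$bounds)) stop("model not embedded", call. = FALSE)
  beam <- beam_parameters(config$energy_keV)
  t_total <- model$bounds[["thickness"]]
  nz <- ceiling(round(t_total / config$delta_z, 9))
  if (abs(nz * config$delta_z - t_total) > 1e-9) {
    stop("delta_z must divide the slab thickness", call. = FALSE)
  }
  scan_extent <- config$scan_n * config$scan_step
  L_vox <- scan_extent + 2 * config$margin_nm
  N_vox <- ceiling(L_vox / config$voxel_nm)
  L_vox <- N_vox * config$voxel_nm
  maps <- rasterize(model, N = N_vox, L = L_vox, delta_t = config$delta_z)
  vox <- array(0L, dim = c(N_vox, N_vox, nz))
  for (i in seq_len(nz)) vox[, , i] <- maps$maps[[i]]
  mats <- model$materials[maps$palette]
  rate_el <- vapply(mats, function(m) 1 / elastic_mfp(m, beam), numeric(1))
  rate_in <- vapply(mats, function(m) 1 / inelastic_mfp(m, beam), numeric(1))
  rate_tot <- rate_el + rate_in
  p_inel <- ifelse(rate_tot > 0, rate_in / rate_tot, 0)
  rate_max <- max(rate_tot)
  det <- config$detector
  nb <- det$n_bins
  # ring lookup per exit angle handled by edges below
  sample_loss <- .loss_sampler()
  # scan positions centred in the voxel field
  off <- (L_vox - scan_extent) / 2 + config$scan_step / 2
  xs <- off + (seq_len(config$scan_n) - 1L) * config$scan_step
  n_chunks <- ceiling(config$electrons_per_pixel / config$chunk_size)
  counts <- array(0L, dim = c(config$scan_n, config$scan_n, nb))
  out_of_range <- matrix(0L, config$scan_n, config$scan_n)
  unscattered <- matrix(0L, config$scan_n, config$scan_n)
  sum_loss <- matrix(0, config$scan_n, config$scan_n)
  # element tables per material for elastic sampling
  el_w <- lapply(mats, function(m) {
    Z <- vapply(names(m$fractions), .atomic_number, numeric(1))
    w <- m$fractions * Z^(4 / 3)
    list(eta = .screening_eta(Z, beam), p = w / sum(w))
  })
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (iy in seq_len(config$scan_n)) {
    for (ix in seq_len(config$scan_n)) {
      pos_id <- (iy - 1L) * config$scan_n + ix
      left <- config$electrons_per_pixel
      for (ch in seq_len(n_chunks)) {
        ne <- min(config$chunk_size, left)
        left <- left - ne
        set.seed(.derive_seed(config$seed,
                              pos_id * 131071 + (ch + chunk_offset)))
        res <- .mc_chunk(ne, xs[ix], xs[iy], t_total, vox, N_vox, nz,
                         config$voxel_nm, config$delta_z, rate_tot, p_inel,
                         rate_max, el_w, sample_loss, beam, det,
                         config$max_events)
        counts[ix, iy, ] <- counts[ix, iy, ] + res$bins
        out_of_range[ix, iy] <- out_of_range[ix, iy] + res$out
        unscattered[ix, iy] <- unscattered[ix, iy] + res$unscattered
        sum_loss[ix, iy] <- sum_loss[ix, iy] + res$sum_loss
      }
    }
  }
  structure(list(counts = counts, out_of_range = out_of_range,
                 unscattered = unscattered,
                 mean_loss_eV = sum_loss / config$electrons_per_pixel,
                 config = config, detector = det, scan_x = xs,
                 palette = maps$palette),
            class = "em_mc")
}

# one chunk of ne electrons from a single probe position
.mc_chunk <- function(ne, x0, y0, t_total, vox, N_vox, nz, voxel, dz,
                      rate_tot, p_inel, rate_max, el_w, sample_loss, beam,
                      det, max_events) {
  x <- rep(x0, ne); y <- rep(y0, ne); z <- rep(0, ne)
  d <- cbind(rep(0, ne), rep(0, ne), rep(1, ne))
  nev <- integer(ne); eloss <- numeric(ne)
  exit_theta <- rep(NA_real_, ne)
  alive <- rep(TRUE, ne)
  if (rate_max <= 0) {            # all-vacuum field: ballistic transit
    exit_theta[] <- 0
    alive[] <- FALSE
  }
  it <- 0L
  while (any(alive)) {
    it <- it + 1L
    if (it > 100000L) {  # pathological grazing trajectories: tally as lost
      oi <- which(alive)
      exit_theta[oi] <- pi / 2
      alive[oi] <- FALSE
      break
    }
    idx <- which(alive)
    s <- stats::rexp(length(idx), rate_max)
    x[idx] <- x[idx] + s * d[idx, 1]
    y[idx] <- y[idx] + s * d[idx, 2]
    z[idx] <- z[idx] + s * d[idx, 3]
    # exits
    fwd <- z[idx] >= t_total
    bwd <- z[idx] < 0
    done <- fwd | bwd
    if (any(done)) {
      di <- idx[done]
      exit_theta[di] <- acos(pmin(1, pmax(-1, d[di, 3])))
      alive[di] <- FALSE
      idx <- idx[!done]
    }
    if (!length(idx)) break
    # material lookup (outside lateral bounds -> background ice, index 1)
    ixv <- floor(x[idx] / voxel) + 1
    iyv <- floor(y[idx] / voxel) + 1
    izv <- pmin(nz, pmax(1, floor(z[idx] / dz) + 1))
    inside <- ixv >= 1 & ixv <= N_vox & iyv >= 1 & iyv <= N_vox
    mat_i <- rep(1L, length(idx))
    if (any(inside)) {
      ii <- which(inside)
      mat_i[ii] <- vox[cbind(ixv[ii], iyv[ii], izv[ii])]
    }
    # Woodcock: accept a real event with prob rate(mat)/rate_max
    acc <- stats::runif(length(idx)) < rate_tot[mat_i] / rate_max
    if (!any(acc)) next
    ai <- idx[acc]; am <- mat_i[acc]
    inel <- stats::runif(length(ai)) < p_inel[am]
    th <- numeric(length(ai)); ph <- numeric(length(ai))
    if (any(!inel)) {
      ei <- which(!inel)
      # per-material element choice
      for (m in unique(am[ei])) {
        sel <- ei[am[ei] == m]
        ew <- el_w[[m]]
        j <- sample.int(length(ew$p), length(sel), replace = TRUE, prob = ew$p)
        eta <- ew$eta[j]
        u <- stats::runif(length(sel))
        ct <- pmin(1, pmax(-1, 1 - 2 * eta * u / (1 + eta - u)))
        th[sel] <- acos(ct)
      }
      ph[ei] <- stats::runif(length(ei), 0, 2 * pi)
    }
    if (any(inel)) {
      ii <- which(inel)
      dE <- sample_loss(length(ii))
      ia <- .sample_inelastic_angle(dE, beam)
      th[ii] <- ia$theta; ph[ii] <- ia$phi
      eloss[ai[ii]] <- eloss[ai[ii]] + dE
    }
    d[ai, ] <- .deflect(d[ai, , drop = FALSE], th, ph)
    nev[ai] <- nev[ai] + 1L
    overrun <- nev[ai] >= max_events
    if (any(overrun)) {
      warning("max_events cap hit; terminating trajectories")
      oi <- ai[overrun]
      exit_theta[oi] <- acos(pmin(1, pmax(-1, d[oi, 3])))
      alive[oi] <- FALSE
    }
  }
  # bin exit angles
  rings <- det$rings
  bins <- integer(det$n_bins)
  out <- 0L
  th <- exit_theta
  # azimuth of exit direction
  binned <- rep(FALSE, ne)
  if (det$segments > 1L) {
    az <- atan2(d[, 2], d[, 1]) %% (2 * pi)
    seg <- pmin(det$segments, 1L + floor(az / (2 * pi / det$segments)))
  } else seg <- rep(1L, ne)
  for (r in seq_len(nrow(rings))) {
    sel <- if (rings$inner[r] == 0) th <= rings$outer[r] else
      th > rings$inner[r] & th <= rings$outer[r]
    sel <- sel & !binned
    if (any(sel)) {
      tb <- tabulate(seg[sel], nbins = det$segments)
      bins[(r - 1L) * det$segments + seq_len(det$segments)] <-
        bins[(r - 1L) * det$segments + seq_len(det$segments)] + tb
      binned <- binned | sel
    }
  }
  out <- ne - sum(bins)
  list(bins = bins, out = out, unscattered = sum(nev == 0L),
       sum_loss = sum(eloss))
}

#' @export
print.em_mc <- function(x, ...) {
  cat(sprintf("<em_mc> %dx%d scan, %d e-/pixel, %d bins, %g keV\n",
              x$config$scan_n, x$config$scan_n, x$config$electrons_per_pixel,
              x$detector$n_bins, x$config$energy_keV))
  invisible(x)
}

#' Per-detector-bin images from a Monte Carlo result
#'
#' @param result An `em_mc`.
#' @return Named list of `em_image` (one per detector bin, ring-major) plus
#'   `out_of_range`.
#' @export
mc_images <- function(result) {
  stopifnot(inherits(result, "em_mc"))
  det <- result$detector
  out <- vector("list", det$n_bins + 1L)
  nm <- character(det$n_bins + 1L)
  for (b in seq_len(det$n_bins)) {
    r <- det$ring_of[b]
    nm[b] <- sprintf("ring%02d_seg%02d_%.1f-%.1fmrad", r, det$seg_of[b],
                     1e3 * det$rings$inner[r], 1e3 * det$rings$outer[r])
    out[[b]] <- sim_image(matrix(as.numeric(result$counts[, , b]),
                                 result$config$scan_n, result$config$scan_n),
                          pixel_size = result$config$scan_step,
                          seed = result$config$seed,
                          meta = list(bin = b, ring = r))
  }
  nm[det$n_bins + 1L] <- "out_of_range"
  out[[det$n_bins + 1L]] <- sim_image(
    matrix(as.numeric(result$out_of_range), result$config$scan_n,
           result$config$scan_n),
    pixel_size = result$config$scan_step, seed = result$config$seed,
    meta = list(bin = "out_of_range"))
  stats::setNames(out, nm)
}
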