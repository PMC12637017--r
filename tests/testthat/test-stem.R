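test_that("detector geometry: construction, defaults, validation", {
  d <- tcbf_detector()
  expect_identical(nrow(d$rings), 20L)
  expect_identical(d$segments, 90L)
  expect_identical(d$n_bins, 1800L)
  expect_equal(max(d$rings$outer), 4e-3)
  o200 <- opal_detector(200)
  expect_equal(o200$rings$inner, c(0, 10, 20, 30) * 1e-3)
  expect_equal(o200$rings$outer, c(7, 20, 30, 44) * 1e-3)
  o1000 <- opal_detector(1000)
  expect_equal(round(1e3 * o1000$rings$outer[1], 2), 2.43)
  expect_error(detector_geometry(c(3e-3, 1e-3)), "increasing")
  expect_error(detector_geometry(rbind(c(0, 0))), "increasing")
  d2 <- detector_geometry(rbind(c(0, 7e-3), c(10e-3, 20e-3)))
  expect_identical(d2$n_bins, 2L)
})

test_that("probe wave: normalisation, Airy radius, sampling guard", {
  b <- beam_parameters(200)
  N <- 128; L <- 32
  opt <- optics_parameters(Cs_mm = 0, defocus_nm = 0, convergence = 3e-3)
  p <- probe_wave(c(16, 16), 3e-3, opt, b, N, L)
  expect_equal(wave_intensity(p), 1, tolerance = 1e-12)
  # aberration-free probe: first minimum at 0.61 lambda / alpha
  I <- Mod(p$values)^2
  ax <- (seq_len(N) - 0.5) * L / N
  prof <- I[, which.max(colSums(I))]
  ctr <- which.max(prof)
  loc_min <- which(diff(sign(diff(prof[ctr:(ctr + 20)]))) > 0)[1] + ctr
  r_emp <- ax[loc_min] - ax[ctr]
  r_airy <- 0.61 * b$wavelength * 1e-3 / 3e-3
  expect_equal(r_emp, r_airy, tolerance = 0.3)   # grid-limited
  expect_error(probe_wave(c(16, 16), 8e-3, opt, b, N, L), "sampled")
})

test_that("vacuum 4D record: all intensity in the bright-field disc", {
  b <- beam_parameters(200)
  s <- embed_in_ice(ice_slab(background = "vacuum"), 40)
  opt <- optics_parameters(Cs_mm = 2, defocus_nm = 500, convergence = 3e-3)
  det <- tcbf_detector(max_angle = 3.2e-3, rings = 8, segments = 4)
  sg <- scan_grid(4, step = 2, L = 16)
  rec <- record_4d(s, b, opt, det, sg, N = 64, L = 16, delta_t = 10)
  expect_true(all(abs(apply(rec$data, c(1, 2), sum) - 1) < 1e-9))
  expect_true(all(rec$beyond < 1e-12))
  expect_true(all(abs(rec$absorbed) < 1e-9))
})

test_that("per-position electron bookkeeping includes absorption", {
  b <- beam_parameters(200)
  s <- embed_in_ice(ice_slab(), 200)
  opt <- optics_parameters(Cs_mm = 2, defocus_nm = 500, convergence = 3e-3)
  det <- tcbf_detector(max_angle = 3.2e-3, rings = 4, segments = 1)
  sg <- scan_grid(3, step = 2, L = 16)
  rec <- record_4d(s, b, opt, det, sg, N = 64, L = 16, delta_t = 10)
  tot <- apply(rec$data, c(1, 2), sum) + rec$beyond + rec$absorbed
  expect_true(all(abs(tot - 1) < 1e-9))
  # uniform ice: absorbed fraction matches the attenuation oracle
  expect_equal(mean(rec$absorbed), 1 - exp(-1.82e-4 * 2000), tolerance = 1e-4)
})

test_that("parallax shift closed form", {
  opt <- optics_parameters(Cs_mm = 2, defocus_nm = 2000)
  expect_identical(parallax_shift(c(0, 0), opt), matrix(c(0, 0), 1))
  # vanishes at the defocus Cs omega^2
  om <- 2e-3
  opt2 <- optics_parameters(Cs_mm = 2, defocus_nm = 2e6 * om^2)
  expect_equal(max(abs(parallax_shift(c(om, 0), opt2))), 0, tolerance = 1e-12)
  # scalar oracle at 2 um defocus, 2 mrad
  s <- parallax_shift(c(om, 0), opt)
  expect_equal(s[1, 1], (2e6 * om^2 - 2000) * om, tolerance = 1e-12)
  expect_identical(s[1, 2], 0)
})

test_that("tcBF: single on-axis bin is plain BF; zero optics is identity", {
  b <- beam_parameters(200)
  st <- blob_stack(128, 32, b)
  opt <- optics_parameters(Cs_mm = 2, defocus_nm = 500, convergence = 3e-3)
  det1 <- detector_geometry(c(0, 1e-4))
  sg <- scan_grid(8, step = 1, L = 32)
  rec <- record_4d(st, b, opt, det1, sg)
  tc <- tilt_corrected_bf(rec)
  # the bin centre sits at half the (tiny) ring radius, so the correction is
  # a sub-hundredth-pixel shift rather than exactly zero
  expect_equal(tc$counts, pmax(rec$data[, , 1], 0), tolerance = 2e-3)
  # zero Cs and defocus -> correction is the identity for any detector
  det <- tcbf_detector(max_angle = 3e-3, rings = 4, segments = 8)
  rec2 <- record_4d(st, b, opt, det, sg)
  o0 <- rec2$optics; o0$Cs_nm <- 0; o0$defocus <- 0
  tc0 <- tilt_corrected_bf(rec2, optics = o0)
  plain <- apply(rec2$data, c(1, 2), sum)
  expect_equal(tc0$counts, pmax(plain, 0), tolerance = 1e-9)
})

test_that("tcBF warns about and excludes bins outside the BF disc", {
  b <- beam_parameters(200)
  st <- blob_stack(128, 32, b)
  opt <- optics_parameters(Cs_mm = 2, defocus_nm = 500, convergence = 2e-3)
  det <- tcbf_detector(max_angle = 4e-3, rings = 4, segments = 4)
  sg <- scan_grid(6, step = 1, L = 32)
  rec <- record_4d(st, b, opt, det, sg)
  expect_warning(tc <- tilt_corrected_bf(rec), "excluded")
  expect_identical(tc$meta$bins_used, 8L)     # rings 1-2 of 4
})

test_that("reciprocity: small-scale tcBF matches the matched-aperture TEM", {
  b <- beam_parameters(200)
  N <- 96; L <- 24
  st <- blob_stack(N, L, b, scale = 1)
  opt_stem <- optics_parameters(Cs_mm = 2, defocus_nm = 500, convergence = 3e-3)
  opt_tem <- optics_parameters(Cs_mm = 2, defocus_nm = 500, aperture = 3e-3,
                               convergence = 0)
  ref_full <- image_from_exit_wave(exit_wave(st), opt_tem, b)
  det <- tcbf_detector(max_angle = 1.8e-3, rings = 6, segments = 24)
  al <- aligned_scan(32, 2, N, L)
  rec <- record_4d(st, b, opt_stem, det, al$grid)
  tc <- tilt_corrected_bf(rec)
  ref <- ref_full[al$idx, al$idx]
  expect_gt(ncc(tc$counts, ref), 0.97)
  # summed image has better S/N than a single bin: same signal, more counts
  expect_gt(mean(tc$counts), 10 * mean(rec$data[, , 1]))
})

test_that("tcBF Poisson counting at full incident fluence", {
  b <- beam_parameters(200)
  st <- blob_stack(128, 32, b)
  opt <- optics_parameters(Cs_mm = 2, defocus_nm = 500, convergence = 3e-3)
  det <- tcbf_detector(max_angle = 3e-3, rings = 4, segments = 8)
  sg <- scan_grid(8, step = 1, L = 32)
  rec <- record_4d(st, b, opt, det, sg)
  tc1 <- tilt_corrected_bf(rec, fluence = 100, seed = 5, noise = TRUE)
  tc2 <- tilt_corrected_bf(rec, fluence = 100, seed = 5, noise = TRUE)
  expect_identical(tc1$counts, tc2$counts)
  expect_identical(tc1$fluence, 100)
})
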