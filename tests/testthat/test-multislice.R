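test_that("phase gratings: vacuum transmits unity, ice attenuates per mu", {
  b <- beam_parameters(200)
  s <- embed_in_ice(ice_slab(background = "vacuum"), 40)
  st_vac <- phase_gratings(rasterize(s, N = 16, L = 32, delta_t = 10), b)
  expect_equal(slice_transmission(st_vac, 1),
               matrix(as.complex(1), 16, 16))
  s2 <- embed_in_ice(ice_slab(), 40)
  st_ice <- phase_gratings(rasterize(s2, N = 16, L = 32, delta_t = 10), b)
  amp2 <- Mod(slice_transmission(st_ice, 1)[1, 1])^2
  # scalar oracle: intensity attenuation over one slice with Table-3 mu
  expect_equal(amp2, exp(-1.82e-4 * 100), tolerance = 1e-12)
  ph <- Arg(slice_transmission(st_ice, 1)[1, 1])
  expect_equal(ph, phase_per_thickness(default_materials()$ice, b) * 100,
               tolerance = 1e-9)
  expect_error(phase_gratings(rasterize(s2, N = 8, L = 32, delta_t = 10), b,
                              absorb_beyond = 4), "0, pi")
})

test_that("slice stacks reject unphysical gain", {
  b <- beam_parameters(200)
  expect_error(slice_stack(list(matrix(as.complex(1.2), 8, 8)),
                           2, 16, b), "modulus")
})

test_that("free-space propagation is unitary and trivial cases hold", {
  b <- beam_parameters(200)
  N <- 64; L <- 32
  pw <- plane_wave(N, L, b)
  expect_identical(propagate(pw, 0)$values, pw$values)
  p <- propagate(pw, 500)
  # plane wave is an eigenfunction: uniform, unit modulus
  expect_lt(max(Mod(p$values - p$values[1, 1])), 1e-12)
  set.seed(1)
  phi <- blob_phase(N, L, 14, 18, 3, 0.7)
  w <- wave_field(exp(1i * phi), L, b)
  w2 <- propagate(w, 123.4)
  expect_equal(wave_intensity(w2), wave_intensity(w), tolerance = 1e-12)
  expect_error(propagate(w, -1), "negative")
})

test_that("a Gaussian beam spreads with the analytic Fresnel law", {
  b <- beam_parameters(200)
  N <- 256; L <- 128
  ax <- (seq_len(N) - 0.5) * L / N
  s0 <- 4
  psi0 <- outer(exp(-(ax - 64)^2 / (2 * s0^2)), exp(-(ax - 64)^2 / (2 * s0^2)))
  w <- propagate(wave_field(matrix(as.complex(psi0), N, N), L, b), 2e5)
  lam <- b$wavelength * 1e-3
  zr <- 2 * pi * s0^2 / lam
  s_I <- s0 * sqrt(1 + (2e5 / zr)^2) / sqrt(2)   # intensity sigma
  I <- Mod(w$values)^2
  mid <- I[, which.max(colSums(I))]
  s_emp <- sqrt(sum((ax - 64)^2 * mid) / sum(mid))
  expect_equal(s_emp, s_I, tolerance = 1e-3)
})

test_that("exit wave: vacuum identity, unitarity, shape checks", {
  b <- beam_parameters(200)
  N <- 64; L <- 32
  vac <- slice_stack(rep(list(matrix(as.complex(1), N, N)), 4), 10, L, b)
  w <- exit_wave(vac)
  expect_lt(max(Mod(w$values - 1)), 1e-12)
  st <- blob_stack(N, L, b)
  expect_equal(wave_intensity(exit_wave(st)) / N^2, 1, tolerance = 1e-10)
  bad <- plane_wave(32, L, b)
  expect_error(exit_wave(st, bad), "disagree")
})

test_that("single weak slice reproduces the analytic weak-phase image", {
  b <- beam_parameters(200)
  N <- 128; L <- 64
  phi <- blob_phase(N, L, 32, 32, 6, 0.05)
  st <- slice_stack(list(exp(1i * phi)), delta_t = 2, L = L, beam = b)
  opt <- optics_parameters(Cs_mm = 2, defocus_nm = 500, aperture = 6e-3)
  img <- image_from_exit_wave(exit_wave(st), opt, b)
  k1 <- c(0:(N / 2 - 1), -(N / 2):-1) / L
  k2 <- outer(k1^2, k1^2, `+`)
  theta <- (b$wavelength * 1e-3) * sqrt(k2)
  H <- sin(chi(theta, opt, b)) * (theta <= 6e-3)
  dI <- 2 * Re(stats::fft(H * stats::fft(phi), inverse = TRUE) / N^2)
  expect_lt(max(abs((img - 1) - dI)) / max(abs(dI)), 0.01)
})

test_that("two thin slices agree with one double slice within the error bound", {
  b <- beam_parameters(200)
  N <- 64; L <- 32
  # z-uniform specimen: same grating content per unit thickness
  phi <- blob_phase(N, L, 14, 18, 4, 0.2)
  one <- slice_stack(list(exp(2i * phi)), delta_t = 4, L = L, beam = b)
  two <- slice_stack(list(exp(1i * phi), exp(1i * phi)), delta_t = 2, L = L,
                     beam = b)
  w1 <- exit_wave(one); w2 <- exit_wave(two)
  diff_rel <- max(Mod(w1$values - w2$values))
  # bounded by the slice-error budget at the band-limit angle
  thM <- (2 / 3) * max_sampled_angle(N, L, b)
  bound <- 0.4 * 10 * (pi * thM^2 * 40 / (2 * b$wavelength * 1e-2))
  expect_lt(diff_rel, max(bound, 0.02))
})

test_that("maximum sampled angle follows lambda N / 2L", {
  b <- beam_parameters(200)
  expect_equal(1e3 * max_sampled_angle(512, 128, b), 5, tolerance = 5e-3)
  expect_equal(max_sampled_angle(1024, 128, b), 2 * max_sampled_angle(512, 128, b))
  r <- beam_parameters(1000)$wavelength / b$wavelength
  expect_equal(max_sampled_angle(512, 128, beam_parameters(1000)),
               r * max_sampled_angle(512, 128, b))
})

test_that("slice error scales linearly in slice thickness and stays below 10%", {
  b <- beam_parameters(200)
  ice <- default_materials()$ice
  thM <- max_sampled_angle(512, 128, b)
  e2 <- slice_error(ice, b, 2, thM, 200)
  e1 <- slice_error(ice, b, 1, thM, 200)
  expect_equal(as.numeric(e1) / as.numeric(e2), 0.5, tolerance = 1e-9)
  expect_lt(e2, 0.10)
  expect_gt(e2, 0.01)
  e_small <- slice_error(ice, b, 0.125, thM, 200)
  expect_lt(e_small, e2 / 10)
  expect_error(slice_error(ice, b, 3, thM, 200), "divide")
})

test_that("absorptive stacks only lose intensity", {
  b <- beam_parameters(200)
  s <- embed_in_ice(ice_slab(), 200)
  st <- phase_gratings(rasterize(s, N = 32, L = 32, delta_t = 10), b)
  w <- exit_wave(st)
  ratio <- wave_intensity(w) / 32^2
  expect_gt(ratio, 0)
  expect_lt(ratio, 1)
  # matches the scalar attenuation for a uniform slab
  expect_equal(ratio, exp(-1.82e-4 * 2000), tolerance = 1e-6)
})
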