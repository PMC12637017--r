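test_that("beam parameters agree with a constants-only evaluation at 5 voltages", {
  mc2 <- 510.99895; hc <- 1239.8419844
  for (E in c(80, 200, 300, 1000, 4000)) {
    b <- beam_parameters(E)
    lam <- hc / sqrt(E * (E + 2 * mc2))
    expect_equal(b$wavelength, lam, tolerance = 1e-4)
    expect_equal(b$gamma, 1 + E / mc2, tolerance = 1e-4)
    expect_equal(b$wavevector, 2 * pi / lam, tolerance = 1e-4)
  }
  b200 <- beam_parameters(200)
  expect_equal(b200$wavelength, 2.508, tolerance = 2e-4)
  expect_equal(b200$gamma, 1.391, tolerance = 3e-4)
  expect_equal(b200$sigma, 7.288e-4, tolerance = 1e-3)
})

test_that("beam parameters: non-relativistic limit and domain errors", {
  expect_lt(beam_parameters(1e-6)$gamma - 1, 1e-8)
  expect_error(beam_parameters(0), "positive")
  expect_error(beam_parameters(-100), "positive")
  expect_error(beam_parameters(c(100, 200)), "positive|single")
})

test_that("1 MeV detector-angle scaling follows the wavelength ratio", {
  r <- beam_parameters(1000)$wavelength / beam_parameters(200)$wavelength
  expect_equal(round(r * 7, 2), 2.43)
})

test_that("lambda*gamma decreases monotonically and saturates", {
  grid <- c(100, 200, 300, 500, 1000, 2000, 4000)
  lg <- lambda_gamma_product(grid)
  expect_true(all(diff(lg) < 0))
  expect_equal(lg[2], 3.49, tolerance = 2e-3)
  # saturation: MeV-range change is small
  expect_lt(abs(lg[7] - lg[5]) / lg[5], 0.15)
  # approaches the Compton wavelength from above
  expect_gt(min(lg), 2.4263)
  # mean-free-path scaling is the squared inverse ratio
  expect_equal(lambda_gamma_sq_ratio(200), 1)
  expect_equal(lambda_gamma_sq_ratio(1000), (lg[2] / lg[5])^2)
})

test_that("phase per thickness matches a hand evaluation for vitreous ice", {
  b <- beam_parameters(200)
  ice <- default_materials()$ice
  lamA <- b$wavelength * 1e-2
  m_ice <- (15.999 + 2 * 1.008) / 3
  oracle <- lamA * b$gamma * 0.8885 * 0.9 / (1.66053907 * m_ice)
  expect_equal(phase_per_thickness(ice, b), oracle, tolerance = 1e-10)
  expect_equal(oracle, 2.80e-3, tolerance = 2e-3)
})

test_that("phase per thickness: vacuum, density linearity, unknown elements", {
  b <- beam_parameters(200)
  expect_identical(phase_per_thickness(default_materials()$vacuum, b), 0)
  m1 <- material("a", c(O = 1), 1.0)
  m2 <- material("b", c(O = 1), 2.5)
  expect_equal(phase_per_thickness(m2, b), 2.5 * phase_per_thickness(m1, b))
  expect_error(material("bad", c(Xx = 1), 1), "unknown element")
})

test_that("protein and nucleic acid differ mostly by density", {
  b <- beam_parameters(200)
  prot <- material("p", c(C = .31, N = .08, O = .08, H = .525, S = .005), 1.3)
  dna <- material("d", c(C = .24, N = .09, O = .14, H = .51, P = .02), 1.3)
  r <- phase_per_thickness(prot, b) / phase_per_thickness(dna, b)
  # at equal density the compositions differ by ~7%; the real densities
  # differ by 30%, so density dominates the contrast
  expect_lt(abs(r - 1), 0.10)
  prot_rho <- material("p2", prot$fractions, 1.3)
  dna_rho <- material("d2", dna$fractions, 1.7)
  r_rho <- phase_per_thickness(dna_rho, b) / phase_per_thickness(prot_rho, b)
  expect_gt(r_rho, 1.2)
})

test_that("one-radian thickness: errors, value, voltage trend", {
  mats <- default_materials()
  b <- beam_parameters(200)
  expect_error(one_radian_thickness(mats$ice, mats$ice, b), "identical")
  # independent arithmetic oracle with the shipped constants
  lamA <- b$wavelength * 1e-2
  m_ice <- (15.999 + 2 * 1.008) / 3
  m_prot <- .31 * 12.011 + .08 * 14.007 + .08 * 15.999 + .525 * 1.008 + .005 * 32.06
  dphi <- lamA * b$gamma * (1.3 * 1.5170 / m_prot - 0.9 * 0.8885 / m_ice) / 1.66053907
  expect_equal(as.numeric(one_radian_thickness(mats$protein, mats$ice, b)),
               1 / dphi / 10, tolerance = 1e-10)
  # soft checks in lieu of the printed table: increasing, saturating,
  # right order of magnitude
  tt <- vapply(c(200, 300, 1000, 4000), function(E)
    as.numeric(one_radian_thickness(mats$protein, mats$ice, beam_parameters(E))),
    numeric(1))
  expect_true(all(diff(tt) > 0))
  expect_lt(diff(tt)[3] / diff(tt)[1], 1)      # increments shrink
  expect_true(all(tt > 20 & tt < 80))
  expect_false(is.null(attr(one_radian_thickness(mats$protein, mats$ice, b),
                            "phase_per_A_a")))
})

test_that("absorption coefficient: window properties and mfp consistency", {
  b <- beam_parameters(200)
  mat <- ice_derived()
  expect_identical(absorption_coefficient(mat, b, 3e-3, 3e-3), 0)
  expect_error(absorption_coefficient(mat, b, 0.1, 0.05), "theta")
  m1 <- absorption_coefficient(mat, b, 0, 6e-3)
  m2 <- absorption_coefficient(mat, b, 6e-3, 5e-2)
  m3 <- absorption_coefficient(mat, b, 5e-2, pi)
  tot <- absorption_coefficient(mat, b, 0, pi)
  expect_equal(m1 + m2 + m3, tot, tolerance = 1e-7)
  # over (0, pi) the absorption equals the reciprocal elastic mean free path
  expect_equal(tot, 1 / (elastic_mfp(mat, b) * 10), tolerance = 1e-7)
  # derived ice mfp is in the neighbourhood of the measured 581 nm
  expect_gt(elastic_mfp(mat, b), 400)
  expect_lt(elastic_mfp(mat, b), 750)
})

test_that("attenuation: limits, multiplicativity, zero-loss budget", {
  expect_identical(attenuation(0, mfp_nm = 157), 1)
  expect_equal(attenuation(157, mfp_nm = 157), exp(-1))
  expect_error(attenuation(-1, mfp_nm = 157), "negative")
  expect_error(attenuation(1), "exactly one")
  for (t1 in c(10, 57, 123)) {
    expect_equal(attenuation(t1 + 41, mfp_nm = 157),
                 attenuation(t1, mfp_nm = 157) * attenuation(41, mfp_nm = 157),
                 tolerance = 1e-14)
  }
  # 200 nm of ice leaves 28% in the zero-loss peak
  expect_equal(round(100 * attenuation(200, mfp_nm = 157)), 28)
  # strictly decreasing
  tt <- seq(0, 400, by = 40)
  expect_true(all(diff(attenuation(tt, mfp_nm = 157)) < 0))
})

test_that("mean free path overrides rescale with (lambda gamma)^2", {
  mats <- default_materials()
  expect_equal(elastic_mfp(mats$ice, beam_parameters(200)), 581)
  expect_equal(inelastic_mfp(mats$ice, beam_parameters(200)), 157)
  r <- lambda_gamma_sq_ratio(1000)
  expect_equal(elastic_mfp(mats$ice, beam_parameters(1000)), 581 * r)
  # Table-3 orderings: ice > protein > dna in mfp, reversed in mu
  b <- beam_parameters(200)
  mfps <- vapply(mats[c("ice", "protein", "dna")], elastic_mfp, numeric(1), beam = b)
  expect_true(all(diff(mfps) < 0))
  mus <- vapply(mats[c("ice", "protein", "dna")], function(m) m$mu_abs, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("optical constants bundle is coherent", {
  b <- beam_parameters(200)
  oc <- optical_constants(default_materials()$ice, b)
  expect_gt(oc$phase_per_A, 0)
  expect_gt(oc$mu, 0)
  expect_equal(oc$mu, 1.82e-4)
  expect_equal(oc$inelastic_mfp, 157)
})

test_that("material validation", {
  expect_error(material("x", c(O = 0.5, H = 0.4), 1), "sum to 1")
  expect_error(material("x", c(O = 1), -1), "non-negative")
  expect_error(material("x", c(1, 2), 1), "named")
})

test_that("scattering factors decrease with angle", {
  b <- beam_parameters(200)
  th <- seq(0, 0.3, length.out = 40)
  for (el in c("H", "C", "N", "O", "P", "S")) {
    f <- scattering_factor(el, th, b)
    expect_true(all(diff(f) <= 0))
    expect_gt(f[1], 0)
  }
  expect_error(scattering_factor("Fe", 0, b), "unknown element")
})
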