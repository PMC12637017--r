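test_that("hollow capsid when the DNA volume fraction is zero", {
  m <- build_phage(capsid_length = 48, capsid_width = 36,
                   dna_volume_fraction = 0)
  m <- embed_in_ice(m, 64)
  maps <- rasterize(m, N = 64, L = 64, delta_t = 4)
  vv <- voxel_volumes(maps)
  expect_identical(unname(vv["dna"]), 0)
  expect_gt(vv["protein"], 0)
})

test_that("DNA volume fraction is reproduced by a point cloud", {
  target <- 0.35
  m <- mini_phage(target)
  mm <- embed_in_ice(m, 64)                        # top view, centred
  set.seed(101)
  n <- 3e5
  iw <- 36 - 2 * 3; il <- 48 - 2 * 3
  # sample the interior bounding box in the model frame (top view: model ==
  # lab up to the centre offset)
  pts <- cbind(runif(n, -iw / 2, iw / 2) + 32,
               runif(n, -iw / 2, iw / 2) + 32,
               runif(n, -il / 2, il / 2) + 32)
  cls <- classify_points(mm, pts, field_center = c(32, 32))
  v_box <- iw^2 * il
  v_dna <- sum(cls == 3) / n * v_box
  # analytic interior volume of the anisotropically scaled icosahedron
  a <- 4 / sqrt(10 + 2 * sqrt(5))                 # edge for circumradius 1
  v_unit <- (5 / 12) * (3 + sqrt(5)) * a^3
  rho_eq <- 2 / sqrt(5)                            # equatorial vertex radius
  v_int <- v_unit * ((iw / 2) / rho_eq)^2 * (il / 2)
  expect_lt(abs(v_dna / v_int - target), 0.015)
})

test_that("voxel volumes conserve the bounds volume exactly", {
  m <- embed_in_ice(mini_phage(), 64)
  maps <- rasterize(m, N = 64, L = 64, delta_t = 4)
  expect_identical(sum(voxel_volumes(maps)), 64^2 * 64)
  expect_length(maps$maps, 16L)
  expect_identical(dim(maps$maps[[1]]), c(64L, 64L))
})

test_that("rasterisation is deterministic and slice thickness must divide", {
  m <- embed_in_ice(mini_phage(), 64)
  a <- rasterize(m, N = 32, L = 64, delta_t = 8)
  b <- rasterize(m, N = 32, L = 64, delta_t = 8)
  expect_identical(a$maps, b$maps)
  expect_error(rasterize(m, N = 32, L = 64, delta_t = 7), "divide")
})

test_that("90-degree rotation about the beam equals an index permutation", {
  m0 <- embed_in_ice(mini_phage(), 64)
  Rz90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  m1 <- embed_in_ice(mini_phage(), 64, orientation = Rz90)
  N <- 48
  a <- rasterize(m0, N = N, L = 64, delta_t = 8)
  b <- rasterize(m1, N = N, L = 64, delta_t = 8)
  for (i in seq_along(a$maps)) {
    expect_identical(b$maps[[i]], t(a$maps[[i]][N:1, ]))
  }
})

test_that("embedding: protrusion errors and depth translation invariance", {
  m <- build_phage()                                # 110 nm long
  expect_error(embed_in_ice(m, 100), "protrudes")   # top view does not fit
  expect_silent(m_side <- embed_in_ice(m, 100, orientation = "side"))
  m1 <- embed_in_ice(build_phage(), 400, depth_of_center = 100)
  m2 <- embed_in_ice(build_phage(), 400, depth_of_center = 300)
  v1 <- voxel_volumes(rasterize(m1, N = 64, L = 128, delta_t = 8))
  v2 <- voxel_volumes(rasterize(m2, N = 64, L = 128, delta_t = 8))
  expect_equal(v1, v2)
  expect_error(embed_in_ice(build_phage(), 400, depth_of_center = 30),
               "protrudes")
})

test_that("orthogonal views: rings in top view, stripes in side view", {
  m_top <- embed_in_ice(mini_phage(0.4), 64, orientation = "top")
  m_side <- embed_in_ice(mini_phage(0.4), 64, orientation = "side")
  mt <- rasterize(m_top, N = 64, L = 64, delta_t = 4)
  ms <- rasterize(m_side, N = 64, L = 64, delta_t = 4)
  mid <- mt$maps[[8]]                 # slice through the capsid centre
  # top view: DNA voxels form closed rings -> all azimuths populated
  dna <- which(mid == 3L, arr.ind = TRUE)
  expect_gt(nrow(dna), 0)
  az <- atan2(dna[, 2] - 32.5, dna[, 1] - 32.5)
  expect_gt(length(unique(round(az, 1))), 20)
  # side view: a mid slice shows DNA in straight bands parallel to the long
  # axis (x): the set of occupied y-rows is small, each row long
  mids <- ms$maps[[8]]
  dna_s <- which(mids == 3L, arr.ind = TRUE)
  expect_gt(nrow(dna_s), 0)
  rows <- table(dna_s[, 2])
  expect_lt(length(rows), 20)          # few distinct bands
  expect_gt(max(rows), 15)             # bands are extended
})

test_that("ice slab classifies everything as background", {
  s <- embed_in_ice(ice_slab(), 100)
  maps <- rasterize(s, N = 16, L = 32, delta_t = 25)
  expect_true(all(vapply(maps$maps, function(m) all(m == 1L), logical(1))))
})

test_that("DNA voxel volume tracks the lattice fraction estimate", {
  m <- embed_in_ice(mini_phage(0.35), 64)
  maps <- rasterize(m, N = 128, L = 64, delta_t = 2)
  vv <- voxel_volumes(maps)
  frac_claimed <- 0.35
  a <- 4 / sqrt(10 + 2 * sqrt(5))
  v_unit <- (5 / 12) * (3 + sqrt(5)) * a^3
  iw <- 30; il <- 42
  v_int <- v_unit * ((iw / 2) / (2 / sqrt(5)))^2 * (il / 2)
  expect_lt(abs(vv[["dna"]] / v_int - frac_claimed) / frac_claimed, 0.06)
})
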