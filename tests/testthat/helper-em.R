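# shared helpers for the thickEM test suite

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# smooth Gaussian phase blob on the standard grid
blob_phase <- function(N, L, x0, y0, sigma, amp) {
  ax <- (seq_len(N) - 0.5) * L / N
  amp * outer(exp(-(ax - x0)^2 / (2 * sigma^2)),
              exp(-(ax - y0)^2 / (2 * sigma^2)))
}

# a non-centrosymmetric pure-phase test object (single slice)
blob_stack <- function(N, L, beam, delta_t = 2, scale = 1) {
  phi <- blob_phase(N, L, 0.375 * L, 0.5625 * L, 0.0625 * L, 0.6 * scale) +
    blob_phase(N, L, 0.625 * L, 0.46 * L, 0.094 * L, 0.9 * scale) +
    blob_phase(N, L, 0.54 * L, 0.645 * L, 0.052 * L, -0.4 * scale)
  slice_stack(list(exp(1i * phi)), delta_t = delta_t, L = L, beam = beam)
}

# derived-route materials (no Table-3 overrides): exercise the f-table path
ice_derived <- function() material("ice_derived", c(O = 1 / 3, H = 2 / 3), 0.9)

# small phage that fits a 64 nm field
mini_phage <- function(frac = 0.35) {
  build_phage(capsid_length = 48, capsid_width = 36, shell_thickness = 3,
              dna_volume_fraction = frac)
}

# scan grid aligned with the pixel raster of an N/L field: n positions with
# pitch m pixels, centred; returns the grid plus the matching image indices
aligned_scan <- function(n, m, N, L) {
  i0 <- (N - n * m) / 2 + 1
  list(grid = scan_grid(n, step = m * L / N, L, offset = (i0 - 0.5) * L / N),
       idx = i0 + m * (0:(n - 1)))
}
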