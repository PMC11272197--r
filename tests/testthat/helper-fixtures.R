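# compact phantom specs used across tests: smaller grid, fewer slices
small_spec <- function(seed = 1L, n_slices = 2L, noise_sigma = 0.05,
                       bias = 0.15, n_blobs = 12L, spine = TRUE, ...) {
  phantom_spec(grid_shape = c(96L, 96L), n_slices = n_slices,
               pixel_spacing_mm = c(4.5, 4.5),
               vat_blob_params = list(n = n_blobs, r_mm = c(14, 28),
                                      z_mm = c(15, 50), margin_mm = 9),
               spine_params = if (spine)
                 list(body_mm = c(14, 16), pocket_r_mm = 4,
                      pocket_offset_mm = 26),
               noise_sigma = noise_sigma, bias_field_amplitude = bias,
               seed = seed, ...)
}

# a tiny synthetic stack with hand-placed masks, for volumetry arithmetic
toy_seg <- function(nr = 20, nc = 20, ns = 12, sat_vox_per_slice = 0,
                    vat_vox_per_slice = 0, spacing = c(2, 2), thick = 10) {
  sat <- array(0L, c(nr, nc, ns)); vat <- array(0L, c(nr, nc, ns))
  torso <- array(1L, c(nr, nc, ns))
  for (i in seq_len(ns)) {
    if (sat_vox_per_slice > 0) sat[, , i][seq_len(sat_vox_per_slice)] <- 1L
    if (vat_vox_per_slice > 0)
      vat[, , i][nr * nc - seq_len(vat_vox_per_slice) + 1L] <- 1L
  }
  geom <- image_stack(array(1, c(nr, nc, ns)), spacing, thick)
  adiposeg:::new_voxa_seg(sat, vat, array(0L, c(nr, nc, ns)), torso,
                          voxa_params(), geom)
}

rot90_mat <- function(m) t(m)[, nrow(m):1]
rot90_stack <- function(a) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1), c(d[2], d[1], d[3]))
  for (i in seq_len(d[3])) out[, , i] <- rot90_mat(a[, , i])
  out
}
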