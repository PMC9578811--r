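# Shared small fixtures, built in code at test time.

# phantom with widely separated, tight components: segmentation should
# recover the planted labels essentially perfectly
crisp_phantom_spec <- function(seed = 42L, grid = c(14L, 14L, 14L),
                               semi = c(5, 5, 5), sds = rep(0.1, 3),
                               noise = 0) {
  phantom_spec(grid_shape = grid, semi_axes = semi, n_subregions = 3L,
               subregion_means = c(1, 5, 9), subregion_sds = sds,
               noise_sd = noise, seed = seed)
}

# deterministic synthetic feature maps with a class-linked bright square
signal_map <- function(cls, size = 32L) {
  base <- array(runif(size * size * 3) * 0.2, c(size, size, 3L))
  if (cls == 1) {
    i <- seq(size %/% 4, 3 * size %/% 4)
    base[i, i, 1] <- base[i, i, 1] + 0.8
  }
  base
}
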