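test_that("constant images have zero detail and a constant LL subband", {
  sb <- dwt2(matrix(4, 8, 8), dwt_config())
  expect_lt(max(abs(sb$lh)), 1e-13)
  expect_lt(max(abs(sb$hl)), 1e-13)
  expect_lt(max(abs(sb$hh)), 1e-13)
  expect_equal(sb$ll, matrix(8, 4, 4), tolerance = 1e-12) # 2x the constant
})

test_that("the 2x2 all-ones image concentrates into a single LL coefficient", {
  sb <- dwt2(matrix(1, 2, 2), dwt_config())
  expect_equal(as.numeric(sb$ll), 2, tolerance = 1e-12)
  expect_lt(max(abs(c(sb$lh, sb$hl, sb$hh))), 1e-13)
})

test_that("perfect reconstruction and energy conservation hold", {
  set.seed(44)
  for (wav in c("haar", "db2")) {
    img <- matrix(rnorm(256), 16, 16)
    sb <- dwt2(img, dwt_config(wavelet = wav))
    expect_lt(max(abs(idwt2(sb) - img)), 1e-8)
    energy_in <- sum(img^2)
    energy_out <- sum(sb$ll^2) + sum(sb$lh^2) + sum(sb$hl^2) + sum(sb$hh^2)
    expect_equal(energy_out, energy_in, tolerance = 1e-6)
  }
  # odd dimensions: subbands are ceil(n/2) and reconstruction is still exact
  odd <- matrix(rnorm(15 * 17), 15, 17)
  sb <- dwt2(odd, dwt_config())
  expect_identical(dim(sb$ll), c(8L, 9L))
  expect_lt(max(abs(idwt2(sb) - odd)), 1e-8)
})

test_that("bad wavelet configurations are rejected", {
  expect_error(dwt_config(wavelet = "sym9"), "unknown wavelet")
  expect_error(dwt2(matrix(1, 1, 5), dwt_config()), "at least 2x2")
  expect_error(dwt_config(target_size = 4), "target_size")
})

test_that("slice selection policies and tie-breaking", {
  vox <- array(0, c(10, 10, 8))
  mask <- array(0L, c(10, 10, 8))
  mask[1:2, 1:5, 3] <- 1L  # area 10
  mask[1:5, 1:8, 4] <- 1L  # area 40
  mask[1:2, 1:5, 5] <- 1L  # area 10
  vox[] <- rnorm(length(vox))
  vol <- pet_volume(vox)
  rm <- roi_mask(mask)
  top <- select_slice(vol, rm, "max_roi_area")
  expect_length(top, 1L)
  expect_identical(attr(top[[1]], "slice"), 4L)
  expect_true(all(top[[1]][mask[, , 4] == 0] == 0)) # out-of-mask zeroed
  expect_length(select_slice(vol, rm, "all_roi_slices"), 3L)
  expect_identical(attr(select_slice(vol, rm, "central")[[1]], "slice"), 4)

  # symmetric two-way tie goes to the lower slice index
  tie <- array(0L, c(6, 6, 6))
  tie[1:3, 1:3, 2] <- 1L
  tie[1:3, 1:3, 5] <- 1L
  sel <- select_slice(pet_volume(array(1, c(6, 6, 6))), roi_mask(tie, min_voxels = 1),
                      "max_roi_area")
  expect_identical(attr(sel[[1]], "slice"), 2L)
})

test_that("feature maps are 3-channel, ordered (LL, LH, HL), and bounded", {
  set.seed(5)
  img <- matrix(runif(20 * 20), 20, 20)
  cfg <- dwt_config(target_size = 16L)
  fm <- assemble_feature_map(dwt2(img, cfg), cfg)
  expect_identical(dim(fm$channels), c(16L, 16L, 3L))
  expect_identical(dimnames(fm$channels)[[3]], c("LL", "LH", "HL"))
  expect_true(all(fm$channels >= 0 & fm$channels <= 1))
  # determinism
  fm2 <- assemble_feature_map(dwt2(img, cfg), cfg)
  expect_identical(fm$channels, fm2$channels)
})

test_that("constant slices map to an all-zero feature map", {
  cfg <- dwt_config(target_size = 8L)
  fm <- assemble_feature_map(dwt2(matrix(2, 16, 16), cfg), cfg)
  expect_true(all(fm$channels == 0))
})

test_that("resize is the identity when subbands already match the target", {
  set.seed(6)
  img <- matrix(runif(32 * 32), 32, 32)
  cfg <- dwt_config(target_size = 16L)
  sb <- dwt2(img, cfg)
  fm <- assemble_feature_map(sb, cfg)
  expect_identical(fm$channels[, , 1], petlnm:::minmax01(sb$ll))
})

test_that("detail energy concentrates at planted shell boundaries", {
  spec <- crisp_phantom_spec(seed = 23, sds = rep(0, 3), noise = 0)
  s <- generate_phantom(spec)
  lab_grid <- array(0L, dim(s$mask$mask))
  lab_grid[s$mask$mask == 1] <- s$planted_labels
  z <- which.max(apply(s$mask$mask, 3, sum))
  sl <- select_slice(s$volume, s$mask, "max_roi_area")[[1]]
  sb <- dwt2(sl, dwt_config())
  lz <- lab_grid[, , z]
  nb <- dim(sb$lh)
  detail <- abs(sb$lh) + abs(sb$hl)
  boundary <- matrix(FALSE, nb[1], nb[2])
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) {
    blk <- lz[(2 * i - 1):min(2 * i, nrow(lz)), (2 * j - 1):min(2 * j, ncol(lz))]
    boundary[i, j] <- length(unique(as.integer(blk))) > 1
  }
  inner <- !boundary & matrix(lz[cbind(2 * rep(seq_len(nb[1]), nb[2]) - 1,
                                       2 * rep(seq_len(nb[2]), each = nb[1]) - 1)] > 0,
                              nb[1], nb[2])
  expect_gt(mean(detail[boundary]), mean(detail[inner]))
})
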