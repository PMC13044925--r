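test_that("tomogram normalisation is exact, idempotent and invertible", {
  withr::with_seed(15, v <- array(rnorm(20^3, mean = 3, sd = 2), rep(20, 3)))
  nt <- normalize_tomogram(v)
  expect_lt(abs(mean(nt$v)), 1e-5)
  expect_lt(abs(sd(nt$v) - 1), 1e-5)
  nt2 <- normalize_tomogram(nt$v)
  expect_lt(max(abs(nt2$v - nt$v)), 1e-10)
  back <- denormalize_tomogram(nt$v, nt$stats)
  expect_lt(max(abs(back - v)) / max(abs(v)), 1e-5)
  expect_error(normalize_tomogram(array(1, c(4, 4, 4))), "variance")
})

test_that("the interest mask finds a high-variance central slab", {
  withr::with_seed(16, {
    v <- array(rnorm(32^3, sd = 0.2), rep(32, 3))
    v[, , 10:23] <- v[, , 10:23] + array(rnorm(32 * 32 * 14, sd = 2),
                                         c(32, 32, 14))
  })
  im <- build_interest_mask(v, z_fraction = 0.5, density_quantile = 0.3)
  truth <- array(FALSE, dim(v)); truth[, , 10:23] <- TRUE
  expect_gt(sum(im$mask & truth) / sum(im$mask), 0.95)
})

test_that("density_quantile = 0 keeps the whole slab and user masks bypass", {
  v <- array(rnorm(16^3), rep(16, 3))
  im <- build_interest_mask(v, z_fraction = 0.5, density_quantile = 0)
  keep <- round(0.5 * 16)
  z0 <- floor((16 - keep) / 2) + 1
  slab <- array(FALSE, rep(16, 3)); slab[, , z0:(z0 + keep - 1)] <- TRUE
  expect_identical(im$mask, slab)
  user <- array(TRUE, rep(16, 3))
  im2 <- build_interest_mask(v, mask = user)
  expect_identical(im2$mask, user)
  expect_identical(im2$source, "user-file")
})

test_that("patch centres are deterministic, inside the mask, and fully in bounds", {
  withr::with_seed(17, v <- array(rnorm(24^3), rep(24, 3)))
  im <- build_interest_mask(v, z_fraction = 0.8, density_quantile = 0.2)
  cc <- sample_patch_centers(im, 25, patch = 8, seed = 4)
  expect_identical(cc, sample_patch_centers(im, 25, patch = 8, seed = 4))
  expect_true(all(im$mask[cc]))
  expect_true(all(cc - 4 >= 1) && all(cc - 4 + 7 <= 24))
  expect_error(sample_patch_centers(im, 2, patch = 30), "fit")
})

test_that("paired extraction crops identical positions without resampling", {
  withr::with_seed(18, {
    v0 <- array(rnorm(20^3), rep(20, 3))
  })
  v1 <- v0 * 3 + 1
  pr <- extract_pair(v0, v1, center = c(10, 11, 9), patch = 8)
  expect_identical(dim(pr$y0), rep(8L, 3) + 0L)
  expect_identical(pr$y1, pr$y0 * 3 + 1)
  cst <- extract_pair(array(2, rep(20, 3)), array(2, rep(20, 3)),
                      c(10, 10, 10), 6)
  expect_true(all(cst$y0 == 2))
  expect_error(extract_pair(v0, v1, center = c(2, 10, 10), patch = 8), "bounds")
})

test_that("tiling plus blending of untouched patches is an exact partition of unity", {
  withr::with_seed(19, v <- array(rnorm(30 * 26 * 22), c(30, 26, 22)))
  g <- tile_for_inference(dim(v), patch = 12, overlap = 4)
  out <- blend_patches(extract_patches(v, g), g)
  expect_lt(max(abs(out - v)) / max(abs(v)), 1e-5)
  # accumulated weight field is one everywhere
  ones <- blend_patches(extract_patches(array(1, dim(v)), g), g)
  expect_lt(max(abs(ones - 1)), 1e-6)
})

test_that("randomised tilings always cover every voxel", {
  withr::with_seed(20, {
    for (trial in 1:12) {
      sh <- sample(13:40, 3, replace = TRUE)
      p <- sample(6:12, 1)
      ov <- sample(0:(p - 1), 1)
      g <- tile_for_inference(sh, p, ov)
      cov <- array(0L, sh)
      for (i in seq_len(nrow(g$corners))) {
        cr <- g$corners[i, ]
        cov[cr[1]:(cr[1] + p - 1), cr[2]:(cr[2] + p - 1),
            cr[3]:(cr[3] + p - 1)] <- 1L
      }
      expect_identical(sum(cov == 0L), 0L)
    }
  })
  expect_error(tile_for_inference(c(8, 8, 8), 12), "exceeds")
  expect_error(tile_for_inference(c(16, 16, 16), 8, overlap = 8), "overlap")
})

test_that("crop-then-wedge differs from wedge-then-crop on a random volume", {
  withr::with_seed(21, v <- array(rnorm(64^3), rep(64, 3)))
  m <- make_wedge_mask(rep(64, 3), tilt_scheme(-60, 60, 3))
  leak <- crop_commutator_leakage(v, m, corner = c(17, 17, 17), size = 32)
  expect_gt(leak, 0)
})
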