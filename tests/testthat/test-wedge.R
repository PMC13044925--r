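test_that("full angular coverage gives an all-ones mask", {
  m <- make_wedge_mask(c(8, 8, 8), tilt_scheme(-90, 90, 1))
  expect_true(all(m$mask == 1))
})

test_that("wedge fraction matches a brute-force per-voxel angle test at 32^3", {
  sc <- tilt_scheme(-60, 60, 3)
  m <- make_wedge_mask(c(32, 32, 32), sc)
  kx <- equitomo:::fft_freqs(32)
  miss <- 0
  for (ix in 1:32) for (iz in 1:32) {
    if (ix == 1 && iz == 1) next
    a <- atan2(kx[iz], kx[ix]) * 180 / pi
    if (a > 90) a <- a - 180
    if (a <= -90) a <- a + 180
    if (a < -60 || a > 60) miss <- miss + 1
  }
  expect_equal(mean(m$mask == 0), miss * 32 / 32^3)
})

test_that("mask is Hermitian-symmetric, ky-independent, observed at the origin", {
  for (n in c(16, 9)) {
    m <- make_wedge_mask(rep(n, 3), tilt_scheme(-55, 62, 2))$mask
    neg <- c(1, n:2)
    expect_identical(m, m[neg, neg, neg])
    expect_true(all(apply(m, c(1, 3), function(col) length(unique(col)) == 1)))
    expect_equal(m[1, 1, 1], 1)
  }
})

test_that("on-axis kz frequencies are missing whenever the tilt range is limited", {
  m <- make_wedge_mask(c(16, 16, 16), tilt_scheme(-60, 60, 2))$mask
  expect_true(all(m[1, , 2:16] == 0))   # (0, ky, kz != 0)
})

test_that("the projector A is idempotent, self-adjoint and energy non-increasing", {
  withr::with_seed(4, {
    v <- array(rnorm(16^3), c(16, 16, 16))
    u <- array(rnorm(16^3), c(16, 16, 16))
  })
  m <- make_wedge_mask(c(16, 16, 16), tilt_scheme(-60, 60, 3))
  av <- apply_wedge(v, m)
  expect_lt(max(abs(apply_wedge(av, m) - av)) / max(abs(av)), 1e-5)
  expect_lt(abs(sum(apply_wedge(u, m) * v) - sum(u * apply_wedge(v, m))) /
              abs(sum(u * apply_wedge(v, m))), 1e-5)
  expect_lte(sum(av^2), sum(v^2))
  # equality iff already supported on the observed region
  expect_lt(abs(sum(apply_wedge(av, m)^2) - sum(av^2)) / sum(av^2), 1e-10)
})

test_that("self-adjointness matches direct Fourier-coefficient masking on an 8^3 grid", {
  withr::with_seed(5, {
    u <- array(rnorm(8^3), c(8, 8, 8))
    w <- array(rnorm(8^3), c(8, 8, 8))
  })
  m <- make_wedge_mask(c(8, 8, 8), tilt_scheme(-50, 70, 5))
  # oracle: mask the coefficients explicitly and invert
  direct <- Re(fft(fft(u) * m$mask, inverse = TRUE)) / length(u)
  expect_equal(apply_wedge(u, m), direct, tolerance = 1e-12)
  expect_lt(abs(sum(direct * w) - sum(u * apply_wedge(w, m))) /
              abs(sum(u * apply_wedge(w, m))), 1e-10)
})

test_that("full-coverage mask makes A (and every A_g) the identity", {
  withr::with_seed(6, v <- array(rnorm(8^3), c(8, 8, 8)))
  m <- make_wedge_mask(c(8, 8, 8), tilt_scheme(-90, 90, 1))
  expect_lt(max(abs(apply_wedge(v, m) - v)) / max(abs(v)), 1e-5)
  for (g in build_group()$elements[c(1, 20, 40)])
    expect_lt(max(abs(apply_rotated_wedge(g, v, m) - v)) / max(abs(v)), 1e-5)
})

test_that("A_g equals R_g A R_g^-1 exhaustively over all 40 elements at 16^3", {
  withr::with_seed(7, v <- array(rnorm(16^3), c(16, 16, 16)))
  m <- make_wedge_mask(c(16, 16, 16), tilt_scheme(-60, 60, 3))
  scale <- max(abs(v))
  for (g in build_group()$elements) {
    direct <- apply_rotated_wedge(g, v, m)
    composed <- apply_transform(g, apply_wedge(
      apply_transform(group_inverse(g), v), m))
    expect_lt(max(abs(direct - composed)) / scale, 1e-5)
    # conjugated projectors stay idempotent
    expect_lt(max(abs(apply_rotated_wedge(g, direct, m) - direct)) / scale,
              1e-5)
  }
})

test_that("soft-edged masks interpolate between 0 and 1 only near the boundary", {
  hard <- make_wedge_mask(c(32, 32, 32), tilt_scheme(-60, 60, 3))
  soft <- make_wedge_mask(c(32, 32, 32), tilt_scheme(-60, 60, 3), rolloff = 10)
  expect_true(all(soft$mask >= 0 & soft$mask <= 1))
  expect_true(any(soft$mask > 0 & soft$mask < 1))
  expect_true(all(soft$mask[hard$mask == 1] == 1))
})

test_that("crop/wedge commutator leakage is strictly positive", {
  withr::with_seed(8, v <- array(rnorm(32^3), c(32, 32, 32)))
  m <- make_wedge_mask(c(32, 32, 32), tilt_scheme(-60, 60, 3))
  leak <- crop_commutator_leakage(v, m, corner = c(9, 9, 9), size = 16)
  expect_gt(leak, 0)
})
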