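test_that("the zero-tilt projection is the sum over z", {
  v <- smooth_phantom(32)
  ts <- project(v, tilt_scheme(-30, 30, 30))
  zsum <- apply(v, c(1, 2), sum)
  i0 <- which(ts$angles == 0)
  expect_lt(max(abs(ts$projections[, , i0] - zsum)) / max(abs(zsum)), 1e-3)
})

test_that("a centred spherical phantom projects identically at every angle", {
  n <- 32
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  ctr <- floor(n / 2) + 1                     # the rotation centre voxel
  v <- array(exp(-rowSums(sweep(co, 2, rep(ctr, 3))^2) / (2 * 9)), rep(n, 3))
  pr <- project(v, tilt_scheme(-60, 60, 30))$projections
  for (i in 2:dim(pr)[3])
    expect_lt(max(abs(pr[, , i] - pr[, , 1])) / max(pr), 1e-3)
})

test_that("projections match the exact central-slice oracle at an oblique angle", {
  n <- 16
  v <- smooth_phantom(n, centers = matrix(c(0.5, 0.45, 0.55) * n, 1),
                      sigmas = 2, weights = 1)
  th <- 30 * pi / 180
  ctr <- floor(n / 2) + 1
  xs <- (1:n) - ctr
  kp <- equitomo:::fft_freqs(n)
  # exact discrete central slice by direct (centred) DFT
  P <- matrix(0i, n, n)
  for (a in 1:n) {
    fx <- kp[a] * cos(th); fz <- kp[a] * sin(th)
    pz <- exp(-2i * pi * fz * xs / n)
    vz <- matrix(0i, n, n)
    for (z in 1:n) vz <- vz + v[, , z] * pz[z]
    row <- colSums(vz * exp(-2i * pi * fx * xs / n))
    P[a, ] <- vapply(kp, function(kq)
      sum(row * exp(-2i * pi * kq * xs / n)), 0i)
  }
  pex <- equitomo:::fsh(array(Re(fft(P, inverse = TRUE)) / n^2, c(n, n, 1)),
                        axes = 1:2)[, , 1]
  got <- project(v, tilt_scheme(-60, 60, 90))$projections[, , 2]
  expect_lt(max(abs(got - pex)) / max(abs(pex)), 0.02)
})

test_that("fbp of a dense full-range series recovers a smooth phantom", {
  v <- smooth_phantom(32)
  r <- fbp(project(v, tilt_scheme(-90, 89, 1)), c(32, 32, 32))
  nrmse <- sqrt(mean((r - v)^2)) / sqrt(mean(v^2))
  expect_lt(nrmse, 0.05)
})

test_that("fbp leaves the missing-wedge interior empty for a limited scheme", {
  v <- smooth_phantom(32)
  sc <- tilt_scheme(-60, 60, 3)
  r <- fbp(project(v, sc), c(32, 32, 32))
  Fr <- Mod(fft(r))^2
  m2d <- 1 - make_wedge_mask(c(32, 32, 32), sc)$mask[, 1, ]
  # erode the missing region by the 2-voxel gridding-kernel boundary shell
  n <- 32
  er <- m2d
  for (k in 1:2) {
    e <- er
    for (dx in -1:1) for (dz in -1:1)
      e <- e * er[((seq_len(n) - 1 - dx) %% n) + 1,
                  ((seq_len(n) - 1 - dz) %% n) + 1]
    er <- e
  }
  interior <- aperm(array(rep(er, n), c(n, n, n)), c(1, 3, 2))
  expect_lt(sum(Fr * interior) / sum(Fr), 1e-3)
})

test_that("project and fbp are linear and fbp of zeros is zero", {
  v1 <- smooth_phantom(16)
  withr::with_seed(9, v2 <- array(rnorm(16^3, sd = 0.1), rep(16, 3)))
  sc <- tilt_scheme(-60, 60, 10)
  p1 <- project(v1, sc); p2 <- project(v2, sc)
  p12 <- project(v1 + 2 * v2, sc)
  expect_lt(max(abs(p12$projections - p1$projections - 2 * p2$projections)) /
              max(abs(p12$projections)), 1e-5)
  r1 <- fbp(p1, rep(16, 3)); r2 <- fbp(p2, rep(16, 3))
  r12 <- fbp(tilt_series(p1$projections + 2 * p2$projections, sc$angles),
             rep(16, 3))
  expect_lt(max(abs(r12 - r1 - 2 * r2)) / max(abs(r12)), 1e-5)
  z <- fbp(tilt_series(array(0, c(16, 16, 3)), c(-30, 0, 30)), rep(16, 3))
  expect_identical(unique(as.vector(z)), 0)
})

test_that("gaussian noise has the requested scale and is seed-reproducible", {
  p <- array(0, c(100, 100, 100))   # 1e6 samples
  ts <- tilt_series(p, seq(-49.5, 49.5, 1))
  nm <- noise_model("gaussian", sigma = 0.7, seed = 42)
  n1 <- add_noise(ts, nm)
  expect_lt(abs(sd(n1$projections - p) / 0.7 - 1), 0.01)
  expect_identical(add_noise(ts, nm)$projections, n1$projections)
  # different seeds decorrelate
  n2 <- add_noise(ts, noise_model("gaussian", sigma = 0.7, seed = 43))
  expect_lt(abs(cor(as.vector(n1$projections), as.vector(n2$projections))),
            0.01)
  # degenerate noise
  expect_identical(add_noise(ts, noise_model("gaussian", sigma = 0))$projections, p)
})

test_that("poisson-gaussian noise adds shot noise scaling with the gain", {
  withr::with_seed(44, p <- array(abs(rnorm(50 * 50 * 20)) + 1, c(50, 50, 20)))
  ts <- tilt_series(p, seq_len(20))
  lo <- add_noise(ts, noise_model("poisson-gaussian", sigma = 0, gain = 5, seed = 1))
  hi <- add_noise(ts, noise_model("poisson-gaussian", sigma = 0, gain = 500, seed = 1))
  expect_gt(sd(lo$projections - p), sd(hi$projections - p))
  expect_error(add_noise(ts, structure(list(kind = "salt"), class = "noise_model")))
})

test_that("dose splitting averages the assigned frames per tilt", {
  withr::with_seed(10, fr <- array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3)))
  ts <- tilt_series(fr, c(-10, 0, 10))
  s <- split_scheme("dose", split0 = c(1, 2), split1 = c(3, 4))
  halves <- make_split_pair(ts, s)
  expect_equal(halves[[1]]$projections,
               (fr[, , 1, ] + fr[, , 2, ]) / 2)
  expect_equal(halves[[2]]$projections,
               (fr[, , 3, ] + fr[, , 4, ]) / 2)
  expect_identical(halves[[1]]$angles, ts$angles)
})

test_that("angle splitting partitions 66 tilts into 33 + 33 by parity", {
  angles <- seq(-65, 65, 2)
  expect_length(angles, 66)
  p <- array(rnorm(4 * 4 * 66), c(4, 4, 66))
  halves <- make_split_pair(tilt_series(p, angles), split_scheme("angle"))
  expect_length(halves[[1]]$angles, 33)
  expect_length(halves[[2]]$angles, 33)
  expect_identical(halves[[1]]$angles, angles[seq(1, 66, 2)])
  expect_length(intersect(halves[[1]]$angles, halves[[2]]$angles), 0)
})

test_that("excluding frames 9 and 10 of a 10-frame stack leaves two 4-frame splits", {
  withr::with_seed(11, fr <- array(rnorm(6 * 6 * 10 * 2), c(6, 6, 10, 2)))
  ts <- tilt_series(fr, c(0, 2))
  s <- split_scheme("dose", split0 = c(1, 3, 5, 7), split1 = c(2, 4, 6, 8),
                    excluded_frames = c(9, 10))
  halves <- make_split_pair(ts, s)
  expect_equal(halves[[1]]$projections, apply(fr[, , c(1, 3, 5, 7), ], c(1, 2, 4), mean))
  # overlapping assignment is rejected
  expect_error(split_scheme("dose", split0 = 1:3, split1 = 3:4), "overlap")
  # excluded frames may not be assigned
  expect_error(split_scheme("dose", split0 = 1:2, split1 = 3:4,
                            excluded_frames = 4), "excluded")
})

test_that("dose splits of a noise-free series are identical to each other and the full average", {
  withr::with_seed(12, base <- array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  # four identical frames per tilt
  fr <- aperm(array(rep(base, times = 4), c(8, 8, 3, 4)), c(1, 2, 4, 3))
  ts <- tilt_series(fr, c(-10, 0, 10))
  halves <- make_split_pair(ts, split_scheme("dose", split0 = 1:2, split1 = 3:4))
  expect_equal(halves[[1]]$projections, halves[[2]]$projections)
  expect_equal(halves[[1]]$projections, base)
})

test_that("slice sampling and its matched-weight backinsertion are exact adjoints", {
  # the gather (project) and scatter (fbp insertion) share one geometry
  # table; <gather(V), P> must equal <V, scatter(P)> exactly
  n <- 16; n2 <- 32
  geo <- equitomo:::slice_geometry(n, 23)
  withr::with_seed(14, {
    V <- matrix(complex(real = rnorm(n2 * n2), imaginary = rnorm(n2 * n2)),
                n2 * n2, 1)
    P <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)), n, 1)
  })
  rows_all <- geo$ix + n2 * (geo$iz - 1L)
  gather <- rep(0i, n)
  for (c in seq_len(geo$ncorner))
    gather <- gather + geo$w[, c] * V[rows_all[, c]]
  scatter <- rep(0i, n2 * n2)
  for (c in seq_len(geo$ncorner)) {
    re <- rowsum(geo$w[, c] * Re(P), rows_all[, c])
    im <- rowsum(geo$w[, c] * Im(P), rows_all[, c])
    r <- as.integer(rownames(re))
    scatter[r] <- scatter[r] + complex(real = re, imaginary = im)
  }
  lhs <- sum(Re(gather * Conj(P)))
  rhs <- sum(Re(V * Conj(scatter)))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
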