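test_that("the data-fidelity loss vanishes for identical observations under identity", {
  withr::with_seed(27, y <- array(rnorm(8^3), rep(8, 3)))
  pair <- list(y0 = y, y1 = y)
  expect_identical(n2n_loss(identity_predictor, pair), 0)
})

test_that("the symmetrised losses are exactly swap-invariant", {
  withr::with_seed(28, {
    p <- list(y0 = array(rnorm(8^3), rep(8, 3)),
              y1 = array(rnorm(8^3), rep(8, 3)))
  })
  ps <- list(y0 = p$y1, y1 = p$y0)
  f <- function(v) v * 0.6 + 0.1
  expect_identical(n2n_loss(f, p), n2n_loss(f, ps))
  g <- build_group()$elements[[17]]
  m <- make_wedge_mask(rep(8, 3), tilt_scheme(-60, 60, 3))
  expect_identical(equivariance_loss(f, p, g, m), equivariance_loss(f, ps, g, m))
})

test_that("Monte-Carlo: the self-supervised objective equals the supervised one plus the noise variance", {
  # scalar model: y_i = x + noise; for any predictor independent of y1,
  # E(f(y0) - y1)^2 = E(f(y0) - x)^2 + sigma^2
  nmc <- 1e5
  sigma <- 0.8
  withr::with_seed(29, {
    x <- rnorm(nmc, sd = 1.5)
    y0 <- x + rnorm(nmc, sd = sigma)
    y1 <- x + rnorm(nmc, sd = sigma)
  })
  f <- 0.5 * y0 + 0.2                     # a fixed affine denoiser
  lhs <- mean((f - y1)^2)
  rhs <- mean((f - x)^2) + sigma^2
  expect_lt(abs(lhs - rhs) / rhs, 0.02)
  # and the loss-minimising constant is the target mean
  cgrid <- seq(-1, 1, 0.01)
  risks <- vapply(cgrid, function(c0) mean((c0 - y1)^2), 0)
  expect_lt(abs(cgrid[which.min(risks)] - mean(y1)), 0.02)
})

test_that("the data-fidelity loss only sees observed-wedge content", {
  sc <- tilt_scheme(-60, 60, 3)
  m <- make_wedge_mask(rep(16, 3), sc)
  withr::with_seed(30, {
    base0 <- array(rnorm(16^3), rep(16, 3))
    base1 <- array(rnorm(16^3), rep(16, 3))
    pert <- array(rnorm(16^3), rep(16, 3))
  })
  wedge_only <- pert - apply_wedge(pert, m)    # supported inside the wedge
  pair_a <- list(y0 = apply_wedge(base0, m), y1 = apply_wedge(base1, m))
  pair_b <- list(y0 = pair_a$y0, y1 = apply_wedge(base1 + wedge_only, m))
  f <- function(v) 0.7 * v
  la <- n2n_loss(f, pair_a); lb <- n2n_loss(f, pair_b)
  expect_lt(abs(la - lb) / la, 1e-4)
})

test_that("identity + invariant patch + full coverage zeroes the equivariance loss", {
  n <- 16
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  sph <- array(exp(-rowSums(sweep(co, 2, rep(ctr, 3))^2) / 18), rep(n, 3))
  pair <- list(y0 = sph, y1 = sph)
  mfull <- make_wedge_mask(rep(n, 3), tilt_scheme(-90, 90, 1))
  for (g in build_group()$elements[c(4, 18, 33)])
    expect_lt(equivariance_loss(identity_predictor, pair, g, mfull), 1e-10)
})

test_that("identity + wedge corruption + asymmetric patch gives a positive loss", {
  withr::with_seed(31, raw <- generate_phantom(phantom_spec(rep(48, 3), seed = 13)))
  sc <- tilt_scheme(-60, 60, 3)
  m <- make_wedge_mask(rep(48, 3), sc)
  y <- apply_wedge(raw, m)
  g <- build_group()$elements[[7]]
  expect_gt(equivariance_loss(identity_predictor, list(y0 = y, y1 = y), g, m),
            1e-4)
})

test_that("disabling the wedge masking reduces to the plain equivariant-imaging residual", {
  withr::with_seed(32, {
    p <- list(y0 = array(rnorm(16^3), rep(16, 3)),
              y1 = array(rnorm(16^3), rep(16, 3)))
  })
  m <- make_wedge_mask(rep(16, 3), tilt_scheme(-60, 60, 3))
  g <- build_group()$elements[[29]]
  f <- function(v) 0.8 * v + 0.05
  cfg <- loss_config(mask_original_wedge = FALSE, swap_augment = FALSE)
  got <- equivariance_loss(f, p, g, m, cfg)
  # plain equivariant-imaging form, coded independently
  xs <- f(p$y0); xt <- f(p$y1)
  want <- mean((f(apply_wedge(apply_transform(g, xs), m)) -
                  apply_transform(g, xt))^2)
  expect_equal(got, want, tolerance = 1e-12)
  # the masked default differs
  expect_false(isTRUE(all.equal(
    equivariance_loss(f, p, g, m, loss_config(swap_augment = FALSE)), want)))
})

test_that("the total objective is data term plus lambda times equivariance", {
  withr::with_seed(33, {
    p <- list(y0 = array(rnorm(8^3), rep(8, 3)),
              y1 = array(rnorm(8^3), rep(8, 3)))
  })
  m <- make_wedge_mask(rep(8, 3), tilt_scheme(-60, 60, 3))
  g <- build_group()$elements[[11]]
  f <- function(v) 0.9 * v
  l0 <- total_loss(f, p, g, m, loss_config(lambda = 1e-12))
  expect_equal(l0, n2n_loss(f, p), tolerance = 1e-6)
  lt <- total_loss(f, p, g, m, loss_config(lambda = 2))
  expect_equal(lt, n2n_loss(f, p) + 2 * equivariance_loss(f, p, g, m))
  expect_gte(lt, n2n_loss(f, p))
  expect_equal(formals(loss_config)$lambda, 2)
})

test_that("gradients flow through both network applications of the equivariance term", {
  net <- build_network(network_spec(depth = 2, base_channels = 2,
                                    precision = "double", seed = 6))
  withr::with_seed(34, {
    p0 <- array(rnorm(8^3), rep(8, 3))
    p1 <- array(rnorm(8^3), rep(8, 3))
  })
  G <- build_group()
  pm <- make_wedge_mask(rep(8, 3), tilt_scheme(-60, 60, 3))
  masks <- list(m = pm$mask, rotated = lapply(G$elements, function(g)
    rotate_wedge_mask(pm, g)$mask))
  attached <- equitomo:::example_grad(net, p0, p1, 9, G, masks,
                                      loss_config(lambda = 2))
  detached <- equitomo:::example_grad(net, p0, p1, 9, G, masks,
                                      loss_config(lambda = 2, detach_plugin = TRUE))
  expect_true(any(attached$grad != 0))
  # the plug-in path carries gradient: detaching changes the result
  expect_gt(max(abs(attached$grad - detached$grad)), 0)
})

test_that("two trainings with one seed produce matching loss histories", {
  pd <- tiny_paired(n = 24, seed = 4)
  sc <- pd$provenance$scheme
  tcfg <- train_config(patch_size = 16, batch_size = 2, max_iterations = 12,
                       learning_rate = 1e-3, seed = 77)
  spec <- network_spec(depth = 2, base_channels = 2, seed = 77)
  h1 <- train(list(pd), sc, tcfg, loss_config(), spec = spec)$history
  h2 <- train(list(pd), sc, tcfg, loss_config(), spec = spec)$history
  expect_equal(h1$total, h2$total, tolerance = 1e-4)
  expect_identical(nrow(h1), 12L)
})

test_that("training reduces the loss and aborts cleanly on divergence", {
  pd <- tiny_paired(n = 24, seed = 5)
  sc <- pd$provenance$scheme
  tr <- train(list(pd), sc,
              train_config(patch_size = 16, batch_size = 2,
                           max_iterations = 40, learning_rate = 3e-3,
                           seed = 3),
              loss_config(), spec = network_spec(depth = 2, base_channels = 3,
                                                 seed = 3))
  h <- tr$history$total
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
  expect_error(train(list(), sc), "empty")
  expect_error(
    train(list(pd), sc,
          train_config(patch_size = 16, batch_size = 1, max_iterations = 8,
                       learning_rate = 1e18, seed = 3),
          loss_config(),
          spec = network_spec(depth = 2, base_channels = 2, seed = 3)),
    "non-finite")
})

test_that("fine-tuning with zero iterations returns the pretrained network unchanged", {
  net <- build_network(network_spec(depth = 2, base_channels = 2, seed = 8))
  ft <- finetune(net, list(), tilt_scheme(-60, 60, 3),
                 train_config(max_iterations = 0))
  expect_identical(ft$network$params, net$params)
  expect_identical(nrow(ft$history), 0L)
  # protocol defaults: 50000 training iterations, 5000 for fine-tuning
  expect_equal(formals(train_config)$max_iterations, 50000)
  ft_default <- eval(formals(finetune)$tcfg)
  expect_equal(ft_default$max_iterations, 5000L)
})
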