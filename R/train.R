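# Training loop: stochastic minimisation of the combined objective with
# Adam, per-example group sampling, random observation swap, and
# warm-start fine-tuning.

# Flatten nested parameter lists to a vector and back (dims preserved).
flatten_params <- function(p) unlist(p, use.names = FALSE)
unflatten_params <- function(vec, skeleton) {
  pos <- 0
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- vec[(pos + 1):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(x)
    out
  }
  fill(skeleton)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mh / (sqrt(vh) + eps))
}

#' Training configuration
#'
#' @param patch_size cubic patch edge (default 72).
#' @param batch_size examples per iteration (default 8).
#' @param max_iterations stopping point (default 50000); training always
#'   runs a fixed budget unless a `plateau` rule is supplied.
#' @param learning_rate Adam step size (default 4e-4).
#' @param mixed_precision run the convolution arithmetic in single
#'   precision (the CPU analogue of half-precision network compute on
#'   GPUs); FFT-based operators always run in double precision.
#' @param seed seed for patch, group and swap sampling.
#' @param checkpoint_every write a checkpoint every this many iterations
#'   (NULL = only at the end, and only when `checkpoint_dir` is set).
#' @param checkpoint_dir directory for periodic checkpoints.
#' @param plateau optional early-stopping rule `list(window, tol)`: stop
#'   when the moving-average total loss over `window` iterations
#'   improves by less than `tol` (relative); off by default.
#' @return A `train_config`.
#' @export
train_config <- function(patch_size = 72, batch_size = 8,
                         max_iterations = 50000, learning_rate = 4e-4,
                         mixed_precision = TRUE, seed = 1,
                         checkpoint_every = NULL, checkpoint_dir = NULL,
                         plateau = NULL) {
  stopifnot(patch_size >= 4, batch_size >= 1, max_iterations >= 0,
            learning_rate > 0)
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 learning_rate = learning_rate,
                 mixed_precision = isTRUE(mixed_precision),
                 seed = as.integer(seed),
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir, plateau = plateau),
            class = "train_config")
}

# Loss and parameter gradient for one example. `masks` carries the patch
# wedge mask array and the list of 40 rotated mask arrays.
example_grad <- function(net, p0, p1, g_index, group, masks, lcfg) {
  n <- length(p0)
  fw0 <- network_forward(net, p0, keep = TRUE)
  fw1 <- network_forward(net, p1, keep = TRUE)
  l_dc <- (mean((fw0$y - p1)^2) + mean((fw1$y - p0)^2)) / 2
  dt <- (fw0$y - p1) / n
  ds <- (fw1$y - p0) / n
  g <- group$elements[[g_index]]
  u <- apply_wedge(apply_transform(g, fw0$y), masks$m)
  fw2 <- network_forward(net, u, keep = TRUE)
  r <- fw2$y - apply_transform(g, fw1$y)
  rm <- if (lcfg$mask_original_wedge)
    Re(fft(fft(r) * masks$rotated[[g_index]], inverse = TRUE)) / n else r
  l_eq <- mean(rm^2)
  dvv <- (2 * lcfg$lambda / n) * rm
  bk2 <- network_backward(net, fw2$cache, dvv, need_dx = TRUE)
  du_m <- Re(fft(fft(bk2$dx) * masks$m, inverse = TRUE)) / n
  gi <- group_inverse(g)
  dt <- dt + apply_transform(gi, du_m)
  if (!lcfg$detach_plugin)
    ds <- ds - (2 * lcfg$lambda / n) * apply_transform(gi, rm)
  bk0 <- network_backward(net, fw0$cache, dt, need_dx = FALSE)
  bk1 <- network_backward(net, fw1$cache, ds, need_dx = FALSE)
  list(l_dc = l_dc, l_eq = l_eq,
       grad = flatten_params(bk2$grads) + flatten_params(bk0$grads) +
         flatten_params(bk1$grads))
}

prepare_training_volumes <- function(dataset, masks, patch) {
  lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    if (!all(dim(d$y0) == dim(d$y1)))
      stop("paired volumes must share a shape", call. = FALSE)
    both <- c(d$y0, d$y1)
    st <- c(mean = mean(both), sd = sd(both))
    if (st[["sd"]] == 0) stop("zero-variance training volume", call. = FALSE)
    mk <- if (!is.null(masks)) {
      if (inherits(masks[[i]], "interest_mask")) masks[[i]]$mask else masks[[i]]
    } else array(TRUE, dim(d$y0))
    dd <- dim(d$y0)
    lo <- rep(floor(patch / 2) + 1, 3)
    hi <- dd - (patch - floor(patch / 2) - 1)
    if (any(hi < lo))
      stop(sprintf("patch %d does not fit in volume %s", patch,
                   paste(dd, collapse = "x")), call. = FALSE)
    feas <- array(FALSE, dd)
    feas[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    ok <- which(mk & feas)
    if (length(ok) == 0)
      stop("no feasible patch centres for volume ", i, call. = FALSE)
    list(y0 = (d$y0 - st[["mean"]]) / st[["sd"]],
         y1 = (d$y1 - st[["mean"]]) / st[["sd"]],
         stats = st, centers = ok, dim = dd)
  })
}

idx_to_coord <- function(idx, d) {
  cbind((idx - 1) %% d[1],
        ((idx - 1) %/% d[1]) %% d[2],
        (idx - 1) %/% (d[1] * d[2])) + 1L
}

#' Train the denoising network
#'
#' Minimises the combined Noise2Noise + equivariance objective by
#' stochastic gradient steps with Adam. Each iteration samples, per
#' batch example: a source tomogram, a patch centre inside its interest
#' mask, a group element (uniform over the 40), and a random assignment
#' of the two observations to source/target roles. Gradients flow
#' through both network applications of the equivariance term unless
#' `lcfg$detach_plugin` is set. Deterministic given the seeds.
#'
#' @param dataset list of paired observations (each with `y0`, `y1`
#'   volumes of equal shape); multiple tomograms train a single shared
#'   network.
#' @param scheme the [tilt_scheme()] whose missing wedge corrupts the
#'   data (used to build the patch-level projector).
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @param net optional starting `et_network` (used by [finetune()]);
#'   by default a fresh network from `spec` is built.
#' @param spec a [network_spec()] for the fresh network.
#' @param masks optional list of interest masks (one per dataset entry).
#' @return An `et_training`: `network`, `history` (per-iteration data
#'   frame with the loss terms), `config`.
#' @export
train <- function(dataset, scheme, tcfg = train_config(),
                  lcfg = loss_config(), net = NULL,
                  spec = network_spec(), masks = NULL) {
  if (length(dataset) == 0) stop("empty dataset", call. = FALSE)
  if (is.null(net)) {
    spec$precision <- if (tcfg$mixed_precision) "single" else "double"
    net <- build_network(spec)
  }
  check_patch(tcfg$patch_size, net$spec$depth)
  vols <- prepare_training_volumes(dataset, masks, tcfg$patch_size)
  pm <- make_wedge_mask(rep(tcfg$patch_size, 3), scheme)
  masks_all <- list(m = pm$mask,
                    rotated = lapply(build_group()$elements, function(g)
                      rotate_wedge_mask(pm, g)$mask))
  group <- build_group()
  theta <- flatten_params(net$params)
  opt <- adam_init(length(theta))
  hist <- matrix(NA_real_, tcfg$max_iterations, 3,
                 dimnames = list(NULL, c("n2n", "equi", "total")))
  withr::with_seed(tcfg$seed, {
    for (it in seq_len(tcfg$max_iterations)) {
      gsum <- 0; ldc <- 0; leq <- 0
      for (b in seq_len(tcfg$batch_size)) {
        vi <- sample.int(length(vols), 1)
        v <- vols[[vi]]
        ctr <- as.integer(idx_to_coord(v$centers[sample.int(length(v$centers), 1)], v$dim))
        gidx <- sample.int(length(group$elements), 1)
        swap <- lcfg$swap_augment && runif(1) < 0.5
        p0 <- crop_patch(if (swap) v$y1 else v$y0, ctr, tcfg$patch_size)
        p1 <- crop_patch(if (swap) v$y0 else v$y1, ctr, tcfg$patch_size)
        eg <- example_grad(net, p0, p1, gidx, group, masks_all, lcfg)
        gsum <- gsum + eg$grad
        ldc <- ldc + eg$l_dc; leq <- leq + eg$l_eq
      }
      ldc <- ldc / tcfg$batch_size; leq <- leq / tcfg$batch_size
      tot <- ldc + lcfg$lambda * leq
      if (!is.finite(tot))
        stop(sprintf("non-finite loss at iteration %d (n2n = %g, equi = %g); aborting",
                     it, ldc, leq), call. = FALSE)
      hist[it, ] <- c(ldc, leq, tot)
      st <- adam_step(opt, theta, gsum / tcfg$batch_size, tcfg$learning_rate)
      opt <- st$state; theta <- st$theta
      net$params <- unflatten_params(theta, net$params)
      net$iteration <- net$iteration + 1L
      if (!is.null(tcfg$checkpoint_every) && !is.null(tcfg$checkpoint_dir) &&
          it %% tcfg$checkpoint_every == 0)
        save_checkpoint(net, file.path(tcfg$checkpoint_dir,
                                       sprintf("checkpoint_%06d.rds", net$iteration)))
      if (!is.null(tcfg$plateau) && it >= 2 * tcfg$plateau$window) {
        w <- tcfg$plateau$window
        recent <- mean(hist[(it - w + 1):it, "total"])
        prev <- mean(hist[(it - 2 * w + 1):(it - w), "total"])
        if (prev - recent < tcfg$plateau$tol * prev) break
      }
    }
  })
  hist <- as.data.frame(hist[!is.na(hist[, 1]), , drop = FALSE])
  hist$iteration <- seq_len(nrow(hist))
  structure(list(network = net, history = hist,
                 config = list(train = tcfg, loss = lcfg)),
            class = "et_training")
}

#' @export
print.et_training <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<training run: %d iterations, final total loss %.4g>\n",
              n, x$history$total[n]))
  invisible(x)
}

#' Fine-tune a pretrained network
#'
#' Identical loop to [train()] but warm-started from an existing
#' network (or checkpoint path); the default budget is 5000 iterations,
#' an order of magnitude below from-scratch training.
#'
#' @param pretrained an `et_network` or checkpoint path.
#' @param dataset,scheme,tcfg,lcfg,masks as in [train()].
#' @return An `et_training`.
#' @export
finetune <- function(pretrained, dataset, scheme,
                     tcfg = train_config(max_iterations = 5000),
                     lcfg = loss_config(), masks = NULL) {
  net <- if (is.character(pretrained)) load_checkpoint(pretrained) else pretrained
  stopifnot(inherits(net, "et_network"))
  if (tcfg$max_iterations == 0)
    return(structure(list(network = net,
                          history = data.frame(n2n = numeric(), equi = numeric(),
                                               total = numeric(), iteration = integer()),
                          config = list(train = tcfg, loss = lcfg)),
                     class = "et_training"))
  train(dataset, scheme, tcfg, lcfg, net = net, masks = masks)
}
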