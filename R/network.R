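# The shape-preserving 3D denoising network f: a compact residual U-Net
# (3^3 convolutions, average-pool down, nearest-neighbour up, additive
# skips, 1x1x1 output head). Forward, backward (hand-derived) and
# checkpointing. The network is deliberately pluggable: the training
# objective is architecture-agnostic, and any callable that maps a patch
# to a same-shaped patch can stand in for it in the loss functions.

#' Specify the denoising network
#'
#' @param depth number of resolution levels (>= 1); level l works at
#'   1/2^(l-1) resolution with `base_channels * 2^(l-1)` channels.
#' @param base_channels channels at full resolution.
#' @param activation `"leaky_relu"` (slope 0.1) or `"relu"`.
#' @param normalization `"none"` (the compact network trains stably
#'   without normalisation layers; no other scheme is implemented).
#' @param residual add the input to the output (learn a correction).
#' @param precision `"single"` (default) or `"double"` compute for the
#'   convolution kernels.
#' @param seed parameter initialisation seed.
#' @return A `network_spec`.
#' @export
network_spec <- function(depth = 3, base_channels = 16,
                         activation = c("leaky_relu", "relu"),
                         normalization = "none", residual = TRUE,
                         precision = c("single", "double"), seed = 1) {
  activation <- match.arg(activation)
  precision <- match.arg(precision)
  normalization <- match.arg(normalization, "none")
  stopifnot(depth >= 1, base_channels >= 1)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 activation = activation, normalization = normalization,
                 residual = isTRUE(residual), precision = precision,
                 seed = as.integer(seed)),
            class = "network_spec")
}

spec_channels <- function(spec) spec$base_channels * 2^(seq_len(spec$depth) - 1)

he_init <- function(d, fan_in) array(rnorm(prod(d), sd = sqrt(2 / fan_in)), d)

#' Build (initialise) a network
#'
#' Parameters are drawn deterministically from the spec's seed (He
#' initialisation); two builds from the same spec are identical.
#'
#' @param spec a [network_spec()].
#' @return An `et_network` (spec, parameters, iteration counter).
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  ch <- spec_channels(spec)
  params <- withr::with_seed(spec$seed, {
    p <- list(conv_in = list(W = he_init(c(3, 3, 3, 1, ch[1]), 27),
                             b = numeric(ch[1])))
    if (spec$depth > 1) {
      p$enc <- lapply(2:spec$depth, function(l) list(
        a = list(W = he_init(c(3, 3, 3, ch[l - 1], ch[l]), 27 * ch[l - 1]),
                 b = numeric(ch[l])),
        b = list(W = he_init(c(3, 3, 3, ch[l], ch[l]), 27 * ch[l]),
                 b = numeric(ch[l]))))
      p$dec <- lapply(2:spec$depth, function(l) list(
        W = he_init(c(3, 3, 3, ch[l], ch[l - 1]), 27 * ch[l]),
        b = numeric(ch[l - 1])))
    }
    p$head <- list(W = he_init(c(ch[1], 1), ch[1]), b = 0)
    p
  })
  structure(list(spec = spec, params = params, iteration = 0L),
            class = "et_network")
}

#' @export
print.et_network <- function(x, ...) {
  np <- length(unlist(x$params))
  cat(sprintf(
    "<network: depth %d, base %d channels, %s, %s precision, %d parameters, iteration %d>\n",
    x$spec$depth, x$spec$base_channels, x$spec$activation,
    x$spec$precision, np, x$iteration))
  invisible(x)
}

act_code <- function(kind) if (kind == "relu") 1L else 2L

check_patch <- function(n, depth) {
  if (n %% 2^(depth - 1) != 0)
    stop(sprintf("patch size %d is not divisible by 2^(depth-1) = %d",
                 n, 2^(depth - 1)), call. = FALSE)
}

conv_dims <- function(x, W) as.integer(c(dim(x)[1:3], dim(W)[4], dim(W)[5]))

# Forward pass; returns the output volume and, when `keep` is TRUE, the
# cache of conv inputs and pre-activations needed by network_backward().
network_forward <- function(net, v, keep = FALSE) {
  spec <- net$spec; p <- net$params
  single <- spec$precision == "single"
  d <- dim(v)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("network input must be a cubic 3D array", call. = FALSE)
  check_patch(d[1], spec$depth)
  acode <- act_code(spec$activation)
  cache <- if (keep) list(conv = list(), out = list(), col = list()) else NULL
  cv <- function(x, layer, name) {
    r <- .conv3_fwd(x, layer$W, layer$b, conv_dims(x, layer$W), single, acode,
                    keep)
    if (keep) {
      cache$conv[[name]] <<- x; cache$out[[name]] <<- r$y
      cache$col[[name]] <<- r$col
    }
    r$y
  }
  x <- array(v, c(d, 1L))
  s <- list()
  s[[1]] <- cv(x, p$conv_in, "conv_in")
  h <- s[[1]]
  if (spec$depth > 1) {
    for (l in 2:spec$depth) {
      hp <- .pool2_fwd(h, dim(h))
      t1 <- cv(hp, p$enc[[l - 1]]$a, paste0("enc", l, "a"))
      h <- cv(t1, p$enc[[l - 1]]$b, paste0("enc", l, "b"))
      s[[l]] <- h
    }
    for (l in spec$depth:2) {
      r <- cv(h, p$dec[[l - 1]], paste0("dec", l))
      h <- s[[l - 1]] + .up2_fwd(r, dim(r))
    }
  }
  nvox <- prod(d)
  y <- matrix(h, nvox, dim(h)[4]) %*% p$head$W + p$head$b
  if (keep) cache$head_in <- h
  y <- array(y, d)
  if (spec$residual) y <- y + v
  if (keep) list(y = y, cache = cache) else list(y = y)
}

# Backward pass: given the cache of a forward call and the gradient of a
# scalar loss w.r.t. the output, returns gradients w.r.t. all parameters
# (same nesting as `net$params`) and, optionally, w.r.t. the input.
network_backward <- function(net, cache, dy, need_dx = FALSE) {
  spec <- net$spec; p <- net$params
  single <- spec$precision == "single"
  d <- dim(dy)
  nvox <- prod(d)
  acode <- act_code(spec$activation)
  g <- list()
  cvb <- function(name, layer, dpost, need_input_grad = TRUE) {
    x <- cache$conv[[name]]
    r <- .conv3_bwd(x, layer$W, dpost, cache$out[[name]],
                    conv_dims(x, layer$W), single, need_input_grad, acode,
                    cache$col[[name]])
    g[[name]] <<- list(W = r$dW, b = r$db)
    r$dx
  }
  hin <- cache$head_in
  dyf <- matrix(dy, nvox, 1)
  g$head <- list(W = crossprod(matrix(hin, nvox, dim(hin)[4]), dyf),
                 b = sum(dyf))
  dh <- array(dyf %*% t(p$head$W), dim(hin))
  dskip <- vector("list", spec$depth)
  if (spec$depth > 1) {
    # decoder chain, top level first in forward = last in backward order
    for (l in 2:spec$depth) {
      dskip[[l - 1]] <- dh                       # skip add at level l-1
      dr <- .up2_bwd(dh, c(dim(dh)[1:3] %/% 2L, dim(cache$out[[paste0("dec", l)]])[4]))
      dh <- cvb(paste0("dec", l), p$dec[[l - 1]], dr)
    }
    # dh now is gradient w.r.t. s[[depth]] (bottom encoder output)
    for (l in spec$depth:2) {
      if (!is.null(dskip[[l]])) dh <- dh + dskip[[l]]
      dt <- cvb(paste0("enc", l, "b"), p$enc[[l - 1]]$b, dh)
      dhp <- cvb(paste0("enc", l, "a"), p$enc[[l - 1]]$a, dt)
      dh <- .pool2_bwd(dhp, c(2L * dim(dhp)[1:3], dim(dhp)[4]))
    }
    dh <- dh + dskip[[1]]
  }
  dx <- cvb("conv_in", p$conv_in, dh, need_dx)
  grads <- list(conv_in = g$conv_in)
  if (spec$depth > 1) {
    grads$enc <- lapply(2:spec$depth, function(l)
      list(a = g[[paste0("enc", l, "a")]], b = g[[paste0("enc", l, "b")]]))
    grads$dec <- lapply(2:spec$depth, function(l) g[[paste0("dec", l)]])
  }
  grads$head <- g$head
  out <- list(grads = grads)
  if (need_dx) {
    dxv <- array(dx, d)
    if (spec$residual) dxv <- dxv + dy
    out$dx <- dxv
  }
  out
}

#' Apply the network to a patch
#'
#' Evaluation is deterministic: two calls on the same input and
#' parameters agree bitwise. Supports double application `f(f(y))`.
#'
#' @param net an `et_network`.
#' @param v cubic patch whose edge is divisible by `2^(depth-1)`.
#' @return Same-shaped output patch.
#' @export
apply_network <- function(net, v) {
  stopifnot(inherits(net, "et_network"))
  assert_volume(v, cubic = TRUE)
  network_forward(net, v)$y
}

#' Save a network checkpoint
#'
#' The checkpoint is self-describing: spec, parameters and iteration
#' count travel together.
#'
#' @param net an `et_network`.
#' @param path destination file.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "et_network"))
  saveRDS(list(format = "equitomo-checkpoint-1", spec = net$spec,
               params = net$params, iteration = net$iteration), path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param expect_spec optional `network_spec`; mismatched fields raise an
#'   error naming them.
#' @return The restored `et_network`.
#' @export
load_checkpoint <- function(path, expect_spec = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format, "equitomo-checkpoint-1"))
    stop("not an equitomo checkpoint: ", path, call. = FALSE)
  if (!is.null(expect_spec)) {
    fields <- c("depth", "base_channels", "activation", "normalization",
                "residual", "precision")
    bad <- fields[vapply(fields, function(f)
      !identical(ck$spec[[f]], expect_spec[[f]]), TRUE)]
    if (length(bad) > 0)
      stop("checkpoint incompatible with requested spec; mismatched: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(spec = ck$spec, params = ck$params,
                 iteration = ck$iteration),
            class = "et_network")
}
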