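# Synthetic ground-truth volumes with the content classes seen in
# cellular tomograms -- spherical shells (membranes), rods (filaments)
# and gaussian blobs (globular particles) -- plus the paired-observation
# generator that pushes them through the acquisition simulator.

#' Specify a synthetic phantom
#'
#' Object counts may be given as a single number or a `c(min, max)` range
#' (drawn uniformly). Object centres are placed by rejection sampling
#' with a minimum mutual separation so that counts are unambiguous.
#' Densities are additive on top of the background level.
#'
#' @param shape length-3 dimensions (cubic recommended).
#' @param n_shells,n_rods,n_blobs count (or range) per object class.
#' @param contrast density contrast of objects over background.
#' @param background constant background level.
#' @param margin_frac object centres stay this fraction of the edge
#'   length away from the volume border (default 0.2), keeping content
#'   away from projection wrap-around.
#' @param seed integer seed; identical spec + seed gives an identical
#'   phantom, bitwise.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), n_shells = c(1, 2),
                         n_rods = c(1, 3), n_blobs = c(3, 8),
                         contrast = 1, background = 0,
                         margin_frac = 0.2, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0),
            all(c(n_shells, n_rods, n_blobs) >= 0), contrast >= 0,
            margin_frac >= 0, margin_frac < 0.5)
  structure(list(shape = shape, n_shells = n_shells, n_rods = n_rods,
                 n_blobs = n_blobs, contrast = contrast,
                 background = background, margin_frac = margin_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

draw_count <- function(x) if (length(x) == 1) as.integer(x) else
  sample(seq(x[1], x[2]), 1)

# Rejection-sample `k` centres with minimum separation `min_sep` inside
# the margin box; falls back to the best effort after many tries.
draw_centers <- function(k, shape, margin, min_sep) {
  if (k == 0) return(matrix(0, 0, 3))
  lo <- margin + 1; hi <- shape - margin
  pts <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(pts) < k && tries < 2000) {
    cand <- runif(3, lo, hi)
    if (nrow(pts) == 0 || min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep)
      pts <- rbind(pts, cand)
    tries <- tries + 1
  }
  pts
}

#' Generate a synthetic phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return 3D array of densities (background plus additive objects).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  n <- d[1]
  withr::with_seed(spec$seed, {
    co <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
                rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                rep(seq_len(d[3]), each = d[1] * d[2]))
    v <- rep(0, prod(d))
    margin <- spec$margin_frac * n
    ns <- draw_count(spec$n_shells)
    nr <- draw_count(spec$n_rods)
    nb <- draw_count(spec$n_blobs)
    # membranes: thin spherical shells with a soft gaussian profile
    ctrs <- draw_centers(ns, d, margin, 0.25 * n)
    for (i in seq_len(nrow(ctrs))) {
      r <- runif(1, 0.12, 0.22) * n
      th <- runif(1, 0.8, 1.5)
      dist <- sqrt(rowSums(sweep(co, 2, ctrs[i, ])^2))
      v <- v + exp(-(dist - r)^2 / (2 * th^2))
    }
    # filaments: straight rods with a gaussian radial profile
    ctrs <- draw_centers(nr, d, margin, 0.15 * n)
    for (i in seq_len(nrow(ctrs))) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len <- runif(1, 0.3, 0.7) * n
      rad <- runif(1, 0.8, 1.6)
      rel <- sweep(co, 2, ctrs[i, ])
      t <- pmin(pmax(rel %*% dir, -len / 2), len / 2)
      dist2 <- rowSums((rel - t %*% t(dir))^2)
      v <- v + 0.9 * exp(-dist2 / (2 * rad^2))
    }
    # particles: isotropic gaussian blobs
    ctrs <- draw_centers(nb, d, margin, 0.15 * n)
    for (i in seq_len(nrow(ctrs))) {
      sg <- runif(1, 1.2, 2.5)
      dist2 <- rowSums(sweep(co, 2, ctrs[i, ])^2)
      v <- v + exp(-dist2 / (2 * sg^2))
    }
  })
  array(spec$background + spec$contrast * v, d)
}

#' Generate paired noisy observations of synthetic phantoms
#'
#' For each phantom x the generator simulates one tilt series and
#' corrupts it with two independent noise draws, reconstructing
#' y_i = fbp(noise_i(project(x))) for i in {0, 1}: two observations of
#' the same signal whose noise fields are independent by construction,
#' with the clean x retained for evaluation.
#'
#' @param spec a [phantom_spec()]; phantom i uses seed `spec$seed + i - 1`.
#' @param scheme a [tilt_scheme()].
#' @param nm a [noise_model()]; the two draws for phantom i use seeds
#'   `nm$seed + 2 * (i - 1)` and `nm$seed + 2 * (i - 1) + 1`.
#' @param n number of phantoms.
#' @return List of `paired_observation`s: `y0`, `y1`, clean `x`, and
#'   `provenance` (scheme, noise model, seeds).
#' @export
generate_paired_dataset <- function(spec, scheme, nm, n = 1) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "tilt_scheme"),
            inherits(nm, "noise_model"), n >= 1)
  lapply(seq_len(n), function(i) {
    sp <- spec; sp$seed <- spec$seed + i - 1L
    x <- generate_phantom(sp)
    t <- project(x, scheme)
    nm0 <- nm; nm0$seed <- nm$seed + 2L * (i - 1L)
    nm1 <- nm; nm1$seed <- nm$seed + 2L * (i - 1L) + 1L
    structure(list(
      y0 = fbp(add_noise(t, nm0), dim(x)),
      y1 = fbp(add_noise(t, nm1), dim(x)),
      x = x,
      provenance = list(scheme = scheme, noise = nm,
                        phantom_seed = sp$seed,
                        noise_seeds = c(nm0$seed, nm1$seed))),
      class = "paired_observation")
  })
}

#' @export
print.paired_observation <- function(x, ...) {
  cat(sprintf("<paired observation %s: y0, y1%s>\n",
              paste(dim(x$y0), collapse = "x"),
              if (!is.null(x$x)) " + clean reference" else ""))
  invisible(x)
}
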