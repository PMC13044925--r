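# Tilt-series acquisition simulator: Fourier-slice projection, gridded
# filtered backprojection, per-frame noise and dose/angle splitting.

#' Construct a tilt series
#'
#' @param projections 3D array `[nx, ny, n_angles]` of projection images,
#'   or 4D `[nx, ny, n_frames, n_angles]` of unaveraged frames.
#' @param angles tilt angles in degrees, one per projection.
#' @param pixel_size physical pixel size in Angstrom.
#' @return A `tilt_series`.
#' @export
tilt_series <- function(projections, angles, pixel_size = 1) {
  d <- dim(projections)
  if (!(length(d) %in% c(3, 4)))
    stop("`projections` must be a 3D stack or 4D frame stack", call. = FALSE)
  if (d[length(d)] != length(angles))
    stop(sprintf("number of projections (%d) != number of angles (%d)",
                 d[length(d)], length(angles)), call. = FALSE)
  structure(list(projections = projections, angles = as.numeric(angles),
                 frames_per_tilt = if (length(d) == 4) d[3] else NULL,
                 pixel_size = pixel_size),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("<tilt series: %d tilts of %d x %d px%s, %.4g A/px>\n",
              length(x$angles), d[1], d[2],
              if (!is.null(x$frames_per_tilt))
                sprintf(" (%d frames/tilt)", x$frames_per_tilt) else "",
              x$pixel_size))
  invisible(x)
}

# Centred-phase FFT helpers: project()/fbp() place the rotation centre at
# the phase origin so that bilinear interpolation of the (otherwise
# rapidly oscillating) complex spectrum is accurate for content near the
# volume centre.
shift_axis <- function(v, axis, by) {
  n <- dim(v)[axis]
  idx <- ((seq_len(n) - 1 - by) %% n) + 1
  switch(axis, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}
fsh <- function(v, axes = 1:3) { for (a in axes) v <- shift_axis(v, a, floor(dim(v)[a] / 2)); v }
ifsh <- function(v, axes = 1:3) { for (a in axes) v <- shift_axis(v, a, -floor(dim(v)[a] / 2)); v }

# Kaiser-Bessel gridding kernels on the twofold oversampled plane, shape
# parameter from the Beatty formula. project() samples oblique central
# slices with a width-6 kernel (plus deapodization from its continuous
# transform); fbp() scatters unit-spaced samples back with a width-4
# kernel whose discrete transform is divided out after reconstruction.
kb_width <- 6          # gather kernel (slice sampling)
kb_width_scatter <- 4  # scatter kernel (gridded insertion)
kb_beta_for <- function(w) pi * sqrt((w / 2)^2 * (2 - 0.5)^2 - 0.8)

kb_kernel <- function(t, w = kb_width) {
  beta <- kb_beta_for(w)
  a <- 1 - (2 * t / w)^2
  ifelse(a > 0, besselI(beta * sqrt(pmax(a, 0)), 0) / besselI(beta, 0), 0)
}

# Continuous FT of the gather kernel at real-space coordinate x on a grid
# of size G (numerical quadrature; exact at the accuracy scale needed).
kb_transform <- function(x, G) {
  t <- seq(-kb_width / 2, kb_width / 2, length.out = 801)
  psi <- kb_kernel(t)
  vapply(x, function(xx) {
    f <- psi * cos(2 * pi * t * xx / G)
    sum((f[-1] + f[-length(f)]) / 2) * diff(t[1:2])
  }, 0)
}

# Deapodization weights over the (x, z) plane of an n-grid volume whose
# spectrum is gridded on the 2n plane. `normalized` rescales to unit DC
# gain (used after weight-normalised scattering in fbp()).
deapod_xz <- function(n, normalized = FALSE) {
  xc <- seq_len(n) - (floor(n / 2) + 1)
  s <- kb_transform(xc, 2 * n)
  if (normalized) s <- s / kb_transform(0, 2 * n)
  outer(s, s)
}
apply_deapod <- function(v, normalized = FALSE) {
  f <- 1 / deapod_xz(dim(v)[1], normalized)
  aperm(aperm(v, c(1, 3, 2)) * as.vector(f), c(1, 3, 2))
}

# Gridding geometry for tilt angle theta (about y): the sample point for
# in-plane frequency k is (2 k cos theta, 2 k sin theta) on the padded
# grid, spread over the kernel's 4 x 4 neighbourhood (periodic indexing).
slice_geometry <- function(n, theta_deg) {
  th <- theta_deg * pi / 180
  n2 <- 2L * n
  kp <- 2 * fft_freqs(n)
  fx <- kp * cos(th); fz <- kp * sin(th)
  x0 <- floor(fx); z0 <- floor(fz)
  offs <- (-(kb_width / 2 - 1)):(kb_width / 2)
  idx <- function(a) (a %% n2) + 1L
  nc <- kb_width^2
  ix <- iz <- matrix(0L, n, nc); w <- matrix(0, n, nc)
  c <- 1
  for (ox in offs) for (oz in offs) {
    ix[, c] <- idx(x0 + ox); iz[, c] <- idx(z0 + oz)
    w[, c] <- kb_kernel(fx - (x0 + ox)) * kb_kernel(fz - (z0 + oz))
    c <- c + 1
  }
  list(ix = ix, iz = iz, w = w, ncorner = nc)
}

# Fine gridding geometry for fbp(): the projection is zero-padded twofold
# before transforming, so its spectrum is known at unit spacing on the
# oversampled plane. Scattering unit-spaced samples through the kernel and
# normalising by the accumulated weight is then a standard kernel smoother
# whose transfer function is the kernel's *discrete* transform, divided
# out in real space after reconstruction.
slice_geometry_fine <- function(n, theta_deg) {
  th <- theta_deg * pi / 180
  n2 <- 2L * n
  w0 <- kb_width_scatter
  kp <- fft_freqs(n2)
  fx <- kp * cos(th); fz <- kp * sin(th)
  x0 <- floor(fx); z0 <- floor(fz)
  offs <- (-(w0 / 2 - 1)):(w0 / 2)
  idx <- function(a) (a %% n2) + 1L
  nc <- w0^2
  ix <- iz <- matrix(0L, n2, nc); w <- matrix(0, n2, nc)
  c <- 1
  for (ox in offs) for (oz in offs) {
    ix[, c] <- idx(x0 + ox); iz[, c] <- idx(z0 + oz)
    w[, c] <- kb_kernel(fx - (x0 + ox), w0) * kb_kernel(fz - (z0 + oz), w0)
    c <- c + 1
  }
  list(ix = ix, iz = iz, w = w, ncorner = nc)
}

# Normalised discrete transform of the kernel sampled at integer offsets,
# evaluated at real-space coordinate x on a grid of size G.
kb_discrete_transform <- function(x, G) {
  j <- seq_len(kb_width_scatter / 2)
  psi <- kb_kernel(j, kb_width_scatter)
  h <- 1 + 2 * colSums(psi * cos(2 * pi * outer(j, x) / G))
  h / (1 + 2 * sum(psi))
}
apply_discrete_deapod <- function(v) {
  n <- dim(v)[1]
  xc <- seq_len(n) - (floor(n / 2) + 1)
  f <- 1 / outer(kb_discrete_transform(xc, 2 * n), kb_discrete_transform(xc, 2 * n))
  aperm(aperm(v, c(1, 3, 2)) * as.vector(f), c(1, 3, 2))
}

# Embed a stack of 1D signals (rows) centred in a twofold zero-pad.
pad_rows <- function(p) {
  n <- nrow(p)
  off <- ceiling(n / 2)
  out <- matrix(0, 2 * n, ncol(p))
  out[(off + 1):(off + n), ] <- p
  out
}

# Embed v centred in a grid zero-padded twofold along x and z.
pad_xz <- function(v) {
  d <- dim(v)
  off <- ceiling(d[c(1, 3)] / 2)
  out <- array(0, c(2 * d[1], d[2], 2 * d[3]))
  out[(off[1] + 1):(off[1] + d[1]), , (off[2] + 1):(off[2] + d[3])] <- v
  out
}

#' Project a volume into a tilt series
#'
#' Computes line-integral projections along beams tilted about the y
#' axis, implemented in Fourier space via the central-slice theorem: the
#' 2D transform of the projection at angle theta equals the central slice
#' of the 3D transform at that orientation, sampled here with bilinear
#' interpolation in the (kx, kz) plane (the ky axis lies exactly on the
#' grid).
#'
#' @param v 3D array with equal x and z extents (cubic is typical).
#' @param scheme a [tilt_scheme()].
#' @param pixel_size propagated to the output.
#' @return A [tilt_series()] of `[nx, ny, n_angles]` projections.
#' @export
project <- function(v, scheme, pixel_size = 1) {
  assert_volume(v)
  if (!inherits(scheme, "tilt_scheme") || length(scheme$angles) == 0)
    stop("`scheme` must be a non-empty tilt_scheme", call. = FALSE)
  d <- dim(v)
  if (d[1] != d[3])
    stop("projection requires equal x and z extents", call. = FALSE)
  n <- d[1]; ny <- d[2]; n2 <- 2L * n
  V <- fft(ifsh(pad_xz(apply_deapod(v))))
  Vp <- matrix(aperm(V, c(1, 3, 2)), n2 * n2, ny)   # rows: (kx, kz), cols: ky
  out <- array(0, c(n, ny, length(scheme$angles)))
  for (t in seq_along(scheme$angles)) {
    geo <- slice_geometry(n, scheme$angles[t])
    P <- matrix(0i, n, ny)
    for (c in seq_len(geo$ncorner)) {
      rows <- geo$ix[, c] + n2 * (geo$iz[, c] - 1L)
      P <- P + geo$w[, c] * Vp[rows, , drop = FALSE]
    }
    pr <- Re(fft(P, inverse = TRUE)) / (n * ny)
    out[, , t] <- fsh(array(pr, c(n, ny, 1)), axes = 1:2)[, , 1]
  }
  tilt_series(out, scheme$angles, pixel_size)
}

#' Filtered backprojection by Fourier gridding
#'
#' Inserts each projection's 2D Fourier transform on its central plane
#' with bilinear gridding weights, normalises every frequency voxel by
#' the accumulated insertion weight, leaves never-touched voxels (the
#' missing wedge) at zero, and inverse transforms.
#'
#' @param t a [tilt_series()] (frames, if present, are averaged first).
#' @param shape output dimensions; the x/z extents must equal the
#'   projection width and y extent the projection height.
#' @return Reconstructed 3D array.
#' @export
fbp <- function(t, shape) {
  stopifnot(inherits(t, "tilt_series"))
  p <- average_frames(t)$projections
  d <- dim(p); shape <- as.integer(shape)
  if (length(shape) != 3 || shape[1] != d[1] || shape[3] != d[1] || shape[2] != d[2])
    stop(sprintf("shape %s inconsistent with %d x %d projections",
                 paste(shape, collapse = "x"), d[1], d[2]), call. = FALSE)
  n <- shape[1]; ny <- shape[2]; n2 <- 2L * n
  acc <- matrix(0i, n2 * n2, ny)
  wt <- numeric(n2 * n2)
  for (ti in seq_len(d[3])) {
    pp <- pad_rows(p[, , ti])                      # fine sampling along x
    P <- fft(ifsh(array(pp, c(n2, ny, 1)), axes = 1:2)[, , 1])
    geo <- slice_geometry_fine(n, t$angles[ti])
    for (c in seq_len(geo$ncorner)) {
      rows <- geo$ix[, c] + n2 * (geo$iz[, c] - 1L)
      # rowsum() accumulates safely when several samples hit one voxel
      re <- rowsum(geo$w[, c] * Re(P), rows)
      im <- rowsum(geo$w[, c] * Im(P), rows)
      r <- as.integer(rownames(re))
      acc[r, ] <- acc[r, ] + complex(real = re, imaginary = im)
      wt[r] <- wt[r] + rowsum(geo$w[, c], rows)
    }
  }
  touched <- wt > 1e-12
  acc[touched, ] <- acc[touched, ] / wt[touched]
  acc[!touched, ] <- 0
  # decimate to the even frequencies of the oversampled plane: exactly the
  # n-grid spectrum, leaving never-touched (missing wedge) voxels at zero
  keep <- ((2 * fft_freqs(n)) %% n2) + 1L
  Wn <- array(matrix(acc, n2, n2 * ny)[keep, ], c(n, n2, ny))[, keep, ]
  W <- aperm(array(Wn, c(n, n, ny)), c(1, 3, 2))
  apply_discrete_deapod(fsh(Re(fft(W, inverse = TRUE)) / length(W)))
}

average_frames <- function(t) {
  if (is.null(t$frames_per_tilt)) return(t)
  p <- apply(t$projections, c(1, 2, 4), mean)
  tilt_series(p, t$angles, t$pixel_size)
}

#' Define a noise model
#'
#' @param kind `"gaussian"` (additive, scale `sigma`) or
#'   `"poisson-gaussian"` (shot noise at `gain` counts per density unit,
#'   plus additive gaussian read noise of scale `sigma`).
#' @param sigma noise scale in normalised density units (>= 0).
#' @param gain counts per density unit (poisson-gaussian only).
#' @param seed integer seed; two models with different seeds draw
#'   statistically independent noise fields.
#' @return A `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian", "poisson-gaussian"),
                        sigma = 1, gain = 10, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0, gain > 0)
  structure(list(kind = kind, sigma = sigma, gain = gain,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Add noise to a tilt series
#'
#' Applies the noise model independently per pixel (and per frame when
#' frames are present). Deterministic: the same input and seed give the
#' same output.
#'
#' @param t a [tilt_series()].
#' @param nm a [noise_model()].
#' @return The noisy `tilt_series`.
#' @export
add_noise <- function(t, nm) {
  stopifnot(inherits(t, "tilt_series"), inherits(nm, "noise_model"))
  if (!nm$kind %in% c("gaussian", "poisson-gaussian"))
    stop("unknown noise kind: ", nm$kind, call. = FALSE)
  p <- t$projections
  if (nm$sigma == 0 && nm$kind == "gaussian") return(t)
  withr::with_seed(nm$seed, {
    if (nm$kind == "gaussian") {
      p <- p + array(rnorm(length(p), sd = nm$sigma), dim(p))
    } else {
      lo <- min(p)
      counts <- rpois(length(p), lambda = nm$gain * (p - lo))
      p <- array(counts / nm$gain + lo, dim(p)) +
        array(rnorm(length(p), sd = nm$sigma), dim(p))
    }
  })
  out <- t
  out$projections <- p
  out
}

#' Define a frame/angle splitting scheme
#'
#' @param mode `"dose"` (partition detector frames within each tilt) or
#'   `"angle"` (partition tilts; even-indexed tilts go to split 0).
#' @param split0,split1 frame index sets for dose mode; must be disjoint.
#' @param excluded_frames frames dropped before splitting (e.g. late,
#'   dose-damaged frames), so the splits have comparable SNR.
#' @return A `split_scheme`.
#' @export
split_scheme <- function(mode = c("dose", "angle"), split0 = NULL,
                         split1 = NULL, excluded_frames = integer()) {
  mode <- match.arg(mode)
  if (mode == "dose") {
    if (is.null(split0) || is.null(split1))
      stop("dose mode requires `split0` and `split1` frame sets", call. = FALSE)
    if (length(intersect(split0, split1)) > 0)
      stop("overlapping frame assignment between splits", call. = FALSE)
    if (length(intersect(c(split0, split1), excluded_frames)) > 0)
      stop("excluded frames may not appear in either split", call. = FALSE)
  }
  structure(list(mode = mode, split0 = split0, split1 = split1,
                 excluded_frames = as.integer(excluded_frames)),
            class = "split_scheme")
}

#' Split a tilt series into two independent halves
#'
#' Dose mode averages each split's frames per tilt (both halves keep all
#' angles); angle mode partitions the tilts by index parity (each half
#' keeps half the angles). Excluded frames are dropped first.
#'
#' @param t a [tilt_series()] (dose mode requires per-tilt frames).
#' @param s a [split_scheme()].
#' @return List of two `tilt_series`.
#' @export
make_split_pair <- function(t, s) {
  stopifnot(inherits(t, "tilt_series"), inherits(s, "split_scheme"))
  if (s$mode == "dose") {
    if (is.null(t$frames_per_tilt))
      stop("dose splitting requires per-tilt frames", call. = FALSE)
    keep <- setdiff(seq_len(t$frames_per_tilt), s$excluded_frames)
    bad <- setdiff(c(s$split0, s$split1), keep)
    if (length(bad) > 0)
      stop(sprintf("split refers to unavailable frames: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    avg <- function(idx) {
      sub <- t$projections[, , idx, , drop = FALSE]
      apply(sub, c(1, 2, 4), mean)
    }
    list(tilt_series(avg(s$split0), t$angles, t$pixel_size),
         tilt_series(avg(s$split1), t$angles, t$pixel_size))
  } else {
    p <- average_frames(t)
    even <- seq_along(p$angles) %% 2 == 1               # 0-based even indices
    list(tilt_series(p$projections[, , even, drop = FALSE], p$angles[even], p$pixel_size),
         tilt_series(p$projections[, , !even, drop = FALSE], p$angles[!even], p$pixel_size))
  }
}
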