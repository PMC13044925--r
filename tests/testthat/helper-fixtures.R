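# Shared fixtures, built in code at test time.

# Smooth phantom: a few gaussian blobs with central support, suitable for
# Fourier-domain accuracy checks.
smooth_phantom <- function(n = 32, centers = NULL, sigmas = NULL,
                           weights = NULL) {
  if (is.null(centers))
    centers <- rbind(c(0.50, 0.47, 0.53), c(0.41, 0.56, 0.47),
                     c(0.59, 0.44, 0.56)) * n
  if (is.null(sigmas)) sigmas <- c(2.5, 3, 2)
  if (is.null(weights)) weights <- c(1, 0.7, 0.5)
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  v <- rep(0, n^3)
  for (i in seq_len(nrow(centers)))
    v <- v + weights[i] *
      exp(-rowSums(sweep(co, 2, centers[i, ])^2) / (2 * sigmas[i]^2))
  array(v, c(n, n, n))
}

# Brute-force voxel transform through the group element's matrix, the
# independent oracle for apply_transform().
brute_transform <- function(g, v) {
  n <- dim(v)[1]
  out <- array(NA_real_, dim(v))
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    x <- c(t(g$matrix) %*% (c(i, j, k) - ctr)) + ctr
    out[i, j, k] <- v[x[1], x[2], x[3]]
  }
  out
}

# A tiny paired synthetic observation at the given size.
tiny_paired <- function(n = 32, seed = 1, sigma_rel = 2,
                        scheme = tilt_scheme(-60, 60, 3)) {
  x <- generate_phantom(phantom_spec(shape = rep(n, 3), seed = seed))
  ts <- project(x, scheme)
  sigma <- sigma_rel * sd(ts$projections)
  structure(list(
    y0 = fbp(add_noise(ts, noise_model("gaussian", sigma, seed = seed * 31 + 1)),
             dim(x)),
    y1 = fbp(add_noise(ts, noise_model("gaussian", sigma, seed = seed * 31 + 2)),
             dim(x)),
    x = x,
    provenance = list(scheme = scheme, sigma = sigma)),
    class = "paired_observation")
}

# Identity "network": passes patches through unchanged; exercises the
# operator-level identities of the losses and the stitching.
identity_predictor <- function(v) v
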