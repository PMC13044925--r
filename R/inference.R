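# Final reconstruction by double application of the trained network with
# patchwise tiling, plus synthetic-data evaluation metrics.

reflect_pad_to <- function(v, target) {
  d <- dim(v)
  pad <- pmax(target - d, 0)
  if (all(pad == 0)) return(list(v = v, orig = d))
  idx <- lapply(1:3, function(a) {
    n <- d[a]
    want <- d[a] + pad[a]
    base <- seq_len(n)
    ref <- c(base, rev(base)[-1])            # reflect without repeating edge
    ref[((seq_len(want) - 1) %% length(ref)) + 1]
  })
  list(v = v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], orig = d)
}

apply_patchwise <- function(net, v, patch, overlap) {
  fp <- as_predictor(net)
  pd <- reflect_pad_to(v, rep(patch, 3))
  grid <- tile_for_inference(dim(pd$v), patch, overlap)
  patches <- lapply(extract_patches(pd$v, grid), function(p)
    fp(array(p, rep(patch, 3))))
  out <- blend_patches(patches, grid)
  d <- pd$orig
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
}

#' Reconstruct a tomogram with the trained network
#'
#' Applies the network twice over full tile-blend passes: the first pass
#' denoises each observation (and averages the two denoised volumes when
#' both are given); the second pass refines the missing-wedge fill by
#' running the network on its own output. A single-pass variant is
#' available via `passes = 1`. Volumes smaller than the patch (or not
#' covered exactly) are reflect-padded and cropped back.
#'
#' @param net a trained `et_network` (or any patch-to-patch function,
#'   e.g. for plumbing checks).
#' @param y0 first (normalised) observation volume.
#' @param y1 optional second observation, same shape.
#' @param patch patch edge length (divisible by the network stride).
#' @param overlap tile overlap (default `patch %/% 4`).
#' @param passes 2 (default) or 1.
#' @param stats optional `c(mean, sd)` from [normalize_tomogram()]; when
#'   given, the output is mapped back to the original intensity scale.
#' @return The reconstructed volume, same shape as the input.
#' @export
reconstruct <- function(net, y0, y1 = NULL, patch = 72,
                        overlap = patch %/% 4, passes = 2, stats = NULL) {
  stopifnot(inherits(net, "et_network") || is.function(net), passes %in% 1:2)
  assert_volume(y0)
  if (!is.null(y1) && !all(dim(y0) == dim(y1)))
    stop(sprintf("y0 (%s) and y1 (%s) shapes differ",
                 paste(dim(y0), collapse = "x"),
                 paste(dim(y1), collapse = "x")), call. = FALSE)
  den <- apply_patchwise(net, y0, patch, overlap)
  if (!is.null(y1))
    den <- (den + apply_patchwise(net, y1, patch, overlap)) / 2
  out <- if (passes == 2) apply_patchwise(net, den, patch, overlap) else den
  if (!is.null(stats)) out <- denormalize_tomogram(out, stats)
  out
}

# Erode the missing region of a wedge mask in the (kx, kz) plane so that
# the boundary shell -- which gridding kernels inevitably populate -- is
# not counted as wedge interior.
wedge_interior <- function(m, v, shell = 2) {
  a <- as_mask_array(m, v)
  miss <- 1 - a[, 1, ]
  n1 <- dim(a)[1]; n3 <- dim(a)[3]
  for (k in seq_len(shell)) {
    e <- miss
    for (dx in -1:1) for (dz in -1:1)
      e <- e * miss[((seq_len(n1) - 1 - dx) %% n1) + 1,
                    ((seq_len(n3) - 1 - dz) %% n3) + 1]
    miss <- e
  }
  aperm(array(rep(miss, dim(a)[2]), c(n1, n3, dim(a)[2])), c(1, 3, 2))
}

#' Spectral energy ratio inside the missing wedge
#'
#' Fraction of total spectral energy (DC excluded) lying in the interior
#' of the missing region -- the wedge eroded by `shell` frequency voxels
#' in the (kx, kz) plane, so that boundary voxels touched by gridding
#' kernels are not counted. Raw FBP reconstructions have a ratio near
#' zero; restoring this energy is precisely the wedge-filling task.
#'
#' @param v 3D array.
#' @param m a `wedge_mask` for `dim(v)`.
#' @param shell boundary-shell width excluded from the wedge (default 2).
#' @return Scalar in \[0, 1\].
#' @export
wedge_energy_ratio <- function(v, m, shell = 2) {
  w <- wedge_interior(m, v, shell)
  P <- Mod(fft(v))^2
  P[1, 1, 1] <- 0
  sum(P * w) / sum(P)
}

#' Spectral correlation with a reference inside the missing wedge
#'
#' Normalised real cross-correlation of the Fourier coefficients of `v`
#' and `ref` restricted to the missing-wedge interior (eroded as in
#' [wedge_energy_ratio()]).
#'
#' @param v estimate volume.
#' @param ref reference volume (e.g. the clean phantom).
#' @param m a `wedge_mask`.
#' @param shell boundary-shell width excluded from the wedge (default 2).
#' @return Scalar in \[-1, 1\] (0 when `v` has no wedge energy).
#' @export
wedge_correlation <- function(v, ref, m, shell = 2) {
  a <- wedge_interior(m, v, shell)
  a[1, 1, 1] <- 0
  V <- fft(v) * a; R <- fft(ref) * a
  den <- sqrt(sum(Mod(V)^2) * sum(Mod(R)^2))
  if (den == 0) return(0)
  Re(sum(V * Conj(R))) / den
}

#' Evaluate a reconstruction against the clean synthetic reference
#'
#' @param net a trained `et_network` (or NULL to evaluate `recon`).
#' @param paired a `paired_observation` with clean `x`.
#' @param scheme the [tilt_scheme()] of the acquisition.
#' @param patch,overlap,passes as in [reconstruct()].
#' @param recon optional precomputed reconstruction (skips the network).
#' @return List with `psnr`, `psnr_input`, `wedge_energy`,
#'   `wedge_energy_input`, `wedge_correlation`,
#'   `wedge_correlation_input`, and the reconstruction.
#' @export
evaluate_synthetic <- function(net, paired, scheme, patch = dim(paired$y0)[1],
                               overlap = patch %/% 4, passes = 2,
                               recon = NULL) {
  stopifnot(!is.null(paired$x))
  m <- make_wedge_mask(dim(paired$x), scheme)
  nt0 <- normalize_tomogram(paired$y0)
  nt1 <- normalize_tomogram(paired$y1)
  if (is.null(recon))
    recon <- reconstruct(net, nt0$v, nt1$v, patch = patch, overlap = overlap,
                         passes = passes, stats = nt0$stats)
  x <- paired$x
  list(psnr = psnr(recon, x),
       psnr_input = psnr(paired$y0, x),
       wedge_energy = wedge_energy_ratio(recon, m),
       wedge_energy_input = wedge_energy_ratio(paired$y0, m),
       wedge_correlation = wedge_correlation(recon, x, m),
       wedge_correlation_input = wedge_correlation(paired$y0, x, m),
       recon = recon)
}
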