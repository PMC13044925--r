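# Fourier shell correlation between two volumes, with the conventional
# summaries (threshold crossing, central crop).

#' Fourier shell correlation
#'
#' Per spherical shell of integer radius in centred frequency
#' coordinates, the normalised real cross-correlation
#' Re<A, B> / (||A|| ||B||) of the two spectra. Shell width is one
#' frequency voxel; frequencies are reported in cycles/voxel up to
#' Nyquist (0.5).
#'
#' @param a,b volumes of identical (cubic) shape.
#' @param mask optional real-space mask applied to both before
#'   transforming.
#' @return An `fsc_curve` data frame: `shell`, `freq`, `fsc`, `n_voxels`.
#' @export
fsc <- function(a, b, mask = NULL) {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("shapes differ: %s vs %s", paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  if (!is.null(mask)) { a <- a * mask; b <- b * mask }
  d <- dim(a)
  A <- fft(a); B <- fft(b)
  ks <- lapply(d, fft_freqs)
  r2 <- outer(outer(ks[[1]]^2, ks[[2]]^2, "+"), ks[[3]]^2, "+")
  shell <- round(sqrt(r2))
  nmax <- floor(min(d) / 2)
  keep <- shell <= nmax
  idx <- shell[keep] + 1L
  num <- rowsum(Re(A[keep] * Conj(B[keep])), idx)
  na <- rowsum(Mod(A[keep])^2, idx)
  nb <- rowsum(Mod(B[keep])^2, idx)
  cnt <- tabulate(idx, nbins = nmax + 1)
  corr <- as.vector(num) / sqrt(pmax(as.vector(na) * as.vector(nb), 1e-300))
  out <- data.frame(shell = 0:nmax, freq = (0:nmax) / min(d),
                    fsc = corr, n_voxels = cnt)
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Central crop of a volume
#'
#' @param v 3D array.
#' @param size target edge length(s), `<= dim(v)`.
#' @return The axis-centred crop.
#' @export
central_crop <- function(v, size = 256) {
  d <- dim(v)
  size <- rep(as.integer(size), length.out = 3)
  if (any(size > d))
    stop(sprintf("crop %s exceeds volume %s", paste(size, collapse = "x"),
                 paste(d, collapse = "x")), call. = FALSE)
  start <- (d - size) %/% 2 + 1
  v[start[1]:(start[1] + size[1] - 1), start[2]:(start[2] + size[2] - 1),
    start[3]:(start[3] + size[3] - 1), drop = FALSE]
}

#' Frequency at which an FSC curve crosses a threshold
#'
#' Linear interpolation between the shell just above and the first shell
#' below the threshold; Nyquist is returned when the curve never drops
#' below it.
#'
#' @param curve an [fsc()] result.
#' @param threshold correlation threshold (conventionally 0.143 or 0.5).
#' @return Frequency in cycles/voxel.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  stopifnot(nrow(curve) > 0)
  below <- which(curve$fsc < threshold)
  below <- below[below > 1]
  if (length(below) == 0) return(max(curve$freq))
  i <- below[1]
  if (i == 2) return(curve$freq[2])          # below from the first shell on
  f1 <- curve$fsc[i - 1]; f2 <- curve$fsc[i]
  x1 <- curve$freq[i - 1]; x2 <- curve$freq[i]
  if (f1 == f2) return(x2)
  x1 + (f1 - threshold) / (f1 - f2) * (x2 - x1)
}

#' Plot an FSC curve
#'
#' Uses ggplot2 when available, otherwise base graphics.
#'
#' @param curve an [fsc()] result.
#' @param threshold optional horizontal reference line.
#' @return A ggplot object, or (base graphics) the curve invisibly.
#' @export
plot_fsc <- function(curve, threshold = 0.143) {
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(as.data.frame(curve),
                         ggplot2::aes(x = .data$freq, y = .data$fsc)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
      ggplot2::labs(x = "spatial frequency (cycles/voxel)",
                    y = "Fourier shell correlation") +
      ggplot2::ylim(min(0, min(curve$fsc)), 1)
    return(p)
  }
  plot(curve$freq, curve$fsc, type = "l", xlab = "frequency (cycles/voxel)",
       ylab = "FSC", ylim = c(min(0, min(curve$fsc)), 1))
  abline(h = threshold, lty = 2)
  invisible(curve)
}
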