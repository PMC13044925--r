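#' Pixel size after binning
#'
#' Binning (block-averaging) a tilt series or tomogram by an integer factor
#' multiplies the physical pixel size by that factor. For example a series
#' collected at 2.36 Angstrom binned by 6 has an effective pixel size of
#' 14.16 Angstrom.
#'
#' @param pixel_size physical pixel size in Angstrom before binning.
#' @param factor integer binning factor (>= 1).
#' @return Effective pixel size in Angstrom after binning.
#' @export
#' @examples
#' bin_pixel_size(2.36, 6)
bin_pixel_size <- function(pixel_size, factor) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(factor), factor >= 1, factor == round(factor))
  pixel_size * factor
}

#' Block-average a volume by an integer factor
#'
#' Downsamples a 3D volume by averaging non-overlapping cubic blocks.
#' Dimensions must be divisible by the factor.
#'
#' @param v 3D numeric array.
#' @param factor integer binning factor.
#' @return Binned 3D array of dimension `dim(v) / factor`.
#' @export
bin_volume <- function(v, factor) {
  d <- dim(v)
  stopifnot(length(d) == 3, all(d %% factor == 0))
  f <- as.integer(factor)
  dn <- d %/% f
  a <- array(v, c(f, dn[1], f, dn[2], f, dn[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dn)
}

# Validate a 3D volume argument.
assert_volume <- function(v, cubic = FALSE, name = deparse(substitute(v))) {
  if (!is.array(v) || length(dim(v)) != 3)
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  if (cubic && length(unique(dim(v))) != 1)
    stop(sprintf("`%s` must be cubic, got %s", name,
                 paste(dim(v), collapse = " x ")), call. = FALSE)
  invisible(v)
}

# Signed centred FFT frequency indices for axis length n:
# 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1 in FFT storage order.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k - n * (k >= ceiling(n / 2))
}

# Peak signal-to-noise ratio in dB. Exact equality is reported as the
# `cap` sentinel rather than +Inf.
#' Peak signal-to-noise ratio
#'
#' @param x estimate volume.
#' @param ref reference volume.
#' @param peak peak value; defaults to the dynamic range of `ref`.
#' @param cap value reported when the mean squared error is zero.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, ref, peak = NULL, cap = 120) {
  stopifnot(all(dim(x) == dim(ref)))
  mse <- mean((x - ref)^2)
  if (is.null(peak)) peak <- diff(range(ref))
  if (mse == 0) return(cap)
  min(10 * log10(peak^2 / mse), cap)
}

relative_energy <- function(a, b) sum(a^2) / sum(b^2)
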