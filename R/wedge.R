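# Missing-wedge machinery: the tilt scheme, the binary Fourier support it
# induces, and the orthogonal projector A that zeroes the unobserved
# region (plus its rotated conjugates A_g = R_g A R_g^-1).

#' Define a tilt scheme
#'
#' @param theta_min,theta_max tilt range in degrees, each in (-90, 90).
#' @param increment angular step in degrees (> 0).
#' @return A `tilt_scheme` with the implied angle list.
#' @export
#' @examples
#' tilt_scheme(-60, 60, 3)
tilt_scheme <- function(theta_min = -60, theta_max = 60, increment = 3) {
  if (!is.numeric(theta_min) || !is.numeric(theta_max) ||
      theta_min >= theta_max || theta_min < -90 || theta_max > 90)
    stop("invalid tilt range: need -90 <= theta_min < theta_max <= 90 degrees",
         call. = FALSE)
  if (!is.numeric(increment) || increment <= 0)
    stop("tilt increment must be positive", call. = FALSE)
  angles <- seq(theta_min, theta_max, by = increment)
  if (length(angles) == 0) stop("empty tilt angle list", call. = FALSE)
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 increment = increment, angles = angles, tilt_axis = "y"),
            class = "tilt_scheme")
}

#' @export
print.tilt_scheme <- function(x, ...) {
  cat(sprintf("<tilt scheme: %g to %g deg in %g deg steps (%d tilts), axis y>\n",
              x$theta_min, x$theta_max, x$increment, length(x$angles)))
  invisible(x)
}

# Line angle (degrees, in (-90, 90]) of frequency vector (kx, kz) from the
# kx axis; the zero vector maps to 0 (observed).
line_angle <- function(kx, kz) {
  a <- atan2(kz, kx) * 180 / pi
  a <- ifelse(a > 90, a - 180, a)
  ifelse(a <= -90, a + 180, a)
}

#' Build a missing-wedge Fourier mask
#'
#' A frequency voxel (kx, ky, kz) is observed iff the line through
#' (kx, kz) makes an angle within `[theta_min, theta_max]` with the kx
#' axis; the mask is independent of ky (the tilt axis) and the origin is
#' always observed. The mask lives on the FFT grid (zero frequency at
#' index 1) using signed centred frequency coordinates for the angle test.
#'
#' With `rolloff > 0` the hard edge is replaced by a cosine taper of that
#' angular width (degrees); the default is the hard-edged orthogonal
#' projector.
#'
#' @param shape length-3 integer vector of grid dimensions.
#' @param scheme a [tilt_scheme()].
#' @param rolloff angular soft-edge width in degrees (0 = hard mask).
#' @return A `wedge_mask` with fields `mask` (3D array in \[0, 1\]),
#'   `shape` and `scheme`.
#' @export
make_wedge_mask <- function(shape, scheme, rolloff = 0) {
  if (!inherits(scheme, "tilt_scheme")) stop("`scheme` must be a tilt_scheme")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0))
  kx <- fft_freqs(shape[1]); kz <- fft_freqs(shape[3])
  ang <- outer(kx, kz, line_angle)                       # nx x nz
  if (rolloff <= 0) {
    m2 <- (ang >= scheme$theta_min & ang <= scheme$theta_max) * 1
  } else {
    # distance outside the observed interval, tapered over `rolloff` deg
    d <- pmax(scheme$theta_min - ang, ang - scheme$theta_max, 0)
    # the angle is periodic with period 180: also measure through the ends
    d_wrap <- pmax(scheme$theta_min - (ang - 180), (ang + 180) - scheme$theta_max, 0)
    d <- pmin(d, d_wrap)
    m2 <- ifelse(d <= 0, 1, ifelse(d >= rolloff, 0,
                                   0.5 * (1 + cos(pi * d / rolloff))))
  }
  # sign symmetrization: on even grids the Nyquist row is its own
  # negation partner, so observe a frequency only if both +k and -k pass
  # the angle test; this makes the mask exactly Hermitian for any range
  neg1 <- c(1L, shape[1]:2L); neg3 <- c(1L, shape[3]:2L)
  m2 <- pmin(m2, m2[neg1, neg3])
  m2[1, 1] <- 1                                          # zero frequency observed
  mask <- aperm(array(rep(m2, shape[2]), c(shape[1], shape[3], shape[2])),
                c(1, 3, 2))
  structure(list(shape = shape, mask = mask, scheme = scheme),
            class = "wedge_mask")
}

#' @export
print.wedge_mask <- function(x, ...) {
  cat(sprintf("<wedge mask %s: %.1f%% of frequencies observed>\n",
              paste(x$shape, collapse = "x"), 100 * mean(x$mask)))
  invisible(x)
}

as_mask_array <- function(m, v) {
  a <- if (inherits(m, "wedge_mask")) m$mask else m
  if (!all(dim(a) == dim(v)))
    stop(sprintf("mask shape %s does not match volume shape %s",
                 paste(dim(a), collapse = "x"), paste(dim(v), collapse = "x")),
         call. = FALSE)
  a
}

#' Apply the missing-wedge projector A
#'
#' Multiplies the volume's Fourier transform by the wedge mask and
#' transforms back, discarding the (numerically negligible) imaginary
#' residue. For a binary Hermitian mask this is an orthogonal projection:
#' idempotent, self-adjoint and energy non-increasing.
#'
#' @param v 3D array.
#' @param m a `wedge_mask` (or bare mask array of matching shape).
#' @return The projected volume, real-valued, same shape.
#' @export
apply_wedge <- function(v, m) {
  assert_volume(v)
  a <- as_mask_array(m, v)
  Re(fft(fft(v) * a, inverse = TRUE)) / length(v)
}

#' Rotate a wedge mask by a group element
#'
#' Returns the Fourier support of the conjugated projector
#' A_g = R_g A R_g^-1, obtained by permuting/negating the frequency grid:
#' mask_g(k) = mask(g^-1 k). Negation acts modularly on the FFT grid, so
#' the transform is exact for even and odd sizes.
#'
#' @param m a `wedge_mask` with cubic shape.
#' @param g a `group_element`.
#' @return The rotated `wedge_mask`.
#' @export
rotate_wedge_mask <- function(m, g) {
  stopifnot(inherits(m, "wedge_mask"))
  if (length(unique(m$shape)) != 1)
    stop("rotated wedge masks require a cubic grid", call. = FALSE)
  am <- axis_map(g)
  n <- m$shape[1]
  idx <- lapply(1:3, function(a) if (am$neg[a]) c(1L, n:2L) else 1:n)
  u <- m$mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out <- m
  out$mask <- aperm(u, order(am$from))
  out
}

#' Apply the rotated projector A_g
#'
#' Equivalent to `apply_transform(g, apply_wedge(apply_transform(
#' group_inverse(g), v), m))` but implemented directly by rotating the
#' mask in frequency space (one FFT round trip instead of three index
#' permutations plus one round trip).
#'
#' @param g a `group_element`.
#' @param v cubic 3D array.
#' @param m a `wedge_mask`.
#' @return The projected volume.
#' @export
apply_rotated_wedge <- function(g, v, m) {
  assert_volume(v, cubic = TRUE)
  apply_wedge(v, rotate_wedge_mask(m, g))
}

#' Crop-and-embed operator C
#'
#' Extracts a cubic subtomogram and re-embeds it at the same position in
#' an otherwise zero volume, the form in which cropping can be compared
#' with the wedge projector (A C != C A in general; see
#' [crop_commutator_leakage()]).
#'
#' @param v 3D array.
#' @param corner 1-based corner (length 3) of the crop.
#' @param size crop edge length.
#' @return Volume of the same shape as `v`, zero outside the crop.
#' @export
crop_embed <- function(v, corner, size) {
  d <- dim(v)
  if (any(corner < 1) || any(corner + size - 1 > d))
    stop("crop outside volume bounds", call. = FALSE)
  out <- array(0, d)
  ix <- lapply(1:3, function(a) corner[a]:(corner[a] + size - 1))
  out[ix[[1]], ix[[2]], ix[[3]]] <- v[ix[[1]], ix[[2]], ix[[3]]]
  out
}

#' Energy of the crop/wedge commutator
#'
#' Quantifies the approximation made when the wedge projector is applied
#' to subtomograms rather than whole tomograms: the relative energy of
#' (A C - C A) v, which is nonzero because cropping convolves the
#' spectrum with a sinc that leaks into the wedge.
#'
#' @param v 3D array.
#' @param m a `wedge_mask` for `dim(v)`.
#' @param corner,size crop placement as in [crop_embed()].
#' @return `\|(AC - CA) v\|^2 / \|v\|^2`.
#' @export
crop_commutator_leakage <- function(v, m, corner, size) {
  ac <- apply_wedge(crop_embed(v, corner, size), m)
  ca <- crop_embed(apply_wedge(v, m), corner, size)
  relative_energy(ac - ca, v)
}
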