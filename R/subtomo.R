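# Tomogram-level normalisation, interest masks, paired subtomogram
# extraction (the crop operator) and tiling/blending for inference.
# Coordinates are 1-based with inclusive crop ranges, axis order (x, y, z),
# matching R array indexing throughout the package.

#' Normalise a tomogram to zero mean and unit standard deviation
#'
#' @param v 3D array with nonzero variance.
#' @return List with `v` (normalised volume) and `stats = c(mean, sd)`
#'   of the input for inverse mapping.
#' @export
normalize_tomogram <- function(v) {
  assert_volume(v)
  s <- sd(v)
  if (s == 0) stop("cannot normalise a zero-variance volume", call. = FALSE)
  m <- mean(v)
  list(v = (v - m) / s, stats = c(mean = m, sd = s))
}

#' Undo a tomogram normalisation
#'
#' @param v normalised volume.
#' @param stats the `c(mean, sd)` returned by [normalize_tomogram()].
#' @return Volume on the original intensity scale.
#' @export
denormalize_tomogram <- function(v, stats) v * stats[["sd"]] + stats[["mean"]]

# Box-filtered local mean via cumulative sums along each axis.
box_mean <- function(v, w) {
  half <- w %/% 2
  for (a in 1:3) {
    n <- dim(v)[a]
    cs <- apply(v, setdiff(1:3, a), cumsum)        # first dim = axis a
    hi <- pmin(seq_len(n) + half, n)
    lo <- pmax(seq_len(n) - half, 1) - 1
    counts <- hi - lo
    padded <- rbind(0, matrix(cs, nrow = n))
    sums <- padded[hi + 1, , drop = FALSE] - padded[lo + 1, , drop = FALSE]
    out <- array(sums / counts, c(n, dim(v)[setdiff(1:3, a)]))
    v <- aperm(out, order(c(a, setdiff(1:3, a))))
  }
  v
}

#' Build an interest mask for patch sampling
#'
#' Keeps a central slab along z (the physical sample slab) intersected
#' with voxels whose local standard deviation (cubic window) exceeds the
#' requested quantile of the in-slab distribution, a lightweight built-in
#' for avoiding pure-ice regions. User-supplied masks (e.g. from external
#' slab-detection tools) bypass this entirely via the `mask` argument.
#'
#' @param v 3D array.
#' @param z_fraction fraction of the z extent kept, centred (default 0.6).
#' @param density_quantile quantile of local standard deviation below
#'   which in-slab voxels are dropped (0 keeps the whole slab).
#' @param window cubic window edge for the local statistics.
#' @param mask optional user-provided binary mask, returned unchanged.
#' @return An `interest_mask` with fields `mask` (logical array) and
#'   `source`.
#' @export
build_interest_mask <- function(v, z_fraction = 0.6, density_quantile = 0.5,
                                window = 5, mask = NULL) {
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(v)))
      stop("user mask shape does not match the tomogram", call. = FALSE)
    return(structure(list(mask = mask != 0, source = "user-file"),
                     class = "interest_mask"))
  }
  assert_volume(v)
  d <- dim(v)
  nz <- d[3]
  keep <- max(1, round(z_fraction * nz))
  z0 <- floor((nz - keep) / 2) + 1
  slab <- array(FALSE, d)
  slab[, , z0:(z0 + keep - 1)] <- TRUE
  if (density_quantile <= 0) {
    out <- slab
  } else {
    mu <- box_mean(v, window)
    loc_sd <- sqrt(pmax(box_mean(v^2, window) - mu^2, 0))
    thr <- quantile(loc_sd[slab], density_quantile)
    out <- slab & (loc_sd > thr)
  }
  if (!any(out))
    stop("interest mask is empty; supply a manual mask", call. = FALSE)
  structure(list(mask = out, source = "auto"), class = "interest_mask")
}

#' Sample patch centres from an interest mask
#'
#' Draws positions uniformly over mask voxels whose full cubic patch fits
#' inside the volume. Deterministic given the seed; positions may repeat.
#'
#' @param m an `interest_mask` (or logical array).
#' @param n number of centres.
#' @param patch patch edge length.
#' @param seed integer seed.
#' @return Integer matrix `n x 3` of centre coordinates (1-based).
#' @export
sample_patch_centers <- function(m, n, patch, seed = 1) {
  a <- if (inherits(m, "interest_mask")) m$mask else m
  d <- dim(a)
  lo <- rep(floor(patch / 2) + 1, 3)
  hi <- d - (patch - floor(patch / 2) - 1)
  if (any(hi < lo))
    stop(sprintf("patch size %d does not fit in volume %s", patch,
                 paste(d, collapse = "x")), call. = FALSE)
  feas <- array(FALSE, d)
  feas[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  ok <- which(a & feas)
  if (length(ok) == 0)
    stop("no feasible patch centres inside the mask", call. = FALSE)
  withr::with_seed(seed, picks <- ok[sample.int(length(ok), n, replace = TRUE)])
  cbind((picks - 1) %% d[1],
        ((picks - 1) %/% d[1]) %% d[2],
        (picks - 1) %/% (d[1] * d[2])) + 1L
}

patch_range <- function(center, patch) {
  start <- center - floor(patch / 2)
  cbind(start, start + patch - 1)
}

crop_patch <- function(v, center, patch) {
  r <- patch_range(center, patch)
  if (any(r[, 1] < 1) || any(r[, 2] > dim(v)))
    stop("patch out of volume bounds", call. = FALSE)
  v[r[1, 1]:r[1, 2], r[2, 1]:r[2, 2], r[3, 1]:r[3, 2], drop = FALSE]
}

#' Extract a paired subtomogram
#'
#' Axis-aligned crops at identical positions from two aligned volumes
#' (no resampling).
#'
#' @param v0,v1 aligned volumes of equal shape.
#' @param center integer centre coordinates.
#' @param patch patch edge length.
#' @param x optional clean reference volume to crop alongside.
#' @return A `subtomogram_pair` with `y0`, `y1`, optional `x`, `center`.
#' @export
extract_pair <- function(v0, v1, center, patch, x = NULL) {
  stopifnot(all(dim(v0) == dim(v1)))
  structure(list(y0 = crop_patch(v0, center, patch),
                 y1 = crop_patch(v1, center, patch),
                 x = if (!is.null(x)) crop_patch(x, center, patch),
                 center = center, patch = patch),
            class = "subtomogram_pair")
}

# Per-axis blend window: raised cosine over the overlap margins, flat in
# the middle; margins touching the volume border stay flat so that the
# accumulated weight is bounded away from zero everywhere.
axis_window <- function(patch, taper, at_start, at_end) {
  w <- rep(1, patch)
  if (taper > 0) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(taper) - 0.5) / taper)
    if (!at_start) w[seq_len(taper)] <- ramp
    if (!at_end) w[patch + 1 - seq_len(taper)] <- ramp
  }
  w
}

#' Plan a tiling of a volume into overlapping patches
#'
#' Corners are placed at stride `patch - overlap` with a final corner
#' flush against each upper bound, so every voxel is covered. Each patch
#' carries a separable raised-cosine blend weight; after accumulation the
#' weights are renormalised voxelwise, making stitching an exact
#' partition of unity.
#'
#' @param shape volume dimensions.
#' @param patch patch edge length (<= every dimension).
#' @param overlap voxels of overlap between neighbouring patches
#'   (default `patch %/% 4`); must be < patch.
#' @return A `patch_grid`.
#' @export
tile_for_inference <- function(shape, patch, overlap = patch %/% 4) {
  shape <- as.integer(shape)
  if (any(patch > shape))
    stop(sprintf("patch %d exceeds volume %s", patch,
                 paste(shape, collapse = "x")), call. = FALSE)
  if (overlap >= patch) stop("overlap must be smaller than patch", call. = FALSE)
  stride <- patch - overlap
  corners_axis <- function(n) {
    cs <- seq(1L, max(n - patch + 1L, 1L), by = stride)
    if (cs[length(cs)] != n - patch + 1L) cs <- c(cs, n - patch + 1L)
    cs
  }
  ax <- lapply(shape, corners_axis)
  corners <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  colnames(corners) <- NULL
  structure(list(shape = shape, patch = as.integer(patch),
                 overlap = as.integer(overlap), corners = corners),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch grid: %d patches of %d^3 over %s (overlap %d)>\n",
              nrow(x$corners), x$patch, paste(x$shape, collapse = "x"),
              x$overlap))
  invisible(x)
}

grid_weights <- function(grid, corner) {
  taper <- grid$overlap
  ws <- lapply(1:3, function(a)
    axis_window(grid$patch, taper, corner[a] == 1,
                corner[a] + grid$patch - 1 == grid$shape[a]))
  outer(outer(ws[[1]], ws[[2]]), ws[[3]])
}

#' Extract the patches of a tiling
#'
#' @param v volume matching the grid's shape.
#' @param grid a [tile_for_inference()] grid.
#' @return List of patch arrays, in corner order.
#' @export
extract_patches <- function(v, grid) {
  lapply(seq_len(nrow(grid$corners)), function(i) {
    cr <- grid$corners[i, ]
    v[cr[1]:(cr[1] + grid$patch - 1), cr[2]:(cr[2] + grid$patch - 1),
      cr[3]:(cr[3] + grid$patch - 1), drop = FALSE]
  })
}

#' Blend processed patches back into a volume
#'
#' @param patches list of patch arrays in the grid's corner order.
#' @param grid the [tile_for_inference()] grid used to extract them.
#' @return Blended volume of the grid's shape (weights sum to one
#'   everywhere, so an identity mapping is reproduced exactly).
#' @export
blend_patches <- function(patches, grid) {
  acc <- array(0, grid$shape)
  wacc <- array(0, grid$shape)
  for (i in seq_len(nrow(grid$corners))) {
    cr <- grid$corners[i, ]
    w <- grid_weights(grid, cr)
    ix <- lapply(1:3, function(a) cr[a]:(cr[a] + grid$patch - 1))
    acc[ix[[1]], ix[[2]], ix[[3]]] <-
      acc[ix[[1]], ix[[2]], ix[[3]]] + patches[[i]] * w
    wacc[ix[[1]], ix[[2]], ix[[3]]] <- wacc[ix[[1]], ix[[2]], ix[[3]]] + w
  }
  acc / wacc
}
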