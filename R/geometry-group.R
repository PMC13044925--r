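# The finite symmetry group used for equivariant augmentation: signed
# permutation matrices acting on cubic voxel grids by pure index
# rearrangement, so no interpolation ever touches the data.

#' Construct a group element from a signed permutation matrix
#'
#' @param m 3x3 matrix with entries in {-1, 0, 1}, exactly one nonzero
#'   entry per row and column.
#' @return A `group_element` with fields `matrix`, `is_flip` (determinant
#'   -1) and a stable `label`.
#' @export
group_element <- function(m) {
  m <- matrix(as.integer(m), 3, 3)
  if (!all(m %in% c(-1L, 0L, 1L)) ||
      !all(colSums(m != 0) == 1) || !all(rowSums(m != 0) == 1))
    stop("not a signed permutation matrix", call. = FALSE)
  det <- round(det(m))
  perm <- apply(m != 0, 2, which)          # row of the nonzero in column j
  signs <- m[cbind(perm, 1:3)]
  label <- paste0(ifelse(det < 0, "f", "r"),
                  paste0(perm, collapse = ""),
                  paste0(ifelse(signs < 0, "m", "p"), collapse = ""))
  structure(list(matrix = m, is_flip = det < 0, label = label),
            class = "group_element")
}

#' @export
print.group_element <- function(x, ...) {
  cat(sprintf("<group element %s, det = %+d>\n", x$label,
              ifelse(x$is_flip, -1L, 1L)))
  print(x$matrix)
  invisible(x)
}

#' Inverse of a group element
#'
#' For orthogonal matrices the inverse is the transpose.
#'
#' @param g a `group_element`.
#' @return The inverse `group_element`.
#' @export
group_inverse <- function(g) group_element(t(g$matrix))

#' Compose two group elements
#'
#' @param g,h `group_element`s; the result applies `h` first, then `g`.
#' @return Their composition as a `group_element`.
#' @export
group_compose <- function(g, h) group_element(g$matrix %*% h$matrix)

all_signed_permutations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      m <- matrix(0L, 3, 3)
      m[cbind(p, 1:3)] <- as.integer(c(s1, s2, s3))
      out[[length(out) + 1]] <- m
    }
  out
}

#' Build the 40-element augmentation group
#'
#' Enumerates the rotations of a cube that act on a cubic voxel grid
#' without interpolation: the 24 proper cube rotations minus the identity
#' and the three axis-aligned 180-degree rotations, leaving 20 proper
#' elements; each is also composed with a fixed mirror (reversal of the
#' first axis), giving 20 improper elements, 40 in total. Ordering is
#' lexicographic over (permutation, signs) and frozen, so seeded sampling
#' is reproducible.
#'
#' @return A `rotation_group`: an ordered list of 40 `group_element`s.
#' @export
#' @examples
#' G <- build_group()
#' length(G$elements)
build_group <- function() {
  mirror <- diag(c(-1L, 1L, 1L))
  excluded <- list(diag(3L), diag(c(1L, -1L, -1L)),
                   diag(c(-1L, 1L, -1L)), diag(c(-1L, -1L, 1L)))
  rots <- Filter(function(m) round(det(m)) == 1 &&
                   !any(vapply(excluded, function(e) all(e == m), TRUE)),
                 all_signed_permutations())
  stopifnot(length(rots) == 20)
  elements <- c(lapply(rots, group_element),
                lapply(rots, function(m) group_element(m %*% mirror)))
  structure(list(elements = elements), class = "rotation_group")
}

#' @export
print.rotation_group <- function(x, ...) {
  dets <- vapply(x$elements, function(g) ifelse(g$is_flip, -1L, 1L), 1L)
  cat(sprintf("<rotation group: %d elements (%d proper, %d improper)>\n",
              length(x$elements), sum(dets == 1), sum(dets == -1)))
  invisible(x)
}

#' Sample group elements uniformly
#'
#' @param group a `rotation_group`.
#' @param n number of draws.
#' @return List of `group_element`s drawn uniformly with replacement from
#'   the current RNG stream.
#' @export
sample_group <- function(group, n = 1) {
  group$elements[sample.int(length(group$elements), n, replace = TRUE)]
}

# Axis bookkeeping shared by the real-space and frequency-space actions:
# for output voxel x' = g x, input axis a reads output axis `from[a]`,
# negated when `neg[a]`. (Column a of g has its nonzero in row from[a].)
axis_map <- function(g) {
  m <- g$matrix
  from <- apply(m != 0, 2, which)
  neg <- m[cbind(from, 1:3)] < 0
  list(from = from, neg = neg)
}

#' Apply a group element to a cubic volume
#'
#' Rotates/flips the voxel grid about the patch centre `(N - 1) / 2`
#' (0-based), realised as an axis permutation plus axis reversals. The
#' operation is a pure index permutation: the multiset of voxel values is
#' preserved bitwise, for even and odd edge lengths alike.
#'
#' @param g a `group_element`.
#' @param v cubic 3D array.
#' @return The transformed volume, same dimensions.
#' @export
apply_transform <- function(g, v) {
  assert_volume(v, cubic = TRUE)
  am <- axis_map(g)
  n <- dim(v)[1]
  # per-output-axis offset tables into the flattened input: input axis a
  # reads output axis am$from[a], reversed when am$neg[a]
  offs <- vector("list", 3)
  for (a in 1:3) {
    j <- 0:(n - 1)
    contrib <- if (am$neg[a]) (n - 1 - j) * n^(a - 1) else j * n^(a - 1)
    offs[[am$from[a]]] <- as.integer(contrib)
  }
  .sperm3(v, offs[[1]], offs[[2]], offs[[3]])
}
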