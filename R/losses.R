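# The two training criteria: the Noise2Noise data-fidelity loss and the
# rotation-equivariance loss with plug-in targets and double network
# application, plus their combination.
#
# Loss functions accept either an `et_network` or any plain function
# mapping a patch to a same-shaped patch, so operator-level identities
# can be tested with, e.g., the identity mapping.

as_predictor <- function(f) {
  if (inherits(f, "et_network")) function(v) network_forward(f, v)$y else f
}

#' Loss configuration
#'
#' @param lambda weight of the equivariance term (> 0, default 2).
#' @param mask_original_wedge mask the equivariance residual with the
#'   rotated projector A_g before taking the norm (default TRUE; with
#'   FALSE the term reduces to the plain equivariant-imaging loss).
#' @param swap_augment exploit the symmetry of the two observations:
#'   the standalone losses average both assignment directions; the
#'   training loop draws a random direction per example.
#' @param detach_plugin treat the plug-in target as a constant (no
#'   gradient through its network application); ablation switch, off by
#'   default so gradients flow through both applications.
#' @return A `loss_config`.
#' @export
loss_config <- function(lambda = 2, mask_original_wedge = TRUE,
                        swap_augment = TRUE, detach_plugin = FALSE) {
  stopifnot(lambda >= 0)
  structure(list(lambda = lambda,
                 mask_original_wedge = isTRUE(mask_original_wedge),
                 swap_augment = isTRUE(swap_augment),
                 detach_plugin = isTRUE(detach_plugin)),
            class = "loss_config")
}

#' Noise2Noise data-fidelity loss
#'
#' Mean squared difference between the network output on one observation
#' and the other observation; with `swap_augment` the symmetrised
#' average over both directions.
#'
#' @param f an `et_network` or a patch-to-patch function.
#' @param pair a `subtomogram_pair` (fields `y0`, `y1`).
#' @param cfg a [loss_config()].
#' @return Scalar loss.
#' @export
n2n_loss <- function(f, pair, cfg = loss_config()) {
  fp <- as_predictor(f)
  l01 <- mean((fp(pair$y0) - pair$y1)^2)
  if (!cfg$swap_augment) return(l01)
  (l01 + mean((fp(pair$y1) - pair$y0)^2)) / 2
}

# One direction of the equivariance residual: corrupt the rotated plug-in
# estimate of the source, denoise again, compare with the rotated plug-in
# estimate of the target; optionally mask with the rotated wedge support.
equi_residual <- function(fp, src, tgt, g, m, cfg) {
  xs <- fp(src)
  xt <- fp(tgt)
  u <- apply_wedge(apply_transform(g, xs), m)
  r <- fp(u) - apply_transform(g, xt)
  if (cfg$mask_original_wedge) r <- apply_rotated_wedge(g, r, m)
  r
}

#' Rotation-equivariance loss
#'
#' Uses the current network output as a plug-in estimate of the clean
#' subtomogram: the rotated estimate from one observation is
#' re-corrupted with the wedge projector, passed through the network a
#' second time, and compared with the rotated estimate from the other
#' observation; the residual is masked with the rotated projector A_g
#' when `mask_original_wedge` is set. Symmetrised over the observation
#' swap when `swap_augment` is set.
#'
#' @param f an `et_network` or a patch-to-patch function.
#' @param pair a `subtomogram_pair` of cubic patches.
#' @param g a `group_element`.
#' @param m a `wedge_mask` matching the patch.
#' @param cfg a [loss_config()].
#' @return Scalar loss.
#' @export
equivariance_loss <- function(f, pair, g, m, cfg = loss_config()) {
  assert_volume(pair$y0, cubic = TRUE)
  fp <- as_predictor(f)
  l01 <- mean(equi_residual(fp, pair$y0, pair$y1, g, m, cfg)^2)
  if (!cfg$swap_augment) return(l01)
  (l01 + mean(equi_residual(fp, pair$y1, pair$y0, g, m, cfg)^2)) / 2
}

#' Combined training objective
#'
#' Data-fidelity plus `lambda` times the equivariance term.
#'
#' @inheritParams equivariance_loss
#' @return Scalar loss.
#' @export
total_loss <- function(f, pair, g, m, cfg = loss_config()) {
  n2n_loss(f, pair, cfg) + cfg$lambda * equivariance_loss(f, pair, g, m, cfg)
}
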