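#' Control parameters for the distillation operators
#'
#' Collects the numerical knobs shared by the feature-level and pixel-level
#' distillation losses.
#'
#' @param attention_exponent Positive exponent `p` used when aggregating
#'   absolute activations across channels (`sum_c |z|^p`). Default 1.
#' @param interp_mode Interpolation used for all spatial rescaling; only
#'   `"bilinear"` (half-pixel-centre, constant-preserving) is implemented.
#' @param eps Guard added to the L2-normalisation denominator of attention
#'   vectors so an all-zero map yields a zero vector instead of 0/0.
#' @param norm Norm of the difference between normalised attention vectors,
#'   `"L2"` (default) or `"L1"`.
#' @param kl_direction `"student_first"` (default) computes
#'   `KL(student || teacher)` as the pixel-level losses are written;
#'   `"teacher_first"` gives the classic distillation direction.
#' @param kl_eps Smoothing added inside the KL log ratio.
#' @param temperature Softmax temperature applied to student logits before
#'   the pixel-level losses. Default 1 (no scaling).
#' @return A list of class `hlfd_control`.
#' @export
hlfd_control <- function(attention_exponent = 1, interp_mode = "bilinear",
                         eps = 1e-8, norm = c("L2", "L1"),
                         kl_direction = c("student_first", "teacher_first"),
                         kl_eps = 1e-8, temperature = 1) {
  if (attention_exponent <= 0) stop_hlfd("attention_exponent must be positive")
  if (!identical(interp_mode, "bilinear")) stop_hlfd("only bilinear interpolation is implemented")
  if (eps <= 0 || kl_eps <= 0) stop_hlfd("eps guards must be positive")
  if (temperature <= 0) stop_hlfd("temperature must be positive")
  structure(list(attention_exponent = attention_exponent, interp_mode = interp_mode,
                 eps = eps, norm = match.arg(norm),
                 kl_direction = match.arg(kl_direction), kl_eps = kl_eps,
                 temperature = temperature),
            class = "hlfd_control")
}

#' Weights and hyper-parameters of the multi-task objective
#'
#' `beta` scales the feature-level distillation loss and `lambda` the
#' pixel-level one in the combined objective
#' `total = seg + beta * (ufd + ifd) + lambda * (upd + ipd)`.
#' Defaults follow the sensitivity analysis of the method: `beta = 0.9`,
#' `lambda = 0.1`, keeping the feature-level term dominant.
#'
#' @param beta Nonnegative weight of the feature-level distillation loss.
#' @param lambda Nonnegative weight of the pixel-level distillation loss.
#' @param focal_gamma Focusing exponent of the focal term of the supervised
#'   loss; 2 concentrates the loss on hard pixels.
#' @param dice_eps Additive smoothing of the soft-dice ratio (default 1).
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(beta = 0.9, lambda = 0.1, focal_gamma = 2, dice_eps = 1) {
  if (!is.finite(beta) || beta < 0) stop_hlfd("beta must be finite and >= 0")
  if (!is.finite(lambda) || lambda < 0) stop_hlfd("lambda must be finite and >= 0")
  if (!is.finite(focal_gamma) || focal_gamma < 0) stop_hlfd("focal_gamma must be finite and >= 0")
  if (dice_eps <= 0) stop_hlfd("dice_eps must be positive")
  structure(list(beta = beta, lambda = lambda, focal_gamma = focal_gamma,
                 dice_eps = dice_eps),
            class = "loss_weights")
}
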