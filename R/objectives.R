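## Supervised focal-dice loss and the combined multi-task objective.

#' Supervised focal-dice segmentation loss
#'
#' Sum of a focal cross-entropy term,
#' `-mean_px (1 - p_true)^gamma * log(p_true + eps)`, and a soft-dice term,
#' `1 - (2 * sum(p_fg * g) + eps_d) / (sum(p_fg) + sum(g) + eps_d)`, where
#' `p_true` is the predicted probability of each pixel's true class, `p_fg`
#' the predicted foreground probability and `g` the binary mask. The focal
#' exponent concentrates the loss on hard pixels; the dice term directly
#' optimises overlap and is robust to foreground/background imbalance.
#'
#' @param logits Class-logit array (2 x H x W); channel 1 is background,
#'   channel 2 foreground. An H x W matrix is taken as the foreground logit
#'   with an implicit zero background logit.
#' @param mask Binary H x W matrix (1 = foreground).
#' @param weights A [loss_weights()] list supplying `focal_gamma` and
#'   `dice_eps`.
#' @param eps Smoothing inside the focal log.
#' @return Nonnegative scalar.
#' @export
focal_dice_loss <- function(logits, mask, weights = loss_weights(), eps = 1e-8) {
  if (is.matrix(logits)) {
    l <- array(0, c(2, dim(logits)))
    l[2, , ] <- logits
    logits <- l
  }
  l <- as_pm_values(logits, "logits")
  if (dim(l)[1] != 2L) stop_hlfd("focal_dice_loss expects 2-class logits")
  if (!all(dim(l)[2:3] == dim(mask)))
    stop_hlfd("logits (%s) and mask (%s) are not spatially aligned",
              paste(dim(l)[2:3], collapse = "x"), paste(dim(mask), collapse = "x"))
  if (!all(mask %in% c(0, 1))) stop_hlfd("mask must contain only 0 and 1")
  p <- softmax_chw(l)
  pfg <- p[2, , ]
  ptrue <- pfg * mask + (1 - pfg) * (1 - mask)
  focal <- -mean(pmax(1 - ptrue, 0)^weights$focal_gamma * log(ptrue + eps))
  dice <- 1 - (2 * sum(pfg * mask) + weights$dice_eps) /
    (sum(pfg) + sum(mask) + weights$dice_eps)
  focal + dice
}

#' Combine loss components into the multi-task objective
#'
#' `total = seg + beta * (ufd + ifd) + lambda * (upd + ipd)`: the supervised
#' focal-dice loss plus the weighted feature-level and pixel-level
#' distillation losses. With `beta = lambda = 0` the objective reduces to
#' plain supervised segmentation.
#'
#' @param seg Supervised focal-dice loss value.
#' @param ufd,ifd Feature-level components (see [ufd_loss()], [ifd_loss()]).
#' @param upd,ipd Pixel-level components (see [upd_loss()], [ipd_loss()]).
#' @param weights A [loss_weights()] list.
#' @return An object of class `loss_breakdown`: the five components, the
#'   weights, and the combined `total`.
#' @examples
#' hlfd_loss(1, 2, 0, 3, 0, loss_weights(beta = 0.9, lambda = 0.1))$total  # 3.1
#' @export
hlfd_loss <- function(seg, ufd, ifd, upd, ipd, weights = loss_weights()) {
  comp <- c(seg = seg, ufd = ufd, ifd = ifd, upd = upd, ipd = ipd)
  bad <- names(comp)[!is.finite(comp)]
  if (length(bad)) stop_hlfd("non-finite loss component: %s", paste(bad, collapse = ", "))
  total <- seg + weights$beta * (ufd + ifd) + weights$lambda * (upd + ipd)
  structure(list(seg = seg, ufd = ufd, ifd = ifd, upd = upd, ipd = ipd,
                 beta = weights$beta, lambda = weights$lambda, total = total),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("seg %.4f | ufd %.4f ifd %.4f (beta %.2f) | upd %.4f ipd %.4f (lambda %.2f) | total %.4f\n",
              x$seg, x$ufd, x$ifd, x$beta, x$upd, x$ipd, x$lambda, x$total))
  invisible(x)
}

#' @export
as.data.frame.loss_breakdown <- function(x, ...) {
  data.frame(seg = x$seg, ufd = x$ufd, ifd = x$ifd, upd = x$upd, ipd = x$ipd,
             total = x$total)
}
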