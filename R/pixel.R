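## Pixel-level layer-selective feedback distillation: teacher decoder
## predictive maps, student auxiliary maps, and the UPD / IPD KL losses.

softmax_chw <- function(logits, temperature = 1) {
  l <- as_pm_values(logits, "logits") / temperature
  m <- apply(l, c(2, 3), max)
  for (k in seq_len(dim(l)[1])) l[k, , ] <- l[k, , ] - m
  e <- exp(l)
  s <- apply(e, c(2, 3), sum)
  for (k in seq_len(dim(l)[1])) e[k, , ] <- e[k, , ] / s
  e
}

resize_chw <- function(x, h, w) {
  d <- dim(x)
  if (d[2] == h && d[3] == w) return(x)
  out <- array(0, c(d[1], h, w))
  for (k in seq_len(d[1])) out[k, , ] <- resize2d(x[k, , , drop = TRUE], h, w)
  out
}

#' Unify the teacher's middle predictive maps
#'
#' Resamples each middle-layer probability map to `target_shape`, averages
#' them across layers and renormalises per pixel, producing a single
#' probability map on the simplex (averaging, unlike channel concatenation,
#' keeps class maps type-valid).
#'
#' @param mids Non-empty list of `prob_map`s with a common class count.
#' @param target_shape `(height, width)` of the unified map; defaults to the
#'   smallest spatial size among the inputs.
#' @return A `prob_map`.
#' @export
unify_teacher_mid_probs <- function(mids, target_shape = NULL) {
  if (!length(mids)) stop_hlfd("unify_teacher_mid_probs needs a non-empty list")
  vals <- lapply(mids, as_pm_values)
  ks <- vapply(vals, function(v) dim(v)[1], integer(1))
  if (length(unique(ks)) != 1L) stop_hlfd("middle predictive maps disagree on class count")
  if (is.null(target_shape))
    target_shape <- c(min(vapply(vals, function(v) dim(v)[2], integer(1))),
                      min(vapply(vals, function(v) dim(v)[3], integer(1))))
  acc <- array(0, c(ks[1], target_shape))
  for (v in vals) acc <- acc + resize_chw(v, target_shape[1], target_shape[2])
  acc <- acc / length(vals)
  s <- apply(acc, c(2, 3), sum)
  for (k in seq_len(ks[1])) acc[k, , ] <- acc[k, , ] / s
  prob_map(acc)
}

#' Pixel-wise KL divergence between probability maps
#'
#' `mean_px sum_k p_s[k] log((p_s[k]+eps)/(p_t[k]+eps))` in nats, averaged
#' over pixels so the value is resolution-independent. Nonnegative (up to
#' the eps smoothing), zero when the maps coincide.
#'
#' @param p_student,p_teacher `prob_map`s of identical shape.
#' @param eps Smoothing inside the log ratio.
#' @return Nonnegative scalar.
#' @examples
#' p <- prob_map(array(c(1, 0), c(2, 1, 1)))
#' q <- prob_map(array(c(0.5, 0.5), c(2, 1, 1)))
#' kl_pixelwise(p, q)  # log 2
#' @export
kl_pixelwise <- function(p_student, p_teacher, eps = 1e-8) {
  ps <- as_pm_values(p_student, "student map")
  pt <- as_pm_values(p_teacher, "teacher map")
  if (!all(dim(ps) == dim(pt)))
    stop_hlfd("probability maps disagree in shape: %s vs %s",
              paste(dim(ps), collapse = "x"), paste(dim(pt), collapse = "x"))
  sum(ps * log((ps + eps) / (pt + eps))) / prod(dim(ps)[2:3])
}

kl_directed <- function(ps, pt, control) {
  if (control$kl_direction == "student_first") kl_pixelwise(ps, pt, control$kl_eps)
  else kl_pixelwise(pt, ps, control$kl_eps)
}

#' Unified pixel-level distillation loss
#'
#' Rescales the student's early auxiliary logits to the teacher map's grid,
#' applies the per-pixel softmax, and takes the pixel-wise KL divergence
#' against the teacher's unified middle predictive map.
#'
#' @param student_early_logits Class-logit array (K x h x w) from the
#'   student's early auxiliary head.
#' @param teacher_mid_probs Unified teacher middle `prob_map`
#'   (see [unify_teacher_mid_probs()]).
#' @param control An [hlfd_control()] list.
#' @return Nonnegative scalar.
#' @export
upd_loss <- function(student_early_logits, teacher_mid_probs, control = hlfd_control()) {
  pt <- as_pm_values(teacher_mid_probs, "teacher map")
  l <- as_pm_values(student_early_logits, "student logits")
  ps <- softmax_chw(resize_chw(l, dim(pt)[2], dim(pt)[3]), control$temperature)
  kl_directed(ps, pt, control)
}

#' Individual pixel-level distillation loss
#'
#' Mean over the student's middle auxiliary maps of the pixel-wise KL
#' divergence between each (rescaled, softmaxed) map and the teacher's
#' terminal predictive map. Note the 1/N averaging over layers, in contrast
#' to the feature-level counterpart [ifd_loss()] which sums.
#'
#' @param student_mid_logits Non-empty list of class-logit arrays from the
#'   student's middle auxiliary heads.
#' @param p_late_t Teacher terminal `prob_map`.
#' @param control An [hlfd_control()] list.
#' @return Nonnegative scalar.
#' @export
ipd_loss <- function(student_mid_logits, p_late_t, control = hlfd_control()) {
  if (!length(student_mid_logits)) stop_hlfd("ipd_loss needs a non-empty list of student middle maps")
  pt <- as_pm_values(p_late_t, "teacher map")
  mean(vapply(student_mid_logits, function(l) {
    l <- as_pm_values(l, "student logits")
    ps <- softmax_chw(resize_chw(l, dim(pt)[2], dim(pt)[3]), control$temperature)
    kl_directed(ps, pt, control)
  }, numeric(1)))
}

#' Combined pixel-level distillation loss
#'
#' `upd + ipd`: the teacher's unified middle predictive maps supervise the
#' student's early auxiliary map, and the teacher's terminal predictive map
#' supervises each student middle auxiliary map.
#'
#' @param student_aux List with elements `early` (logit array) and `mids`
#'   (list of logit arrays), as returned by the student forward pass.
#' @param teacher_bundle Teacher `pred_bundle`.
#' @param control An [hlfd_control()] list.
#' @return Nonnegative scalar.
#' @export
plfd_loss <- function(student_aux, teacher_bundle, control = hlfd_control()) {
  pmid <- unify_teacher_mid_probs(teacher_bundle$mids)
  upd_loss(student_aux$early, pmid, control) +
    ipd_loss(student_aux$mids, teacher_bundle$late, control)
}
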