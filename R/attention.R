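## Feature-level layer-selective feedback distillation: the attention
## operator, the unified middle representation, and the UFD / IFD losses.

#' Channel-aggregated attention map of a feature map
#'
#' Aggregates absolute activations across channels,
#' `a[h, w] = sum_c |z[c, h, w]|^p`, on the premise that the magnitude of a
#' neuron activation signals its importance. The result is a nonnegative
#' single-channel spatial map showing where the layer "looks".
#'
#' @param f A `feature_map` or 3-D array (C x H x W).
#' @param exponent Positive aggregation exponent `p` (default 1).
#' @return A nonnegative H x W matrix.
#' @examples
#' f <- array(c(1, -1, 0, 2, -1, 1, 0, 0), c(2, 2, 2))
#' attention_map(f)  # elementwise sum of absolute channel activations
#' @export
attention_map <- function(f, exponent = 1) {
  v <- as_fm_values(f)
  if (exponent <= 0) stop_hlfd("attention exponent must be positive")
  a <- abs(v)
  if (exponent != 1) a <- a^exponent
  apply(a, c(2, 3), sum)
}

#' Unified middle representation
#'
#' Resamples every middle-layer feature map to the smallest spatial size
#' among them and concatenates the results along the channel dimension, in
#' input order. This single tensor summarises all middle layers and is the
#' teacher-side source of the unified feature-level loss.
#'
#' @param mids Non-empty list of `feature_map`s (or 3-D arrays).
#' @param mode Interpolation mode; only `"bilinear"` is implemented.
#' @return A `feature_map` whose channel count is the sum of the inputs'.
#' @export
unify_mids <- function(mids, mode = "bilinear") {
  if (!length(mids)) stop_hlfd("unify_mids needs a non-empty list of middle layers")
  if (!identical(mode, "bilinear")) stop_hlfd("only bilinear interpolation is implemented")
  vals <- lapply(mids, as_fm_values)
  hs <- vapply(vals, function(v) dim(v)[2], integer(1))
  ws <- vapply(vals, function(v) dim(v)[3], integer(1))
  h <- min(hs); w <- min(ws)
  res <- lapply(vals, function(v) {
    if (dim(v)[2] == h && dim(v)[3] == w) return(v)
    out <- array(0, c(dim(v)[1], h, w))
    for (c in seq_len(dim(v)[1])) out[c, , ] <- resize2d(v[c, , , drop = TRUE], h, w)
    out
  })
  total_c <- sum(vapply(res, function(v) dim(v)[1], integer(1)))
  out <- array(0, c(total_c, h, w))
  at <- 0L
  for (v in res) {
    out[at + seq_len(dim(v)[1]), , ] <- v
    at <- at + dim(v)[1]
  }
  feature_map(out, "unified_mid")
}

#' Rescaled, unit-L2-normalised attention vector
#'
#' Computes [attention_map()], bilinearly resamples it to `target_shape`,
#' flattens it and divides by `max(L2 norm, eps)`. Nonzero maps therefore
#' yield unit vectors; an all-zero map passes through the guard as a zero
#' vector. The output is scale-invariant: multiplying the feature map by any
#' `c > 0` leaves it unchanged.
#'
#' @param f A `feature_map` or 3-D array.
#' @param target_shape Integer `(height, width)` of the comparison grid.
#' @param exponent Channel-aggregation exponent.
#' @param eps Normalisation guard.
#' @return An object of class `attention_vector` with fields `values`
#'   (flattened map) and `source_shape`.
#' @export
normalized_attention <- function(f, target_shape = NULL, exponent = 1, eps = 1e-8) {
  a <- attention_map(f, exponent)
  if (is.null(target_shape)) target_shape <- dim(a)
  if (any(target_shape < 1)) stop_hlfd("target_shape must be positive")
  if (!all(dim(a) == target_shape)) a <- resize2d(a, target_shape[1], target_shape[2])
  v <- as.numeric(a)
  v <- v / max(sqrt(sum(v^2)), eps)
  structure(list(values = v, source_shape = as.integer(target_shape)),
            class = "attention_vector")
}

att_vec_distance <- function(va, vb, norm = "L2") {
  d <- va$values - vb$values
  if (norm == "L2") sqrt(sum(d^2)) else sum(abs(d))
}

#' Unified feature-level distillation loss
#'
#' Distance between the normalised attention vector of the student's early
#' representation (rescaled to the teacher grid) and that of the teacher's
#' unified middle representation. Zero iff the two attention patterns
#' coincide; at most 2 for the default L2 norm (unit vectors).
#'
#' @param z_early_s Student early `feature_map`.
#' @param z_mid_t Teacher unified middle `feature_map` (see [unify_mids()]).
#' @param control An [hlfd_control()] list.
#' @return Nonnegative scalar.
#' @export
ufd_loss <- function(z_early_s, z_mid_t, control = hlfd_control()) {
  shape_t <- fm_shape(z_mid_t)
  vs <- normalized_attention(z_early_s, shape_t, control$attention_exponent, control$eps)
  vt <- normalized_attention(z_mid_t, shape_t, control$attention_exponent, control$eps)
  att_vec_distance(vs, vt, control$norm)
}

#' Individual feature-level distillation loss
#'
#' Sum over the student's middle layers of the attention distance between
#' each middle representation (rescaled to the teacher's terminal grid) and
#' the teacher's terminal representation. Note the sum over layers, in
#' contrast to the pixel-level counterpart [ipd_loss()] which averages.
#'
#' @param mids_s Non-empty list of student middle `feature_map`s.
#' @param z_late_t Teacher terminal `feature_map`.
#' @param control An [hlfd_control()] list.
#' @return Nonnegative scalar.
#' @export
ifd_loss <- function(mids_s, z_late_t, control = hlfd_control()) {
  if (!length(mids_s)) stop_hlfd("ifd_loss needs a non-empty list of student middle layers")
  shape_t <- fm_shape(z_late_t)
  vt <- normalized_attention(z_late_t, shape_t, control$attention_exponent, control$eps)
  sum(vapply(mids_s, function(m) {
    vs <- normalized_attention(m, shape_t, control$attention_exponent, control$eps)
    att_vec_distance(vs, vt, control$norm)
  }, numeric(1)))
}

#' Combined feature-level distillation loss
#'
#' `ufd + ifd`: the teacher's unified middle layers supervise the student's
#' early layer, and the teacher's terminal layer supervises each student
#' middle layer.
#'
#' @param reps_s,reps_t Student and teacher `rep_bundle`s.
#' @param control An [hlfd_control()] list.
#' @return Nonnegative scalar.
#' @export
flfd_loss <- function(reps_s, reps_t, control = hlfd_control()) {
  zmid_t <- unify_mids(reps_t$mids, control$interp_mode)
  ufd_loss(reps_s$early, zmid_t, control) + ifd_loss(reps_s$mids, reps_t$late, control)
}
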