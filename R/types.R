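## Domain containers: feature maps, representation bundles, probability maps
## and predictive-map bundles. All are lightweight classed lists over base
## arrays; feature maps are channel-first (C x H x W).

#' Create a feature map
#'
#' A feature map holds the activations of one network layer as a
#' channels x height x width array together with a layer tag.
#'
#' @param values Numeric 3-D array (channels x height x width), all finite.
#'   A matrix is promoted to a single-channel map.
#' @param layer_id Character tag naming the layer the activations came from.
#' @return An object of class `feature_map`.
#' @examples
#' fm <- feature_map(array(rnorm(2 * 4 * 4), c(2, 4, 4)), "early")
#' dim(fm$values)
#' @export
feature_map <- function(values, layer_id = "") {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  if (length(dim(values)) != 3L) stop_hlfd("feature_map values must be a 3-D array (C x H x W)")
  if (any(dim(values) < 1L)) stop_hlfd("feature_map dimensions must all be >= 1")
  check_finite(values, "feature map")
  structure(list(values = values, layer_id = as.character(layer_id)),
            class = "feature_map")
}

as_fm_values <- function(f, what = "feature map") {
  if (inherits(f, "feature_map")) return(f$values)
  if (is.matrix(f)) f <- array(f, c(1L, dim(f)))
  if (!is.array(f) || length(dim(f)) != 3L) stop_hlfd("%s must be a feature_map or 3-D array", what)
  check_finite(f, what)
  f
}

fm_shape <- function(f) dim(as_fm_values(f))[2:3]

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_map '%s': %d channels, %d x %d>\n", x$layer_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Bundle encoder representations tapped at early, middle and late stages
#'
#' @param early,late `feature_map`s from the first and last encoder stages.
#' @param mids List of `feature_map`s from the intermediate stages, ordered
#'   from shallow to deep; spatial size must be non-increasing along
#'   early -> mids -> late (encoder downsampling).
#' @return An object of class `rep_bundle`.
#' @export
rep_bundle <- function(early, mids, late) {
  if (!length(mids)) stop_hlfd("rep_bundle requires at least one middle tap")
  sizes <- rbind(fm_shape(early), do.call(rbind, lapply(mids, fm_shape)), fm_shape(late))
  if (any(diff(sizes[, 1]) > 0) || any(diff(sizes[, 2]) > 0))
    stop_hlfd("rep_bundle spatial sizes must be non-increasing from early to late")
  structure(list(early = early, mids = mids, late = late), class = "rep_bundle")
}

#' @export
print.rep_bundle <- function(x, ...) {
  cat(sprintf("<rep_bundle: early %s, %d mids, late %s>\n",
              paste(fm_shape(x$early), collapse = "x"), length(x$mids),
              paste(fm_shape(x$late), collapse = "x")))
  invisible(x)
}

#' Create a per-pixel class-probability map
#'
#' @param values Numeric 3-D array (classes x height x width); entries in
#'   `[0, 1]` with per-pixel class sums equal to 1 (tolerance `1e-6`).
#' @return An object of class `prob_map`.
#' @export
prob_map <- function(values) {
  if (length(dim(values)) != 3L) stop_hlfd("prob_map values must be a 3-D array (K x H x W)")
  check_finite(values, "probability map")
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9)
    stop_hlfd("probability map entries must lie in [0, 1]")
  sums <- apply(values, c(2, 3), sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop_hlfd("per-pixel class probabilities must sum to 1 (max deviation %.3g)",
              max(abs(sums - 1)))
  structure(list(values = values), class = "prob_map")
}

as_pm_values <- function(p, what = "probability map") {
  if (inherits(p, "prob_map")) return(p$values)
  if (!is.array(p) || length(dim(p)) != 3L) stop_hlfd("%s must be a prob_map or 3-D array", what)
  p
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<prob_map: %d classes, %d x %d>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Bundle decoder predictive maps at early, middle and late scales
#'
#' @param early,late `prob_map`s at the full-resolution and coarsest decoder
#'   taps respectively.
#' @param mids List of `prob_map`s at the intermediate decoder taps.
#' @return An object of class `pred_bundle`. All members must share the same
#'   class count.
#' @export
pred_bundle <- function(early, mids, late) {
  all_maps <- c(list(early), mids, list(late))
  ks <- vapply(all_maps, function(p) dim(as_pm_values(p))[1], integer(1))
  if (length(unique(ks)) != 1L)
    stop_hlfd("all predictive maps in a bundle must share the class count")
  structure(list(early = early, mids = mids, late = late), class = "pred_bundle")
}

#' @export
print.pred_bundle <- function(x, ...) {
  cat(sprintf("<pred_bundle: %d classes, %d mid maps>\n",
              dim(as_pm_values(x$early))[1], length(x$mids)))
  invisible(x)
}
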