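## Segmentation evaluation: Dice similarity coefficient and relative volume
## difference, per-sample and aggregated.

#' Dice similarity coefficient
#'
#' `2|P intersect G| / (|P| + |G|)`, the standard overlap score in `[0, 1]`
#' (higher is better). When both masks are empty the prediction is perfect
#' and the score is defined as 1.
#'
#' @param pred,gt Binary masks of equal shape.
#' @param eps Guard for the both-empty case.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, gt, eps = 1e-8) {
  if (!all(dim(pred) == dim(gt)))
    stop_hlfd("dice_score: masks disagree in shape")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop_hlfd("dice_score: masks must be binary")
  p <- sum(pred); g <- sum(gt)
  if (p + g < eps) return(1)
  2 * sum(pred * gt) / (p + g)
}

#' Relative volume difference
#'
#' `(|P| - |G|) / |G|`, signed: positive for over-segmentation, negative for
#' under-segmentation. Values nearer zero indicate better volume agreement
#' regardless of sign, so rankings use `|RVD|`. Undefined for empty ground
#' truth.
#'
#' @param pred,gt Binary masks of equal shape; `sum(gt)` must be positive.
#' @return Signed scalar.
#' @export
rvd <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop_hlfd("rvd: masks disagree in shape")
  g <- sum(gt)
  if (g == 0) stop_hlfd("rvd is undefined for an empty ground-truth mask")
  (sum(pred) - g) / g
}

#' Evaluate a network on a phantom set
#'
#' Windows each image with the organ's HU window, predicts a foreground
#' mask at the given threshold, and reports per-sample Dice and RVD plus
#' mean and standard deviation. Samples with empty ground-truth masks are
#' excluded from the RVD aggregate (logged in the per-sample table as `NA`).
#'
#' @param net An `hlfd_net`, or a fit object with a `$network`.
#' @param data A `phantom_set` (HU images + masks).
#' @param threshold Foreground-probability binarisation threshold.
#' @param out Optional output directory for `metrics.csv` (per sample) and
#'   `metrics.json` (mean/sd per metric).
#' @return An object of class `hlfd_metrics`: `per_sample` data frame and
#'   `summary` list.
#' @export
evaluate <- function(net, data, threshold = 0.5, out = NULL) {
  if (!inherits(net, "hlfd_net") && !is.null(net$network)) net <- net$network
  if (!length(data)) stop_hlfd("evaluate: empty evaluation set")
  rows <- lapply(seq_along(data), function(i) {
    s <- data[[i]]
    x <- hu_window(s$image, organ_window(s$meta$organ))
    pred <- predict(net, x, type = "mask", threshold = threshold)
    data.frame(sample_id = i,
               dsc = dice_score(pred, s$mask),
               rvd = if (sum(s$mask) > 0) rvd(pred, s$mask) else NA_real_)
  })
  per_sample <- do.call(rbind, rows)
  summ <- list(dsc_mean = mean(per_sample$dsc), dsc_sd = stats::sd(per_sample$dsc),
               rvd_mean = mean(per_sample$rvd, na.rm = TRUE),
               rvd_sd = stats::sd(per_sample$rvd, na.rm = TRUE),
               abs_rvd_mean = mean(abs(per_sample$rvd), na.rm = TRUE),
               n = nrow(per_sample),
               n_rvd_excluded = sum(is.na(per_sample$rvd)))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_sample, file.path(out, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(summ, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(per_sample = per_sample, summary = summ), class = "hlfd_metrics")
}

#' @export
print.hlfd_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("DSC %.4f +/- %.4f | RVD %.4f (|RVD| %.4f) | n = %d (%d excluded from RVD)\n",
              s$dsc_mean, s$dsc_sd, s$rvd_mean, s$abs_rvd_mean, s$n, s$n_rvd_excluded))
  invisible(x)
}
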