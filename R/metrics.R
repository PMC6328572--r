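#' A set of test/reference segmentation pairs for pooled metrics
#'
#' @param test_volumes list of [coro_mask]s (one per structure/plaque).
#' @param reference_volumes list of [coro_mask]s, pairwise same grids.
#' @return A \code{coro_pairs} object.
#' @export
volume_pair_set <- function(test_volumes, reference_volumes) {
  if (inherits(test_volumes, "coro_mask")) test_volumes <- list(test_volumes)
  if (inherits(reference_volumes, "coro_mask"))
    reference_volumes <- list(reference_volumes)
  if (length(test_volumes) != length(reference_volumes))
    stop("test and reference lists must have equal length")
  if (length(test_volumes) == 0) stop("at least one pair is required")
  for (i in seq_along(test_volumes))
    stopifnot_same_grid(test_volumes[[i]], reference_volumes[[i]])
  structure(list(test = test_volumes, ref = reference_volumes),
            class = "coro_pairs")
}

pair_counts <- function(pairs) {
  inter <- vapply(seq_along(pairs$test), function(i)
    sum(pairs$test[[i]]$data & pairs$ref[[i]]$data), 0.0)
  nt <- vapply(pairs$test, function(m) sum(m$data), 0.0)
  nr <- vapply(pairs$ref, function(m) sum(m$data), 0.0)
  vv <- vapply(pairs$test, voxel_volume, 0.0)
  list(inter = inter, nt = nt, nr = nr, voxvol = vv)
}

#' Pooled DICE similarity (%)
#'
#' \code{2 * sum_i |Vt_i ∩ Vr_i| / sum_i (|Vt_i| + |Vr_i|) * 100}.
#' @param pairs a [volume_pair_set].
#' @return percentage in [0, 100].
#' @export
dice <- function(pairs) {
  ct <- pair_counts(pairs)
  denom <- sum(ct$nt) + sum(ct$nr)
  if (denom == 0) stop("DICE undefined: all volumes are empty")
  200 * sum(ct$inter) / denom
}

#' Volume mean squared error
#'
#' \code{(1/n) sum_i (vol(Vt_i) - vol(Vr_i))^2} with volumes in mm^3.
#' Reported in the units the metric is conventionally tabulated in (mm^3).
#' @param pairs a [volume_pair_set].
#' @return non-negative error.
#' @export
volume_mse <- function(pairs) {
  ct <- pair_counts(pairs)
  mean((ct$nt * ct$voxvol - ct$nr * ct$voxvol)^2)
}

#' Relative volume error (%)
#'
#' \code{sum_i |vol(Vt_i) - vol(Vr_i)| / sum_i vol(Vr_i) * 100}.
#' @param pairs a [volume_pair_set].
#' @return percentage >= 0.
#' @export
relative_volume_error <- function(pairs) {
  ct <- pair_counts(pairs)
  if (sum(ct$nr) == 0) stop("relative volume error undefined: empty reference")
  100 * sum(abs(ct$nt * ct$voxvol - ct$nr * ct$voxvol)) /
    sum(ct$nr * ct$voxvol)
}

#' Pooled precision and sensitivity (%)
#'
#' \code{PREC = sum |Vt ∩ Vr| / sum |Vt| * 100};
#' \code{SENS = sum |Vt ∩ Vr| / sum |Vr| * 100}.
#' @param pairs a [volume_pair_set].
#' @return named numeric c(precision, sensitivity).
#' @export
precision_sensitivity <- function(pairs) {
  ct <- pair_counts(pairs)
  if (sum(ct$nt) == 0) stop("precision undefined: empty test volumes")
  if (sum(ct$nr) == 0) stop("sensitivity undefined: empty reference volumes")
  c(precision = 100 * sum(ct$inter) / sum(ct$nt),
    sensitivity = 100 * sum(ct$inter) / sum(ct$nr))
}

#' Full metrics report: pooled and per-pair
#'
#' @param pairs a [volume_pair_set].
#' @return A \code{coro_metrics} list: \code{dice_pct}, \code{vol_mse},
#'   \code{rel_vol_error_pct}, \code{precision_pct}, \code{sensitivity_pct},
#'   and a \code{per_item} data.frame with the same five per pair.
#' @export
metrics_report <- function(pairs) {
  ct <- pair_counts(pairs)
  ps <- precision_sensitivity(pairs)
  per <- data.frame(
    dice_pct = 200 * ct$inter / (ct$nt + ct$nr),
    vol_mse = (ct$nt * ct$voxvol - ct$nr * ct$voxvol)^2,
    rel_vol_error_pct = 100 * abs(ct$nt - ct$nr) / ct$nr,
    precision_pct = 100 * ct$inter / ct$nt,
    sensitivity_pct = 100 * ct$inter / ct$nr)
  structure(list(dice_pct = dice(pairs), vol_mse = volume_mse(pairs),
                 rel_vol_error_pct = relative_volume_error(pairs),
                 precision_pct = unname(ps["precision"]),
                 sensitivity_pct = unname(ps["sensitivity"]),
                 per_item = per),
            class = "coro_metrics")
}

#' Bland-Altman agreement summary for paired volumes
#'
#' @param test_vols,ref_vols numeric vectors (mm^3), equal length >= 2.
#' @return list: \code{bias} (mean test - ref), \code{sd}, \code{limits}
#'   (bias -/+ 1.96 sd), and a per-pair \code{table} of means and diffs.
#' @export
bland_altman <- function(test_vols, ref_vols) {
  if (length(test_vols) != length(ref_vols) || length(test_vols) < 2)
    stop("need equal-length vectors with at least 2 pairs")
  d <- test_vols - ref_vols
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, sd = s, limits = c(bias - 1.96 * s, bias + 1.96 * s),
       table = data.frame(mean = (test_vols + ref_vols) / 2, diff = d))
}

#' Pool metrics by plaque-length quartile
#'
#' Reporting helper: quartiles are computed over the supplied plaque
#' lengths; the five pooled metrics are recomputed per quartile group.
#' @param pairs a [volume_pair_set].
#' @param lengths plaque lengths (mm), one per pair.
#' @return data.frame, one row per quartile.
#' @export
metrics_by_length_quartile <- function(pairs, lengths) {
  if (length(lengths) != length(pairs$test))
    stop("one length per pair is required")
  qs <- stats::quantile(lengths, c(0.25, 0.5, 0.75))
  grp <- cut(lengths, c(-Inf, qs, Inf), labels = c("Q1", "Q2", "Q3", "Q4"))
  do.call(rbind, lapply(levels(grp), function(g) {
    sel <- which(grp == g)
    if (!length(sel)) return(NULL)
    sub <- volume_pair_set(pairs$test[sel], pairs$ref[sel])
    ps <- precision_sensitivity(sub)
    data.frame(quartile = g, n = length(sel), dice_pct = dice(sub),
               vol_mse = volume_mse(sub),
               rel_vol_error_pct = relative_volume_error(sub),
               precision_pct = unname(ps["precision"]),
               sensitivity_pct = unname(ps["sensitivity"]))
  }))
}
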