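#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (feature, sample); then
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt_sample - dCt_calibrator`,
#' and the relative expression is `2^-ddCt` (1 for the calibrator itself).
#' Ct values outside the typical 10-40 range trigger a warning.
#'
#' @param records data.frame with columns `feature_id`, `sample_id`,
#'   `ct_target`, `ct_reference` (one row per technical replicate).
#' @param calibrator_sample Sample id used as the calibrator; must be
#'   present for every feature.
#' @return data.frame(feature_id, sample_id, delta_ct, rel_expr).
#' @export
ddct <- function(records, calibrator_sample) {
  needed <- c("feature_id", "sample_id", "ct_target", "ct_reference")
  stopifnot(all(needed %in% names(records)))
  ct <- c(records$ct_target, records$ct_reference)
  if (any(!is.finite(ct))) stop("non-finite Ct value")
  if (any(ct < 10 | ct > 40))
    warning("Ct value(s) outside the typical 10-40 range")
  agg <- stats::aggregate(
    cbind(ct_target, ct_reference) ~ feature_id + sample_id,
    data = records, FUN = mean)
  agg$delta_ct <- agg$ct_target - agg$ct_reference
  out <- list()
  for (f in unique(agg$feature_id)) {
    sub <- agg[agg$feature_id == f, , drop = FALSE]
    cal <- sub$delta_ct[sub$sample_id == calibrator_sample]
    if (!length(cal))
      stop("calibrator sample '", calibrator_sample,
           "' missing for feature ", f)
    sub$rel_expr <- 2^(-(sub$delta_ct - cal))
    out[[f]] <- sub[, c("feature_id", "sample_id", "delta_ct", "rel_expr")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$feature_id, res$sample_id, method = "radix"), , drop = FALSE]
}

#' qPCR-vs-sequencing concordance fit
#'
#' Ordinary least squares of the qPCR log2 fold changes on the sequencing
#' log2 fold changes, plus the Pearson correlation: the summary used to
#' judge whether sequencing fold changes validate (printed as a slope and
#' an R value per comparison).
#'
#' @param log2fc_qpcr,log2fc_seq Paired numeric vectors, n >= 3.
#' @return List with `slope`, `intercept`, `r`, `n`.
#' @export
concordance_fit <- function(log2fc_qpcr, log2fc_seq) {
  n <- length(log2fc_seq)
  if (n != length(log2fc_qpcr) || n < 3L)
    stop("concordance_fit needs paired vectors of length >= 3")
  if (stats::sd(log2fc_seq) == 0)
    stop("zero variance in the sequencing fold changes")
  fit <- stats::lm(log2fc_qpcr ~ log2fc_seq)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(log2fc_qpcr, log2fc_seq),
       n = n)
}
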