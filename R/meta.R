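#' Inverse-variance fixed-effects meta-analysis of burden effects
#'
#' Combines per-stratum estimates of the burden effect `lambda` for one
#' gene. With weights `v_s = 1 / se_s^2`,
#' `lambda_meta = sum(v_s lambda_s) / sum(v_s)`,
#' `se_meta = 1 / sqrt(sum(v_s))`, and the p-value is the two-sided normal
#' tail probability of `z = lambda_meta / se_meta`. Strata whose test was
#' skipped or failed (missing or non-positive standard error, or a
#' non-`"ok"` status) are omitted. Cochran's Q is reported as a
#' heterogeneity diagnostic only; no filtering is applied on it.
#'
#' @param results Data frame of per-stratum results for one gene, with
#'   columns `lambda_hat`, `se_lambda` and optionally `status` and `gene`.
#' @return One-row data frame: `gene`, `lambda_meta`, `se_meta`, `z_stat`,
#'   `p_value`, `n_strata_used`, `q_het`, `status`. With zero usable
#'   strata the gene is reported with status `"untestable"` and `NA`
#'   estimates.
#' @examples
#' meta_fixed_effects(data.frame(gene = "G", lambda_hat = c(1, 1),
#'                               se_lambda = c(0.5, 0.5)))
#' @export
meta_fixed_effects <- function(results) {
  gene <- if (!is.null(results$gene) && nrow(results) > 0L)
    results$gene[1L] else NA_character_
  ok <- is.finite(results$lambda_hat) & is.finite(results$se_lambda) &
    results$se_lambda > 0
  if (!is.null(results$status)) ok <- ok & results$status == "ok"
  lam <- results$lambda_hat[ok]
  se <- results$se_lambda[ok]
  if (length(lam) == 0L) {
    return(data.frame(gene = gene, lambda_meta = NA_real_, se_meta = NA_real_,
                      z_stat = NA_real_, p_value = NA_real_,
                      n_strata_used = 0L, q_het = NA_real_,
                      status = "untestable", stringsAsFactors = FALSE))
  }
  v <- 1 / se^2
  lambda_meta <- sum(v * lam) / sum(v)
  se_meta <- 1 / sqrt(sum(v))
  z <- lambda_meta / se_meta
  p <- 2 * stats::pnorm(-abs(z))
  q_het <- sum(v * (lam - lambda_meta)^2)
  data.frame(gene = gene, lambda_meta = lambda_meta, se_meta = se_meta,
             z_stat = z, p_value = max(p, 1e-300),
             n_strata_used = length(lam), q_het = q_het,
             status = "ok", stringsAsFactors = FALSE)
}

#' Meta-analyze a stratified scan gene by gene
#'
#' @param stratum_results Concatenated per-stratum results (one row per
#'   gene x stratum), as produced by [burden_scan()] or read from the
#'   per-stratum TSV outputs.
#' @return Data frame with one [meta_fixed_effects()] row per gene, in
#'   first-appearance gene order.
#' @export
meta_scan <- function(stratum_results) {
  pieces <- split(stratum_results,
                  factor(stratum_results$gene,
                         levels = unique(stratum_results$gene)))
  out <- do.call(rbind, lapply(pieces, meta_fixed_effects))
  rownames(out) <- NULL
  out
}
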