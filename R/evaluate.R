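#' Bonferroni-corrected per-gene significance threshold
#'
#' The family-wise level `alpha` divided by the number of testable genes,
#' i.e. genes containing at least the minimum number of rare variants in
#' the current dataset. With `alpha = 0.05` and 1,297 testable genes this
#' is 3.86e-5 (3 significant figures).
#'
#' @param alpha Family-wise type I error level in `(0, 1)`.
#' @param n_testable_genes Number of genes passing the rare-variant
#'   filter (>= 1).
#' @return The per-gene threshold `alpha / n_testable_genes`.
#' @examples
#' signif(bonferroni_threshold(0.05, 1297), 3)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_testable_genes) {
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  n <- check_count(n_testable_genes, "n_testable_genes")
  alpha / n
}

#' Replicate study design for power / type I error estimation
#'
#' @param trait Trait analyzed (e.g. `"Q1"`, `"CC"`).
#' @param missingness_models List of [missingness_model()]s to compare
#'   (include `missingness_model("none")` for the complete-data arm).
#' @param n_replicates Number of study replicates per model.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param causal_genes Character vector: the truth set of genes causal for
#'   `trait` (power is tallied on these, type I error on the rest).
#' @param config A [test_config()] for the per-gene tests.
#' @param master_seed Integer; all replicate-level randomness (phenotype
#'   replicate draws, missingness masks) derives deterministically from
#'   it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(trait = "Q1",
                         missingness_models = list(missingness_model("none")),
                         n_replicates = 1000L,
                         alpha = 0.05,
                         causal_genes = character(0),
                         config = test_config(),
                         master_seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  stopifnot(length(missingness_models) >= 1L,
            all(vapply(missingness_models, inherits, TRUE,
                       "missingness_model")),
            inherits(config, "test_config"))
  labels <- vapply(missingness_models, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("missingness model labels must be unique")
  names(missingness_models) <- labels
  structure(list(trait = trait, missingness_models = missingness_models,
                 n_replicates = n_replicates, alpha = alpha,
                 causal_genes = as.character(causal_genes),
                 config = config, master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Run the replicate study: power and type I error per gene and model
#'
#' For each missingness model and each of `n_replicates` study
#' replicates: a phenotype replicate is drawn uniformly with replacement
#' from the phenotype table, missing calls are injected, the stratified
#' burden scan plus meta-analysis is run for every testable gene, and
#' significance is recorded at the Bonferroni threshold
#' `alpha / n_testable_genes` (the denominator is recomputed from the
#' current dataset's rare-variant filter, on pre-missingness MAFs).
#'
#' The same phenotype-replicate draw is shared across missingness models
#' within a study replicate (common random numbers), so that power
#' differences between models are paired comparisons; missingness masks
#' use model-specific seed streams. All randomness derives from
#' `design$master_seed`, making the tallies bit-reproducible.
#'
#' Replicate tests whose meta-analysis did not complete (`status !=
#' "ok"`) are counted in `n_failed`, not in the power denominator.
#'
#' @param dataset A `rareload_dataset` (pre-missingness genotypes).
#' @param phenotypes Phenotype table from [simulate_phenotypes()].
#' @param design A [study_design()].
#' @param keep_pvalues Also return the gene x replicate meta p-value
#'   matrices (attribute `"pvalues"`, one matrix per model)?
#' @param verbose Print a progress line every 100 replicates?
#' @return A power table: one row per gene x model with columns `gene`,
#'   `model`, `n_tested`, `n_significant`, `n_failed`,
#'   `proportion_significant`, `wilson_ci_low`, `wilson_ci_high`,
#'   `is_causal`. The threshold and testable-gene count are attached as
#'   attributes `"threshold"` and `"n_testable_genes"`.
#' @export
run_replicates <- function(dataset, phenotypes, design,
                           keep_pvalues = FALSE, verbose = FALSE) {
  stopifnot(inherits(dataset, "rareload_dataset"),
            inherits(design, "study_design"))
  prep <- prepare_gene_tests(dataset$variants, dataset$genes, design$config)
  if (prep$n_testable == 0L) stop("no testable genes under the rare-variant filter")
  threshold <- bonferroni_threshold(design$alpha, prep$n_testable)
  genes <- names(prep$gene_sets)
  R <- design$n_replicates
  n_pheno <- n_phenotype_replicates(phenotypes)
  models <- design$missingness_models
  M <- length(models)

  seeds <- matrix(derive_seeds(design$master_seed, R * (M + 1L)),
                  nrow = R, ncol = M + 1L)
  pmats <- lapply(models, function(m)
    matrix(NA_real_, length(genes), R, dimnames = list(genes, NULL)))

  for (r in seq_len(R)) {
    pheno_rep <- with_seed(seeds[r, 1L], sample.int(n_pheno, 1L))
    for (m in seq_len(M)) {
      model <- models[[m]]
      model$seed <- seeds[r, m + 1L]
      Gm <- inject_missing(dataset$genotypes, dataset$variants, model)
      scan <- .scan_prepared(Gm, phenotypes, design$trait, pheno_rep,
                             design$config, prep)
      meta <- scan$meta_results
      p <- ifelse(meta$status == "ok", meta$p_value, NA_real_)
      pmats[[m]][match(meta$gene, genes), r] <- p
    }
    if (verbose && r %% 100L == 0L) {
      message(sprintf("replicate %d/%d done", r, R))
    }
  }

  tabs <- lapply(seq_len(M), function(m) {
    P <- pmats[[m]]
    n_tested <- rowSums(!is.na(P))
    n_sig <- rowSums(P <= threshold, na.rm = TRUE)
    ci <- t(vapply(seq_along(genes), function(i) {
      if (n_tested[i] == 0L) c(low = NA_real_, high = NA_real_)
      else wilson_interval(n_sig[i], n_tested[i])
    }, c(low = 0, high = 0)))
    data.frame(gene = genes, model = names(models)[m],
               n_tested = as.integer(n_tested),
               n_significant = as.integer(n_sig),
               n_failed = as.integer(R - n_tested),
               proportion_significant = ifelse(n_tested > 0, n_sig / n_tested, NA),
               wilson_ci_low = ci[, "low"], wilson_ci_high = ci[, "high"],
               is_causal = genes %in% design$causal_genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_testable_genes") <- prep$n_testable
  if (keep_pvalues) attr(out, "pvalues") <- pmats
  out
}

#' Combine power tables across missingness models
#'
#' Stacks one or more power tables from [run_replicates()] into a single
#' long-format comparison table (gene x model x proportion with Wilson
#' 95% intervals), ordering rows by gene then model.
#'
#' @param ... Power tables, or a single list of them.
#' @return The stacked power table.
#' @seealso [plot_power()]
#' @export
summarize_power <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.data.frame(tabs[[1L]])) return(tabs[[1L]])
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  out <- do.call(rbind, tabs)
  out <- out[order(out$gene, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot power against missingness model
#'
#' @param power_table A power table from [run_replicates()] /
#'   [summarize_power()].
#' @param genes Optional subset of genes to display.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_power <- function(power_table, genes = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_power() requires the ggplot2 package")
  }
  d <- power_table
  if (!is.null(genes)) d <- d[d$gene %in% genes, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model,
                                  y = .data$proportion_significant,
                                  group = .data$gene,
                                  colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$wilson_ci_low,
                                          ymax = .data$wilson_ci_high)) +
    ggplot2::labs(x = "missingness model",
                  y = "proportion of replicates significant") +
    ggplot2::theme_minimal()
}
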