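#' Configuration of the mutational-load association test
#'
#' @param link Link function of the generalized linear model:
#'   `"identity"` for quantitative (Gaussian) traits, `"logit"` for
#'   dichotomous (Bernoulli) traits.
#' @param covariates Names of phenotype-table columns used as covariates.
#' @param rare_maf_threshold Variants with MAF strictly below this are
#'   "rare" (default 0.05; a variant at exactly the threshold is common).
#' @param min_rare_variants Minimum number of rare variants for a gene to
#'   be testable (default 2).
#' @param nonsynonymous_only Restrict the rare set to nonsynonymous
#'   variants?
#' @param exclude Individual ids dropped before analysis (e.g. phenotype
#'   outliers).
#' @return An object of class `test_config`.
#' @export
test_config <- function(link = c("identity", "logit"),
                        covariates = c("sex", "age", "smoking"),
                        rare_maf_threshold = 0.05,
                        min_rare_variants = 2L,
                        nonsynonymous_only = FALSE,
                        exclude = character(0)) {
  link <- match.arg(link)
  check_number(rare_maf_threshold, "rare_maf_threshold", 0, 0.5,
               closed_lower = FALSE)
  min_rare_variants <- check_count(min_rare_variants, "min_rare_variants",
                                   lower = 2L)
  structure(list(link = link, covariates = covariates,
                 rare_maf_threshold = rare_maf_threshold,
                 min_rare_variants = min_rare_variants,
                 nonsynonymous_only = isTRUE(nonsynonymous_only),
                 exclude = as.character(exclude)),
            class = "test_config")
}

#' Select the rare variants entering gene tests
#'
#' Applies the strict MAF cutoff (`maf < rare_maf_threshold`) and,
#' optionally, the nonsynonymous filter.
#'
#' @param variants Variant table with `maf` and (if filtering)
#'   `nonsynonymous` columns.
#' @param config A [test_config()].
#' @return The subset of `variants` passing the filters.
#' @export
classify_rare_variants <- function(variants, config = test_config()) {
  stopifnot(!is.null(variants$maf))
  keep <- variants$maf < config$rare_maf_threshold
  if (config$nonsynonymous_only) {
    stopifnot(!is.null(variants$nonsynonymous))
    keep <- keep & as.logical(variants$nonsynonymous)
  }
  variants[keep, , drop = FALSE]
}

#' Per-individual mutational load in one gene
#'
#' For each individual, `n_called` is the number of the gene's rare
#' variants with a non-missing genotype call, and `n_carrier` the number
#' of those at which the individual carries at least one copy of the
#' minor allele (dosage >= 1). Individuals with `n_called = 0` carry no
#' information and are excluded from the gene's test downstream.
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param variant_ids Column names (or indices) of the gene's rare
#'   variants.
#' @param individuals Optional subset of row names to use.
#' @return Data frame `individual_id`, `n_called`, `n_carrier`, with the
#'   gene's rare-variant count in `attr(, "n_rare_variants")`.
#' @export
compute_burden <- function(genotypes, variant_ids, individuals = NULL) {
  if (length(variant_ids) == 0L) stop("empty rare-variant set")
  sub <- genotypes[, variant_ids, drop = FALSE]
  if (!is.null(individuals)) sub <- sub[individuals, , drop = FALSE]
  out <- data.frame(individual_id = rownames(sub),
                    n_called = as.integer(rowSums(!is.na(sub))),
                    n_carrier = as.integer(rowSums(sub > 0, na.rm = TRUE)),
                    stringsAsFactors = FALSE)
  attr(out, "n_rare_variants") <- length(variant_ids)
  out
}

# ---- weighted GLM machinery ------------------------------------------------
#
# The individual contribution to the log-likelihood is weighted by
# w_i = n_i / J (call count over the gene's rare-variant count), which
# equals weighting by n_i up to a constant, is identically 1 under
# complete data, and preserves the chi-square calibration of the deviance.

# coefficient covariance from a (pivoted) QR of sqrt(W) X
.cov_from_qr <- function(qr_obj, p_total, scale = 1) {
  p <- qr_obj$rank
  R <- qr.R(qr_obj)[seq_len(p), seq_len(p), drop = FALSE]
  cov <- chol2inv(R) * scale
  out <- matrix(NA_real_, p_total, p_total)
  piv <- qr_obj$pivot[seq_len(p)]
  out[piv, piv] <- cov
  out
}

# maximize the weighted log-likelihood for one design matrix
#   identity: Gaussian with residual variance profiled out
#   logit:    Bernoulli, fitted by IRLS (stats::glm.fit)
.fit_weighted <- function(X, y, w, link) {
  p_total <- ncol(X)
  if (link == "identity") {
    fit <- stats::lm.wfit(X, y, w)
    W <- sum(w)
    rssw <- sum(w * fit$residuals^2)
    s2 <- rssw / W
    loglik <- if (s2 <= 0) Inf else -0.5 * W * (log(2 * pi * s2) + 1)
    df <- length(y) - fit$rank
    sigma2 <- if (df > 0) rssw / df else NaN
    cov <- .cov_from_qr(fit$qr, p_total, scale = sigma2)
    list(coef = fit$coefficients, se = sqrt(diag(cov)), loglik = loglik,
         rssw = rssw, W = W, converged = TRUE, rank = fit$rank)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, weights = w, family = stats::binomial()))
    mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    loglik <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    cov <- .cov_from_qr(fit$qr, p_total, scale = 1)
    coefs <- fit$coefficients
    converged <- isTRUE(fit$converged) &&
      all(is.na(coefs) | abs(coefs) < 1e3)
    list(coef = coefs, se = sqrt(diag(cov)), loglik = loglik,
         rssw = NA_real_, W = sum(w), converged = converged, rank = fit$rank)
  }
}

#' Fit the weighted burden GLM for one gene
#'
#' Maximizes the weighted log-likelihood of the model
#' `g(E[y_i]) = x_i' beta + lambda * (r_i / n_i)`, where `r_i / n_i` is the
#' individual's carrier proportion over the gene's rare variants and each
#' individual's likelihood contribution carries weight `w_i = n_i / J`
#' (J = the gene's rare-variant count), accommodating differential call
#' rates. `lambda` is the expected increase in the (link-scale) phenotype
#' for an individual carrying minor alleles at every rare variant relative
#' to one carrying none. With `constrain_lambda_zero = TRUE` the burden
#' term is omitted (the null model of the likelihood-ratio test).
#'
#' For the identity link the residual variance is profiled out of the
#' Gaussian likelihood within each model; the logit fit runs IRLS.
#' Individuals with `n_called = 0` or a missing phenotype are dropped.
#'
#' @param burden Burden records from [compute_burden()].
#' @param y Phenotype vector aligned with `burden` rows.
#' @param covariates Optional numeric matrix / data frame of covariates
#'   aligned with `burden` rows (no intercept column; one is added).
#' @param config A [test_config()] (supplies the link).
#' @param constrain_lambda_zero Fit the null model (`lambda = 0`)?
#' @return List with `coef`, `se`, `loglik`, `lambda_hat`, `se_lambda`,
#'   `n_used`, `converged`, `status` (`"ok"`, `"skipped_constant_burden"`
#'   or `"failed_fit"`).
#' @export
fit_weighted_glm <- function(burden, y, covariates = NULL,
                             config = test_config(),
                             constrain_lambda_zero = FALSE) {
  J <- attr(burden, "n_rare_variants")
  stopifnot(!is.null(J), length(y) == nrow(burden))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(burden))
  }
  use <- burden$n_called > 0L & is.finite(y)
  n_used <- sum(use)
  if (n_used < 1L) stop("no usable individuals (all n_called = 0 or phenotype missing)")
  w <- burden$n_called[use] / J
  x <- burden$n_carrier[use] / burden$n_called[use]
  X <- cbind(`(Intercept)` = rep(1, n_used),
             if (!is.null(covariates)) covariates[use, , drop = FALSE])
  status <- "ok"
  if (!constrain_lambda_zero) {
    if (stats::var(x) == 0) {
      return(list(coef = NULL, se = NULL, loglik = NA_real_,
                  lambda_hat = NA_real_, se_lambda = NA_real_,
                  n_used = n_used, converged = FALSE,
                  status = "skipped_constant_burden"))
    }
    X <- cbind(X, burden = x)
  }
  fit <- .fit_weighted(X, y[use], w, config$link)
  lambda_hat <- if (constrain_lambda_zero) NA_real_ else
    unname(fit$coef[["burden"]])
  se_lambda <- if (constrain_lambda_zero) NA_real_ else
    unname(fit$se[[ncol(X)]])
  if (!constrain_lambda_zero &&
      (is.na(lambda_hat) || !fit$converged || !is.finite(se_lambda))) {
    status <- "failed_fit"
  }
  list(coef = fit$coef, se = fit$se, loglik = fit$loglik,
       rssw = fit$rssw, W = fit$W,
       lambda_hat = lambda_hat, se_lambda = se_lambda,
       n_used = n_used, converged = fit$converged, status = status)
}

#' Likelihood-ratio test of mutational-load association for one gene
#'
#' Compares, by analysis of deviance, the null model (`lambda = 0`) with
#' the alternative where `lambda` is unconstrained:
#' `LRT = 2 (l_alt - l_null)`, referred to a chi-square distribution with
#' one degree of freedom. Negative values from numerical jitter (below
#' 1e-10 in magnitude) are clamped to zero.
#'
#' @inheritParams fit_weighted_glm
#' @param gene,stratum Labels copied into the result row.
#' @return One-row data frame: `gene`, `stratum`, `n_rare_variants`,
#'   `n_individuals`, `lambda_hat`, `se_lambda`, `lrt_stat`, `p_value`,
#'   `status`.
#' @export
lrt_association <- function(burden, y, covariates = NULL,
                            config = test_config(),
                            gene = NA_character_, stratum = NA_character_) {
  J <- attr(burden, "n_rare_variants")
  res <- data.frame(gene = gene, stratum = stratum,
                    n_rare_variants = J, n_individuals = NA_integer_,
                    lambda_hat = NA_real_, se_lambda = NA_real_,
                    lrt_stat = NA_real_, p_value = NA_real_,
                    status = "untestable", stringsAsFactors = FALSE)
  n_param <- 2L + if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (sum(burden$n_called > 0L & is.finite(y)) <= n_param) return(res)

  alt <- fit_weighted_glm(burden, y, covariates, config,
                          constrain_lambda_zero = FALSE)
  res$n_individuals <- alt$n_used
  if (alt$status != "ok") {
    res$status <- alt$status
    return(res)
  }
  null <- fit_weighted_glm(burden, y, covariates, config,
                           constrain_lambda_zero = TRUE)
  lrt <- if (config$link == "identity") {
    # deviance via weighted residual sums of squares: W log(rss0/rss1),
    # robust when a model fits exactly (rssw ~ 0)
    eps <- 1e-12 * max(1, null$W)
    if (null$rssw <= eps && alt$rssw <= eps) 0
    else if (alt$rssw <= eps) Inf
    else null$W * log(null$rssw / alt$rssw)
  } else {
    2 * (alt$loglik - null$loglik)
  }
  if (is.nan(lrt)) lrt <- 0
  if (lrt < 0) lrt <- if (lrt > -1e-10) 0 else 0  # clamp numerical jitter
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  res$lambda_hat <- alt$lambda_hat
  res$se_lambda <- alt$se_lambda
  res$lrt_stat <- lrt
  res$p_value <- max(p, 1e-300)
  res$status <- "ok"
  res
}

# precompute, for one dataset + config, the per-gene rare-variant column
# sets and the testable-gene panel (>= min_rare_variants rare variants)
prepare_gene_tests <- function(variants, genes, config) {
  rare <- classify_rare_variants(variants, config)
  map <- assign_variants_to_genes(rare, genes)
  sets <- split(map$variant_id, map$gene)
  sets <- sets[lengths(sets) >= config$min_rare_variants]
  list(gene_sets = sets, n_testable = length(sets))
}

#' Stratified mutational-load scan over all testable genes
#'
#' Runs the per-gene likelihood-ratio test ([lrt_association()])
#' separately within each ancestry stratum, then combines the per-stratum
#' burden effects with inverse-variance fixed-effects meta-analysis
#' ([meta_fixed_effects()]). A gene is testable when it contains at least
#' `config$min_rare_variants` rare variants (pooled classification);
#' within a stratum a test can still be skipped (constant burden) or fail
#' (non-convergence), in which case that stratum is omitted from the
#' gene's meta-analysis.
#'
#' @param genotypes Dosage matrix (individuals x variants); rows must
#'   match `phenotypes$individual_id`.
#' @param variants Variant table (`variant_id`, `chrom`, `pos`,
#'   `nonsynonymous`, `maf`).
#' @param genes Gene regions (`gene`, `chrom`, `start`, `stop`).
#' @param phenotypes Phenotype table with `individual_id`, `stratum`,
#'   covariate columns and trait replicate columns.
#' @param trait Trait name (e.g. `"Q1"`).
#' @param replicate Phenotype replicate index.
#' @param config A [test_config()].
#' @return List with `stratum_results` (one row per gene x stratum),
#'   `meta_results` (one row per gene) and `n_testable_genes`.
#' @export
burden_scan <- function(genotypes, variants, genes, phenotypes,
                        trait = "Q1", replicate = 1L,
                        config = test_config()) {
  prep <- prepare_gene_tests(variants, genes, config)
  .scan_prepared(genotypes, phenotypes, trait, replicate, config, prep)
}

# worker shared by burden_scan() and run_replicates(); `prep` comes from
# prepare_gene_tests()
.scan_prepared <- function(genotypes, phenotypes, trait, replicate, config,
                           prep) {
  col <- trait_column(trait, replicate)
  if (!col %in% names(phenotypes)) {
    stop(sprintf("phenotype column `%s` not found", col))
  }
  keep <- !(phenotypes$individual_id %in% config$exclude)
  phen <- phenotypes[keep, , drop = FALSE]
  G <- genotypes[phen$individual_id, , drop = FALSE]
  y <- phen[[col]]
  miss_cov <- setdiff(config$covariates, names(phen))
  if (length(miss_cov) > 0L) {
    stop("covariate column(s) not found: ", paste(miss_cov, collapse = ", "))
  }
  Xc <- if (length(config$covariates))
    as.matrix(phen[config$covariates]) else NULL
  strata <- unique(phen$stratum)
  if (length(prep$gene_sets) == 0L) {
    empty <- data.frame(gene = character(0), stratum = character(0),
                        n_rare_variants = integer(0),
                        n_individuals = integer(0), lambda_hat = numeric(0),
                        se_lambda = numeric(0), lrt_stat = numeric(0),
                        p_value = numeric(0), status = character(0))
    return(list(stratum_results = empty, meta_results = NULL,
                n_testable_genes = 0L))
  }
  rows <- vector("list", length(prep$gene_sets) * length(strata))
  k <- 0L
  for (s in strata) {
    in_s <- phen$stratum == s
    Gs <- G[in_s, , drop = FALSE]
    ys <- y[in_s]
    Xs <- if (is.null(Xc)) NULL else Xc[in_s, , drop = FALSE]
    for (g in names(prep$gene_sets)) {
      b <- compute_burden(Gs, prep$gene_sets[[g]])
      k <- k + 1L
      rows[[k]] <- lrt_association(b, ys, Xs, config, gene = g, stratum = s)
    }
  }
  stratum_results <- do.call(rbind, rows)
  meta_results <- meta_scan(stratum_results)
  list(stratum_results = stratum_results, meta_results = meta_results,
       n_testable_genes = prep$n_testable)
}
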