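# Fixtures for the study-scale analyses, cached per test run because two
# test files share them.

.fixture_cache <- new.env(parent = emptyenv())

# 697 individuals in three ancestry strata, 40 genes of ~6 variants, one
# causal gene with lambda = 1 on Q1, 500 phenotype replicates
power_fixture <- function() {
  if (!is.null(.fixture_cache$power)) return(.fixture_cache$power)
  dat <- simulate_genotypes(population_model(
    n_per_stratum = c(EUR = 233L, ASN = 232L, AFR = 232L),
    n_genes = 40L, variants_per_gene = 6, seed = 201))
  tm <- trait_model(q1_effects = c(GENE0001 = 1.0), n_replicates = 500L,
                    seed = 202)
  phen <- simulate_phenotypes(dat, tm)
  .fixture_cache$power <- list(dat = dat, phen = phen, causal = "GENE0001",
                               lambda_true = 1.0)
  .fixture_cache$power
}

# stratified meta-analytic estimate of lambda for one gene
meta_lambda <- function(G, phen, gene_cols, trait_col, config = test_config()) {
  rows <- lapply(unique(phen$stratum), function(s) {
    in_s <- phen$stratum == s
    b <- compute_burden(G[phen$individual_id[in_s], , drop = FALSE],
                        gene_cols)
    f <- fit_weighted_glm(b, phen[[trait_col]][in_s],
                          as.matrix(phen[in_s, c("sex", "age", "smoking")]),
                          config)
    data.frame(gene = "g", lambda_hat = f$lambda_hat,
               se_lambda = f$se_lambda, status = f$status)
  })
  meta_fixed_effects(do.call(rbind, rows))$lambda_meta
}
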