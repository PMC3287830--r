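test_that("generation is deterministic under a seed and seed-sensitive", {
  m <- population_model(n_per_stratum = c(A = 40L, B = 40L), n_genes = 6L,
                        seed = 7)
  d1 <- simulate_genotypes(m)
  d2 <- simulate_genotypes(m)
  expect_identical(d1, d2)
  m$seed <- 8
  expect_false(identical(simulate_genotypes(m)$genotypes, d1$genotypes))
})

test_that("pooled MAF is exact, minor-oriented, and every gene has variants", {
  d <- tiny_dataset(seed = 3, n_genes = 15L)
  n <- nrow(d$genotypes)
  expect_equal(d$variants$maf, unname(colSums(d$genotypes) / (2 * n)))
  expect_true(all(d$variants$maf > 0 & d$variants$maf < 0.5))
  expect_setequal(unique(d$variants$gene), d$genes$gene)
  # coordinates: inside the assigned gene, sorted, genes non-overlapping
  for (g in d$genes$gene) {
    v <- d$variants[d$variants$gene == g, ]
    gr <- d$genes[d$genes$gene == g, ]
    expect_true(all(v$pos >= gr$start & v$pos <= gr$stop))
    expect_false(is.unsorted(v$pos))
  }
  per_chr <- split(d$genes, d$genes$chrom)
  for (ch in per_chr) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1L) expect_true(all(ch$start[-1L] > ch$stop[-nrow(ch)]))
  }
})

test_that("with no divergence, stratum frequencies differ only by sampling noise", {
  d <- simulate_genotypes(population_model(
    n_per_stratum = c(A = 500L, B = 500L), fst = c(0, 0),
    n_genes = 70L, variants_per_gene = 8, seed = 21))
  strat <- d$individuals$stratum
  pvals <- apply(d$genotypes, 2, function(g) {
    alt <- tapply(g, strat, sum)
    ref <- tapply(g, strat, length) * 2 - alt
    suppressWarnings(stats::chisq.test(rbind(alt, ref))$p.value)
  })
  expect_gt(mean(pvals > 0.001), 0.95)
})

test_that("empirical Fst increases monotonically in the divergence parameter", {
  grid <- c(0.005, 0.02, 0.05, 0.1, 0.2)
  emp <- vapply(grid, function(f) {
    d <- simulate_genotypes(population_model(
      n_per_stratum = c(A = 300L, B = 300L, C = 300L), fst = rep(f, 3),
      n_genes = 25L, variants_per_gene = 8, seed = 31))
    fr <- apply(d$genotypes, 2, function(g)
      tapply(g, d$individuals$stratum, mean) / 2)
    pbar <- colMeans(fr)
    mean(apply(fr, 2, stats::var) / (pbar * (1 - pbar)), na.rm = TRUE)
  }, 0)
  expect_gt(stats::cor(emp, grid, method = "spearman"), 0.9)
})

test_that("invalid population model parameters name the offending field", {
  expect_error(population_model(fst = c(1, 1, 1)), "fst")
  expect_error(population_model(variants_per_gene = 1), "variants_per_gene")
  expect_error(population_model(fraction_nonsynonymous = 2),
               "fraction_nonsynonymous")
  expect_error(population_model(sfs_shape = list(min = 0, max = 0.2)),
               "sfs_shape")
})

test_that("null phenotypes are pure noise and replicates share genotypes", {
  d <- tiny_dataset(seed = 5, n_genes = 8L, n = c(A = 400L, B = 400L))
  tm <- trait_model(covariate_effects = c(sex = 0, age = 0, smoking = 0),
                    n_replicates = 3L, seed = 9)
  phen <- simulate_phenotypes(d, tm)
  n <- nrow(phen)
  for (r in 1:3) {
    expect_lt(abs(mean(phen[[trait_column("Q1", r)]])), 4 / sqrt(n))
  }
  # replicates are noise draws on one fixed genotype matrix: regenerating
  # phenotypes does not touch the genotypes
  expect_identical(d$genotypes, tiny_dataset(seed = 5, n_genes = 8L,
                                             n = c(A = 400L, B = 400L))$genotypes)
})

test_that("disease prevalence is honored per replicate", {
  d <- tiny_dataset(seed = 6, n_genes = 8L, n = c(A = 500L, B = 500L))
  tm <- trait_model(disease_prevalence = 0.3, n_replicates = 5L, seed = 10)
  phen <- simulate_phenotypes(d, tm)
  for (r in 1:5) {
    frac <- mean(phen[[trait_column("CC", r)]])
    expect_gte(frac, 0.27)
    expect_lte(frac, 0.33)
  }
})

test_that("a positive causal effect raises carrier phenotypes across replicates", {
  d <- tiny_dataset(seed = 12, n_genes = 8L, n = c(A = 150L, B = 150L))
  gene <- d$genes$gene[1L]
  tm <- trait_model(q1_effects = stats::setNames(2, gene),
                    covariate_effects = c(sex = 0, age = 0, smoking = 0),
                    n_replicates = 200L, seed = 13)
  phen <- simulate_phenotypes(d, tm)
  rare <- d$variants$variant_id[d$variants$gene == gene & d$variants$maf < 0.05]
  carrier <- rowSums(d$genotypes[, rare, drop = FALSE] > 0) > 0
  skip_if(sum(carrier) < 5, "fixture produced too few carriers")
  diffs <- vapply(1:200, function(r) {
    y <- phen[[trait_column("Q1", r)]]
    mean(y[carrier]) - mean(y[!carrier])
  }, 0)
  # sign test: under no effect, positive differences ~ Binomial(200, 1/2)
  expect_lt(stats::binom.test(sum(diffs > 0), 200, 0.5,
                              alternative = "greater")$p.value, 0.001)
})

test_that("a causal gene absent from the panel is a configuration error", {
  d <- tiny_dataset(seed = 14, n_genes = 6L)
  tm <- trait_model(q1_effects = c(NOT_A_GENE = 1), n_replicates = 2L)
  expect_error(simulate_phenotypes(d, tm), "NOT_A_GENE")
})
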