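test_that("the Bonferroni threshold is alpha over the testable gene count", {
  expect_equal(signif(bonferroni_threshold(0.05, 1297L), 3), 3.86e-5)
  expect_equal(bonferroni_threshold(0.05, 1L), 0.05)
  expect_equal(bonferroni_threshold(0.01, 200L), 5e-5)
  expect_error(bonferroni_threshold(0.05, 0L), "n_testable_genes")
})

make_null_study <- function(n_reps = 30L, master_seed = 71L) {
  d <- tiny_dataset(seed = 61, n_genes = 15L, n = c(A = 80L, B = 80L))
  tm <- trait_model(n_replicates = 10L, seed = 62)
  phen <- simulate_phenotypes(d, tm)
  des <- study_design(trait = "Q4",
                      missingness_models = list(missingness_model("none")),
                      n_replicates = n_reps, master_seed = master_seed)
  list(d = d, phen = phen, des = des)
}

test_that("power tallies are reproducible bit-for-bit from the master seed", {
  s <- make_null_study(n_reps = 8L)
  p1 <- run_replicates(s$d, s$phen, s$des, keep_pvalues = TRUE)
  p2 <- run_replicates(s$d, s$phen, s$des, keep_pvalues = TRUE)
  expect_identical(p1, p2)
  s$des$master_seed <- 72L
  p3 <- run_replicates(s$d, s$phen, s$des, keep_pvalues = TRUE)
  expect_false(identical(attr(p1, "pvalues"), attr(p3, "pvalues")))
})

test_that("significance proportions are monotone in the threshold and hit 1 at t = 1", {
  s <- make_null_study(n_reps = 20L)
  pt <- run_replicates(s$d, s$phen, s$des, keep_pvalues = TRUE)
  P <- attr(pt, "pvalues")[[1L]]
  for (g in seq_len(nrow(P))) {
    p <- P[g, !is.na(P[g, ])]
    if (length(p) == 0L) next
    t1 <- mean(p <= 0.001); t2 <- mean(p <= 0.05); t3 <- mean(p <= 1)
    expect_lte(t1, t2)
    expect_lte(t2, t3)
    expect_equal(t3, 1)  # degenerate threshold: every completed test significant
  }
})

test_that("false positives on a null trait stay within the Poisson envelope", {
  s <- make_null_study(n_reps = 40L)
  pt <- run_replicates(s$d, s$phen, s$des, keep_pvalues = TRUE)
  P <- attr(pt, "pvalues")[[1L]]
  thr <- 3.9e-5
  n_tests <- sum(!is.na(P))
  fp <- sum(P <= thr, na.rm = TRUE)
  # mean thr * n_tests ~ 0.02; 5 would be a wild excess even allowing for
  # finite-sample inflation of the chi-square tail
  expect_lte(fp, 5L)
  expect_gt(n_tests, 0.9 * length(P))
})

test_that("Wilson intervals never degenerate at proportions of 0 or 1", {
  ci0 <- rareload:::wilson_interval(0, 50)
  ci1 <- rareload:::wilson_interval(50, 50)
  expect_equal(unname(ci0[1]), 0)
  expect_gt(unname(ci0[2]), 0)
  expect_lt(unname(ci1[1]), 1)
  expect_equal(unname(ci1[2]), 1)
})

test_that("a strong causal gene with complete data is detected in every replicate", {
  d <- tiny_dataset(seed = 63, n_genes = 10L, n = c(A = 250L, B = 250L))
  gene <- d$genes$gene[1L]
  tm <- trait_model(q1_effects = stats::setNames(8, gene),
                    n_replicates = 10L, seed = 64)
  phen <- simulate_phenotypes(d, tm)
  des <- study_design(trait = "Q1",
                      missingness_models = list(missingness_model("none")),
                      n_replicates = 25L, causal_genes = gene,
                      master_seed = 65L)
  pt <- run_replicates(d, phen, des)
  row <- pt[pt$gene == gene, ]
  expect_true(row$is_causal)
  expect_equal(row$proportion_significant, 1)
  expect_equal(row$n_failed, 0L)
})

test_that("summarize_power stacks model tables into one long comparison", {
  s <- make_null_study(n_reps = 5L)
  pt <- run_replicates(s$d, s$phen, s$des)
  single <- summarize_power(pt)
  expect_identical(single, pt)
  both <- summarize_power(list(pt, transform(pt, model = "other")))
  expect_equal(nrow(both), 2L * nrow(pt))
  expect_setequal(unique(both$model), c("complete", "other"))
})
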