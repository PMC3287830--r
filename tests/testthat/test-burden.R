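test_that("rare-variant classification uses a strict MAF cutoff and the NS filter", {
  v <- data.frame(variant_id = paste0("v", 1:10),
                  chrom = "1", pos = 1:10,
                  maf = c(0.05, 0.049, 0.2, 0.01, 0.04, 0.001, 0.3, 0.049,
                          0.02, 0.03),
                  nonsynonymous = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                                    TRUE, FALSE, TRUE, FALSE))
  cfg <- test_config(rare_maf_threshold = 0.05)
  rare <- classify_rare_variants(v, cfg)
  expect_false("v1" %in% rare$variant_id)   # MAF exactly at threshold: common
  expect_equal(nrow(rare), 7L)   # v2, v4, v5, v6, v8, v9, v10
  rare_ns <- classify_rare_variants(v, test_config(nonsynonymous_only = TRUE))
  expect_equal(nrow(rare_ns), 4L)  # of those, v2, v4, v6, v9 are nonsynonymous
  # all variants common -> nothing testable
  v2 <- v; v2$maf <- 0.2
  expect_equal(nrow(classify_rare_variants(v2, cfg)), 0L)
})

test_that("burden records count called and carried variants by definition", {
  G <- rbind(i1 = c(0L, 1L, 2L, NA),
             i2 = c(NA, NA, NA, NA),
             i3 = c(0L, 0L, 0L, 0L))
  colnames(G) <- paste0("v", 1:4)
  b <- compute_burden(G, paste0("v", 1:4))
  expect_equal(b$n_called, c(3L, 0L, 4L))
  expect_equal(b$n_carrier, c(2L, 0L, 0L))
  expect_equal(attr(b, "n_rare_variants"), 4L)
  # complete data: n_called = J for everyone
  b3 <- compute_burden(G[c(1, 3), ], paste0("v", 1:3))
  expect_equal(b3$n_called, c(3L, 3L))
})

test_that("with complete data the identity-link fit reduces to OLS", {
  set.seed(101)
  n <- 60L
  nc <- sample(0:4, n, replace = TRUE)
  b <- make_burden(rep(4L, n), nc, J = 4L)
  x <- nc / 4
  y <- 1 + 0.8 * x + rnorm(n)
  fit <- fit_weighted_glm(b, y, config = test_config(link = "identity"))
  ols <- stats::lm(y ~ x)
  expect_equal(fit$lambda_hat, unname(coef(ols)[2L]), tolerance = 1e-10)
  expect_equal(fit$se_lambda, unname(summary(ols)$coefficients[2L, 2L]),
               tolerance = 1e-10)
  # and weighting is inert: results identical whether n_called varies the
  # weights or not, because complete data makes every w_i = 1
  expect_equal(unname(fit$coef), unname(coef(ols)), tolerance = 1e-10)
})

test_that("the constrained fit without covariates returns the weighted mean", {
  b <- make_burden(c(4L, 2L, 1L, 3L), c(1L, 0L, 1L, 2L), J = 4L)
  y <- c(2, 4, 6, 8)
  fit <- fit_weighted_glm(b, y, config = test_config(),
                          constrain_lambda_zero = TRUE)
  w <- c(4, 2, 1, 3) / 4
  expect_equal(unname(fit$coef[1L]), sum(w * y) / sum(w), tolerance = 1e-12)
})

test_that("individuals with no called rare variants are dropped from the fit", {
  b <- make_burden(c(4L, 0L, 4L, 4L, 4L, 4L), c(1L, 0L, 0L, 2L, 0L, 1L),
                   J = 4L)
  y <- c(1, 99, 2, 3, 4, 5)   # the n_called = 0 individual has a wild value
  fit <- fit_weighted_glm(b, y)
  expect_equal(fit$n_used, 5L)
  res <- lrt_association(b, y, gene = "g", stratum = "s")
  expect_equal(res$n_individuals, 5L)
})

test_that("LRT degenerate cases: no signal, constant burden, perfect fit", {
  # constant phenotype -> zero deviance difference, p = 1
  b <- make_burden(rep(3L, 10), c(0:2, 0:2, 0:2, 1L), J = 3L)
  res <- lrt_association(b, rep(2.5, 10))
  expect_equal(res$lrt_stat, 0)
  expect_equal(res$p_value, 1)
  # constant burden -> inestimable, skipped with a reason code
  b2 <- make_burden(rep(3L, 10), rep(1L, 10), J = 3L)
  res2 <- lrt_association(b2, rnorm(10))
  expect_equal(res2$status, "skipped_constant_burden")
  expect_true(is.na(res2$p_value))
  # phenotype an exact linear function of the burden -> p collapses to ~0
  x <- b$n_carrier / b$n_called
  res3 <- lrt_association(b, 2 * x)
  expect_gt(res3$lrt_stat, 1e3)
  expect_lt(res3$p_value, 1e-100)
})

test_that("LRT statistic agrees with the squared Wald ratio on clear signals", {
  set.seed(202)
  for (link in c("identity", "logit")) {
    n <- 300L
    nc <- pmin(stats::rpois(n, 1.2), 4L)
    b <- make_burden(rep(4L, n), nc, J = 4L)
    x <- nc / 4
    eta <- -0.5 + 2.5 * x
    y <- if (link == "identity") eta + rnorm(n) else
      rbinom(n, 1L, stats::plogis(eta))
    res <- lrt_association(b, y, config = test_config(link = link))
    z2 <- (res$lambda_hat / res$se_lambda)^2
    if (z2 > 4) {
      expect_gt(res$lrt_stat / z2, 0.5)
      expect_lt(res$lrt_stat / z2, 2)
    }
  }
})

test_that("rescaling the burden covariate rescales lambda and not the test", {
  set.seed(303)
  inst <- random_small_instance("identity", seed = 77)
  # refit with the covariate scaled by c via a doubled variant count:
  # r/n is halved when every n_called and J double with r fixed
  b1 <- inst$burden
  b2 <- make_burden(2L * b1$n_called, b1$n_carrier,
                    J = 2L * attr(b1, "n_rare_variants"))
  f1 <- lrt_association(b1, inst$y)
  f2 <- lrt_association(b2, inst$y)
  expect_equal(f2$lambda_hat, 2 * f1$lambda_hat, tolerance = 1e-8)
  expect_equal(f2$lrt_stat, f1$lrt_stat, tolerance = 1e-8)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-8)
})

test_that("weighted fits match the grid-search oracle on small instances", {
  for (seed in 1:6) {
    for (link in c("identity", "logit")) {
      inst <- random_small_instance(link, seed = seed)
      fit <- fit_weighted_glm(inst$burden, inst$y,
                              config = test_config(link = link))
      oracle <- oracle_grid_max(link, inst$x, inst$y, inst$w)
      expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
    }
  }
})

test_that("parameter recovery: mean lambda-hat tracks the true effect", {
  set.seed(404)
  n <- 250L
  nc <- pmin(stats::rpois(n, 1.0), 5L)
  b <- make_burden(rep(5L, n), nc, J = 5L)
  x <- nc / 5
  lam <- vapply(1:200, function(r) {
    y <- 1.5 * x + rnorm(n)
    fit_weighted_glm(b, y)$lambda_hat
  }, 0)
  expect_lt(abs(mean(lam) - 1.5), 2 * stats::sd(lam) / sqrt(200))
})

test_that("excluded individuals are removed before the scan", {
  d <- tiny_dataset(seed = 15, n_genes = 10L)
  tm <- trait_model(n_replicates = 2L, seed = 16)
  phen <- simulate_phenotypes(d, tm)
  drop_ids <- d$individuals$individual_id[1:5]
  cfg <- test_config(exclude = drop_ids)
  scan <- burden_scan(d$genotypes, d$variants, d$genes, phen, "Q1", 1L,
                      config = cfg)
  expect_true(all(scan$stratum_results$n_individuals <=
                    nrow(phen) - 5L, na.rm = TRUE))
  full <- burden_scan(d$genotypes, d$variants, d$genes, phen, "Q1", 1L)
  expect_false(identical(scan$stratum_results$lambda_hat,
                         full$stratum_results$lambda_hat))
})
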