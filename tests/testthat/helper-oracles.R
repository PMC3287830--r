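# Independent brute-force oracles and small fixture builders.
# The oracles evaluate the weighted log-likelihoods directly from their
# definitions and maximize them by iterative grid refinement; they share
# no code with the package's fitting path.

# profiled-variance weighted Gaussian log-likelihood on a (b0, lambda) grid
oracle_ll_grid_identity <- function(b0s, lams, x, y, w) {
  W <- sum(w)
  M <- outer(x, lams)                       # n x L
  vapply(b0s, function(b0) {
    e <- (y - b0) - M
    s2 <- colSums(w * e^2) / W
    -0.5 * W * (log(2 * pi * s2) + 1)
  }, numeric(length(lams)))                  # L x B
}

# weighted Bernoulli log-likelihood on a (b0, lambda) grid
oracle_ll_grid_logit <- function(b0s, lams, x, y, w) {
  M <- outer(x, lams)
  vapply(b0s, function(b0) {
    p <- stats::plogis(b0 + M)
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    colSums(w * (y * log(p) + (1 - y) * log(1 - p)))
  }, numeric(length(lams)))
}

# maximize over (b0, lambda) by 6 rounds of grid refinement
oracle_grid_max <- function(link, x, y, w, centre = c(0, 0), half = 15,
                            n = 41, rounds = 6) {
  grid_fun <- if (link == "identity") oracle_ll_grid_identity else
    oracle_ll_grid_logit
  for (r in seq_len(rounds)) {
    b0s <- seq(centre[1] - half, centre[1] + half, length.out = n)
    lams <- seq(centre[2] - half, centre[2] + half, length.out = n)
    ll <- grid_fun(b0s, lams, x, y, w)       # lambda x b0
    ix <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
    centre <- c(b0s[ix[2L]], lams[ix[1L]])
    half <- 2 * (b0s[2L] - b0s[1L])
  }
  list(loglik = max(ll), b0 = centre[1L], lambda = centre[2L])
}

# burden records with given call/carrier counts for a J-variant gene
make_burden <- function(n_called, n_carrier, J = max(n_called)) {
  stopifnot(all(n_carrier <= n_called))
  out <- data.frame(individual_id = sprintf("i%03d", seq_along(n_called)),
                    n_called = as.integer(n_called),
                    n_carrier = as.integer(n_carrier),
                    stringsAsFactors = FALSE)
  attr(out, "n_rare_variants") <- as.integer(J)
  out
}

# random small weighted-GLM instance with a non-degenerate burden
# covariate; for the logit link the classes are forced to overlap in x
# so the MLE is finite
random_small_instance <- function(link, seed, J = 4L) {
  set.seed(seed)
  repeat {
    n <- sample(10:20, 1L)
    n_called <- sample(1:J, n, replace = TRUE)
    n_carrier <- vapply(n_called, function(k) sample(0:k, 1L), 0L)
    x <- n_carrier / n_called
    if (stats::var(x) < 0.02) next
    if (link == "identity") {
      y <- stats::rnorm(n)
    } else {
      y <- stats::rbinom(n, 1L, 0.5)
      if (sum(y) < 3L || sum(1 - y) < 3L) next
      if (!(min(x[y == 1]) < max(x[y == 0]) &&
            min(x[y == 0]) < max(x[y == 1]))) next
    }
    return(list(burden = make_burden(n_called, n_carrier, J), y = y, x = x,
                w = n_called / J))
  }
}

# small deterministic dataset used across IO / scan tests
tiny_dataset <- function(seed = 42, n_genes = 12L, n = c(A = 60L, B = 60L)) {
  simulate_genotypes(population_model(
    n_per_stratum = n, n_genes = n_genes, variants_per_gene = 5,
    seed = seed))
}
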