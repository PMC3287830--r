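#' Population model for the synthetic exome generator
#'
#' Describes the sampled population and variant panel from which
#' [simulate_genotypes()] draws a genotype matrix: a set of ancestry strata
#' diverged from a shared ancestral population under the Balding-Nichols
#' model, and a gene panel whose variants have a rare-skewed ancestral
#' site-frequency spectrum (density proportional to 1/x on a truncated
#' range, so rare alleles dominate).
#'
#' Defaults emulate a 697-individual multi-ancestry exome panel: three
#' strata of European, Asian and African origin with stratum-specific
#' divergence, and ancestral frequencies spanning roughly a singleton
#' frequency up to 17%.
#'
#' @param n_per_stratum Named integer vector, individuals per stratum.
#' @param fst Per-stratum divergence from the ancestral population, each in
#'   `[0, 1)`. `0` means the stratum frequency equals the ancestral one.
#'   Defaults to `c(0.02, 0.03, 0.05)` for a 3-stratum panel and `0.02`
#'   per stratum otherwise.
#' @param sfs_shape List with elements `min` and `max`: the truncation range
#'   of the 1/x ancestral allele-frequency density (both in `(0, 1)`).
#' @param n_genes Number of gene regions.
#' @param variants_per_gene Mean number of variants per gene (>= 2); counts
#'   are drawn as `1 + Poisson(variants_per_gene - 1)`.
#' @param fraction_nonsynonymous Probability that a variant is labelled
#'   nonsynonymous.
#' @param seed Integer seed; fixing it makes the generated dataset
#'   bit-reproducible.
#' @return An object of class `population_model`.
#' @seealso [simulate_genotypes()], [trait_model()]
#' @export
population_model <- function(n_per_stratum = c(EUR = 233L, ASN = 232L, AFR = 232L),
                             fst = NULL,
                             sfs_shape = list(min = 5e-4, max = 0.17),
                             n_genes = 300L,
                             variants_per_gene = 8,
                             fraction_nonsynonymous = 0.7,
                             seed = NULL) {
  if (length(n_per_stratum) < 1L) stop("`n_per_stratum` must name at least one stratum")
  for (i in seq_along(n_per_stratum)) check_count(n_per_stratum[[i]], "n_per_stratum")
  if (is.null(names(n_per_stratum))) {
    names(n_per_stratum) <- paste0("S", seq_along(n_per_stratum))
  }
  if (is.null(fst)) {
    # continental-scale divergence for the default 3-stratum panel,
    # a single moderate value otherwise
    fst <- if (length(n_per_stratum) == 3L) c(0.02, 0.03, 0.05) else
      rep(0.02, length(n_per_stratum))
  }
  if (length(fst) == 1L) fst <- rep(fst, length(n_per_stratum))
  if (length(fst) != length(n_per_stratum)) {
    stop("`fst` must have one entry per stratum")
  }
  check_number(fst, "fst", lower = 0, upper = 1, closed_upper = FALSE)
  check_number(sfs_shape$min, "sfs_shape$min", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(sfs_shape$max, "sfs_shape$max", lower = sfs_shape$min, upper = 1,
               closed_upper = FALSE)
  n_genes <- check_count(n_genes, "n_genes")
  check_number(variants_per_gene, "variants_per_gene", lower = 2)
  check_number(fraction_nonsynonymous, "fraction_nonsynonymous", 0, 1)
  names(fst) <- names(n_per_stratum)
  structure(list(n_per_stratum = vapply(n_per_stratum, as.integer, 0L),
                 fst = fst, sfs_shape = sfs_shape, n_genes = n_genes,
                 variants_per_gene = variants_per_gene,
                 fraction_nonsynonymous = fraction_nonsynonymous,
                 seed = seed),
            class = "population_model")
}

# inverse-CDF draw from density proportional to 1/x on [a, b]
r_loguniform <- function(n, a, b) a * (b / a)^stats::runif(n)

#' Simulate a structured genotype matrix with a rare-skewed spectrum
#'
#' Draws, for every variant, an ancestral allele frequency from the model's
#' truncated 1/x spectrum, then stratum-specific frequencies from the
#' Balding-Nichols beta distribution
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` (collapsing to `p` when
#' `F = 0`), and finally Hardy-Weinberg genotypes within each stratum.
#' Variants that come out monomorphic in the pooled sample are redrawn so
#' every gene retains its variants; alleles are then oriented so dosages
#' count the pooled *minor* allele, and the realized pooled MAF is recorded.
#'
#' Gene regions are laid out on chromosomes 1-22 round-robin in
#' non-overlapping 10 kb windows with sorted variant positions.
#'
#' @param model A [population_model()].
#' @return A `rareload_dataset` list with elements
#'   \describe{
#'     \item{genotypes}{integer matrix individuals x variants with entries
#'       0/1/2 (minor-allele dosage) and `NA` for missing calls;
#'       `rownames` are individual ids, `colnames` variant ids.}
#'     \item{variants}{data frame: `variant_id`, `chrom`, `pos`, `gene`,
#'       `nonsynonymous`, `maf` (realized pooled minor-allele frequency).}
#'     \item{genes}{data frame: `gene`, `chrom`, `start`, `stop`
#'       (1-based, inclusive).}
#'     \item{individuals}{data frame: `individual_id`, `stratum`.}
#'   }
#' @examples
#' dat <- simulate_genotypes(population_model(
#'   n_per_stratum = c(A = 60, B = 60), n_genes = 10, seed = 1))
#' dim(dat$genotypes)
#' range(dat$variants$maf)
#' @export
simulate_genotypes <- function(model) {
  stopifnot(inherits(model, "population_model"))
  with_seed(model$seed, {
    strata <- names(model$n_per_stratum)
    n_s <- model$n_per_stratum
    n_total <- sum(n_s)
    stratum_of <- rep(strata, n_s)
    ids <- sprintf("I%04d", seq_len(n_total))

    nv <- 1L + stats::rpois(model$n_genes, model$variants_per_gene - 1)
    V <- sum(nv)
    gene_names <- sprintf("GENE%04d", seq_len(model$n_genes))
    gene_of <- rep(gene_names, nv)

    draw_variants <- function(k) {
      p_anc <- r_loguniform(k, model$sfs_shape$min, model$sfs_shape$max)
      G <- matrix(0L, n_total, k)
      row0 <- 0L
      for (s in seq_along(strata)) {
        f <- model$fst[[s]]
        p_s <- if (f == 0) p_anc else
          stats::rbeta(k, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
        # guard against beta draws numerically at 0/1
        p_s <- pmin(pmax(p_s, 0), 1)
        G[row0 + seq_len(n_s[[s]]), ] <-
          stats::rbinom(n_s[[s]] * k, 2L, rep(p_s, each = n_s[[s]]))
        row0 <- row0 + n_s[[s]]
      }
      G
    }

    G <- draw_variants(V)
    # redraw pooled-monomorphic variants (thinning of the SFS tails);
    # keeps every gene's variant count intact
    for (try in 1:100) {
      mac <- colSums(G)
      mono <- which(mac == 0L | mac == 2L * n_total)
      if (length(mono) == 0L) break
      G[, mono] <- draw_variants(length(mono))
    }
    mac <- colSums(G)
    if (any(mac == 0L | mac == 2L * n_total)) {
      stop("failed to realize a polymorphic variant after 100 redraws")
    }

    # minor-allele orientation, fixed once on the pooled sample
    flip <- mac > n_total               # pooled frequency > 0.5
    G[, flip] <- 2L - G[, flip]
    maf <- colSums(G) / (2 * n_total)

    nonsyn <- stats::runif(V) < model$fraction_nonsynonymous

    # genome layout: 10 kb gene windows, 10 kb gaps, chromosomes round-robin
    chrom_of_gene <- as.character((seq_len(model$n_genes) - 1L) %% 22L + 1L)
    slot <- unlist(lapply(split(seq_len(model$n_genes), chrom_of_gene),
                          seq_along), use.names = FALSE)
    slot <- slot[order(unlist(split(seq_len(model$n_genes), chrom_of_gene),
                              use.names = FALSE))]
    start <- (slot - 1L) * 20000L + 1L
    stop_ <- start + 9999L
    pos <- unlist(lapply(seq_len(model$n_genes), function(g) {
      sort(sample.int(10000L, nv[g])) + start[g] - 1L
    }), use.names = FALSE)

    storage.mode(G) <- "integer"
    dimnames(G) <- list(ids, sprintf("V%05d", seq_len(V)))
    variants <- data.frame(variant_id = colnames(G),
                           chrom = rep(chrom_of_gene, nv),
                           pos = pos,
                           gene = gene_of,
                           nonsynonymous = nonsyn,
                           maf = maf,
                           stringsAsFactors = FALSE)
    genes <- data.frame(gene = gene_names, chrom = chrom_of_gene,
                        start = start, stop = stop_,
                        stringsAsFactors = FALSE)
    individuals <- data.frame(individual_id = ids, stratum = stratum_of,
                              stringsAsFactors = FALSE)
    structure(list(genotypes = G, variants = variants, genes = genes,
                   individuals = individuals),
              class = "rareload_dataset")
  })
}

#' @export
print.rareload_dataset <- function(x, ...) {
  cat(sprintf("rareload_dataset: %d individuals x %d variants in %d genes\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$genes)))
  cat(sprintf("  strata: %s\n",
              paste(sprintf("%s (%d)", names(table(x$individuals$stratum)),
                            table(x$individuals$stratum)), collapse = ", ")))
  cat(sprintf("  pooled MAF range: %.4f-%.4f\n",
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' Trait model: causal architecture for synthetic phenotypes
#'
#' Defines how phenotypes are generated from a fixed genotype matrix.
#' Two quantitative traits (`Q1`, `Q2`) receive gene-level burden effects
#' from disjoint causal gene sets; `Q4` has an empty causal set (pure
#' covariates + noise, the null trait); a dichotomous trait `CC` is
#' obtained by thresholding a liability score built from Q1, Q2, Q4,
#' additional causal-gene burdens and unit Gaussian noise at the quantile
#' giving the requested prevalence.
#'
#' A gene's contribution to a trait is `effect * (r / J)`, where `r` is the
#' number of the gene's rare variants at which the individual carries at
#' least one minor allele and `J` the gene's rare-variant count — the same
#' carrier-burden proportion the association test uses.
#'
#' @param q1_effects,q2_effects Named numeric vectors mapping causal gene
#'   names to effect sizes (phenotype units per unit burden proportion).
#' @param liability_gene_effects Named numeric vector: extra genes acting
#'   directly on disease liability.
#' @param liability_weights Coefficients of `Q1`, `Q2`, `Q4` in the
#'   liability score.
#' @param disease_prevalence Target case proportion in `(0, 1)`.
#' @param residual_sd Residual standard deviation of the quantitative
#'   traits.
#' @param covariate_effects Coefficients for the simulated covariates
#'   `sex` (Bernoulli 0.5), `age` (uniform on 20-80 years) and `smoking`
#'   (Bernoulli 0.3).
#' @param rare_maf_threshold Variants with pooled MAF below this enter the
#'   causal burden (matches the analysis definition of "rare").
#' @param n_replicates Number of phenotype replicates drawn on the one
#'   fixed genotype matrix.
#' @param seed Integer seed for the phenotype noise draws.
#' @return An object of class `trait_model`.
#' @seealso [simulate_phenotypes()], [default_trait_model()]
#' @export
trait_model <- function(q1_effects = NULL, q2_effects = NULL,
                        liability_gene_effects = NULL,
                        liability_weights = c(Q1 = 0.4, Q2 = 0.4, Q4 = 0.4),
                        disease_prevalence = 0.3,
                        residual_sd = 1,
                        covariate_effects = c(sex = 0.5, age = 0.01, smoking = 0.3),
                        rare_maf_threshold = 0.05,
                        n_replicates = 200L,
                        seed = NULL) {
  check_number(disease_prevalence, "disease_prevalence", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(residual_sd, "residual_sd", lower = 0, closed_lower = FALSE)
  check_number(rare_maf_threshold, "rare_maf_threshold", 0, 0.5,
               closed_lower = FALSE)
  n_replicates <- check_count(n_replicates, "n_replicates")
  stopifnot(all(c("Q1", "Q2", "Q4") %in% names(liability_weights)),
            all(c("sex", "age", "smoking") %in% names(covariate_effects)))
  named_or_empty <- function(x, nm) {
    if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(x)) || any(names(x) == "")) {
      stop(sprintf("`%s` must be a named numeric vector (gene -> effect)", nm))
    }
    x
  }
  structure(list(q1_effects = named_or_empty(q1_effects, "q1_effects"),
                 q2_effects = named_or_empty(q2_effects, "q2_effects"),
                 liability_gene_effects =
                   named_or_empty(liability_gene_effects, "liability_gene_effects"),
                 liability_weights = liability_weights,
                 disease_prevalence = disease_prevalence,
                 residual_sd = residual_sd,
                 covariate_effects = covariate_effects,
                 rare_maf_threshold = rare_maf_threshold,
                 n_replicates = n_replicates,
                 seed = seed),
            class = "trait_model")
}

#' Default causal architecture for a simulated dataset
#'
#' Picks causal genes deterministically from the dataset's gene panel:
#' 9 genes for Q1 (one strong, one moderate, seven weak effects), 13 for
#' Q2 (uniformly weak), and 15 further genes acting on disease liability.
#' Effect sizes are in residual-SD units per unit burden proportion.
#'
#' @param dataset A `rareload_dataset`.
#' @param ... Passed on to [trait_model()].
#' @return A [trait_model()].
#' @export
default_trait_model <- function(dataset, ...) {
  genes <- dataset$genes$gene
  need <- 9 + 13 + 15
  if (length(genes) < need) {
    stop(sprintf("dataset has %d genes; >= %d needed for the default architecture",
                 length(genes), need))
  }
  pick <- genes[seq_len(need)]
  q1 <- stats::setNames(c(3, 1.5, rep(0.5, 7)), pick[1:9])
  q2 <- stats::setNames(rep(0.6, 13), pick[10:22])
  extra <- stats::setNames(rep(0.8, 15), pick[23:37])
  trait_model(q1_effects = q1, q2_effects = q2,
              liability_gene_effects = extra, ...)
}

# carrier-burden proportion r/J per individual for each named gene,
# using the gene's rare variants (pooled MAF < threshold)
gene_burden_matrix <- function(dataset, genes, maf_threshold) {
  v <- dataset$variants
  out <- matrix(0, nrow(dataset$genotypes), length(genes),
                dimnames = list(rownames(dataset$genotypes), genes))
  for (g in genes) {
    cols <- v$variant_id[v$gene == g & v$maf < maf_threshold]
    if (length(cols) == 0L) {
      warning(sprintf("causal gene %s has no rare variants; contributes 0", g))
      next
    }
    sub <- dataset$genotypes[, cols, drop = FALSE]
    out[, g] <- rowSums(sub > 0, na.rm = TRUE) / length(cols)
  }
  out
}

#' Simulate replicate phenotypes on a fixed genotype matrix
#'
#' Generates covariates once per dataset, then `n_replicates` independent
#' noise draws of the quantitative traits `Q1`, `Q2`, `Q4` and the
#' liability-threshold disease trait `CC` (see [trait_model()]), all on the
#' same genotypes. Replicate columns are named `<trait>_r<k>`, e.g.
#' `Q1_r17`; see [trait_column()].
#'
#' @param dataset A `rareload_dataset` from [simulate_genotypes()].
#' @param tm A [trait_model()]; causal genes must exist in the dataset.
#' @return Data frame with `individual_id`, `stratum`, `sex`, `age`,
#'   `smoking`, then one column per trait replicate. The replicate count is
#'   stored in `attr(, "n_replicates")`.
#' @export
simulate_phenotypes <- function(dataset, tm) {
  stopifnot(inherits(dataset, "rareload_dataset"), inherits(tm, "trait_model"))
  all_causal <- unique(c(names(tm$q1_effects), names(tm$q2_effects),
                         names(tm$liability_gene_effects)))
  missing_genes <- setdiff(all_causal, dataset$genes$gene)
  if (length(missing_genes) > 0L) {
    stop("causal gene(s) absent from the dataset: ",
         paste(missing_genes, collapse = ", "))
  }
  n <- nrow(dataset$genotypes)
  with_seed(tm$seed, {
    sex <- stats::rbinom(n, 1L, 0.5)
    age <- stats::runif(n, 20, 80)
    smoking <- stats::rbinom(n, 1L, 0.3)
    covar_part <- tm$covariate_effects[["sex"]] * sex +
      tm$covariate_effects[["age"]] * age +
      tm$covariate_effects[["smoking"]] * smoking

    B <- gene_burden_matrix(dataset, all_causal, tm$rare_maf_threshold)
    gen_q1 <- if (length(tm$q1_effects))
      drop(B[, names(tm$q1_effects), drop = FALSE] %*% tm$q1_effects) else 0
    gen_q2 <- if (length(tm$q2_effects))
      drop(B[, names(tm$q2_effects), drop = FALSE] %*% tm$q2_effects) else 0
    gen_extra <- if (length(tm$liability_gene_effects))
      drop(B[, names(tm$liability_gene_effects), drop = FALSE] %*%
             tm$liability_gene_effects) else 0

    R <- tm$n_replicates
    cols <- vector("list", 4L * R)
    nms <- character(4L * R)
    w <- tm$liability_weights
    for (r in seq_len(R)) {
      q1 <- covar_part + gen_q1 + stats::rnorm(n, 0, tm$residual_sd)
      q2 <- covar_part + gen_q2 + stats::rnorm(n, 0, tm$residual_sd)
      q4 <- covar_part + stats::rnorm(n, 0, tm$residual_sd)
      liab <- w[["Q1"]] * q1 + w[["Q2"]] * q2 + w[["Q4"]] * q4 +
        gen_extra + stats::rnorm(n)
      n_cases <- max(1L, round(n * tm$disease_prevalence))
      thr <- sort(liab, decreasing = TRUE)[n_cases]
      cc <- as.integer(liab >= thr)
      k <- 4L * (r - 1L)
      cols[[k + 1L]] <- q1; nms[k + 1L] <- trait_column("Q1", r)
      cols[[k + 2L]] <- q2; nms[k + 2L] <- trait_column("Q2", r)
      cols[[k + 3L]] <- q4; nms[k + 3L] <- trait_column("Q4", r)
      cols[[k + 4L]] <- cc; nms[k + 4L] <- trait_column("CC", r)
    }
    names(cols) <- nms
    out <- cbind(data.frame(individual_id = dataset$individuals$individual_id,
                            stratum = dataset$individuals$stratum,
                            sex = sex, age = age, smoking = smoking,
                            stringsAsFactors = FALSE),
                 as.data.frame(cols, check.names = FALSE))
    attr(out, "n_replicates") <- R
    attr(out, "traits") <- c("Q1", "Q2", "Q4", "CC")
    out
  })
}

#' Column name of a trait replicate in a phenotype table
#'
#' @param trait Trait name, e.g. `"Q1"` or `"CC"`.
#' @param replicate Replicate index (1-based).
#' @return Character column name, e.g. `"Q1_r17"`.
#' @export
trait_column <- function(trait, replicate) {
  sprintf("%s_r%d", trait, as.integer(replicate))
}

#' Number of phenotype replicates stored in a phenotype table
#'
#' @param phenotypes A phenotype table from [simulate_phenotypes()] or
#'   [read_phenotypes()].
#' @return Integer replicate count.
#' @export
n_phenotype_replicates <- function(phenotypes) {
  r <- attr(phenotypes, "n_replicates")
  if (!is.null(r)) return(as.integer(r))
  reps <- grep("^Q1_r[0-9]+$", names(phenotypes), value = TRUE)
  if (length(reps) == 0L) stop("no trait replicate columns found")
  max(as.integer(sub("^Q1_r", "", reps)))
}
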