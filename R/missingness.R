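#' Missing-genotype injection model
#'
#' Two failure mechanisms are supported, mirroring how genotype calls fail
#' in practice. Under `random`, every eligible call fails independently
#' with probability `random_rate`. Under `allele_specific`, the failure
#' probability depends on the underlying genotype, because the minor
#' (mutant) allele is harder to call than the reference allele: major-
#' allele homozygotes fail at `rate_common_hom`, heterozygotes at
#' `rate_het`, minor-allele homozygotes at `rate_rare_hom` (defaults
#' 1%/5%/10%). `none` is the identity.
#'
#' By default only calls at *rare* variants (pooled MAF below
#' `rare_maf_threshold`) are eligible for removal; set
#' `restrict_to_rare = FALSE` to expose all variants.
#'
#' @param kind One of `"none"`, `"random"`, `"allele_specific"`.
#' @param random_rate Per-call failure probability for `kind = "random"`.
#' @param rate_common_hom,rate_het,rate_rare_hom Class-specific failure
#'   probabilities for `kind = "allele_specific"`.
#' @param restrict_to_rare Restrict eligibility to rare variants?
#' @param rare_maf_threshold MAF threshold defining "rare" for
#'   eligibility.
#' @param seed Optional integer seed for the failure mask; `NULL` uses the
#'   ambient RNG stream.
#' @param label Short label used in power tables; a default is derived
#'   from the model kind and rates.
#' @return An object of class `missingness_model`.
#' @export
missingness_model <- function(kind = c("none", "random", "allele_specific"),
                              random_rate = 0,
                              rate_common_hom = 0.01,
                              rate_het = 0.05,
                              rate_rare_hom = 0.10,
                              restrict_to_rare = TRUE,
                              rare_maf_threshold = 0.05,
                              seed = NULL,
                              label = NULL) {
  kind <- match.arg(kind)
  check_number(random_rate, "random_rate", 0, 1)
  check_number(rate_common_hom, "rate_common_hom", 0, 1)
  check_number(rate_het, "rate_het", 0, 1)
  check_number(rate_rare_hom, "rate_rare_hom", 0, 1)
  check_number(rare_maf_threshold, "rare_maf_threshold", 0, 0.5,
               closed_lower = FALSE)
  if (is.null(label)) {
    label <- switch(kind,
      none = "complete",
      random = sprintf("random_%g", random_rate),
      allele_specific = sprintf("allele_specific_%g_%g_%g",
                                rate_common_hom, rate_het, rate_rare_hom))
  }
  structure(list(kind = kind, random_rate = random_rate,
                 rate_common_hom = rate_common_hom, rate_het = rate_het,
                 rate_rare_hom = rate_rare_hom,
                 restrict_to_rare = isTRUE(restrict_to_rare),
                 rare_maf_threshold = rare_maf_threshold,
                 seed = seed, label = label),
            class = "missingness_model")
}

#' Inject missing genotype calls
#'
#' Sets eligible genotype calls to `NA` according to a
#' [missingness_model()]. Each (individual, variant) call is an
#' independent Bernoulli failure; retained calls are never altered, and
#' the input matrix is not modified in place. Genotype classes for the
#' allele-specific model are defined on the minor-allele dosage: 0 =
#' common (major-allele) homozygote, 1 = heterozygote, 2 = rare
#' (minor-allele) homozygote, with the minor allele fixed on the
#' pre-missingness pooled sample.
#'
#' @param genotypes Integer dosage matrix (individuals x variants, `NA` =
#'   already missing).
#' @param variants Variant table with `variant_id` and `maf` columns;
#'   required when eligibility is restricted to rare variants.
#' @param model A [missingness_model()].
#' @return The genotype matrix with additional `NA` entries. Realized
#'   per-variant call rates are available via [call_rates()].
#' @examples
#' G <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("v1", "v2")))
#' v <- data.frame(variant_id = c("v1", "v2"), maf = c(0.01, 0.02))
#' inject_missing(G, v, missingness_model("random", random_rate = 1, seed = 1))
#' @export
inject_missing <- function(genotypes, variants = NULL, model = missingness_model()) {
  stopifnot(is.matrix(genotypes), inherits(model, "missingness_model"))
  if (model$kind == "none") return(genotypes)

  elig_cols <- seq_len(ncol(genotypes))
  if (model$restrict_to_rare || model$kind == "allele_specific") {
    if (is.null(variants) || is.null(variants$maf)) {
      stop("`variants` with a `maf` column is required for this model")
    }
  }
  if (model$restrict_to_rare) {
    maf <- variants$maf[match(colnames(genotypes), variants$variant_id)]
    if (anyNA(maf)) stop("some genotype columns are absent from `variants`")
    elig_cols <- which(maf < model$rare_maf_threshold)
    if (length(elig_cols) == 0L) return(genotypes)
  }

  with_seed(model$seed, {
    sub <- genotypes[, elig_cols, drop = FALSE]
    p <- if (model$kind == "random") {
      matrix(model$random_rate, nrow(sub), ncol(sub))
    } else {
      rates <- c(model$rate_common_hom, model$rate_het, model$rate_rare_hom)
      matrix(rates[sub + 1L], nrow(sub), ncol(sub))
    }
    fail <- matrix(stats::runif(length(sub)) < p, nrow(sub), ncol(sub))
    fail[is.na(fail)] <- FALSE          # already-missing calls stay as they are
    sub[fail] <- NA_integer_
    genotypes[, elig_cols] <- sub
    genotypes
  })
}

#' Realized per-variant call rates
#'
#' @param genotypes Genotype dosage matrix with `NA` for missing calls.
#' @return Named numeric vector: fraction of non-missing calls per
#'   variant.
#' @export
call_rates <- function(genotypes) {
  colMeans(!is.na(genotypes))
}
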