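# internal validation and numeric helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG seed, restoring the ambient RNG state;
# seed = NULL means "use the current stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!all(lo_ok & hi_ok)) {
    stop(sprintf("`%s` out of range %s%s, %s%s", name,
                 if (closed_lower) "[" else "(", format(lower), format(upper),
                 if (closed_upper) "]" else ")"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower) {
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Smallest attainable nonzero minor allele frequency
#'
#' In a diploid sample of `n` individuals the rarest polymorphic variant is
#' a singleton: one minor-allele copy among `2 * n` chromosomes. For the
#' 697-individual exome panel emulated by [simulate_genotypes()] this equals
#' 1/1394, i.e. 0.07% when rounded to two decimals.
#'
#' @param n_individuals Number of diploid individuals (positive integer).
#' @return The frequency `1 / (2 * n_individuals)` as a proportion.
#' @examples
#' round(100 * min_attainable_maf(697), 2)
#' @export
min_attainable_maf <- function(n_individuals) {
  n <- check_count(n_individuals, "n_individuals")
  1 / (2 * n)
}

# Wilson score interval for a binomial proportion; returns c(low, high).
# Nondegenerate (never collapses to [0,0] or [1,1]) for finite n.
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# draw independent sub-seeds from a master seed (kept below 2^31)
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
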