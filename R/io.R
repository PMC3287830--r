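# Readers and writers for the plain-text interchange formats: VCF,
# TSV genotype matrix, gene list, variant map and phenotype table.
# All coordinates are 1-based inclusive, matching VCF convention.

#' Assign variants to gene regions by position
#'
#' A variant belongs to gene G iff the chromosome matches and
#' `start <= pos <= stop` (inclusive bounds). A variant inside several
#' overlapping genes is assigned to each of them; a variant inside none
#' is omitted from the mapping (and hence from all gene tests).
#' Chromosome naming conventions must agree across files: a mismatch such
#' as `"chr1"` vs `"1"` raises an error rather than being silently
#' normalized.
#'
#' @param variants Variant table with `variant_id`, `chrom`, `pos`.
#' @param genes Gene regions with `gene`, `chrom`, `start`, `stop`.
#' @return Data frame `variant_id`, `gene` (long format, one row per
#'   assignment).
#' @export
assign_variants_to_genes <- function(variants, genes) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            all(c("gene", "chrom", "start", "stop") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("gene names must be unique")
  if (any(genes$start > genes$stop)) stop("gene with start > stop")
  vchr <- unique(as.character(variants$chrom))
  gchr <- unique(as.character(genes$chrom))
  if (nrow(variants) > 0L && !any(vchr %in% gchr)) {
    strip <- function(x) sub("^chr", "", x)
    if (any(strip(vchr) %in% strip(gchr))) {
      stop("chromosome naming convention mismatch between variant and gene ",
           "files (e.g. \"chr1\" vs \"1\"); harmonize the inputs")
    }
  }
  out <- vector("list", length(gchr))
  for (i in seq_along(gchr)) {
    ch <- gchr[i]
    vi <- which(as.character(variants$chrom) == ch)
    gi <- which(as.character(genes$chrom) == ch)
    if (length(vi) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(variants$pos[vi], variants$pos[vi]),
      IRanges::IRanges(genes$start[gi], genes$stop[gi]))
    out[[i]] <- data.frame(
      variant_id = variants$variant_id[vi[S4Vectors::queryHits(hits)]],
      gene = genes$gene[gi[S4Vectors::subjectHits(hits)]],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(variant_id = character(0),
                                      gene = character(0))
  rownames(res) <- NULL
  res
}

# dosage (0/1/2/NA) -> VCF GT strings
.dosage_to_gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write genotypes as a plain-text VCF
#'
#' One sample column per individual; dosages map to GT as 0 -> `0/0`,
#' 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`. The ALT allele is the minor
#' allele (the allele the dosages count). Nonsynonymous variants carry
#' the INFO tag `NS=1`.
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param variants Variant table with `variant_id`, `chrom`, `pos` and
#'   optionally `nonsynonymous`.
#' @param path Output file path (`.vcf`, uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, variants, path) {
  idx <- match(colnames(genotypes), variants$variant_id)
  if (anyNA(idx)) stop("genotype columns missing from variant table")
  v <- variants[idx, , drop = FALSE]
  gt <- matrix(.dosage_to_gt[as.character(genotypes)],
               nrow(genotypes), ncol(genotypes))
  gt[is.na(genotypes)] <- "./."
  info <- if (is.null(v$nonsynonymous)) rep(".", nrow(v)) else
    ifelse(as.logical(v$nonsynonymous), "NS=1", ".")
  header <- c("##fileformat=VCFv4.2",
              "##source=rareload",
              "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Nonsynonymous (1) or synonymous (0)\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- apply(cbind(as.character(v$chrom), v$pos, v$variant_id, "A", "C",
                      ".", "PASS", info, "GT", t(gt)),
                1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write genotypes as a TSV matrix
#'
#' Rows are individuals, columns variants, cells minor-allele dosages in
#' `{0, 1, 2, NA}`. The first column, `individual_id`, holds row names.
#'
#' @inheritParams write_genotypes_vcf
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(individual_id = rownames(genotypes),
                   genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from VCF or TSV
#'
#' VCF GT fields are converted to dosages of the *minor* allele: after
#' parsing, the pooled ALT-allele frequency is computed and variants where
#' ALT is the major allele (frequency > 0.5) are flipped, so dosages
#' always count the minor allele (orientation fixed on the pooled
#' sample). `./.` and `.` become `NA`. Multi-allelic records are
#' rejected. The INFO tag `NS=1` is honored as the nonsynonymous flag.
#'
#' For the TSV dialect (see [write_genotypes_tsv()]) coordinates and
#' functional class are not stored in the file; the returned variant
#' table carries realized MAFs only, and positions should be merged from
#' the map file ([read_variant_map()]).
#'
#' @param path Input file.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @return List with `genotypes` (dosage matrix) and `variants` (data
#'   frame `variant_id`, `chrom`, `pos`, `nonsynonymous`, `maf`; `chrom`,
#'   `pos` and `nonsynonymous` are `NA` for TSV input).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") .read_genotypes_vcf(path) else .read_genotypes_tsv(path)
}

.read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    bad <- fix$ID[grepl(",", fix$ALT, fixed = TRUE)]
    stop("multi-allelic record(s) not supported: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf)                 # variants x samples
  # GT -> ALT dosage; any token containing "." is a missing call
  gvec <- as.vector(gt)
  dose <- rep(NA_integer_, length(gvec))
  known <- !is.na(gvec) & !grepl(".", gvec, fixed = TRUE)
  if (any(known)) {
    alleles <- strsplit(gvec[known], "[/|]")
    if (any(lengths(alleles) != 2L)) {
      stop("malformed (non-diploid) GT field encountered")
    }
    av <- unlist(alleles, use.names = FALSE)
    if (any(!av %in% c("0", "1"))) {
      stop("GT allele index other than 0/1 encountered")
    }
    dose[known] <- vapply(alleles, function(a) sum(a == "1"), 0L)
  }
  G <- t(matrix(dose, nrow(gt), ncol(gt), dimnames = dimnames(gt)))
  # minor-allele orientation on the pooled sample
  freq <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  G[, flip] <- 2L - G[, flip]
  storage.mode(G) <- "integer"
  maf <- colMeans(G, na.rm = TRUE) / 2
  info <- fix$INFO
  nonsyn <- grepl("(^|;)NS=1(;|$)", info)
  variants <- data.frame(variant_id = colnames(G),
                         chrom = as.character(fix$CHROM),
                         pos = as.integer(fix$POS),
                         nonsynonymous = nonsyn,
                         maf = maf,
                         stringsAsFactors = FALSE)
  list(genotypes = G, variants = variants)
}

.read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "individual_id") {
    stop("TSV genotype matrix must start with an `individual_id` column")
  }
  G <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df$individual_id
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) stop("genotype codes outside {0, 1, 2, NA} in ", path)
  variants <- data.frame(variant_id = colnames(G),
                         chrom = NA_character_, pos = NA_integer_,
                         nonsynonymous = NA,
                         maf = colMeans(G, na.rm = TRUE) / 2,
                         stringsAsFactors = FALSE)
  list(genotypes = G, variants = variants)
}

#' Write / read the gene list (gene, chrom, start, stop)
#'
#' Tab-separated, 1-based inclusive coordinates.
#'
#' @param genes Gene regions data frame.
#' @param path File path.
#' @return `path` invisibly (writer); the gene data frame (reader).
#' @export
write_gene_list <- function(genes, path) {
  utils::write.table(genes[c("gene", "chrom", "start", "stop")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character",
                                        "integer", "integer"),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "stop") %in% names(g)))
  if (anyDuplicated(g$gene)) stop("duplicate gene names in ", path)
  if (any(g$start > g$stop)) stop("gene with start > stop in ", path)
  g
}

#' Write / read the variant map (variant_id, chrom, pos, nonsynonymous)
#'
#' @param variants Variant table.
#' @param path File path.
#' @return `path` invisibly (writer); the variant map data frame
#'   (reader).
#' @export
write_variant_map <- function(variants, path) {
  v <- variants[c("variant_id", "chrom", "pos")]
  v$nonsynonymous <- if (is.null(variants$nonsynonymous)) NA_integer_ else
    as.integer(variants$nonsynonymous)
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_map
#' @export
read_variant_map <- function(path) {
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character",
                                        "integer", "integer"),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(v)))
  if (!is.null(v$nonsynonymous)) v$nonsynonymous <- v$nonsynonymous == 1L
  v
}

#' Write / read the phenotype table
#'
#' Tab-separated: `individual_id`, `stratum`, covariates, then one column
#' per trait replicate (`<trait>_r<k>`).
#'
#' @param phenotypes Phenotype table.
#' @param path File path.
#' @return `path` invisibly (writer); the phenotype data frame (reader).
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("individual_id" %in% names(p))
  reps <- grep("^Q1_r[0-9]+$", names(p), value = TRUE)
  if (length(reps) > 0L) {
    attr(p, "n_replicates") <- max(as.integer(sub("^Q1_r", "", reps)))
  }
  p
}

#' Write a simulated dataset to a directory
#'
#' Emits `genotypes.vcf`, `genotypes.tsv`, `genes.tsv`, `variants.tsv`
#' and (when phenotypes are supplied) `phenotypes.tsv`.
#'
#' @param dataset A `rareload_dataset`.
#' @param dir Output directory (created if absent).
#' @param phenotypes Optional phenotype table.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, phenotypes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotypes_vcf(dataset$genotypes, dataset$variants,
                      file.path(dir, "genotypes.vcf"))
  write_genotypes_tsv(dataset$genotypes, file.path(dir, "genotypes.tsv"))
  write_gene_list(dataset$genes, file.path(dir, "genes.tsv"))
  write_variant_map(dataset$variants, file.path(dir, "variants.tsv"))
  if (!is.null(phenotypes)) {
    write_phenotypes(phenotypes, file.path(dir, "phenotypes.tsv"))
  }
  invisible(dir)
}

#' Write per-gene association results as TSV
#'
#' @param results A stratum-results or meta-results data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
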