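# Small in-code fixtures shared across test files.

# genotype object from a plain codes matrix; metadata generated. Columns
# whose counted-allele frequency exceeds 0.5 are re-oriented (the container
# counts MINOR alleles); het/hom status is unaffected.
make_geno <- function(codes, chrom = "1", pos = NULL, ids = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  pos <- pos %||% seq(1000, by = 1000, length.out = m)
  chrom <- rep_len(chrom, m)
  ids <- ids %||% paste0("v", seq_len(m))
  f <- colMeans(codes, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  codes[, flip] <- 2 - codes[, flip, drop = FALSE]
  variants <- tibble::tibble(
    id = ids, chrom = chrom, pos = pos,
    ref = rep("A", m), alt = rep("G", m),
    minor = ifelse(flip, "A", "G"))
  geno_matrix(codes, variants, sprintf("s%02d", seq_len(nrow(codes))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small LD-free random genotypes under HWE
random_geno <- function(n, m, maf = NULL, seed = 1, chrom = "1") {
  set.seed(seed)
  p <- maf %||% runif(m, 0.1, 0.5)
  codes <- sapply(seq_len(m), function(j) rbinom(n, 2, p[j]))
  make_geno(codes, chrom = chrom)
}
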