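# Readers/writers for the standard exchange formats: VCF 4.2 (GT only),
# PLINK .ped/.map text, and the TSV phenotype/covariate table.

#' Read genotypes from VCF or PLINK text files
#'
#' Biallelic SNV records are mapped to minor-allele counts; the minor allele
#' is determined from the sample allele frequencies in the file and fixed
#' from then on. `./.` (or `0 0` in a .ped) becomes a missing call.
#'
#' @param path For `format = "vcf"`, the VCF file; for `format =
#'   "plink_text"`, the common prefix of the `.ped`/`.map` pair (a path
#'   ending in `.ped` or `.map` is also accepted).
#' @param format `"vcf"` or `"plink_text"`.
#' @return A [geno_matrix()].
#' @details A `DR2=` entry in the VCF INFO column is carried through as the
#'   per-variant `quality` metadata field (imputation dosage-R2 style
#'   pass-through; it is never computed by this package). Multi-allelic
#'   records are rejected with their coordinates; unsorted input is rejected
#'   naming the first offending pair of positions. When the allele frequency
#'   is exactly 0.5 the ALT (VCF) or lexicographically larger (PLINK) allele
#'   is labelled minor, so the orientation is deterministic.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  if (format == "vcf") read_vcf_geno(path) else read_plink_geno(path)
}

read_vcf_geno <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi)) {
    i <- which(multi)[1]
    stop("multi-allelic or non-SNV record at ", fix$CHROM[i], ":", fix$POS[i])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  # count ALT alleles; any genotype containing '.' is missing
  alt_count <- function(g) {
    out <- rep(NA_real_, length(g))
    known <- !is.na(g) & !grepl("\\.", g)
    out[known] <- vapply(strsplit(g[known], "[/|]"),
                         function(a) sum(a == "1"), numeric(1))
    out
  }
  ac <- t(apply(gt, 1, alt_count))  # variants x samples
  codes <- t(ac)                     # samples x variants (ALT counts)
  pos <- as.numeric(fix$POS)
  quality <- rep(NA_real_, nrow(fix))
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("DR2=[0-9.eE+-]+", fix$INFO))
    has <- grepl("DR2=", fix$INFO)
    quality[has] <- as.numeric(sub("DR2=", "", m))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  # orient to minor-allele counts from sample frequencies
  nn <- colSums(!is.na(codes))
  if (any(nn == 0)) stop("variant ", ids[which(nn == 0)[1]], " is entirely missing")
  f_alt <- unname(colSums(codes, na.rm = TRUE) / (2 * nn))
  minor_is_alt <- f_alt <= 0.5
  codes[, !minor_is_alt] <- 2 - codes[, !minor_is_alt, drop = FALSE]
  variants <- tibble(
    id = ids, chrom = fix$CHROM, pos = pos,
    ref = fix$REF, alt = fix$ALT,
    minor = ifelse(minor_is_alt, fix$ALT, fix$REF),
    quality = quality
  )
  check_sorted_input(variants)
  geno_matrix(codes, variants, samples)
}

check_sorted_input <- function(variants) {
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    d <- diff(p)
    if (length(d) && any(d <= 0)) {
      i <- which(d <= 0)[1]
      stop("input not sorted on chromosome ", ch, ": position ", p[i + 1],
           " follows ", p[i])
    }
  }
  invisible(TRUE)
}

plink_prefix <- function(path) sub("\\.(ped|map)$", "", path)

read_plink_geno <- function(path) {
  prefix <- plink_prefix(path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  map <- read.table(map_path, header = FALSE, sep = "",
                    colClasses = c("character", "character", "numeric", "numeric"))
  names(map) <- c("chrom", "id", "cm", "pos")
  ped <- read.table(ped_path, header = FALSE, sep = "",
                    colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop(".ped has ", ncol(ped), " columns; expected ", 6 + 2 * m,
         " for ", m, " variants")
  }
  samples <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  codes <- matrix(NA_real_, nrow(ped), m)
  alleles_ref <- character(m)
  alleles_alt <- character(m)
  minor <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    missing <- x1 == "0" | x2 == "0"
    obs <- c(x1[!missing], x2[!missing])
    if (!length(obs)) stop("variant ", map$id[j], " is entirely missing")
    tab <- sort(table(obs), decreasing = TRUE)
    als <- names(tab)
    if (length(als) > 2) stop("more than two alleles for variant ", map$id[j],
                              " at ", map$chrom[j], ":", map$pos[j])
    if (length(als) == 1) {
      als <- c(als, setdiff(c("A", "C", "G", "T"), als)[1])
      tab <- c(tab, 0)
    }
    # minor = rarer allele; lexicographically larger one on an exact tie
    if (tab[[1]] == tab[[2]]) {
      mi <- max(als)
    } else {
      mi <- als[which.min(c(tab[[1]], tab[[2]]))]
    }
    ma <- setdiff(als, mi)[1]
    codes[, j] <- (x1 == mi) + (x2 == mi)
    codes[missing, j] <- NA_real_
    alleles_ref[j] <- ma
    alleles_alt[j] <- mi
    minor[j] <- mi
  }
  variants <- tibble(id = map$id, chrom = map$chrom, pos = map$pos,
                     ref = alleles_ref, alt = alleles_alt, minor = minor,
                     quality = NA_real_)
  check_sorted_input(variants)
  geno_matrix(codes, variants, samples)
}

#' Write genotypes to VCF or PLINK text files
#'
#' Emits a standard-conformant GT-only VCF 4.2 file or a space-separated
#' `.ped`/`.map` pair. Reading the result back with [read_genotypes()]
#' round-trips codes, sample order and variant metadata.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path (for PLINK, the prefix of the `.ped`/`.map` pair).
#' @param format `"vcf"` or `"plink_text"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(geno$samples) == 0) stop("refusing to write a genotype file with no samples")
  if (nrow(geno$variants) == 0) stop("refusing to write a genotype file with no variants")
  if (format == "vcf") write_vcf_geno(geno, path) else write_plink_geno(geno, path)
  invisible(path)
}

write_vcf_geno <- function(geno, path) {
  v <- geno$variants
  minor_is_alt <- v$minor == v$alt
  # convert minor counts back to ALT counts
  alt_counts <- t(t(geno$codes) * ifelse(minor_is_alt, 1, -1) +
                    ifelse(minor_is_alt, 0, 2))
  gt_strings <- matrix("./.", nrow(alt_counts), ncol(alt_counts))
  gt_strings[!is.na(alt_counts) & alt_counts == 0] <- "0/0"
  gt_strings[!is.na(alt_counts) & alt_counts == 1] <- "0/1"
  gt_strings[!is.na(alt_counts) & alt_counts == 2] <- "1/1"
  info <- ifelse(is.na(v$quality), ".", sprintf("DR2=%g", v$quality))
  body <- cbind(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                v$id, v$ref, v$alt, ".", "PASS", info, "GT",
                t(gt_strings))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Pass-through dosage R-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
}

write_plink_geno <- function(geno, path) {
  prefix <- plink_prefix(path)
  v <- geno$variants
  map <- data.frame(chrom = v$chrom, id = v$id, cm = 0,
                    pos = format(v$pos, scientific = FALSE, trim = TRUE))
  write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  major <- ifelse(v$minor == v$alt, v$ref, v$alt)
  n <- length(geno$samples)
  m <- nrow(v)
  al <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    cj <- geno$codes[, j]
    a1 <- ifelse(is.na(cj), "0", ifelse(cj >= 1, v$minor[j], major[j]))
    a2 <- ifelse(is.na(cj), "0", ifelse(cj == 2, v$minor[j], major[j]))
    al[, 2 * j - 1] <- a1
    al[, 2 * j] <- a2
  }
  ped <- cbind("FAM", geno$samples, "0", "0", "0", "-9", al)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  writeLines(apply(ped, 1, paste, collapse = " "), con)
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with a header row and at least the columns `sample`,
#' one or more trait columns, and any of `age_days`, `age_class`, `sex`,
#' `judge`, `event`.
#'
#' @param path TSV file path.
#' @return A tibble, one row per sample.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"sample" %in% names(df)) stop("phenotype table lacks a 'sample' column")
  df$sample <- as.character(df$sample)
  as_tibble(df)
}

#' Write a phenotype/covariate table
#'
#' @param pheno A data frame with a `sample` column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Validate a phenotype table against a genotype matrix
#'
#' Checks that every phenotyped sample resolves to a genotyped sample and
#' that ordinal trait scores are integers within their scale.
#'
#' @param pheno Phenotype tibble.
#' @param geno A [geno_matrix()].
#' @param ordinal_traits Character vector of ordinal trait columns scored on
#'   the signed -3..+3 scale.
#' @param defect_traits Character vector of defect-trait columns scored on
#'   the 0..+3 scale.
#' @return `pheno`, invisibly, or an error.
#' @export
validate_phenotypes <- function(pheno, geno, ordinal_traits = character(),
                                defect_traits = character()) {
  unknown <- setdiff(pheno$sample, geno$samples)
  if (length(unknown)) {
    stop("phenotyped sample(s) absent from genotypes: ",
         paste(head(unknown, 3), collapse = ", "))
  }
  check_scale <- function(cols, lo, hi) {
    for (tr in cols) {
      x <- pheno[[tr]]
      x <- x[!is.na(x)]
      if (any(x != round(x)) || any(x < lo | x > hi)) {
        stop("trait ", tr, " has scores outside the integer ", lo, "..",
             hi, " scale")
      }
    }
  }
  check_scale(ordinal_traits, -3, 3)
  check_scale(defect_traits, 0, 3)
  invisible(pheno)
}
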