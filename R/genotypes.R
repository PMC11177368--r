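# Genotype container: individuals x biallelic variants, coded as counts of
# the MINOR allele (0/1/2, NA = missing). The minor allele is fixed when the
# object is built and never re-polarised downstream, so conditional analyses
# and LD stay on one consistent dosage scale.

#' Construct a genotype matrix object
#'
#' Bundles a numeric matrix of minor-allele counts with per-variant metadata
#' and sample identifiers. Genotype codes count copies of the minor allele
#' (0, 1, 2); `NA` marks a missing call. The per-variant minor-allele
#' frequency is recomputed from the codes and stored in `variants$maf`.
#'
#' @param codes Numeric matrix, samples in rows, variants in columns; values
#'   in \{0, 1, 2, NA\}.
#' @param variants Data frame with one row per variant and columns `id`,
#'   `chrom`, `pos` (1-based bp), `ref`, `alt`, `minor` (which of ref/alt is
#'   the minor allele); an optional `quality` column (pass-through dosage-R2
#'   style metadata in \[0, 1\]) is retained but never computed here.
#' @param samples Character vector of unique sample identifiers.
#' @param max_missing Maximum tolerated fraction of missing calls per
#'   variant.
#'
#' @return An object of class `geno_matrix`: a list with elements `codes`,
#'   `variants` (tibble) and `samples`.
#' @export
geno_matrix <- function(codes, variants, samples, max_missing = 1) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  variants <- as_tibble(variants)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in genotype matrix")
  }
  if (nrow(codes) != length(samples)) {
    stop("codes has ", nrow(codes), " rows but ", length(samples), " samples")
  }
  if (ncol(codes) != nrow(variants)) {
    stop("codes has ", ncol(codes), " columns but ", nrow(variants),
          " variant records")
  }
  needed <- c("id", "chrom", "pos", "ref", "alt", "minor")
  miss <- setdiff(needed, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  if (!"quality" %in% names(variants)) variants$quality <- NA_real_
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt allele identical for variant ",
          variants$id[which(variants$ref == variants$alt)[1]])
  }
  if (any(codes != 0 & codes != 1 & codes != 2, na.rm = TRUE)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  # sorted, tie-free positions within each chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (length(p) > 1) {
      d <- diff(p)
      if (any(d <= 0)) {
        i <- which(d <= 0)[1]
        stop("variants unsorted or tied on chromosome ", ch,
              " between positions ", p[i], " and ", p[i + 1])
      }
    }
  }
  mfrac <- colMeans(is.na(codes))
  if (any(mfrac > max_missing)) {
    stop("variant ", variants$id[which(mfrac > max_missing)[1]],
          " exceeds the missing-call bound of ", max_missing)
  }
  variants$maf <- maf_from_codes(codes, variants$id)
  dimnames(codes) <- list(samples, variants$id)
  structure(list(codes = codes, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$samples), " samples x ",
      nrow(x$variants), " variants on ",
      length(unique(x$variants$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

# minor-allele frequency from minor-allele-count codes; errors on
# all-missing variants (naming the first offender).
maf_from_codes <- function(codes, ids = colnames(codes)) {
  nn <- colSums(!is.na(codes))
  if (any(nn == 0)) {
    stop("variant ", ids[which(nn == 0)[1]], " has no non-missing genotypes")
  }
  f <- colSums(codes, na.rm = TRUE) / (2 * nn)
  unname(pmin(f, 1 - f))
}

#' Per-variant minor-allele frequency
#'
#' Recomputes MAF = min(f, 1 - f) from the non-missing genotype codes.
#'
#' @param geno A [geno_matrix()].
#' @return A tibble with columns `id`, `chrom`, `pos`, `maf`.
#' @export
compute_maf <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  tibble(id = geno$variants$id, chrom = geno$variants$chrom,
         pos = geno$variants$pos,
         maf = maf_from_codes(geno$codes, geno$variants$id))
}

#' Genomic region specification
#'
#' 1-based coordinates with inclusive endpoints (VCF convention). All
#' internal arithmetic is in bp.
#'
#' @param chrom Chromosome name.
#' @param start,end Interval endpoints in bp, `start <= end`, inclusive.
#' @param label Optional label carried through to derived objects.
#' @return A named list of class `qg_region`.
#' @export
region <- function(chrom, start, end, label = NULL) {
  if (start > end) stop("region start ", start, " exceeds end ", end)
  if (start < 1) stop("region start must be >= 1")
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end),
                 label = label %||% paste0(chrom, ":", start, "-", end)),
            class = "qg_region")
}

in_region <- function(variants, reg) {
  variants$chrom == reg$chrom & variants$pos >= reg$start &
    variants$pos <= reg$end
}

#' Filter variants by MAF and genomic region
#'
#' Retains variants with MAF at or above `min_maf`, inside `keep_region`
#' (when given) and outside `drop_region` (when given). Variant order is
#' preserved; an empty result is returned, not an error.
#'
#' @param geno A [geno_matrix()].
#' @param min_maf Minimum minor-allele frequency (default 0).
#' @param keep_region,drop_region Optional [region()] objects.
#' @return A filtered `geno_matrix`.
#' @export
filter_variants <- function(geno, min_maf = 0, keep_region = NULL,
                            drop_region = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  keep <- geno$variants$maf >= min_maf
  if (!is.null(keep_region)) keep <- keep & in_region(geno$variants, keep_region)
  if (!is.null(drop_region)) keep <- keep & !in_region(geno$variants, drop_region)
  subset_variants(geno, which(keep))
}

# index-based subsetting helpers (order preserved / as given)
subset_variants <- function(geno, idx) {
  g <- geno
  g$codes <- geno$codes[, idx, drop = FALSE]
  g$variants <- geno$variants[idx, , drop = FALSE]
  g
}

subset_samples <- function(geno, sample_ids) {
  idx <- match(sample_ids, geno$samples)
  if (anyNA(idx)) stop("unknown sample id: ", sample_ids[which(is.na(idx))[1]])
  g <- geno
  g$codes <- geno$codes[idx, , drop = FALSE]
  g$samples <- geno$samples[idx]
  g
}

# minor-allele dosage vector for one variant id
dosage_of <- function(geno, id) {
  j <- match(id, geno$variants$id)
  if (is.na(j)) stop("unknown variant id: ", id)
  geno$codes[, j]
}
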