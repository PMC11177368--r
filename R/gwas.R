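# Mixed-linear-model association with leave-one-chromosome-out (LOCO)
# polygenic control. Two-stage scheme: per chromosome the null variance
# components are estimated once (REML with the LOCO GRM), then every SNP on
# that chromosome is tested by a generalised-least-squares Wald test at the
# fitted covariance — the same approximation the standard MLMA-LOCO tools
# make. Missing dosages are mean-imputed for the scan.

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(13091438)   # 3.8e-9
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / n_tests
}

# GLS scan of the columns of G given the null covariance pieces.
# Returns beta, se per column. P is the REML projection matrix at the
# fitted null covariance; testing each SNP as an extra fixed effect by GLS
# gives beta = g'Py / g'Pg, var(beta) = 1 / g'Pg.
gls_scan <- function(G, P, Py) {
  G <- as.matrix(G)
  mu <- colMeans(G, na.rm = TRUE)
  naidx <- which(is.na(G))
  if (length(naidx)) G[naidx] <- mu[((naidx - 1) %/% nrow(G)) + 1]
  num <- as.vector(crossprod(G, Py))
  den <- unname(colSums(G * (P %*% G)))
  list(beta = num / den, se = sqrt(1 / den))
}

#' Mixed-linear-model LOCO association scan
#'
#' For each chromosome: fit the null model `y = X beta + g + e` by REML
#' with the LOCO GRM (all variants not on that chromosome), then test every
#' SNP on the chromosome with a Wald test of its per-minor-allele effect
#' under the fitted covariance. Reports the genomic inflation factor
#' (median Wald chi-square over 0.4549) and the Bonferroni threshold for
#' the number of tests actually performed.
#'
#' @param geno A [geno_matrix()].
#' @param pheno Phenotype tibble.
#' @param model A [qg_model()].
#' @param loco_grms Optional named list of LOCO GRMs as produced by
#'   [build_partitioned_grms()]`(scheme = "loco")` (names `loco_<chrom>`);
#'   computed when missing.
#' @param chromosomes Chromosomes to scan (default: all in `geno`).
#' @param condition_snp,condition_trait Optional conditioning covariates: a
#'   variant id whose minor-allele dosage, or a phenotype column whose
#'   value, is added as a fixed effect. The conditioning SNP itself is
#'   skipped in the scan.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param genetic_variance Optional fixed genetic variance for the null
#'   covariance instead of estimating it by REML; `0` collapses the scan to
#'   ordinary least squares (useful as an oracle check).
#' @return An object of class `qg_gwas`: tibble of per-variant results
#'   (`id`, `chrom`, `pos`, `ref`, `alt`, `minor`, `maf`, `n_used`, `beta`,
#'   `se`, `p_value`) with attributes `lambda_gc`, `threshold`, `n_tests`,
#'   `trait`. Betas are per copy of the minor allele.
#' @export
run_mlm_loco <- function(geno, pheno, model, loco_grms = NULL,
                         chromosomes = NULL, condition_snp = NULL,
                         condition_trait = NULL, alpha = 0.05,
                         genetic_variance = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  chroms <- chromosomes %||% unique(geno$variants$chrom)
  if (is.null(loco_grms)) {
    loco_grms <- build_partitioned_grms(geno, scheme = "loco")
  }
  extra <- NULL
  skip_ids <- character()
  if (!is.null(condition_snp)) {
    dos <- dosage_of(geno, condition_snp)
    dos <- dos[match(pheno$sample, geno$samples)]
    extra <- list(cond_snp = dos)
    skip_ids <- condition_snp
  }
  if (!is.null(condition_trait)) {
    if (!condition_trait %in% names(pheno)) {
      stop("unknown conditioning trait: ", condition_trait)
    }
    extra <- c(extra, list(cond_trait = pheno[[condition_trait]]))
  }
  res <- list()
  for (ch in chroms) {
    gname <- paste0("loco_", ch)
    if (!gname %in% names(loco_grms) && is.null(genetic_variance)) {
      stop("no LOCO GRM for chromosome ", ch,
           " (single-chromosome input needs a fixed genetic_variance)")
    }
    grm <- loco_grms[[gname]]
    common <- intersect(pheno$sample, geno$samples)
    if (!is.null(grm)) common <- intersect(common, grm$samples)
    d <- build_design(pheno, model, samples = common, extra = extra)
    A <- if (is.null(grm)) diag(length(d$y)) else
      align_grms(list(grm), d$samples)[[1]]$values
    theta <- if (is.null(genetic_variance)) {
      reml_core(d$y, d$X, list(A))$theta
    } else {
      s2 <- stats::var(stats::lm.fit(d$X, d$y)$residuals)
      c(genetic_variance, s2)
    }
    parts <- reml_parts(theta, d$y, d$X, list(A))
    vidx <- which(geno$variants$chrom == ch & !geno$variants$id %in% skip_ids)
    if (!length(vidx)) next
    G <- geno$codes[match(d$samples, geno$samples), vidx, drop = FALSE]
    mono <- apply(G, 2, function(x) stats::var(x, na.rm = TRUE) == 0 ||
                    all(is.na(x)))
    sc <- gls_scan(G[, !mono, drop = FALSE], parts$P, parts$Py)
    v <- geno$variants[vidx, ][!mono, ]
    res[[ch]] <- tibble(
      id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      minor = v$minor, maf = maf_from_codes(G[, !mono, drop = FALSE], v$id),
      n_used = length(d$y), beta = sc$beta, se = sc$se,
      p_value = pchisq((sc$beta / sc$se)^2, df = 1, lower.tail = FALSE))
  }
  out <- bind_rows(res) %>% arrange(.data$chrom, .data$pos)
  chi2 <- (out$beta / out$se)^2
  lambda <- median(chi2, na.rm = TRUE) / qchisq(0.5, df = 1)
  n_tests <- sum(!is.na(out$p_value))
  structure(out, class = c("qg_gwas", class(out)),
            lambda_gc = lambda,
            threshold = bonferroni_threshold(max(n_tests, 1), alpha),
            n_tests = n_tests, trait = model$trait)
}

#' Conditional association scan
#'
#' Re-runs [run_mlm_loco()] with either a conditioning SNP's minor-allele
#' dosage or a conditioning trait added to the fixed effects. Used to test
#' whether a significant peak is explained by a single QTL, or whether a
#' secondary trait's signal reflects pleiotropy with a primary trait.
#'
#' @inheritParams run_mlm_loco
#' @param condition Either `list(snp = "<variant id>")` or
#'   `list(trait = "<column>")`.
#' @return A `qg_gwas`.
#' @export
conditional_gwas <- function(geno, pheno, model, condition, loco_grms = NULL,
                             chromosomes = NULL, alpha = 0.05) {
  if (!is.list(condition) || !any(c("snp", "trait") %in% names(condition))) {
    stop("condition must be list(snp = ...) or list(trait = ...)")
  }
  run_mlm_loco(geno, pheno, model, loco_grms = loco_grms,
               chromosomes = chromosomes,
               condition_snp = condition$snp,
               condition_trait = condition$trait, alpha = alpha)
}

#' Genomic inflation factor of a scan
#'
#' @param gwas A `qg_gwas`.
#' @return Median Wald chi-square divided by 0.4549 (the null median).
#' @export
lambda_gc <- function(gwas) attr(gwas, "lambda_gc")

#' Summarise genome-wide significant variants into QTL regions
#'
#' Significant variants are clustered into regions: consecutive significant
#' variants on one chromosome separated by more than `merge_gap_bp` start a
#' new region. The region's top SNP has the lowest p-value, ties broken by
#' lowest bp position.
#'
#' @param gwas A `qg_gwas`.
#' @param threshold Significance level (default: the scan's Bonferroni
#'   attribute).
#' @param merge_gap_bp Gap above which significant variants are split into
#'   separate regions (default 1 Mb).
#' @param min_snps Minimum number of significant SNPs for a region to be
#'   reported (default 1).
#' @return Tibble with `chrom`, `start`, `end`, `n_significant`,
#'   `top_snp`, `top_pos`, `top_p`.
#' @export
summarize_regions <- function(gwas, threshold = NULL, merge_gap_bp = 1e6,
                              min_snps = 1) {
  threshold <- threshold %||% attr(gwas, "threshold")
  sig <- gwas %>% filter(!is.na(.data$p_value), .data$p_value <= threshold) %>%
    arrange(.data$chrom, .data$pos)
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_significant = integer(), top_snp = character(),
                  top_pos = numeric(), top_p = numeric()))
  }
  sig <- sig %>% group_by(.data$chrom) %>%
    mutate(cluster = cumsum(c(0, diff(.data$pos)) > merge_gap_bp)) %>%
    ungroup()
  out <- sig %>% group_by(.data$chrom, .data$cluster) %>%
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_significant = n(),
              top_snp = .data$id[order(.data$p_value, .data$pos)][1],
              top_pos = .data$pos[order(.data$p_value, .data$pos)][1],
              top_p = min(.data$p_value), .groups = "drop") %>%
    select(-"cluster") %>%
    filter(.data$n_significant >= min_snps) %>%
    arrange(.data$chrom, .data$start)
  out
}

#' Write per-variant association results to TSV
#'
#' @param gwas A `qg_gwas`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  write.table(as.data.frame(gwas), path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
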