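# Two-pronged candidate-causal-variant procedure: an LD-based set (high r2
# to the top associated SNPs, restricted to high/moderate-impact
# annotations), an IBD/ROH-sharing-based set (high/moderate-impact
# significant variants inside ROH shared by all top-k individuals ranked by
# a chromosomal gEBV component), and their intersection with pairwise LD
# among the finalists.

#' Squared dosage correlation (LD r2) between variants
#'
#' Pearson correlation of minor-allele-count vectors over mutually
#' non-missing individuals, squared.
#'
#' @param geno A [geno_matrix()].
#' @param variant_a Reference variant id.
#' @param variant_b_set Character vector of comparison variant ids.
#' @return Tibble with `id`, `r2` (`NA` with a warning for monomorphic
#'   pairs).
#' @export
ld_r2 <- function(geno, variant_a, variant_b_set) {
  da <- dosage_of(geno, variant_a)
  r2 <- vapply(variant_b_set, function(b) {
    db <- dosage_of(geno, b)
    ok <- !is.na(da) & !is.na(db)
    if (sum(ok) < 2 || stats::var(da[ok]) == 0 || stats::var(db[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(da[ok], db[ok])^2
  }, numeric(1))
  if (anyNA(r2)) {
    warning("monomorphic variant pair(s); r2 undefined for ",
            sum(is.na(r2)), " variant(s)")
  }
  tibble(id = variant_b_set, r2 = unname(r2))
}

#' LD-based candidate set
#'
#' Genome-wide significant variants in high LD (`r2 > r2_threshold`) with
#' any of the top SNPs, intersected with the high/moderate-impact
#' annotation shortlist.
#'
#' @param geno A [geno_matrix()].
#' @param gwas A `qg_gwas`.
#' @param top_snps Character vector of top SNP ids (e.g. from
#'   [summarize_regions()]).
#' @param annotations Output of [annotate_variants()]; when `NULL` the
#'   impact filter is skipped and the full r2 set is returned.
#' @param r2_threshold LD threshold (default 0.8, exclusive).
#' @param threshold Significance level (default: the scan's Bonferroni
#'   attribute).
#' @return Tibble `id`, `r2_to_top` (max r2 over top SNPs), `in_shortlist`
#'   (passes the impact filter); the candidate set proper is
#'   `id[in_shortlist]`.
#' @export
ld_candidate_set <- function(geno, gwas, top_snps, annotations = NULL,
                             r2_threshold = 0.8, threshold = NULL) {
  threshold <- threshold %||% attr(gwas, "threshold")
  sig <- gwas$id[!is.na(gwas$p_value) & gwas$p_value <= threshold]
  if (!length(sig)) {
    return(tibble(id = character(), r2_to_top = numeric(),
                  in_shortlist = logical()))
  }
  r2max <- rep(0, length(sig))
  for (ts in top_snps) {
    r2 <- ld_r2(geno, ts, sig)$r2
    r2max <- pmax(r2max, r2, na.rm = TRUE)
  }
  keep <- r2max > r2_threshold
  ids <- sig[keep]
  shortlist <- if (is.null(annotations)) rep(TRUE, length(ids)) else
    ids %in% impact_filter(annotations, "MODERATE")
  tibble(id = ids, r2_to_top = r2max[keep], in_shortlist = shortlist)
}

#' IBD-sharing (shared-ROH) candidate set
#'
#' Ranks individuals by a chromosomal gEBV component, takes the top-k and
#' bottom-k, detects ROH for both groups over the significant-association
#' window, intersects the top group's segments, and returns the
#' significant high/moderate-impact variants inside the intervals shared
#' by all top-k individuals. Intervals where bottom-k carriers hold a
#' different allele class are reported alongside.
#'
#' @param blup A [predict_gebv()] result.
#' @param component gEBV component (GRM label) used for ranking.
#' @param geno A [geno_matrix()].
#' @param gwas A `qg_gwas` (defines significance and the scan window).
#' @param annotations Output of [annotate_variants()].
#' @param chrom Chromosome holding the QTL.
#' @param k Group size (default 10).
#' @param params [roh_params()].
#' @param buffer_bp Scan-window flank (default 100 kb).
#' @param share_fraction Fraction of the top group that must share an
#'   interval (default 1 = all individuals, the strict rule).
#' @return List with `candidates` (tibble `id`, `pos`, `p_value`,
#'   `impact`), `shared_top` (intervals shared by the top group),
#'   `shared_all` (intersection table over both groups with allele-class
#'   flags), `groups` (the ranked sample ids).
#' @export
ibd_candidate_set <- function(blup, component, geno, gwas, annotations,
                              chrom, k = 10, params = roh_params(),
                              buffer_bp = 100000, share_fraction = 1) {
  stopifnot(inherits(blup, "qg_blup"))
  if (!component %in% names(blup$gebv)) {
    stop("unknown gEBV component: ", component)
  }
  ge <- blup$gebv[[component]]
  if (stats::sd(ge) < 1e-10) {
    stop("gEBV component '", component, "' has no variance; ",
         "extreme-group selection is degenerate")
  }
  if (2 * k > nrow(blup$gebv)) stop("k = ", k, " exceeds half the cohort")
  ord <- order(ge, decreasing = TRUE)
  top <- blup$gebv$sample[ord[seq_len(k)]]
  bottom <- blup$gebv$sample[rev(ord)[seq_len(k)]]
  win <- roh_scan_window(gwas, chrom, buffer_bp = buffer_bp)
  segs <- detect_roh(geno, c(top, bottom), region = win, params = params)
  groups <- setNames(c(rep("top", k), rep("bottom", k)), c(top, bottom))
  shared_all <- shared_roh(segs, groups, geno, min_carriers = 2)
  need <- ceiling(share_fraction * k)
  shared_top <- if (nrow(shared_all) && "carriers_top" %in% names(shared_all)) {
    shared_all[shared_all$carriers_top >= need, , drop = FALSE]
  } else {
    shared_all[integer(), , drop = FALSE]
  }
  if (nrow(shared_top) == 0) {
    message("no ROH shared by ", need, " of ", k, " top-gEBV individuals")
    return(list(candidates = tibble(id = character(), pos = numeric(),
                                    p_value = numeric(), impact = character()),
                shared_top = shared_top, shared_all = shared_all,
                groups = groups))
  }
  threshold <- attr(gwas, "threshold")
  sig <- gwas[!is.na(gwas$p_value) & gwas$p_value <= threshold &
                gwas$chrom == chrom, ]
  impact_ids <- impact_filter(annotations, "MODERATE")
  inside <- vapply(seq_len(nrow(sig)), function(i) {
    any(sig$pos[i] >= shared_top$start & sig$pos[i] <= shared_top$end)
  }, logical(1))
  cand <- sig[inside & sig$id %in% impact_ids, ]
  imp <- annotations %>%
    filter(.data$id %in% cand$id) %>%
    mutate(rank = IMPACT_RANK[.data$impact]) %>%
    group_by(.data$id) %>% slice_min(order_by = -.data$rank, n = 1,
                                     with_ties = FALSE) %>% ungroup()
  list(candidates = cand %>%
         left_join(select(imp, "id", "impact"), by = "id") %>%
         select("id", "pos", "p_value", "impact"),
       shared_top = shared_top, shared_all = shared_all, groups = groups)
}

#' Combine the LD-based and IBD-based candidate sets
#'
#' Intersects the two shortlists, ranks by ascending p-value (ties by
#' position), and reports pairwise LD among the finalists together with
#' full provenance of both source sets.
#'
#' @param ld_set Tibble from [ld_candidate_set()] (its `in_shortlist`
#'   members are used).
#' @param ibd_set List from [ibd_candidate_set()] (its `candidates$id` are
#'   used).
#' @param gwas A `qg_gwas` for effect sizes and p-values.
#' @param geno A [geno_matrix()] for pairwise r2.
#' @param annotations Output of [annotate_variants()] for consequence terms.
#' @return An object of class `qg_candidates`: tibble of finalists (`id`,
#'   `chrom`, `pos`, `ref`, `alt`, `maf`, `beta`, `se`, `p_value`,
#'   `consequence`, `gene`, `amino_acids`, `impact`, `r2_to_top`,
#'   `source`) with attributes `pairwise_r2` (matrix) and `provenance`
#'   (list of both input sets).
#' @export
combine_candidates <- function(ld_set, ibd_set, gwas, geno,
                               annotations = NULL) {
  ld_ids <- ld_set$id[ld_set$in_shortlist]
  ibd_ids <- ibd_set$candidates$id
  final <- intersect(ld_ids, ibd_ids)
  rows <- gwas[match(final, gwas$id), , drop = FALSE]
  rows <- as_tibble(rows)[, c("id", "chrom", "pos", "ref", "alt", "maf",
                              "beta", "se", "p_value")]
  rows$r2_to_top <- ld_set$r2_to_top[match(final, ld_set$id)]
  rows$source <- "both"
  if (!is.null(annotations) && nrow(rows)) {
    ann <- annotations %>%
      filter(.data$id %in% final, !is.na(.data$transcript_id)) %>%
      mutate(rank = IMPACT_RANK[.data$impact]) %>%
      group_by(.data$id) %>%
      slice_min(order_by = -.data$rank, n = 1, with_ties = FALSE) %>%
      ungroup() %>%
      select("id", "consequence", "gene", "amino_acids", "impact")
    rows <- left_join(rows, ann, by = "id")
  }
  rows <- rows %>% arrange(.data$p_value, .data$pos)
  r2_mat <- NULL
  if (nrow(rows) > 1) {
    r2_mat <- matrix(1, nrow(rows), nrow(rows),
                     dimnames = list(rows$id, rows$id))
    for (i in seq_len(nrow(rows) - 1)) {
      r2 <- ld_r2(geno, rows$id[i], rows$id[(i + 1):nrow(rows)])$r2
      r2_mat[i, (i + 1):nrow(rows)] <- r2
      r2_mat[(i + 1):nrow(rows), i] <- r2
    }
  }
  structure(rows, class = c("qg_candidates", class(rows)),
            pairwise_r2 = r2_mat,
            provenance = list(ld = ld_set, ibd = ibd_set$candidates))
}

#' Write a candidate report to TSV
#'
#' @param candidates A `qg_candidates`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  write.table(as.data.frame(candidates), path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
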