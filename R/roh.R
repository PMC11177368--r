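# Runs-of-homozygosity detection with scanning-window rules, and
# cross-individual shared-segment analysis with allele-class
# discrimination. The window-hit-proportion step follows the published
# --homozyg algorithm of the standard tool: a SNP becomes ROH-eligible when
# the fraction of overlapping 50-SNP windows that are "homozygous" (at most
# 3 heterozygous and 5 missing calls) exceeds 0.05; maximal runs of
# eligible SNPs are split at large gaps and filtered by SNP count, length
# and density.

#' Scanning-window ROH parameters
#'
#' Defaults: runs must contain at least 50 SNPs, span at least 100 kb, have
#' at least one SNP per 50 kb, and contain no inter-SNP gap above 1000 kb;
#' each 50-SNP scanning window tolerates at most 3 heterozygous and 5
#' missing genotypes; a SNP is ROH-eligible when more than 5% of its
#' overlapping windows are homozygous.
#'
#' @param min_snps,min_length_bp,min_density_bp_per_snp,max_gap_bp Run
#'   filters.
#' @param window_snps,window_max_het,window_max_missing,window_hit_threshold
#'   Scanning-window rules.
#' @return An object of class `qg_roh_params`.
#' @export
roh_params <- function(min_snps = 50, min_length_bp = 100000,
                       min_density_bp_per_snp = 50000, max_gap_bp = 1000000,
                       window_snps = 50, window_max_het = 3,
                       window_max_missing = 5, window_hit_threshold = 0.05) {
  p <- list(min_snps = min_snps, min_length_bp = min_length_bp,
            min_density_bp_per_snp = min_density_bp_per_snp,
            max_gap_bp = max_gap_bp, window_snps = window_snps,
            window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            window_hit_threshold = window_hit_threshold)
  if (any(unlist(p[1:5]) <= 0)) stop("ROH parameters must be positive")
  if (window_max_het >= window_snps) {
    stop("window_max_het must be smaller than window_snps")
  }
  structure(p, class = "qg_roh_params")
}

# eligible-SNP mask for one individual's genotype vector over the region
roh_eligible <- function(g, params) {
  m <- length(g)
  w <- params$window_snps
  if (m < w) return(rep(FALSE, m))
  het <- as.numeric(!is.na(g) & g == 1)
  mis <- as.numeric(is.na(g))
  csh <- c(0, cumsum(het))
  csm <- c(0, cumsum(mis))
  starts <- seq_len(m - w + 1)
  hom_win <- (csh[starts + w] - csh[starts]) <= params$window_max_het &
    (csm[starts + w] - csm[starts]) <= params$window_max_missing
  # per SNP j, windows covering j start at max(1, j-w+1) .. min(j, m-w+1)
  cs_hw <- c(0, cumsum(as.numeric(hom_win)))
  lo <- pmax(1, seq_len(m) - w + 1)
  hi <- pmin(seq_len(m), m - w + 1)
  hits <- cs_hw[hi + 1] - cs_hw[lo]
  denom <- hi - lo + 1
  hits / denom > params$window_hit_threshold
}

# split an index run at gaps and apply the run filters
roh_runs_from_mask <- function(eligible, pos, g, params) {
  out <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split at inter-SNP gaps beyond max_gap_bp
    gaps <- diff(pos[idx])
    cuts <- which(gaps > params$max_gap_bp)
    pieces <- split(idx, cumsum(c(0, seq_along(gaps) %in% cuts)))
    for (pc in pieces) {
      len <- pos[pc[length(pc)]] - pos[pc[1]] + 1
      nsnp <- length(pc)
      if (nsnp >= params$min_snps && len >= params$min_length_bp &&
          len / nsnp <= params$min_density_bp_per_snp) {
        out[[length(out) + 1]] <- tibble(
          start = pos[pc[1]], end = pos[pc[length(pc)]], n_snps = nsnp,
          n_het = sum(g[pc] == 1, na.rm = TRUE),
          n_missing = sum(is.na(g[pc])))
      }
    }
  }
  bind_rows(out)
}

#' Detect runs of homozygosity
#'
#' @param geno A [geno_matrix()].
#' @param sample_ids Individuals to scan (default: all).
#' @param region A [region()] restricting the scan; `NULL` scans each
#'   chromosome fully.
#' @param params A [roh_params()].
#' @return Tibble of segments: `sample`, `chrom`, `start`, `end`, `n_snps`,
#'   `n_het`, `n_missing`. Segment endpoints are the outermost eligible SNP
#'   positions (runs are not extended into flanking gaps). A region with
#'   fewer SNPs than one scanning window yields an empty result with a
#'   warning.
#' @export
detect_roh <- function(geno, sample_ids = NULL, region = NULL,
                       params = roh_params()) {
  stopifnot(inherits(geno, "geno_matrix"))
  sample_ids <- sample_ids %||% geno$samples
  g <- if (is.null(region)) geno else
    filter_variants(geno, keep_region = region)
  chroms <- unique(g$variants$chrom)
  res <- list()
  for (ch in chroms) {
    vsel <- which(g$variants$chrom == ch)
    pos <- g$variants$pos[vsel]
    if (length(vsel) < params$window_snps) {
      warning("chromosome ", ch, if (!is.null(region)) " (region)",
              " has fewer SNPs (", length(vsel), ") than one scanning window (",
              params$window_snps, "); no ROH can be called")
      next
    }
    for (s in sample_ids) {
      gv <- g$codes[match(s, g$samples), vsel]
      mask <- roh_eligible(gv, params)
      runs <- roh_runs_from_mask(mask, pos, gv, params)
      if (nrow(runs)) {
        runs$sample <- s
        runs$chrom <- ch
        res[[length(res) + 1]] <- runs
      }
    }
  }
  if (!length(res)) {
    return(tibble(sample = character(), chrom = character(), start = numeric(),
                  end = numeric(), n_snps = integer(), n_het = integer(),
                  n_missing = integer()))
  }
  bind_rows(res) %>%
    select("sample", "chrom", "start", "end", "n_snps", "n_het", "n_missing")
}

#' Intersect ROH segments across individuals
#'
#' Reports maximal intervals with a constant set of carriers (individuals
#' whose ROH covers the interval), per-group carrier counts, and — for each
#' interval — whether all carriers of a group share the same homozygous
#' allele class. The allele class of a carrier is its genotype vector over
#' the interval's SNPs; classes are compared only at mutually non-missing
#' SNPs, so missing calls never break equality.
#'
#' @param segments Output of [detect_roh()].
#' @param groups Named character vector or list mapping sample id to group
#'   label.
#' @param geno The [geno_matrix()] the segments came from.
#' @param min_carriers Keep only intervals covered by at least this many
#'   carriers (default 2).
#' @return Tibble: `chrom`, `start`, `end`, `n_carriers`, one
#'   `carriers_<group>` count column per group, `classes_differ` (do any
#'   two carrier groups hold different allele classes over the interval),
#'   and a list column `carriers`.
#' @export
shared_roh <- function(segments, groups, geno, min_carriers = 2) {
  if (nrow(segments) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_carriers = integer(), classes_differ = logical(),
                  carriers = list()))
  }
  groups <- unlist(groups)
  unknown <- setdiff(names(groups), geno$samples)
  if (length(unknown)) stop("unknown sample in groups map: ", unknown[1])
  group_levels <- unique(groups)
  out <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, ]
    # elementary intervals between consecutive breakpoints
    bp <- sort(unique(c(seg$start, seg$end + 1)))
    if (length(bp) < 2) next
    for (i in seq_len(length(bp) - 1)) {
      lo <- bp[i]; hi <- bp[i + 1] - 1
      cov <- seg[seg$start <= lo & seg$end >= hi, ]
      carriers <- unique(cov$sample)
      if (length(carriers) < min_carriers) next
      vidx <- which(geno$variants$chrom == ch & geno$variants$pos >= lo &
                      geno$variants$pos <= hi)
      classes_differ <- NA
      if (length(vidx)) {
        cmat <- geno$codes[match(carriers, geno$samples), vidx, drop = FALSE]
        classes_differ <- FALSE
        for (a in seq_len(length(carriers) - 1)) {
          for (b in (a + 1):length(carriers)) {
            both <- !is.na(cmat[a, ]) & !is.na(cmat[b, ])
            if (any(both) && any(cmat[a, both] != cmat[b, both])) {
              classes_differ <- TRUE
            }
          }
        }
      }
      row <- tibble(chrom = ch, start = lo, end = hi,
                    n_carriers = length(carriers),
                    classes_differ = classes_differ,
                    carriers = list(carriers))
      for (gl in group_levels) {
        row[[paste0("carriers_", gl)]] <-
          sum(carriers %in% names(groups)[groups == gl])
      }
      out[[length(out) + 1]] <- row
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_carriers = integer(), classes_differ = logical(),
                  carriers = list()))
  }
  res <- bind_rows(out)
  # merge adjacent elementary intervals with identical carrier sets
  res <- res %>% arrange(.data$chrom, .data$start)
  merged <- list()
  cur <- res[1, ]
  if (nrow(res) > 1) {
    for (i in 2:nrow(res)) {
      nxt <- res[i, ]
      if (nxt$chrom == cur$chrom && nxt$start == cur$end + 1 &&
          setequal(nxt$carriers[[1]], cur$carriers[[1]])) {
        cur$end <- nxt$end
        cur$classes_differ <- cur$classes_differ | nxt$classes_differ
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- nxt
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  bind_rows(merged)
}

#' Write ROH segments to TSV, optionally in the .hom column layout
#'
#' `format = "hom"` writes the FID/IID/CHR/POS1/POS2/KB/NSNP columns of the
#' standard --homozyg output for cross-checking against an external run.
#'
#' @param segments Output of [detect_roh()].
#' @param path Output path.
#' @param format `"tsv"` (native columns) or `"hom"`.
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path, format = c("tsv", "hom")) {
  format <- match.arg(format)
  out <- if (format == "tsv") segments else
    data.frame(FID = "FAM", IID = segments$sample, CHR = segments$chrom,
               POS1 = segments$start, POS2 = segments$end,
               KB = (segments$end - segments$start + 1) / 1000,
               NSNP = segments$n_snps)
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Scan window around the significant association span
#'
#' The ROH fine-mapping interval: minimum to maximum genome-wide
#' significant position on the target chromosome, widened by `buffer_bp`.
#'
#' @param gwas A `qg_gwas`.
#' @param chrom Target chromosome.
#' @param buffer_bp Flank added on each side (default 100 kb).
#' @param threshold Significance level (default: the scan's Bonferroni
#'   attribute).
#' @return A [region()].
#' @export
roh_scan_window <- function(gwas, chrom, buffer_bp = 100000, threshold = NULL) {
  threshold <- threshold %||% attr(gwas, "threshold")
  sig <- gwas[!is.na(gwas$p_value) & gwas$p_value <= threshold &
                gwas$chrom == chrom, ]
  if (nrow(sig) == 0) {
    stop("no genome-wide significant variants on chromosome ", chrom)
  }
  region(chrom, max(1, min(sig$pos) - buffer_bp), max(sig$pos) + buffer_bp)
}
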