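# Genomic relationship matrices from variant subsets: whole genome, single
# chromosomes, leave-one-chromosome-out sets, and QTL windows with exclusion
# buffers.

#' Compute a genomic relationship matrix
#'
#' Per-SNP-standardised (VanRaden method 1 / GCTA style) estimator:
#' \deqn{A_{jk} = \frac{1}{m} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)}}
#' with \eqn{p_i} the sample minor-allele frequency of variant \eqn{i}.
#' The same cross-product expression is used on the diagonal. Missing
#' genotypes are mean-imputed to \eqn{2p_i} before centring.
#'
#' @param geno A [geno_matrix()].
#' @param variant_ids Optional character vector naming the variant subset
#'   (defaults to all variants).
#' @param label Label stored on the result.
#' @return An object of class `qg_grm`: list with `values` (symmetric n x n
#'   matrix), `samples`, `label`, `n_variants_used`.
#' @export
compute_grm <- function(geno, variant_ids = NULL, label = "all") {
  stopifnot(inherits(geno, "geno_matrix"))
  idx <- if (is.null(variant_ids)) seq_len(nrow(geno$variants)) else {
    i <- match(variant_ids, geno$variants$id)
    if (anyNA(i)) stop("unknown variant id: ", variant_ids[which(is.na(i))[1]])
    i
  }
  if (length(idx) == 0) stop("empty variant subset for GRM '", label, "'")
  Z <- geno$codes[, idx, drop = FALSE]
  # frequency of the counted (minor) allele; f(1-f) is symmetric, so the
  # scale term equals 2p(1-p) with p the folded MAF
  nn <- colSums(!is.na(Z))
  f <- colSums(Z, na.rm = TRUE) / (2 * nn)
  if (any(f == 0 | f == 1)) {
    stop("variant ", geno$variants$id[idx][which(f == 0 | f == 1)[1]],
         " is monomorphic in the sample; cannot standardise")
  }
  Zc <- sweep(Z, 2, 2 * f)
  Zc[is.na(Zc)] <- 0  # mean imputation after centring
  Zs <- sweep(Zc, 2, sqrt(2 * f * (1 - f)), "/")
  A <- tcrossprod(Zs) / length(idx)
  dimnames(A) <- list(geno$samples, geno$samples)
  structure(list(values = A, samples = geno$samples, label = label,
                 n_variants_used = length(idx)), class = "qg_grm")
}

#' @export
print.qg_grm <- function(x, ...) {
  cat("<qg_grm> '", x$label, "': ", length(x$samples), " samples, ",
      x$n_variants_used, " variants\n", sep = "")
  invisible(x)
}

#' QTL region specification with exclusion buffer
#'
#' A window (the QTL region proper) inside a wider exclusion interval; the
#' rest-of-chromosome GRM excludes the whole exclusion interval to guard
#' against LD leakage between the window and its flanks.
#'
#' @param chrom Chromosome.
#' @param center Window centre in bp (typically the top associated SNP).
#' @param window_halfwidth Half-width of the window in bp (default 3 Mb,
#'   giving a 6-Mb window).
#' @param exclusion_halfwidth Half-width of the exclusion interval in bp
#'   (default 7 Mb, giving a 14-Mb buffer); must be >= `window_halfwidth`.
#' @param label Component label.
#' @return An object of class `qg_region_spec` with `window` and
#'   `exclusion` [region()]s.
#' @export
region_spec <- function(chrom, center, window_halfwidth = 3e6,
                        exclusion_halfwidth = 7e6,
                        label = paste0("qtl_", chrom)) {
  if (exclusion_halfwidth < window_halfwidth) {
    stop("exclusion half-width must be at least the window half-width")
  }
  structure(list(
    label = label, chrom = as.character(chrom), center = center,
    window = region(chrom, max(1, center - window_halfwidth),
                    center + window_halfwidth),
    exclusion = region(chrom, max(1, center - exclusion_halfwidth),
                       center + exclusion_halfwidth)),
    class = "qg_region_spec")
}

#' Build partitioned GRMs
#'
#' Three schemes over a genotype set:
#' * `per_chromosome`: one GRM per chromosome;
#' * `loco`: per chromosome, a GRM from all variants *not* on it;
#' * `qtl_plus_rest`: per [region_spec()], a window GRM plus a
#'   rest-of-chromosome GRM that excludes the full exclusion interval, and a
#'   rest-of-genome GRM from all other chromosomes (excluding every listed
#'   region's exclusion interval).
#'
#' @param geno A [geno_matrix()].
#' @param scheme Partition scheme.
#' @param regions List of [region_spec()] (required for `qtl_plus_rest`).
#' @param rest_of_genome For `qtl_plus_rest`, also return the rest-of-genome
#'   component (default `TRUE`).
#' @param combine_rest For `qtl_plus_rest`: instead of one
#'   rest-of-chromosome GRM per region plus a rest-of-genome GRM, build a
#'   single `rest_of_genome` GRM from every variant outside all exclusion
#'   intervals (the "windows + one rest" design used for local genetic
#'   correlations).
#' @return Named list of `qg_grm` objects.
#' @export
build_partitioned_grms <- function(geno,
                                   scheme = c("per_chromosome", "qtl_plus_rest",
                                              "loco"),
                                   regions = NULL, rest_of_genome = TRUE,
                                   combine_rest = FALSE) {
  scheme <- match.arg(scheme)
  v <- geno$variants
  chroms <- unique(v$chrom)
  if (scheme == "per_chromosome") {
    out <- lapply(chroms, function(ch) {
      compute_grm(geno, v$id[v$chrom == ch], label = paste0("chr", ch))
    })
    names(out) <- paste0("chr", chroms)
    return(out)
  }
  if (scheme == "loco") {
    keep <- chroms[vapply(chroms, function(ch) any(v$chrom != ch), logical(1))]
    if (length(keep) == 0) return(list())
    out <- lapply(keep, function(ch) {
      compute_grm(geno, v$id[v$chrom != ch], label = paste0("loco_", ch))
    })
    names(out) <- paste0("loco_", keep)
    return(out)
  }
  if (is.null(regions)) stop("qtl_plus_rest requires a list of region_spec")
  if (inherits(regions, "qg_region_spec")) regions <- list(regions)
  for (ch in chroms) {
    rs <- Filter(function(r) r$chrom == ch, regions)
    if (length(rs) > 1) {
      for (i in seq_len(length(rs) - 1)) {
        if (rs[[i]]$window$end >= rs[[i + 1]]$window$start &&
            rs[[i + 1]]$window$end >= rs[[i]]$window$start) {
          stop("overlapping QTL windows on chromosome ", ch)
        }
      }
    }
  }
  out <- list()
  excluded_ids <- character()
  for (r in regions) {
    win_ids <- v$id[in_region(v, r$window)]
    if (!length(win_ids)) stop("window ", r$window$label, " contains no variants")
    out[[r$label]] <- compute_grm(geno, win_ids, label = r$label)
    if (!combine_rest) {
      rest_ids <- v$id[v$chrom == r$chrom & !in_region(v, r$exclusion)]
      if (length(rest_ids)) {
        out[[paste0(r$label, "_rest_chr")]] <-
          compute_grm(geno, rest_ids, label = paste0(r$label, "_rest_chr"))
      }
    }
    excluded_ids <- c(excluded_ids, v$id[in_region(v, r$exclusion)])
  }
  if (rest_of_genome) {
    qtl_chroms <- vapply(regions, `[[`, character(1), "chrom")
    rog_ids <- if (combine_rest) {
      v$id[!v$id %in% excluded_ids]
    } else {
      v$id[!v$chrom %in% qtl_chroms & !v$id %in% excluded_ids]
    }
    if (length(rog_ids)) {
      out$rest_of_genome <- compute_grm(geno, rog_ids, label = "rest_of_genome")
    }
  }
  out
}

#' Write a GRM to disk
#'
#' `format = "tsv"` writes a three-column table (sample_i, sample_j, value)
#' of the lower triangle including the diagonal plus a `.id` file;
#' `format = "gcta"` writes the GCTA binary-triplet convention
#' (`.grm.bin` single-precision lower triangle, `.grm.N.bin` variant counts,
#' `.grm.id` two-column id file).
#'
#' @param grm A `qg_grm`.
#' @param prefix Output path prefix.
#' @param format `"tsv"` or `"gcta"`.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix, format = c("tsv", "gcta")) {
  format <- match.arg(format)
  n <- length(grm$samples)
  ii <- sequence(seq_len(n))              # lower triangle, row-major
  jj <- rep(seq_len(n), seq_len(n))
  vals <- grm$values[cbind(jj, ii)]
  if (format == "tsv") {
    path <- paste0(prefix, ".grm.tsv")
    writeLines(paste0("# n_variants_used: ", grm$n_variants_used), path)
    suppressWarnings(write.table(data.frame(i = jj, j = ii, value = vals),
                                 path, quote = FALSE, sep = "\t",
                                 row.names = FALSE, append = TRUE))
    writeLines(grm$samples, paste0(prefix, ".grm.tsv.id"))
  } else {
    con <- file(paste0(prefix, ".grm.bin"), "wb")
    writeBin(as.numeric(vals), con, size = 4)
    close(con)
    con <- file(paste0(prefix, ".grm.N.bin"), "wb")
    writeBin(rep(as.numeric(grm$n_variants_used), length(vals)), con, size = 4)
    close(con)
    write.table(data.frame(fid = grm$samples, iid = grm$samples),
                paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}

#' Read a GRM written by [write_grm()]
#'
#' @param prefix Path prefix used when writing.
#' @param format `"tsv"` or `"gcta"`.
#' @param label Label for the returned object.
#' @return A `qg_grm`.
#' @export
read_grm <- function(prefix, format = c("tsv", "gcta"), label = basename(prefix)) {
  format <- match.arg(format)
  if (format == "tsv") {
    samples <- readLines(paste0(prefix, ".grm.tsv.id"))
    first <- readLines(paste0(prefix, ".grm.tsv"), n = 1)
    nv <- as.integer(sub("# n_variants_used: ", "", first))
    tri <- read.table(paste0(prefix, ".grm.tsv"), header = TRUE, sep = "\t",
                      comment.char = "#")
    n <- length(samples)
    A <- matrix(0, n, n)
    A[cbind(tri$i, tri$j)] <- tri$value
    A[cbind(tri$j, tri$i)] <- tri$value
  } else {
    ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE, sep = "\t")
    samples <- as.character(ids[[2]])
    n <- length(samples)
    nvals <- n * (n + 1) / 2
    con <- file(paste0(prefix, ".grm.bin"), "rb")
    vals <- readBin(con, "numeric", nvals, size = 4)
    close(con)
    con <- file(paste0(prefix, ".grm.N.bin"), "rb")
    nv <- as.integer(readBin(con, "numeric", 1, size = 4))
    close(con)
    ii <- sequence(seq_len(n))
    jj <- rep(seq_len(n), seq_len(n))
    A <- matrix(0, n, n)
    A[cbind(jj, ii)] <- vals
    A[cbind(ii, jj)] <- vals
  }
  dimnames(A) <- list(samples, samples)
  structure(list(values = A, samples = samples, label = label,
                 n_variants_used = nv), class = "qg_grm")
}

# align a list of GRMs to a common sample set (order of `samples`)
align_grms <- function(grms, samples) {
  lapply(grms, function(g) {
    idx <- match(samples, g$samples)
    if (anyNA(idx)) {
      stop("GRM '", g$label, "' lacks sample ",
           samples[which(is.na(idx))[1]])
    }
    g$values <- g$values[idx, idx, drop = FALSE]
    g$samples <- samples
    g
  })
}
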