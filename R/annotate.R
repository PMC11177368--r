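# Minimal variant-consequence annotation on a toy gene model: the
# consequence terms the fine-mapping stage consumes (stop_gained,
# missense_variant, synonymous_variant, intron_variant, upstream/downstream
# within a configurable distance, intergenic fallback), with impact classes
# via a fixed map. SNVs only; standard genetic code; stop codons rendered
# "*".

IMPACT_MAP <- c(stop_gained = "HIGH", missense_variant = "MODERATE",
                synonymous_variant = "LOW", intron_variant = "MODIFIER",
                upstream_gene_variant = "MODIFIER",
                downstream_gene_variant = "MODIFIER",
                intergenic_variant = "MODIFIER")
IMPACT_RANK <- c(MODIFIER = 0, LOW = 1, MODERATE = 2, HIGH = 3)

new_gene_model <- function(transcripts, exons, cds, ref) {
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  cds <- as_tibble(cds)
  for (tid in transcripts$transcript_id) {
    cd <- cds[cds$transcript_id == tid, ]
    if (nrow(cd) && sum(cd$end - cd$start + 1) %% 3 != 0) {
      stop("CDS length of transcript ", tid, " is not a multiple of 3")
    }
    ex <- exons[exons$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript ", tid)
    }
  }
  structure(list(transcripts = transcripts, exons = exons, cds = cds,
                 ref = ref), class = "qg_gene_model")
}

#' @export
print.qg_gene_model <- function(x, ...) {
  cat("<qg_gene_model> ", nrow(x$transcripts), " transcript(s), ",
      nrow(x$cds), " CDS interval(s)\n", sep = "")
  invisible(x)
}

ref_base <- function(model, chrom, pos, n = 1) {
  r <- model$ref[[chrom]]
  if (is.null(r)) stop("no reference sequence for chromosome ", chrom)
  i <- pos - r$offset + 1
  if (i < 1 || i + n - 1 > nchar(r$seq)) {
    stop("position ", pos, " outside the stored reference slice for ", chrom)
  }
  substr(r$seq, i, i + n - 1)
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon ", codon)
  aa
}

#' Read a toy gene model from GFF3 and FASTA
#'
#' Accepts the GFF3 subset gene/mRNA/exon/CDS (1-based inclusive). The
#' FASTA provides the reference sequence; a record named `chrom` covers the
#' chromosome from position 1, a record named `chrom:start-end` covers that
#' slice only (the usual form for toy models around a QTL).
#'
#' @param gff_path GFF3 file.
#' @param fasta_path FASTA file with the reference slices.
#' @return A `qg_gene_model`.
#' @export
read_gene_model <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path)
  df <- as.data.frame(gr)
  getp <- function(x) vapply(x, function(p) if (length(p)) p[1] else NA_character_,
                             character(1))
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  genes <- df[df$type == "gene", ]
  gene_name <- setNames(
    if ("Name" %in% names(genes) && !all(is.na(genes$Name))) as.character(genes$Name)
    else as.character(genes$ID),
    as.character(genes$ID))
  transcripts <- tibble(
    transcript_id = as.character(mrna$ID),
    gene = unname(gene_name[getp(mrna$Parent)]),
    chrom = as.character(mrna$seqnames),
    strand = as.character(mrna$strand))
  ex <- df[df$type == "exon", ]
  exons <- tibble(transcript_id = getp(ex$Parent), start = ex$start, end = ex$end)
  cd <- df[df$type == "CDS", ]
  cds <- tibble(transcript_id = getp(cd$Parent), start = cd$start, end = cd$end)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ref <- list()
  for (nm in names(seqs)) {
    nm1 <- strsplit(nm, "\\s+")[[1]][1]
    if (grepl(":", nm1)) {
      chrom <- sub(":.*", "", nm1)
      offset <- as.numeric(sub("-.*", "", sub(".*:", "", nm1)))
    } else {
      chrom <- nm1
      offset <- 1
    }
    ref[[chrom]] <- list(offset = offset, seq = as.character(seqs[[nm]]))
  }
  new_gene_model(transcripts, exons, cds, ref)
}

#' Write a toy gene model to GFF3 and FASTA
#'
#' @param model A `qg_gene_model`.
#' @param gff_path,fasta_path Output paths.
#' @return `gff_path`, invisibly.
#' @export
write_gene_model <- function(model, gff_path, fasta_path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(model$transcripts))) {
    tr <- model$transcripts[i, ]
    ex <- model$exons[model$exons$transcript_id == tr$transcript_id, ]
    cd <- model$cds[model$cds$transcript_id == tr$transcript_id, ]
    lo <- min(ex$start); hi <- max(ex$end)
    gid <- paste0("gene:", tr$gene)
    lines <- c(lines,
      paste(tr$chrom, "qtlfine", "gene", lo, hi, ".", tr$strand, ".",
            paste0("ID=", gid, ";Name=", tr$gene), sep = "\t"),
      paste(tr$chrom, "qtlfine", "mRNA", lo, hi, ".", tr$strand, ".",
            paste0("ID=", tr$transcript_id, ";Parent=", gid), sep = "\t"))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(tr$chrom, "qtlfine", "exon", ex$start[j],
                              ex$end[j], ".", tr$strand, ".",
                              paste0("Parent=", tr$transcript_id), sep = "\t"))
    }
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, paste(tr$chrom, "qtlfine", "CDS", cd$start[j],
                              cd$end[j], ".", tr$strand, "0",
                              paste0("Parent=", tr$transcript_id), sep = "\t"))
    }
  }
  writeLines(lines, gff_path)
  seqs <- Biostrings::DNAStringSet(vapply(model$ref, `[[`, character(1), "seq"))
  names(seqs) <- vapply(names(model$ref), function(ch) {
    r <- model$ref[[ch]]
    if (r$offset == 1) ch else
      paste0(ch, ":", format(r$offset, scientific = FALSE),
             "-", format(r$offset + nchar(r$seq) - 1, scientific = FALSE))
  }, character(1))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(gff_path)
}

#' Generate a toy gene model around the planted causal variants
#'
#' For every causal variant whose consequence archetype is genic, a
#' single-exon gene (CDS = exon, 600 bp, causal at the first base of a
#' codon) is placed around it with a reference slice that matches every
#' variant's reference allele; the causal codon is chosen so that the
#' minor/alternate allele produces the archetype consequence
#' (`stop_gained`: GAA>TAA E/*, `missense`: ATT>TTT I/F, `synonymous`:
#' CTG>TTG L/L).
#'
#' @param geno A simulated [geno_matrix()].
#' @param truth The matching `qg_sim_truth`.
#' @param cds_halfwidth Bases of CDS on each side of the causal codon
#'   (multiple of 3; default 300).
#' @return A `qg_gene_model` (plus-strand genes; the consequence archetypes
#'   fix the causal ref/alt bases on the plus strand).
#' @export
simulate_gene_model <- function(geno, truth, cds_halfwidth = 300) {
  strand <- "+"
  if (cds_halfwidth %% 3 != 0) stop("cds_halfwidth must be a multiple of 3")
  causal <- truth$causal[truth$causal$consequence != "intergenic", ]
  transcripts <- list(); exons <- list(); cds <- list(); ref <- list()
  for (i in seq_len(nrow(causal))) {
    cv <- causal[i, ]
    lo <- cv$pos - cds_halfwidth
    hi <- cv$pos + cds_halfwidth - 1  # total length 2*halfwidth, %3 == 0
    tid <- paste0("tx_", cv$id)
    gene <- paste0("gene_", cv$id)
    transcripts[[i]] <- tibble(transcript_id = tid, gene = gene,
                               chrom = cv$chrom, strand = strand)
    exons[[i]] <- tibble(transcript_id = tid, start = lo, end = hi)
    cds[[i]] <- tibble(transcript_id = tid, start = lo, end = hi)
    # reference slice: random bases, variant ref alleles asserted, causal
    # codon written last
    width <- hi - lo + 1
    seq <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    vin <- geno$variants[geno$variants$chrom == cv$chrom &
                           geno$variants$pos >= lo &
                           geno$variants$pos <= hi, ]
    seq[vin$pos - lo + 1] <- vin$ref
    codon <- switch(cv$consequence, stop_gained = c("G", "A", "A"),
                    missense = c("A", "T", "T"),
                    synonymous = c("C", "T", "G"))
    clash <- vin$pos %in% c(cv$pos + 1, cv$pos + 2)
    if (any(clash)) {
      stop("variant ", vin$id[clash][1], " collides with the causal codon of ",
           cv$id, "; re-simulate with a different seed")
    }
    seq[cv$pos - lo + 1 + 0:2] <- codon
    if (is.null(ref[[cv$chrom]])) {
      ref[[cv$chrom]] <- list(offset = lo, seq = paste(seq, collapse = ""))
    } else {
      # extend the stored slice to also cover this gene
      r <- ref[[cv$chrom]]
      new_lo <- min(r$offset, lo)
      new_hi <- max(r$offset + nchar(r$seq) - 1, hi)
      full <- sample(c("A", "C", "G", "T"), new_hi - new_lo + 1, replace = TRUE)
      full[seq_len(nchar(r$seq)) + (r$offset - new_lo)] <-
        strsplit(r$seq, "")[[1]]
      full[(lo - new_lo + 1):(hi - new_lo + 1)] <- seq
      ref[[cv$chrom]] <- list(offset = new_lo,
                              seq = paste(full, collapse = ""))
    }
  }
  new_gene_model(bind_rows(transcripts), bind_rows(exons), bind_rows(cds), ref)
}

# genomic positions of a transcript's CDS in translation order
cds_positions <- function(model, tid, strand) {
  cd <- model$cds[model$cds$transcript_id == tid, ]
  cd <- cd[order(cd$start), ]
  pos <- unlist(Map(seq, cd$start, cd$end))
  if (strand == "-") rev(pos) else pos
}

#' Predict variant consequences on a toy gene model
#'
#' Every variant receives at least one record (intergenic fallback). For a
#' variant inside a transcript's CDS both codons are translated (reverse
#' complement on the minus strand) and the change is classified as
#' `stop_gained`, `missense_variant` or `synonymous_variant`; inside the
#' transcript but outside its exons gives `intron_variant`; within
#' `updown_distance_bp` of the transcript span gives `upstream_` or
#' `downstream_gene_variant` (strand-aware); otherwise
#' `intergenic_variant`. Impacts follow the fixed map (stop_gained HIGH,
#' missense MODERATE, synonymous LOW, others MODIFIER).
#'
#' @param variants A [geno_matrix()] or a tibble with `id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param model A `qg_gene_model`.
#' @param updown_distance_bp Up/downstream assignment distance (default
#'   100,000 bp).
#' @return Tibble: `id`, `transcript_id`, `gene`, `consequence`, `impact`,
#'   `amino_acids` ("X/Y" for coding changes, `NA` otherwise).
#' @export
annotate_variants <- function(variants, model, updown_distance_bp = 100000) {
  if (inherits(variants, "geno_matrix")) variants <- variants$variants
  v <- as.data.frame(variants)
  tr <- model$transcripts
  hit <- rep(FALSE, nrow(v))
  out <- list()
  for (j in seq_len(nrow(tr))) {
    tid <- tr$transcript_id[j]
    strand <- tr$strand[j]
    ex <- model$exons[model$exons$transcript_id == tid, ]
    lo <- min(ex$start); hi <- max(ex$end)
    sel <- which(v$chrom == tr$chrom[j] &
                   v$pos >= lo - updown_distance_bp &
                   v$pos <= hi + updown_distance_bp)
    if (!length(sel)) next
    hit[sel] <- TRUE
    pos <- v$pos[sel]
    cons <- character(length(sel))
    aa <- rep(NA_character_, length(sel))
    before <- pos < lo
    after <- pos > hi
    if (strand == "+") {
      cons[before] <- "upstream_gene_variant"
      cons[after] <- "downstream_gene_variant"
    } else {
      cons[before] <- "downstream_gene_variant"
      cons[after] <- "upstream_gene_variant"
    }
    cpos <- cds_positions(model, tid, strand)
    k <- match(pos, cpos)
    # toy models have CDS == exons; an exonic non-CDS base would be UTR,
    # which the minimal term set folds into intron_variant
    cons[!before & !after & is.na(k)] <- "intron_variant"
    for (i in which(!is.na(k))) {
      cc <- codon_change(model, tr$chrom[j], strand, cpos, k[i],
                         v$ref[sel[i]], v$alt[sel[i]], v$id[sel[i]])
      cons[i] <- cc$consequence
      aa[i] <- cc$aa
    }
    out[[length(out) + 1]] <- tibble(
      id = v$id[sel], transcript_id = tid, gene = tr$gene[j],
      consequence = cons, impact = unname(IMPACT_MAP[cons]),
      amino_acids = aa)
  }
  if (any(!hit)) {
    out[[length(out) + 1]] <- tibble(
      id = v$id[!hit], transcript_id = NA_character_, gene = NA_character_,
      consequence = "intergenic_variant", impact = "MODIFIER",
      amino_acids = NA_character_)
  }
  recs <- bind_rows(out)
  recs[order(match(recs$id, v$id)), ]
}

# classify a single CDS substitution by translating both codons
codon_change <- function(model, chrom, strand, cpos, k, ref, alt, id) {
  ci <- (k - 1) %/% 3
  codon_pos <- cpos[ci * 3 + 1:3]
  bases <- vapply(codon_pos, function(p) ref_base(model, chrom, p), character(1))
  if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  ref_codon <- paste(bases, collapse = "")
  genome_ref <- ref_base(model, chrom, cpos[k])
  if (genome_ref != ref) {
    stop("reference allele of variant ", id, " (", ref,
         ") disagrees with the gene-model reference (", genome_ref,
         ") at ", chrom, ":", cpos[k])
  }
  alt_base <- if (strand == "-") chartr("ACGT", "TGCA", alt) else alt
  alt_codon_bases <- bases
  alt_codon_bases[(k - 1) %% 3 + 1] <- alt_base
  alt_codon <- paste(alt_codon_bases, collapse = "")
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  consequence <- if (aa_alt == aa_ref) "synonymous_variant"
    else if (aa_alt == "*") "stop_gained"
    else "missense_variant"
  list(consequence = consequence, aa = paste0(aa_ref, "/", aa_alt))
}

#' Filter variants by maximal predicted impact
#'
#' @param records Output of [annotate_variants()].
#' @param min_impact `"HIGH"` or `"MODERATE"` (the minimum retained class).
#' @return Character vector of variant ids whose maximal impact over
#'   transcripts is at least `min_impact`.
#' @export
impact_filter <- function(records, min_impact = c("MODERATE", "HIGH")) {
  min_impact <- match.arg(min_impact)
  if (nrow(records) == 0) return(character())
  records %>%
    mutate(rank = IMPACT_RANK[.data$impact]) %>%
    group_by(.data$id) %>%
    summarise(max_rank = max(.data$rank), .groups = "drop") %>%
    filter(.data$max_rank >= IMPACT_RANK[min_impact]) %>%
    pull("id")
}
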