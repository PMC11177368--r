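# build a toy gene model on disk: one plus-strand and one minus-strand
# transcript carrying the same codons, plus an intron-containing gene
write_toy_model <- function() {
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(
    "##gff-version 3",
    "1\ttoy\tgene\t101\t106\t.\t+\t.\tID=gene:GA;Name=GA",
    "1\ttoy\tmRNA\t101\t106\t.\t+\t.\tID=tx_plus;Parent=gene:GA",
    "1\ttoy\texon\t101\t106\t.\t+\t.\tParent=tx_plus",
    "1\ttoy\tCDS\t101\t106\t.\t+\t0\tParent=tx_plus",
    "2\ttoy\tgene\t101\t106\t.\t-\t.\tID=gene:GB;Name=GB",
    "2\ttoy\tmRNA\t101\t106\t.\t-\t.\tID=tx_minus;Parent=gene:GB",
    "2\ttoy\texon\t101\t106\t.\t-\t.\tParent=tx_minus",
    "2\ttoy\tCDS\t101\t106\t.\t-\t0\tParent=tx_minus",
    "3\ttoy\tgene\t101\t301\t.\t+\t.\tID=gene:GC;Name=GC",
    "3\ttoy\tmRNA\t101\t301\t.\t+\t.\tID=tx_split;Parent=gene:GC",
    "3\ttoy\texon\t101\t103\t.\t+\t.\tParent=tx_split",
    "3\ttoy\texon\t299\t301\t.\t+\t.\tParent=tx_split",
    "3\ttoy\tCDS\t101\t103\t.\t+\t0\tParent=tx_split",
    "3\ttoy\tCDS\t299\t301\t.\t+\t0\tParent=tx_split"), gff)
  # chrom 1: GAA GAA from position 101; chrom 2 carries its reverse
  # complement so the minus-strand transcript reads the same codons;
  # chrom 3: ATG ... TAA with an intron between
  pad <- function(s) paste0(strrep("C", 100), s)
  writeLines(c(">1", pad("GAAGAA"),
               ">2", pad("TTCTTC"),
               ">3", paste0(strrep("C", 100), "ATG", strrep("C", 195), "TAA")),
             fa)
  read_gene_model(gff, fa)
}

test_that("coding changes are translated and classified", {
  model <- write_toy_model()
  v <- tibble::tibble(
    id = c("stop", "mis", "syn"),
    chrom = "1", pos = c(101, 102, 106),
    ref = c("G", "A", "A"), alt = c("T", "T", "G"))
  rec <- annotate_variants(v, model)
  rec <- rec[rec$transcript_id == "tx_plus" & !is.na(rec$transcript_id), ]
  # GAA->TAA: E/*, HIGH
  expect_equal(rec$consequence[rec$id == "stop"], "stop_gained")
  expect_equal(rec$amino_acids[rec$id == "stop"], "E/*")
  expect_equal(rec$impact[rec$id == "stop"], "HIGH")
  # GAA->GTA: E/V missense, MODERATE
  expect_equal(rec$consequence[rec$id == "mis"], "missense_variant")
  expect_equal(rec$amino_acids[rec$id == "mis"], "E/V")
  # GAA->GAG: E/E synonymous, LOW
  expect_equal(rec$consequence[rec$id == "syn"], "synonymous_variant")
  expect_equal(rec$impact[rec$id == "syn"], "LOW")
})

test_that("the missense archetype ATT->TTT reads I/F", {
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  writeLines(c("##gff-version 3",
               "1\ttoy\tgene\t11\t13\t.\t+\t.\tID=gene:GI;Name=GI",
               "1\ttoy\tmRNA\t11\t13\t.\t+\t.\tID=tx;Parent=gene:GI",
               "1\ttoy\texon\t11\t13\t.\t+\t.\tParent=tx",
               "1\ttoy\tCDS\t11\t13\t.\t+\t0\tParent=tx"), gff)
  writeLines(c(">1", paste0(strrep("C", 10), "ATT")), fa)
  model <- read_gene_model(gff, fa)
  rec <- annotate_variants(tibble::tibble(id = "x", chrom = "1", pos = 11,
                                          ref = "A", alt = "T"), model)
  rec <- rec[!is.na(rec$transcript_id), ]
  expect_equal(rec$consequence, "missense_variant")
  expect_equal(rec$amino_acids, "I/F")
  expect_equal(rec$impact, "MODERATE")
})

test_that("minus-strand annotation equals the reverse-complement construction", {
  model <- write_toy_model()
  plus <- annotate_variants(tibble::tibble(id = "p", chrom = "1", pos = 101,
                                           ref = "G", alt = "T"), model)
  # same codon change on the minus strand: transcript-first base sits at
  # genomic position 106 with complemented alleles
  minus <- annotate_variants(tibble::tibble(id = "m", chrom = "2", pos = 106,
                                            ref = "C", alt = "A"), model)
  p <- plus[plus$transcript_id == "tx_plus" & !is.na(plus$transcript_id), ]
  m <- minus[minus$transcript_id == "tx_minus" & !is.na(minus$transcript_id), ]
  expect_equal(m$consequence, p$consequence)
  expect_equal(m$amino_acids, p$amino_acids)
})

test_that("distance rules assign intron, up/downstream, and intergenic", {
  model <- write_toy_model()
  v <- tibble::tibble(
    id = c("intron", "up", "down", "far"),
    chrom = c("3", "1", "1", "1"),
    pos = c(200, 50, 5000, 150106),
    ref = "C", alt = "T")
  rec <- annotate_variants(v, model, updown_distance_bp = 100000)
  expect_equal(rec$consequence[rec$id == "intron"][1], "intron_variant")
  expect_equal(rec$consequence[rec$id == "up"][1], "upstream_gene_variant")
  expect_equal(rec$consequence[rec$id == "down"][1], "downstream_gene_variant")
  expect_equal(rec$consequence[rec$id == "far"][1], "intergenic_variant")
  # every variant gets at least one record
  expect_true(all(v$id %in% rec$id))
})

test_that("a reference-allele mismatch is an error naming the site", {
  model <- write_toy_model()
  expect_error(annotate_variants(
    tibble::tibble(id = "bad", chrom = "1", pos = 101, ref = "C", alt = "T"),
    model), "disagrees")
})

test_that("impact filtering takes the maximum over transcripts", {
  rec <- tibble::tibble(
    id = c("a", "a", "b", "c"),
    transcript_id = c("t1", "t2", "t1", "t1"),
    gene = "g",
    consequence = c("intron_variant", "missense_variant",
                    "synonymous_variant", "stop_gained"),
    impact = c("MODIFIER", "MODERATE", "LOW", "HIGH"),
    amino_acids = NA_character_)
  expect_setequal(impact_filter(rec, "MODERATE"), c("a", "c"))
  expect_setequal(impact_filter(rec, "HIGH"), "c")
  expect_equal(impact_filter(rec[0, ], "MODERATE"), character())
})

test_that("a generated gene model round-trips through GFF3 and FASTA", {
  cfg <- sim_config(n_individuals = 100,
                    chromosomes = data.frame(name = "3", n_variants = 120,
                                             length_bp = 20e6),
                    causal = list(causal_variant("3", 10e6, target_maf = 0.4,
                                                 beta = 1)),
                    qtl_dense_variants = 30, seed = 17)
  sim <- simulate_genotypes(cfg)
  gm <- simulate_gene_model(sim$geno, sim$truth)
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_gene_model(gm, gff, fa)
  gm2 <- read_gene_model(gff, fa)
  expect_equal(gm2$cds, gm$cds)
  expect_equal(gm2$ref[["3"]]$seq, gm$ref[["3"]]$seq)
  # the planted stop_gained annotates as such after the round trip
  rec <- annotate_variants(sim$geno, gm2)
  causal_rec <- rec[rec$id == sim$truth$causal$id & !is.na(rec$transcript_id), ]
  expect_equal(causal_rec$consequence, "stop_gained")
  expect_equal(causal_rec$amino_acids, "E/*")
})
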