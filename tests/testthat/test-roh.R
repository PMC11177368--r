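test_that("a clean homozygous stretch is called as one ROH", {
  # 60 consecutive homozygous SNPs evenly spaced over 150 kb
  pos <- round(seq(1e6, 1e6 + 150000 - 1, length.out = 60))
  g <- make_geno(matrix(0, nrow = 1, ncol = 60), pos = pos)
  segs <- detect_roh(g, params = roh_params())
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 60)
  expect_equal(segs$start, pos[1])
  expect_equal(segs$end, pos[60])
})

test_that("runs below the SNP-count minimum are not called", {
  pos <- round(seq(1e6, 1e6 + 150000, length.out = 49))
  g <- make_geno(matrix(0, nrow = 1, ncol = 49), pos = pos)
  expect_warning(segs <- detect_roh(g, params = roh_params()), "scanning window")
  expect_equal(nrow(segs), 0)
})

test_that("a gap beyond the limit splits the run and kills both halves", {
  pos <- c(round(seq(1e6, 1e6 + 70000, length.out = 30)),
           round(seq(2.3e6, 2.3e6 + 70000, length.out = 30)))
  g <- make_geno(matrix(0, nrow = 1, ncol = 60), pos = pos)
  segs <- detect_roh(g, params = roh_params())
  expect_equal(nrow(segs), 0)
})

test_that("scattered heterozygotes within window tolerance do not break a run", {
  pos <- round(seq(1e6, 1e6 + 200000, length.out = 80))
  codes <- rep(0, 80)
  codes[c(20, 45, 70)] <- 1   # 3 hets, within the 3-per-window allowance
  g <- make_geno(matrix(codes, nrow = 1), pos = pos)
  segs <- detect_roh(g, params = roh_params())
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_het, 3)
})

test_that("detection matches a brute-force enumeration oracle", {
  params <- roh_params(min_snps = 15, min_length_bp = 10000,
                       min_density_bp_per_snp = 5000, max_gap_bp = 20000,
                       window_snps = 10, window_max_het = 1,
                       window_max_missing = 1, window_hit_threshold = 0.05)
  for (s in 1:5) {
    set.seed(s)
    m <- sample(60:200, 1)
    n_ind <- sample(2:10, 1)
    pos <- sort(sample.int(3e5, m))
    codes <- matrix(sample(c(0, 0, 0, 2, 2, 2, 1, NA), n_ind * m,
                           replace = TRUE, prob = c(3, 3, 3, 3, 3, 3, 1.2, 0.4)),
                    nrow = n_ind)
    codes[, 1] <- 0   # guard against all-missing columns
    g <- make_geno(codes, pos = pos)
    got <- detect_roh(g, params = params)
    for (i in seq_len(n_ind)) {
      want <- oracle_roh_one(codes[i, ], pos, params)
      mine <- got[got$sample == g$samples[i], ]
      expect_equal(nrow(mine), nrow(want),
                   info = sprintf("seed %d ind %d", s, i))
      if (nrow(want)) {
        expect_equal(mine$start, want$start)
        expect_equal(mine$end, want$end)
        expect_equal(mine$n_snps, want$n_snps)
      }
    }
  }
})

test_that("relaxing any single threshold never removes a reported ROH", {
  set.seed(42)
  pos <- sort(sample.int(4e5, 150))
  codes <- matrix(sample(c(0, 2, 1), 150 * 4, replace = TRUE,
                         prob = c(6, 6, 1)), nrow = 4)
  g <- make_geno(codes, pos = pos)
  base <- roh_params(min_snps = 20, min_length_bp = 20000,
                     min_density_bp_per_snp = 8000, max_gap_bp = 30000,
                     window_snps = 10, window_max_het = 1)
  got <- detect_roh(g, params = base)
  relaxed <- list(
    roh_params(min_snps = 10, min_length_bp = 20000,
               min_density_bp_per_snp = 8000, max_gap_bp = 30000,
               window_snps = 10, window_max_het = 1),
    roh_params(min_snps = 20, min_length_bp = 5000,
               min_density_bp_per_snp = 8000, max_gap_bp = 30000,
               window_snps = 10, window_max_het = 1),
    roh_params(min_snps = 20, min_length_bp = 20000,
               min_density_bp_per_snp = 8000, max_gap_bp = 60000,
               window_snps = 10, window_max_het = 1))
  for (rp in relaxed) {
    more <- detect_roh(g, params = rp)
    for (i in seq_len(nrow(got))) {
      hit <- more$sample == got$sample[i] & more$start <= got$start[i] &
        more$end >= got$end[i]
      expect_true(any(hit))
    }
  }
})

test_that("shared intervals intersect segments with carrier counts", {
  segs <- tibble::tibble(
    sample = c("s01", "s02"), chrom = "1",
    start = c(100000, 150000), end = c(200000, 250000),
    n_snps = c(50, 50), n_het = 0, n_missing = 0)
  g <- make_geno(matrix(0, nrow = 3, ncol = 4), chrom = "1",
                 pos = c(120000, 160000, 190000, 230000))
  sh <- shared_roh(segs, c(s01 = "top", s02 = "top"), g)
  expect_equal(nrow(sh), 1)
  expect_equal(c(sh$start, sh$end), c(150000, 200000))
  expect_equal(sh$n_carriers, 2)
  expect_equal(sh$carriers_top, 2)
})

test_that("a third individual without overlap leaves carrier count at 2 of 3", {
  segs <- tibble::tibble(
    sample = c("s01", "s02", "s03"), chrom = "1",
    start = c(100000, 150000, 400000), end = c(200000, 250000, 500000),
    n_snps = 50, n_het = 0, n_missing = 0)
  g <- make_geno(matrix(0, nrow = 3, ncol = 2), pos = c(160000, 450000))
  sh <- shared_roh(segs, c(s01 = "a", s02 = "a", s03 = "a"), g)
  mid <- sh[sh$start == 150000, ]
  expect_equal(mid$n_carriers, 2)
})

test_that("opposite homozygotes are flagged as different allele classes", {
  codes <- rbind(c(2, 2, 2), c(0, 0, 0), c(2, NA, 2))
  g <- make_geno(codes, pos = c(100000, 150000, 200000))
  segs <- tibble::tibble(sample = c("s01", "s02", "s03"), chrom = "1",
                         start = 100000, end = 200000,
                         n_snps = 3, n_het = 0, n_missing = c(0, 0, 1))
  sh <- shared_roh(segs, c(s01 = "top", s02 = "bottom", s03 = "top"), g)
  expect_true(sh$classes_differ)
  expect_equal(sh$carriers_top, 2)
  expect_equal(sh$carriers_bottom, 1)
  # missing calls never break equality: s01 vs s03 agree
  sh2 <- shared_roh(segs[c(1, 3), ], c(s01 = "top", s03 = "top"), g)
  expect_false(sh2$classes_differ)
  expect_error(shared_roh(segs, c(nope = "x"), g), "unknown sample")
})

test_that("segments export natively and in the .hom column layout", {
  segs <- tibble::tibble(sample = "s01", chrom = "1", start = 100000,
                         end = 250000, n_snps = 60L, n_het = 1L,
                         n_missing = 0L)
  path <- tempfile(fileext = ".hom")
  write_roh(segs, path, format = "hom")
  hom <- read.table(path, header = TRUE)
  expect_equal(names(hom), c("FID", "IID", "CHR", "POS1", "POS2", "KB", "NSNP"))
  expect_equal(hom$KB, 150.001)
  path2 <- tempfile(fileext = ".tsv")
  write_roh(segs, path2, format = "tsv")
  expect_equal(read.table(path2, header = TRUE)$n_snps, 60L)
})
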