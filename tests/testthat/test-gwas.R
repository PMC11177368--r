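test_that("the Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(10), 0.005)
  # the genome-wide sequence-level threshold rounds to 3.8e-9
  thr <- bonferroni_threshold(13091438)
  expect_equal(thr, 0.05 / 13091438)
  expect_equal(round(thr * 1e9, 1), 3.8)
  expect_error(bonferroni_threshold(0), "at least 1")
  expect_error(bonferroni_threshold(10, alpha = 1.2), "alpha")
})

test_that("with zero genetic variance the scan collapses to least squares", {
  set.seed(12)
  g <- random_geno(150, 12, seed = 12)
  pheno <- tibble::tibble(sample = g$samples,
                          y = rnorm(150, 20, 2),
                          age_days = runif(150, 700, 3000))
  gw <- run_mlm_loco(g, pheno, qg_model("y"), genetic_variance = 0)
  for (j in c(1, 5, 12)) {
    ols <- lm(pheno$y ~ pheno$age_days + g$codes[, j])
    expect_equal(gw$beta[j], unname(coef(ols)[3]), tolerance = 1e-6)
    expect_equal(gw$p_value[j],
                 summary(ols)$coefficients[3, 4], tolerance = 1e-2)
  }
})

fake_gwas <- function(pos, p, chrom = "3", threshold = 1e-8) {
  n <- length(pos)
  tb <- tibble::tibble(id = paste0("v", seq_len(n)), chrom = chrom, pos = pos,
                       ref = "A", alt = "G", minor = "G", maf = 0.4,
                       n_used = 100, beta = 1, se = 0.1, p_value = p)
  structure(tb, class = c("qg_gwas", class(tb)), threshold = threshold,
            lambda_gc = 1, n_tests = n, trait = "y")
}

test_that("region summaries merge, filter, and break top-SNP ties by position", {
  # four tied top SNPs: the lowest-position one is reported
  gw <- fake_gwas(pos = c(107373887, 107374136, 107374798, 107375521,
                          120e6),
                  p = c(rep(4.2e-154, 4), 1e-3))
  reg <- summarize_regions(gw)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$top_pos, 107373887)
  expect_equal(reg$n_significant, 4)
  # a gap larger than merge_gap_bp splits regions
  gw2 <- fake_gwas(pos = c(1e6, 1.2e6, 1.4e6, 5e6, 5.1e6, 5.2e6, 5.3e6, 5.4e6),
                   p = rep(1e-10, 8))
  reg2 <- summarize_regions(gw2, merge_gap_bp = 1e6)
  expect_equal(nrow(reg2), 2)
  # the minimum-SNP filter drops small regions
  reg3 <- summarize_regions(gw2, merge_gap_bp = 1e6, min_snps = 5)
  expect_equal(nrow(reg3), 1)
  expect_equal(reg3$n_significant, 5)
  # no significant variants: empty list, not an error
  expect_equal(nrow(summarize_regions(fake_gwas(1e6, 0.5))), 0)
})

test_that("the ROH scan window widens the significant span by the buffer", {
  gw <- fake_gwas(pos = c(97840010, 1e8, 117983557), p = rep(1e-12, 3))
  win <- roh_scan_window(gw, "3", buffer_bp = 100000)
  expect_equal(win$start, 97740010)
  expect_equal(win$end, 118083557)
  win0 <- roh_scan_window(gw, "3", buffer_bp = 0)
  expect_equal(c(win0$start, win0$end), c(97840010, 117983557))
  gw1 <- fake_gwas(pos = 5e6, p = 1e-12)
  win1 <- roh_scan_window(gw1, "3", buffer_bp = 100000)
  expect_equal(c(win1$start, win1$end), c(4900000, 5100000))
  expect_error(roh_scan_window(fake_gwas(1e6, 0.5), "3"), "significant")
})

test_that("conditioning on an unlinked marker leaves the causal peak intact", {
  cfg <- sim_config(n_individuals = 600,
                    chromosomes = data.frame(name = c("1", "2"),
                                             n_variants = c(200, 200),
                                             length_bp = c(40e6, 40e6)),
                    causal = list(causal_variant("2", 20e6, target_maf = 0.45,
                                                 beta = 2.68)),
                    qtl_dense_variants = 50, seed = 13)
  sim <- simulate_cohort(cfg)
  g <- filter_variants(sim$geno, min_maf = 0.01)
  causal <- sim$truth$causal$id
  base <- run_mlm_loco(g, sim$pheno, qg_model("height"), chromosomes = "2")
  far_snp <- g$variants$id[g$variants$chrom == "1"][5]
  cond <- conditional_gwas(g, sim$pheno, qg_model("height"),
                           list(snp = far_snp), chromosomes = "2")
  p0 <- min(base$p_value, na.rm = TRUE)
  p1 <- min(cond$p_value[cond$chrom == "2"], na.rm = TRUE)
  expect_lt(abs(log10(p1) - log10(p0)), 1)
  # the conditioning SNP itself is skipped from its own scan
  cond2 <- conditional_gwas(g, sim$pheno, qg_model("height"),
                            list(snp = causal), chromosomes = "2")
  expect_false(causal %in% cond2$id)
  expect_error(conditional_gwas(g, sim$pheno, qg_model("height"),
                                list(trait = "nope"), chromosomes = "2"),
               "nope")
})

test_that("scan tibbles carry calibration metadata and tidiers work", {
  gw <- fake_gwas(pos = c(1e6, 2e6), p = c(1e-10, 0.5))
  expect_equal(lambda_gc(gw), 1)
  gl <- glance(gw)
  expect_equal(gl$n_significant, 1)
  expect_equal(gl$top_snp, "v1")
  td <- tidy(gw)
  expect_false(inherits(td, "qg_gwas"))
})
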