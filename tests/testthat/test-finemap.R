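test_that("dosage r2 matches the correlation-formula oracle", {
  g <- make_geno(cbind(c(0, 1, 2, 1), c(2, 1, 0, 1), c(0, 0, 1, 2),
                       c(0, 1, 1, 2), c(1, 1, 1, 1)))
  expect_equal(ld_r2(g, "v1", "v1")$r2, 1)
  # perfect negative correlation squares to 1
  expect_equal(ld_r2(g, "v1", "v2")$r2, 1)
  expect_equal(ld_r2(g, "v3", "v4")$r2,
               cor(c(0, 0, 1, 2), c(0, 1, 1, 2))^2, tolerance = 1e-12)
  expect_warning(r <- ld_r2(g, "v1", "v5"), "monomorphic")
  expect_true(is.na(r$r2))
})

test_that("r2 uses mutually non-missing individuals", {
  g <- make_geno(cbind(c(0, 1, 2, NA, 1), c(0, 1, 2, 1, NA)))
  expect_equal(ld_r2(g, "v1", "v2")$r2, 1)   # complete pairs agree exactly
})

finemap_fixture <- function() {
  cfg <- sim_config(n_individuals = 500,
                    chromosomes = data.frame(name = c("1", "2"),
                                             n_variants = c(150, 200),
                                             length_bp = c(40e6, 40e6)),
                    causal = list(causal_variant("2", 20e6, target_maf = 0.45,
                                                 beta = 2.68)),
                    qtl_dense_variants = 100, seed = 19)
  sim <- simulate_cohort(cfg)
  g <- filter_variants(sim$geno, min_maf = 0.01)
  gw <- run_mlm_loco(g, sim$pheno, qg_model("height"), chromosomes = "2")
  gm <- simulate_gene_model(g, sim$truth)
  list(sim = sim, g = g, gw = gw, ann = annotate_variants(g, gm),
       causal = sim$truth$causal$id)
}

test_that("the LD candidate set keeps high-r2 significant variants and is monotone", {
  fx <- finemap_fixture()
  tops <- summarize_regions(fx$gw)
  ld8 <- ld_candidate_set(fx$g, fx$gw, tops$top_snp, annotations = fx$ann,
                          r2_threshold = 0.8)
  # the top SNP itself always qualifies (r2 = 1)
  expect_true(tops$top_snp[1] %in% ld8$id)
  expect_true(all(ld8$r2_to_top > 0.8))
  # impact shortlist keeps only the planted coding variant
  expect_equal(ld8$id[ld8$in_shortlist], fx$causal)
  # raising the threshold never adds members
  ld9 <- ld_candidate_set(fx$g, fx$gw, tops$top_snp, annotations = fx$ann,
                          r2_threshold = 0.95)
  expect_true(all(ld9$id %in% ld8$id))
})

test_that("candidate combination is the ranked intersection with provenance", {
  ld_set <- tibble::tibble(id = c("a", "b", "c"), r2_to_top = c(1, 0.9, 0.85),
                           in_shortlist = TRUE)
  ibd_set <- list(candidates = tibble::tibble(
    id = c("b", "c", "d"), pos = c(2e6, 3e6, 4e6), p_value = c(1e-10, 1e-12, 1e-9),
    impact = "HIGH"))
  gw <- tibble::tibble(id = c("a", "b", "c", "d"), chrom = "3",
                       pos = c(1e6, 2e6, 3e6, 4e6), ref = "A", alt = "G",
                       minor = "G", maf = 0.4, n_used = 100, beta = 2,
                       se = 0.2, p_value = c(1e-11, 1e-10, 1e-12, 1e-9))
  geno <- random_geno(30, 4, seed = 20)
  geno$variants$id <- c("a", "b", "c", "d")
  colnames(geno$codes) <- geno$variants$id
  out <- combine_candidates(ld_set, ibd_set, gw, geno)
  expect_equal(out$id, c("c", "b"))   # ascending p-value
  expect_equal(out$source, c("both", "both"))
  expect_equal(dim(attr(out, "pairwise_r2")), c(2, 2))
  expect_named(attr(out, "provenance"), c("ld", "ibd"))
  # empty intersection gives an empty report that still lists both sources
  out0 <- combine_candidates(ld_set[ld_set$id == "a", ],
                             ibd_set, gw, geno)
  expect_equal(nrow(out0), 0)
  expect_equal(attr(out0, "provenance")$ld$id, "a")
})

test_that("extreme-group selection requires a live gEBV component", {
  blup <- structure(list(
    gebv = tibble::tibble(sample = sprintf("s%02d", 1:30),
                          qtl = rep(0, 30), total = rep(0, 30)),
    fixed = c(mu = 0), trait = "y", components = "qtl"),
    class = "qg_blup")
  g <- random_geno(30, 5, seed = 21)
  gw <- tibble::tibble(id = "v1", chrom = "1", pos = 1000, ref = "A",
                       alt = "G", minor = "G", maf = 0.4, n_used = 30,
                       beta = 1, se = 0.1, p_value = 1e-10)
  gw <- structure(gw, class = c("qg_gwas", class(gw)), threshold = 1e-8,
                  lambda_gc = 1, n_tests = 1, trait = "y")
  expect_error(ibd_candidate_set(blup, "qtl", g, gw, NULL, chrom = "1"),
               "no variance")
  blup$gebv$qtl <- rnorm(30)
  expect_error(ibd_candidate_set(blup, "qtl", g, gw, NULL, chrom = "1",
                                 k = 20), "exceeds")
  expect_error(ibd_candidate_set(blup, "nope", g, gw, NULL, chrom = "1"),
               "unknown gEBV")
})
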