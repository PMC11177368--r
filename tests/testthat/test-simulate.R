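small_cfg <- function(seed = 1, ...) {
  sim_config(
    n_individuals = 300,
    chromosomes = data.frame(name = c("1", "2"), n_variants = c(150, 150),
                             length_bp = c(40e6, 40e6)),
    causal = list(causal_variant("2", 20e6, target_maf = 0.4, beta = 2)),
    qtl_dense_variants = 50, seed = seed, ...)
}

test_that("the simulator is a pure function of config and seed", {
  s1 <- simulate_cohort(small_cfg(7))
  s2 <- simulate_cohort(small_cfg(7))
  expect_identical(s1$geno$codes, s2$geno$codes)
  expect_identical(s1$pheno, s2$pheno)
  s3 <- simulate_cohort(small_cfg(8))
  expect_false(identical(s1$geno$codes, s3$geno$codes))
})

test_that("an unreachable causal MAF suggests enlarging the founder pool", {
  cfg <- small_cfg(1, n_founders = 20)
  cfg$causal[[1]]$target_maf <- 0.01
  expect_error(simulate_genotypes(cfg), "founder")
})

test_that("LD decays with distance: near pairs exceed far pairs in r2", {
  cfg <- sim_config(n_individuals = 400,
                    chromosomes = data.frame(name = "1", n_variants = 500,
                                             length_bp = 25e6),
                    causal = list(), seed = 11)
  g <- filter_variants(simulate_genotypes(cfg)$geno, min_maf = 0.05)
  pos <- g$variants$pos
  C2 <- stats::cor(g$codes)^2
  d <- abs(outer(pos, pos, "-"))
  near <- C2[d > 0 & d < 5e4]
  far <- C2[d > 5e6]
  expect_gt(mean(near), mean(far))
})

test_that("cohort-level targets are realized: mean, causal MAF, tag block", {
  cfg <- sim_config(n_individuals = 2000,
                    causal = list(causal_variant("3", 107373887,
                                                 target_maf = 0.47,
                                                 beta = 2.68)),
                    seed = 5)
  sim <- simulate_cohort(cfg)
  expect_lt(abs(mean(sim$pheno$height) - 167.6), 0.3)
  expect_lt(abs(sim$truth$causal$realized_maf - 0.47), 0.05)
  # at least 5 non-causal variants within 500 kb in tight LD with the causal
  g <- sim$geno
  near <- g$variants$id[g$variants$chrom == "3" &
                          abs(g$variants$pos - 107373887) <= 5e5 &
                          g$variants$id != sim$truth$causal$id]
  r2 <- suppressWarnings(ld_r2(g, sim$truth$causal$id, near)$r2)
  expect_gte(sum(r2 > 0.8, na.rm = TRUE), 5)
})

test_that("a null trait has exactly zero genetic variance", {
  cfg <- small_cfg(3)
  cfg$causal <- list()
  cfg$traits <- list(qg_trait("height", h2 = 0))
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$components$v_genetic, 0)
  expect_equal(sim$truth$components$h2_realized, 0)
})

test_that("homozygote group means differ by about twice the planted effect", {
  cfg <- sim_config(n_individuals = 1000,
                    chromosomes = data.frame(name = "1", n_variants = 300,
                                             length_bp = 50e6),
                    causal = list(causal_variant("1", 25e6, target_maf = 0.4,
                                                 beta = 2)),
                    traits = list(qg_trait("height", fixed = character())),
                    qtl_dense_variants = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  d <- sim$geno$codes[, match(sim$truth$causal$id, sim$geno$variants$id)]
  diff <- mean(sim$pheno$height[d == 2]) - mean(sim$pheno$height[d == 0])
  expect_lt(abs(diff - 4), 1)
})

test_that("realized heritability tracks the target", {
  h2 <- vapply(1:5, function(s) {
    cfg <- small_cfg(s)
    simulate_cohort(cfg)$truth$components$h2_realized
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.528), 0.03)
})

test_that("ordinal scores respect thresholds and scales", {
  thr <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  expect_equal(simulate_linear_scores(-10, thr), -3L)
  expect_equal(simulate_linear_scores(10, thr), 3L)
  set.seed(1)
  sc <- simulate_linear_scores(rnorm(2000), thr)
  expect_lt(abs(mean(sc)), 0.1)
  def <- simulate_linear_scores(rnorm(500), c(0.5, 1.5, 2.5), defect = TRUE)
  expect_true(all(def %in% 0:3))
  expect_error(simulate_linear_scores(0, c(1, 1, 2), defect = TRUE),
               "increasing")
  expect_error(simulate_linear_scores(0, c(-1, 0, 1)), "6 thresholds")
})

test_that("defect-trait simulation stays on the 0..3 scale", {
  cfg <- small_cfg(4)
  cfg$traits <- list(qg_trait("caphock", mean = 0.5, sd = 0.5, h2 = 0.1,
                              fixed = c("age_class", "sex"),
                              ordinal = "defect"))
  cfg$causal <- list()
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$pheno$caphock %in% 0:3))
})
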