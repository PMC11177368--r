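# Heavy simulation replicates shared by several acceptance checks. Each
# set is computed once per test run and cached in the session; seeds are
# the fixed sequence 1..n_reps.

.qg_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .qg_cache)) {
    assign(key, compute(), envir = .qg_cache)
  }
  get(key, envir = .qg_cache)
}

# --- planted-beta cohort: effect-size recovery, fine-mapping end-to-end ---

e2e_config <- function(seed) {
  sim_config(
    n_individuals = 2000,
    causal = list(causal_variant("3", 107373887, target_maf = 0.45,
                                 beta = 2.68)),
    seed = seed)
}

run_e2e_rep <- function(seed) {
  sim <- simulate_cohort(e2e_config(seed))
  g <- filter_variants(sim$geno, min_maf = 0.01)
  causal <- sim$truth$causal$id[1]
  gw <- run_mlm_loco(g, sim$pheno, qg_model("height"), chromosomes = "3")
  ids3 <- g$variants$id[g$variants$chrom == "3"]
  grms <- list(qtl_chrom = compute_grm(g, ids3, label = "chr3"),
               rest = compute_grm(g, setdiff(g$variants$id, ids3),
                                  label = "rest"))
  fit <- fit_greml(sim$pheno, grms, qg_model("height"))
  blup <- predict_gebv(fit, grms)
  gm <- simulate_gene_model(g, sim$truth)
  ann <- annotate_variants(g, gm)
  ibd <- ibd_candidate_set(blup, "qtl_chrom", g, gw, ann, chrom = "3", k = 10)
  regions <- summarize_regions(gw)
  ld <- ld_candidate_set(g, gw, regions$top_snp, annotations = ann)
  cands <- combine_candidates(ld, ibd, gw, g, annotations = ann)
  d <- g$codes[, match(causal, g$variants$id)]
  list(causal_id = causal,
       beta_causal = gw$beta[gw$id == causal],
       top_snp = regions$top_snp[which.min(regions$top_p)],
       candidate_ids = cands$id,
       n_candidates = nrow(cands),
       pairwise_r2 = attr(cands, "pairwise_r2"),
       gebv_dosage_cor = stats::cor(blup$gebv$qtl_chrom, d),
       n_shared_top = nrow(ibd$shared_top),
       shared_top = ibd$shared_top,
       ld_block_ok = sum(ld_r2(g, causal,
         g$variants$id[g$variants$chrom == "3" &
                         abs(g$variants$pos - 107373887) <= 5e5 &
                         g$variants$id != causal])$r2 > 0.8, na.rm = TRUE))
}

e2e_replicates <- function() {
  cache_get("e2e20", function() lapply(1:20, run_e2e_rep))
}

# --- planted-window cohort: variance-partition recovery (two windows) ---

window_config <- function(seed) {
  sim_config(
    n_individuals = 2000,
    causal = list(),
    region_effects = list(
      region_effect("3", 107373887, 3e6, frac = 0.171),
      region_effect("1", 57166410, 1e6, frac = 0.087)),
    seed = seed)
}

run_window_rep <- function(seed) {
  sim <- simulate_cohort(window_config(seed))
  g <- filter_variants(sim$geno, min_maf = 0.01)
  grms <- build_partitioned_grms(
    g, scheme = "qtl_plus_rest",
    regions = list(region_spec("3", 107373887, 3e6, 7e6, label = "qtl3"),
                   region_spec("1", 57166410, 1e6, 2e6, label = "qtl1")))
  fit <- fit_greml(sim$pheno, grms, qg_model("height"))
  fit$fractions
}

window_replicates <- function() {
  cache_get("window10", function() lapply(1:10, run_window_rep))
}

# --- pure polygenic cohort: single-GRM heritability recovery ---

run_h2_rep <- function(seed) {
  cfg <- sim_config(n_individuals = 2000, causal = list(), seed = seed)
  sim <- simulate_cohort(cfg)
  g <- filter_variants(sim$geno, min_maf = 0.01)
  fit <- fit_greml(sim$pheno, compute_grm(g), qg_model("height"))
  sum(fit$fractions)
}

h2_replicates <- function() {
  cache_get("h2_10", function() vapply(1:10, run_h2_rep, numeric(1)))
}

# --- shared-QTL two-trait cohort: local genetic correlation ---

biv_config <- function(seed) {
  sim_config(
    n_individuals = 2000,
    causal = list(causal_variant("3", 107373887, target_maf = 0.45,
                                 frac = 0.171,
                                 pleiotropy = c(height = 1, frame = 0.3))),
    traits = list(qg_trait("height"),
                  qg_trait("frame", mean = 0, sd = 1, h2 = 0.3)),
    seed = seed)
}

run_biv_rep <- function(seed) {
  sim <- simulate_cohort(biv_config(seed))
  g <- filter_variants(sim$geno, min_maf = 0.01)
  grms <- build_partitioned_grms(
    g, scheme = "qtl_plus_rest",
    regions = list(region_spec("3", 107373887, 3e6, 7e6, label = "qtl3")),
    combine_rest = TRUE)
  bf <- fit_bivariate(sim$pheno, grms, qg_model("height"), qg_model("frame"))
  bf$components$r_g[bf$components$component == "qtl3"]
}

biv_replicates <- function() {
  cache_get("biv10", function() vapply(1:10, run_biv_rep, numeric(1)))
}
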