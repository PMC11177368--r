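# Founder-mosaic genotype/phenotype simulator. Each individual's two
# haplotypes are mosaics of a small founder pool, which (i) produces
# block-structured LD without a coalescent simulation and (ii) directly
# creates the shared founder segments that the ROH/IBD fine-mapping stage
# relies on: the founder haplotype carrying the causal minor allele is made
# locally homogeneous, so minor-allele homozygotes are homozygous across the
# QTL window.

#' Describe a simulated trait
#'
#' @param name Trait/column name.
#' @param mean,sd Target phenotypic mean and standard deviation (trait
#'   units; the SD covers genetic plus residual variation, before fixed
#'   effects).
#' @param h2 Target narrow-sense heritability in \[0, 1).
#' @param fixed Fixed-effect structure simulated for this trait: any of
#'   `"age"` (linear in age in days), `"age_class"`, `"sex"`, `"judge"`,
#'   `"event"`.
#' @param ordinal One of `"none"` (continuous), `"signed"` (integer scores
#'   -3..+3) or `"defect"` (integer scores 0..+3).
#' @param thresholds Optional strictly increasing latent cut points (6 for
#'   signed, 3 for defect); defaults to symmetric cuts at
#'   `mean + sd * c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)` (signed) or
#'   `mean + sd * c(0.5, 1.5, 2.5)` (defect).
#' @return An object of class `qg_trait_spec`.
#' @export
qg_trait <- function(name, mean = 167.6, sd = 3.6, h2 = 0.528,
                     fixed = "age", ordinal = c("none", "signed", "defect"),
                     thresholds = NULL) {
  ordinal <- match.arg(ordinal)
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  structure(list(name = name, mean = mean, sd = sd, h2 = h2, fixed = fixed,
                 ordinal = ordinal, thresholds = thresholds),
            class = "qg_trait_spec")
}

#' Describe a planted causal variant
#'
#' Exactly one of `beta` (per-minor-allele effect, trait units of the first
#' configured trait) or `frac` (fraction of that trait's phenotypic variance
#' explained, from which the effect is derived using the realized dosage
#' variance) must be given.
#'
#' @param chrom,pos Location; the position is injected into the variant grid.
#' @param target_maf Target minor-allele frequency (0, 0.5].
#' @param beta Per-minor-allele effect in trait units, or `NULL`.
#' @param frac Fraction of phenotypic variance, or `NULL`.
#' @param consequence Consequence archetype used when a toy gene model is
#'   generated around the variant.
#' @param pleiotropy Named numeric vector mapping trait names to effect
#'   scalings; traits not named get no direct effect of this variant.
#' @return An object of class `qg_causal_spec`.
#' @export
causal_variant <- function(chrom, pos, target_maf = 0.45, beta = NULL,
                           frac = NULL,
                           consequence = c("stop_gained", "missense",
                                           "synonymous", "intergenic"),
                           pleiotropy = NULL) {
  consequence <- match.arg(consequence)
  if (is.null(beta) == is.null(frac)) {
    stop("give exactly one of beta or frac for the causal variant")
  }
  if (target_maf <= 0 || target_maf > 0.5) stop("target_maf must be in (0, 0.5]")
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 target_maf = target_maf, beta = beta, frac = frac,
                 consequence = consequence, pleiotropy = pleiotropy),
            class = "qg_causal_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a warmblood-horse conformation
#' cohort scaled to desk size: n = 2000 individuals, three 120-Mb
#' chromosome-like segments carrying ~5000 LD-structured SNPs, one major
#' additive QTL (a nonsense variant at MAF 0.45 explaining 17.1% of
#' phenotypic variance) on chromosome "3" at 107,373,887 bp, a polygenic
#' background completing a total heritability of 0.528 for a trait with
#' mean 167.6 and SD 3.6, and judge/event/sex fixed effects of SD
#' 0.5 x trait SD.
#'
#' @param n_individuals Number of diploid individuals.
#' @param chromosomes Data frame with columns `name`, `n_variants`,
#'   `length_bp`.
#' @param n_founders Founder haplotypes per chromosome.
#' @param switch_rate Expected founder switches per Mb per haplotype.
#' @param causal List of [causal_variant()] specs.
#' @param region_effects List of [region_effect()] specs (distributed
#'   window-level causal variation).
#' @param traits List of [qg_trait()] specs.
#' @param qtl_block_halfwidth Half-width (bp) of the locally homogeneous
#'   founder block around each causal variant.
#' @param qtl_dense_variants,qtl_dense_halfwidth Extra variants placed
#'   within `qtl_dense_halfwidth` of each causal variant, emulating the
#'   sequence-level marker density of a fine-mapping region (the genome
#'   backbone stays at array-like density). At the defaults this gives one
#'   variant per ~5 kb near the QTL, which is what makes the
#'   50-SNP/50-kb-per-SNP ROH rules attainable.
#' @param n_perfect_tags Number of nearest window variants forced into
#'   complete LD with the causal variant (carrier founders carry the minor
#'   allele, others the major), guaranteeing a taggable haplotype block.
#' @param fixed_effects List with elements `age_range_years`,
#'   `age_slope_sd_per_day`, `sex_sd`, `judge_sd`, `event_sd` (the `*_sd`
#'   entries are in units of trait SD), `n_judges`.
#' @param seed Integer seed; every simulator output is a pure function of
#'   the configuration including this seed.
#' @return An object of class `qg_sim_config`.
#' @export
sim_config <- function(n_individuals = 2000,
                       chromosomes = data.frame(
                         name = c("1", "2", "3"),
                         n_variants = c(1600, 1600, 1800),
                         length_bp = rep(120e6, 3)),
                       n_founders = 20,
                       switch_rate = 1,
                       causal = list(causal_variant("3", 107373887,
                                                    target_maf = 0.45,
                                                    frac = 0.171)),
                       region_effects = list(),
                       traits = list(qg_trait("height")),
                       qtl_block_halfwidth = 600e3,
                       n_perfect_tags = 8,
                       qtl_dense_variants = 400,
                       qtl_dense_halfwidth = 1e6,
                       fixed_effects = list(age_range_years = c(2, 10),
                                            age_slope_sd_per_day = 5e-4,
                                            sex_sd = 0.5, judge_sd = 0.5,
                                            event_sd = 0.5, n_judges = 39),
                       seed = 1L) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(chromosomes$length_bp > 0), all(chromosomes$n_variants > 0))
  if (inherits(causal, "qg_causal_spec")) causal <- list(causal)
  if (inherits(region_effects, "qg_region_effect")) {
    region_effects <- list(region_effects)
  }
  if (inherits(traits, "qg_trait_spec")) traits <- list(traits)
  for (cv in causal) {
    if (!cv$chrom %in% chromosomes$name) {
      stop("causal variant on unknown chromosome ", cv$chrom)
    }
  }
  for (re in region_effects) {
    if (!re$chrom %in% chromosomes$name) {
      stop("region effect on unknown chromosome ", re$chrom)
    }
  }
  structure(list(n_individuals = n_individuals, chromosomes = chromosomes,
                 n_founders = n_founders, switch_rate = switch_rate,
                 causal = causal, region_effects = region_effects,
                 traits = traits,
                 qtl_block_halfwidth = qtl_block_halfwidth,
                 n_perfect_tags = n_perfect_tags,
                 qtl_dense_variants = qtl_dense_variants,
                 qtl_dense_halfwidth = qtl_dense_halfwidth,
                 fixed_effects = fixed_effects, seed = as.integer(seed)),
            class = "qg_sim_config")
}

#' Describe a planted QTL window of distributed effects
#'
#' Plants region-level causal variation: every variant inside the window
#' receives an i.i.d. normal effect, jointly rescaled so the window's
#' realized contribution equals `frac` of the first trait's phenotypic
#' variance exactly. This is the architecture the window/rest GRM
#' partition assumes, and complements [causal_variant()] (one large-effect
#' variant) for variance-partition studies.
#'
#' @param chrom,center Window centre.
#' @param halfwidth Window half-width in bp (default 3 Mb).
#' @param frac Fraction of phenotypic variance contributed by the window.
#' @param pleiotropy Named numeric vector of per-trait scalings applied to
#'   the shared window effect vector (fully concordant allelic effects);
#'   unnamed traits get none.
#' @return An object of class `qg_region_effect`.
#' @export
region_effect <- function(chrom, center, halfwidth = 3e6, frac,
                          pleiotropy = NULL) {
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)")
  structure(list(chrom = as.character(chrom), center = as.numeric(center),
                 halfwidth = as.numeric(halfwidth), frac = frac,
                 pleiotropy = pleiotropy),
            class = "qg_region_effect")
}

causal_id <- function(cv) paste0("v", cv$chrom, "_",
                                 format(cv$pos, scientific = FALSE, trim = TRUE))

#' Simulate LD-structured genotypes with planted causal variants
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `geno` (a [geno_matrix()]) and `truth`
#'   (class `qg_sim_truth`: causal-variant table with realized frequencies,
#'   and the carrier-founder sets).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "qg_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  nf <- cfg$n_founders
  codes_list <- list()
  var_list <- list()
  carrier_sets <- list()
  for (ci in seq_len(nrow(cfg$chromosomes))) {
    ch <- cfg$chromosomes$name[ci]
    m <- cfg$chromosomes$n_variants[ci]
    L <- cfg$chromosomes$length_bp[ci]
    cvs <- Filter(function(cv) cv$chrom == ch, cfg$causal)
    pos <- sample.int(L, m)
    for (cv in cvs) {
      # sequence-density grid around the causal site, plus the site itself
      dense <- round(runif(cfg$qtl_dense_variants,
                           max(1, cv$pos - cfg$qtl_dense_halfwidth),
                           min(L, cv$pos + cfg$qtl_dense_halfwidth)))
      pos <- c(pos, dense, cv$pos)
    }
    pos <- sort(unique(pos))
    m <- length(pos)
    # founder haplotypes: allele frequencies from a U-shaped Beta(0.5, 0.5)
    p <- rbeta(m, 0.5, 0.5)
    F <- matrix(rbinom(nf * m, 1, rep(p, each = nf)), nrow = nf)
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    for (cv in cvs) {
      j0 <- match(cv$pos, pos)
      k <- round(cv$target_maf * nf)
      if (k < 1 || k >= nf) {
        stop("target MAF ", cv$target_maf, " unreachable with ", nf,
             " founder haplotypes; increase n_founders")
      }
      carriers <- sample.int(nf, k)
      F[, j0] <- 0
      F[carriers, j0] <- 1
      win <- which(abs(pos - cv$pos) <= cfg$qtl_block_halfwidth & pos != cv$pos)
      if (length(win)) {
        # carrier founders share one local haplotype (single founder mutation)
        F[carriers, win] <- matrix(F[carriers[1], win], nrow = k,
                                   ncol = length(win), byrow = TRUE)
        # complete-LD tags nearest the causal site
        tags <- win[order(abs(pos[win] - cv$pos))][seq_len(min(cfg$n_perfect_tags,
                                                               length(win)))]
        F[, tags] <- 0
        F[carriers, tags] <- 1
      }
      bases <- causal_bases(cv$consequence)
      ref[j0] <- bases[1]
      alt[j0] <- bases[2]
      carrier_sets[[causal_id(cv)]] <- carriers
    }
    # founder mosaics with Poisson switch points; each planted QTL block is
    # non-recombining (the whole block copies the founder donating the
    # causal site), giving the single-founder-haplotype structure the
    # IBD-sharing stage presumes
    block_cols <- lapply(cvs, function(cv) {
      which(abs(pos - cv$pos) <= cfg$qtl_block_halfwidth)
    })
    causal_col <- vapply(cvs, function(cv) match(cv$pos, pos), integer(1))
    G <- matrix(0, n, m)
    lin <- (seq_len(m) - 1L) * nf
    for (i in seq_len(2L * n)) {
      k_sw <- rpois(1, cfg$switch_rate * L / 1e6)
      breaks <- sort(runif(k_sw, 1, L))
      fid <- sample.int(nf, k_sw + 1L, replace = TRUE)
      assign <- fid[findInterval(pos, breaks) + 1L]
      for (b in seq_along(block_cols)) {
        assign[block_cols[[b]]] <- assign[causal_col[b]]
      }
      ind <- ((i - 1L) %/% 2L) + 1L
      G[ind, ] <- G[ind, ] + F[assign + lin]
    }
    # orient to minor-allele counts
    f1 <- colMeans(G) / 2
    flip <- f1 > 0.5
    G[, flip] <- 2 - G[, flip, drop = FALSE]
    var_list[[ci]] <- tibble(
      id = paste0("v", ch, "_", format(pos, scientific = FALSE, trim = TRUE)),
      chrom = ch, pos = pos,
      ref = ref, alt = alt,
      minor = ifelse(flip, ref, alt),
      quality = NA_real_)
    codes_list[[ci]] <- G
  }
  variants <- bind_rows(var_list)
  codes <- do.call(cbind, codes_list)
  samples <- sprintf("ind%04d", seq_len(n))
  geno <- geno_matrix(codes, variants, samples)
  causal_tab <- bind_rows(
    tibble(id = character(), chrom = character(), pos = numeric(),
           target_maf = numeric(), realized_maf = numeric(),
           consequence = character()),
    lapply(cfg$causal, function(cv) {
      id <- causal_id(cv)
      tibble(id = id, chrom = cv$chrom, pos = cv$pos,
             target_maf = cv$target_maf,
             realized_maf = geno$variants$maf[match(id, geno$variants$id)],
             consequence = cv$consequence)
    }))
  truth <- structure(list(causal = causal_tab, carriers = carrier_sets,
                          components = NULL, polygenic = NULL),
                     class = "qg_sim_truth")
  list(geno = geno, truth = truth)
}

causal_bases <- function(consequence) {
  switch(consequence,
         stop_gained = c("G", "T"),   # GAA (E) -> TAA (*)
         missense    = c("A", "T"),   # ATT (I) -> TTT (F)
         synonymous  = c("C", "T"),   # CTG (L) -> TTG (L)
         intergenic  = c("A", "G"))
}

scale_to_var <- function(x, v) {
  if (v <= 0) return(rep(0, length(x)))
  s <- stats::var(x)
  if (s == 0) stop("cannot scale a constant vector to positive variance")
  (x - mean(x)) * sqrt(v / s)
}

#' Simulate phenotypes with fixed effects, planted QTL and polygenic background
#'
#' Builds, per configured trait, phenotype = intercept + fixed-effect part +
#' causal-variant part + polygenic part + Gaussian residual. The polygenic
#' part assigns i.i.d. normal effects to all non-causal SNPs and is rescaled
#' so that the realized genetic variance matches `h2 * sd^2` exactly;
#' effect sizes of frac-specified causal variants are derived from the
#' realized dosage variance. Polygenic backgrounds are independent across
#' traits; traits share causal effects only through `pleiotropy`.
#'
#' @param geno Genotypes from [simulate_genotypes()].
#' @param truth The matching `qg_sim_truth`.
#' @param cfg The [sim_config()] used to generate them.
#' @param seed Seed for the phenotype stage (defaults to `cfg$seed + 1`).
#' @return A list with `pheno` (tibble: sample, trait columns, age_days,
#'   age_class, sex, judge, event) and the updated `truth`, whose
#'   `components` element records realized per-trait variance fractions.
#' @export
simulate_phenotypes <- function(geno, truth, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "qg_sim_config"), inherits(truth, "qg_sim_truth"))
  set.seed(seed)
  n <- length(geno$samples)
  fe <- cfg$fixed_effects
  age_years <- runif(n, fe$age_range_years[1], fe$age_range_years[2])
  age_days <- round(age_years * 365.25)
  age_class <- cut(age_years, c(-Inf, 3, 4, 5, Inf),
                   labels = c("<3", "3-4", "4-5", ">5"))
  sex <- sample(c("mare", "stallion"), n, replace = TRUE)
  judge <- sample(sprintf("J%02d", seq_len(fe$n_judges)), n, replace = TRUE)
  event <- sample(c("AUC", "MPT", "SBR", "SPS"), n, replace = TRUE)
  pheno <- tibble(sample = geno$samples, age_days = age_days,
                  age_class = as.character(age_class), sex = sex,
                  judge = judge, event = event)

  causal_ids <- truth$causal$id
  dosages <- geno$codes[, match(causal_ids, geno$variants$id), drop = FALSE]
  # polygenic background: all variants outside every planted QTL block and
  # planted window, so a region's realized contribution is exactly what was
  # planted there
  in_block <- rep(FALSE, nrow(geno$variants))
  for (k in seq_len(nrow(truth$causal))) {
    in_block <- in_block |
      (geno$variants$chrom == truth$causal$chrom[k] &
         abs(geno$variants$pos - truth$causal$pos[k]) <= cfg$qtl_block_halfwidth)
  }
  region_raw <- list()
  for (k in seq_along(cfg$region_effects)) {
    re <- cfg$region_effects[[k]]
    win <- geno$variants$chrom == re$chrom &
      abs(geno$variants$pos - re$center) <= re$halfwidth
    if (!any(win)) stop("planted window on chromosome ", re$chrom,
                        " contains no variants")
    in_block <- in_block | win
    Zw <- sweep(geno$codes[, win, drop = FALSE], 2,
                colMeans(geno$codes[, win, drop = FALSE], na.rm = TRUE))
    Zw[is.na(Zw)] <- 0
    region_raw[[k]] <- as.vector(Zw %*% rnorm(sum(win)))
  }
  bg_idx <- which(!in_block)
  Zc <- sweep(geno$codes[, bg_idx, drop = FALSE], 2,
              colMeans(geno$codes[, bg_idx, drop = FALSE], na.rm = TRUE))
  Zc[is.na(Zc)] <- 0

  primary <- cfg$traits[[1]]$name
  comp_rows <- list()
  beta_rows <- list()
  region_comp_rows <- list()
  latents <- list()
  for (tr in cfg$traits) {
    sd2 <- tr$sd^2
    g_causal <- rep(0, n)
    betas <- numeric(length(cfg$causal))
    for (k in seq_along(cfg$causal)) {
      cv <- cfg$causal[[k]]
      d <- dosages[, k]
      vd <- stats::var(d)
      pl <- cv$pleiotropy
      if (is.null(pl)) pl <- setNames(1, primary)
      base_beta <- if (!is.null(cv$beta)) cv$beta else {
        if (vd <= 0) stop("causal variant ", causal_ids[k],
                          " is monomorphic; cannot derive its effect from frac")
        sqrt(cv$frac * cfg$traits[[1]]$sd^2 / vd)
      }
      b <- base_beta * (pl[tr$name] %||% 0)
      b <- ifelse(is.na(b), 0, b)
      betas[k] <- b
      g_causal <- g_causal + b * d
    }
    # planted windows: shared effect direction, per-trait concordant scaling
    g_region <- rep(0, n)
    region_rows <- list()
    for (k in seq_along(cfg$region_effects)) {
      re <- cfg$region_effects[[k]]
      pl <- re$pleiotropy %||% setNames(1, primary)
      s_t <- pl[tr$name] %||% 0
      s_t <- ifelse(is.na(s_t), 0, s_t)
      if (s_t == 0) next
      base <- scale_to_var(region_raw[[k]],
                           re$frac * cfg$traits[[1]]$sd^2)
      contrib <- s_t * base
      g_region <- g_region + contrib
      region_rows[[k]] <- tibble(trait = tr$name, chrom = re$chrom,
                                 center = re$center,
                                 v_region = stats::var(contrib),
                                 frac_planted = re$frac)
    }
    v_causal <- stats::var(g_causal)
    v_qtl <- stats::var(g_causal + g_region)
    v_poly_target <- tr$h2 * sd2 - v_qtl
    if (v_poly_target < -1e-8) {
      stop("planted QTL variance (", round(v_qtl / sd2, 3),
           " of V_P) exceeds target h2 for trait ", tr$name)
    }
    v_poly_target <- max(v_poly_target, 0)
    g_poly <- if (v_poly_target > 0 && length(bg_idx)) {
      scale_to_var(as.vector(Zc %*% rnorm(length(bg_idx))), v_poly_target)
    } else rep(0, n)
    e <- rnorm(n, 0, sqrt((1 - tr$h2) * sd2))
    # each fixed-effect contribution is centred over the cohort so fixed
    # effects shift individuals, not the population mean
    fixed_part <- rep(0, n)
    add_centred <- function(contrib) fixed_part + contrib - mean(contrib)
    if ("age" %in% tr$fixed) {
      fixed_part <- add_centred(fe$age_slope_sd_per_day * tr$sd * age_days)
    }
    if ("age_class" %in% tr$fixed) {
      eff <- rnorm(nlevels(age_class), 0, 0.5 * tr$sd)
      fixed_part <- add_centred(eff[as.integer(age_class)])
    }
    if ("sex" %in% tr$fixed) {
      eff <- rnorm(2, 0, fe$sex_sd * tr$sd)
      fixed_part <- add_centred(eff[(sex == "stallion") + 1L])
    }
    if ("judge" %in% tr$fixed) {
      lev <- sort(unique(judge))
      eff <- rnorm(length(lev), 0, fe$judge_sd * tr$sd)
      fixed_part <- add_centred(eff[match(judge, lev)])
    }
    if ("event" %in% tr$fixed) {
      lev <- sort(unique(event))
      eff <- rnorm(length(lev), 0, fe$event_sd * tr$sd)
      fixed_part <- add_centred(eff[match(event, lev)])
    }
    latent <- tr$mean + fixed_part + (g_causal - mean(g_causal)) +
      g_region + g_poly + e
    g_tot <- g_causal + g_region + g_poly
    v_p <- stats::var(g_tot + e)
    comp_rows[[tr$name]] <- tibble(
      trait = tr$name,
      v_causal = v_causal, v_region = stats::var(g_region),
      v_poly = stats::var(g_poly),
      v_genetic = stats::var(g_tot), v_resid = stats::var(e), v_p = v_p,
      h2_realized = stats::var(g_tot) / v_p)
    region_comp_rows[[tr$name]] <- bind_rows(region_rows)
    beta_rows[[tr$name]] <- tibble(trait = tr$name, id = causal_ids,
                                   beta = betas)
    latents[[tr$name]] <- list(latent = latent, genetic = g_tot)
    if (tr$ordinal == "none") {
      pheno[[tr$name]] <- latent
    } else {
      thr <- tr$thresholds %||% default_thresholds(tr)
      pheno[[tr$name]] <- simulate_linear_scores(latent, thr,
                                                 defect = tr$ordinal == "defect")
    }
  }
  truth$components <- bind_rows(comp_rows)
  truth$betas <- bind_rows(beta_rows)
  truth$region_components <- bind_rows(region_comp_rows)
  truth$polygenic <- lapply(latents, `[[`, "genetic")
  cols <- c("sample", vapply(cfg$traits, `[[`, character(1), "name"),
            "age_days", "age_class", "sex", "judge", "event")
  list(pheno = pheno[, cols], truth = truth)
}

default_thresholds <- function(tr) {
  if (tr$ordinal == "defect") tr$mean + tr$sd * c(0.5, 1.5, 2.5)
  else tr$mean + tr$sd * c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
}

#' Map a latent Gaussian variable to ordinal linear-profiling scores
#'
#' Signed traits use 6 strictly increasing cut points mapping to -3..+3;
#' defect traits use 3 cut points mapping to 0..+3.
#'
#' @param latent Numeric vector.
#' @param thresholds Strictly increasing cut points (6, or 3 with
#'   `defect = TRUE`).
#' @param defect Use the 0..+3 defect-trait scale.
#' @return Integer scores.
#' @export
simulate_linear_scores <- function(latent, thresholds, defect = FALSE) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  n_expected <- if (defect) 3L else 6L
  if (length(thresholds) != n_expected) {
    stop("expected ", n_expected, " thresholds, got ", length(thresholds))
  }
  s <- findInterval(latent, thresholds)
  as.integer(if (defect) s else s - 3L)
}

#' Simulate a full cohort (genotypes, phenotypes, truth) in one call
#'
#' @param cfg A [sim_config()].
#' @return List with `geno`, `pheno`, `truth`.
#' @export
simulate_cohort <- function(cfg) {
  g <- simulate_genotypes(cfg)
  p <- simulate_phenotypes(g$geno, g$truth, cfg)
  list(geno = g$geno, pheno = p$pheno, truth = p$truth)
}
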