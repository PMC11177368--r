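---
title: "Models and methods in qtlfine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in qtlfine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qtlfine)
```

qtlfine implements a complete SNP-based quantitative-genetics workflow for
continuous and ordinal conformation-type traits: genomic relationship
matrices (GRMs) over flexible variant partitions, restricted maximum
likelihood (REML) estimation of one or many genomic variance components,
mixed-linear-model association with leave-one-chromosome-out (LOCO)
polygenic control, BLUP prediction of chromosome- or region-specific
breeding values, runs-of-homozygosity (ROH) detection, minimal variant
consequence annotation, and a two-pronged (LD plus IBD-sharing) procedure
for short-listing candidate causal variants under a major QTL. A
founder-mosaic simulator provides ground-truth cohorts for all of it.

This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and the known limitations.

## The mixed model

Everything rests on the standard additive genomic model
$$
\mathbf{y} = \mathbf{X}\boldsymbol\beta + \sum_c \mathbf{g}_c +
\mathbf{e}, \qquad
\mathbf{g}_c \sim N(\mathbf{0},\, \sigma^2_{g_c}\mathbf{A}_c), \quad
\mathbf{e} \sim N(\mathbf{0},\, \sigma^2_e\mathbf{I}),
$$
with one genomic relationship matrix $\mathbf{A}_c$ per variance
component. The fixed part $\mathbf{X}\boldsymbol\beta$ carries an
intercept plus whatever `qg_model()` declares: a quantitative age
covariate for the measured-height style of trait, and age class, sex,
judge, and event factors for subjectively scored conformation traits.
Ordinal linear-profiling scores (integers $-3..+3$, or $0..+3$ for defect
traits) are analysed as linear responses, exactly as the common practice
for such scores.

### GRM construction

`compute_grm()` uses the per-SNP-standardised (VanRaden method 1 / GCTA
style) estimator
$$
A_{jk} = \frac{1}{m}\sum_{i=1}^{m}
\frac{(x_{ij}-2f_i)(x_{ik}-2f_i)}{2f_i(1-f_i)},
$$
where $x_{ij}$ counts minor alleles and $f_i$ is the sample frequency of
the counted allele. The same cross-product expression is used on the
diagonal; the slightly different diagonal estimator some tools apply is an
$O(1/m)$ refinement that does not affect any recovery property tested
here, and using one formula keeps the partition-consistency identity exact
(a union GRM is the variant-count-weighted average of subset GRMs).
Allele frequencies always come from the analysis sample itself. Missing
genotypes are mean-imputed to $2f_i$ before centring.

`build_partitioned_grms()` produces the three partitions the workflow
needs: per-chromosome, LOCO (all variants *not* on a chromosome), and
QTL-window components. A window component is declared by `region_spec()`
as a window (default half-width 3 Mb, i.e. a 6-Mb window, or 1 Mb for the
smaller secondary QTL) inside a wider exclusion interval (default
half-widths 7 Mb and 2 Mb). The rest-of-chromosome GRM excludes the whole
exclusion interval so that flanking LD cannot leak window variance into
the chromosomal background; `combine_rest = TRUE` instead builds a single
rest-of-genome component excluding all buffers, the design used for
region-local genetic correlations. All coordinates are 1-based with
inclusive endpoints, and all arithmetic is in bp.

### AI-REML

`fit_greml()` maximises the restricted likelihood by average-information
(AI) iterations with one expectation-maximisation step first — the robust
default strategy of the widely used GREML tools. Numerical specifics:

* convergence when the restricted log-likelihood changes by less than
  `1e-4` (`tol`), at most 100 iterations;
* variances constrained to a floor of $10^{-6} \times V_P$, so fractions
  are interpretable as proportions (the unconstrained-REML alternative is
  deliberately not offered);
* traces use $\mathrm{tr}(\mathbf{PA}) = \sum_{ij} P_{ij}A_{ij}$ for
  symmetric $\mathbf{A}$, so one Cholesky factorisation of
  $\mathbf{V}$ per iteration is the only $O(n^3)$ operation;
* a proposed step is halved (up to five times) if it would decrease the
  restricted likelihood; if no admissible improving step exists the
  current point is reported as the constrained optimum;
* standard errors come from the inverse AI matrix, and standard errors of
  variance *fractions* (heritability, per-window shares) by the delta
  method.

The likelihood-ratio test for genetic variance (`lrt_genetic_variance()`)
uses the boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ when one
component is dropped (so $p = 0.5$ at LRT $= 0$) and a plain $\chi^2_k$
for $k>1$; traits with $p > 0.05$ are flagged as carrying no usable
genetic variance.

### Bivariate REML and local genetic correlations

`fit_bivariate()` stacks two traits and gives every component (each GRM
and the residual) a $2\times2$ covariance matrix, parameterised by the
covariance. The same AI machinery applies; the first AI step is damped
(factor $\approx 0.32$) instead of running a literal bivariate EM
recursion, and during iteration the covariance is clamped so each
component matrix stays positive definite ($|c_{12}| \le 0.99\sqrt{v_1
v_2}$); the reported $r_G$ is clamped to $[-1, 1]$ afterwards. A perfect
self-correlation therefore reports $r_G \approx 0.99$ rather than exactly
1 — the cost of keeping the stacked covariance factorisable. $r_G$ is
flagged undefined when either trait's component variance falls below
$10^{-8}$ of its phenotypic variance; its standard error uses the delta
method on the inverse AI matrix. Fitting is complete-case: only
individuals observed for both traits enter.

The *local* genetic correlation design pairs a QTL-window GRM with a
buffer-excluded rest-of-genome GRM, which is how a shared causal variant
inside the window can show $r_G$ near 1 even when genome-wide correlation
is weak or opposite in sign.

### BLUP

`predict_gebv()` returns, per individual and component,
$\hat{\mathbf{u}}_c = \sigma^2_{g_c}\mathbf{A}_c\mathbf{P}\mathbf{y}$,
which equals the Henderson mixed-model-equation solution (the test suite
checks this against an explicit MME solve at $10^{-8}$). Chromosomal
breeding values — e.g. the QTL-chromosome component from a two-GRM fit —
are what rank individuals for the IBD-sharing fine-mapping stage;
ranking by a chromosomal gEBV rather than phenotype isolates the locus
of interest from the rest of the genetic background.

## LOCO association scans

`run_mlm_loco()` uses the two-stage approximation of the standard
MLMA-LOCO tools: per chromosome, the null variance components are
estimated once by REML with the LOCO GRM, then every SNP on that
chromosome is tested by a generalised-least-squares Wald test at the
fitted covariance,
$\hat\beta_j = \mathbf{g}_j'\mathbf{P}\mathbf{y} /
\mathbf{g}_j'\mathbf{P}\mathbf{g}_j$, with variance
$(\mathbf{g}_j'\mathbf{P}\mathbf{g}_j)^{-1}$ and betas reported per minor
allele. Exact per-SNP REML would be prohibitively slow and is not what
the cited tools do either. Missing dosages are mean-imputed for the scan
(per-variant case dropping would force a per-variant $O(n^3)$ solve; the
divergence matters only when missingness is informative, which the
simulator does not model). Monomorphic variants are skipped.

The significance threshold is a Bonferroni correction recomputed from the
number of tests actually performed (`bonferroni_threshold()`), and the
genomic inflation factor $\lambda$ is the median Wald $\chi^2$ over
0.4549. Under the $h^2 = 0$ null the scan is calibrated
($\lambda \in [0.9, 1.1]$ in the test suite); under a polygenic trait
$\lambda$ exceeds 1 because every background SNP carries true signal —
that is enrichment, not confounding.

Conditional scans (`conditional_gwas()`) add either a named SNP's
minor-allele dosage or another trait's value as a fixed covariate; the
conditioning SNP itself is skipped. Conditioning on the causal variant of
a single planted QTL removes the whole peak; conditioning a pleiotropic
secondary trait on the primary trait reduces or removes it.
`summarize_regions()` clusters genome-wide significant variants into
regions split at gaps above 1 Mb (the clustering gap is not derivable
from published tables; 1 Mb is this package's default), reporting the
top SNP with ties broken by lowest position — the convention that makes
the left-most of a set of perfectly tied SNPs the conditioning anchor.

## ROH detection and shared segments

`detect_roh()` implements the published scanning-window --homozyg
algorithm: windows of 50 SNPs tolerate at most 3 heterozygous and 5
missing calls; a SNP is ROH-eligible when more than 5% of its overlapping
windows are homozygous; maximal eligible runs are split at inter-SNP gaps
above 1000 kb and filtered to at least 50 SNPs, at least 100 kb, and at
least one SNP per 50 kb. The hit-proportion threshold (0.05) and the
choice to report endpoints at the outermost eligible SNPs (not extended
into flanking gaps) are that tool's documented behaviour, adopted here
because the source analyses ran exactly that tool; both are exposed in
`roh_params()`. The generous 3-heterozygote allowance mirrors its use as
an imputation-error guard.

`shared_roh()` intersects segments across individuals into maximal
intervals of constant carrier sets, with per-group carrier counts. A
carrier's allele class over an interval is its genotype vector there;
classes are compared only at mutually non-missing sites, so missing calls
never break equality. Opposite-homozygote groups are thereby reported as
carrying different alleles — the signature separating a "tall" founder
haplotype from "short" ones.

## Annotation

`annotate_variants()` is a minimal consequence predictor over a toy gene
model (GFF3 gene/mRNA/exon/CDS subset plus a FASTA reference slice). CDS
variants are classified by translating both codons under the standard
genetic code (reverse-complemented on minus strands; stop codons rendered
`*`, so a nonsense change reads `E/*`); exonic-but-non-CDS positions fold
into `intron_variant` (toy models use CDS = exon); positions within
100 kb of a transcript get strand-aware `upstream_`/`downstream_`
records; everything else falls back to `intergenic_variant`, so every
variant receives at least one record. Impact classes follow the fixed
map stop_gained→HIGH, missense→MODERATE, synonymous→LOW, rest→MODIFIER;
`impact_filter()` takes the maximum over transcripts. Indels, splice
logic, UTR terms and regulatory features are out of scope — the
fine-mapping stage only consumes the terms above.

## Two-pronged fine-mapping

The candidate-variant procedure mirrors a sequence-level fine-mapping
study design:

1. **LD prong** (`ld_candidate_set()`): genome-wide significant variants
   with dosage $r^2 > 0.8$ to any top SNP, intersected with the
   HIGH/MODERATE-impact annotation shortlist. $r^2$ is the squared
   Pearson correlation of minor-allele counts over mutually non-missing
   individuals (genotype, not haplotype, $r^2$ — the common tool
   default; the two can differ for rare unphased pairs).
2. **IBD prong** (`ibd_candidate_set()`): rank individuals by the
   QTL-chromosome gEBV, take the top and bottom 10, detect ROH over the
   significant-span window (±100 kb), intersect the top group's segments
   strictly (every individual must share; a relaxed fraction is exposed
   but defaults to 1), and keep significant HIGH/MODERATE variants inside
   the shared intervals. The approach presumes the shared segments are
   identical by descent, a single founder mutation, and founder-haplotype
   enrichment among one gEBV extreme — assumptions the founder-mosaic
   simulator makes true by construction, and which must be argued, not
   assumed, on real data.
3. **Combination** (`combine_candidates()`): the intersection of both
   shortlists, ranked by ascending p-value with ties broken by position,
   with pairwise $r^2$ among finalists and full provenance of both source
   sets.

## The synthetic cohort generator

`simulate_cohort()` builds each individual's two haplotypes as mosaics of
a small founder pool (default 20 founder haplotypes per chromosome,
Poisson founder switches at 1 per Mb), with founder allele frequencies
from a U-shaped Beta(0.5, 0.5). This produces block-structured LD without
a coalescent simulation, and — decisive for the IBD stage — real shared
founder segments. Defaults emulate a warmblood-horse conformation cohort
at desk scale:

| quantity | default | rationale |
|---|---|---|
| individuals | 2000 | the calibration scale of all recovery checks |
| chromosomes | 3 × 120 Mb, 1600/1600/1800 backbone SNPs | array-like density; ~5000 SNPs total |
| causal variant | nonsense SNV, chr 3 at 107,373,887 bp, MAF 0.45 | the major-QTL archetype |
| causal effect | 17.1% of $V_P$ (or an explicit per-allele beta) | the ECA3-like window share |
| trait | mean 167.6, SD 3.6, $h^2 = 0.528$ | a height-like measured trait |
| fixed effects | age slope $5\times10^{-4}$ SD/day; sex/judge(39)/event(4) level SDs of 0.5 trait SD | makes fixed-effect correction non-trivial |
| QTL block | carriers homogeneous over ±600 kb; 8 complete-LD tags; +400 dense variants within ±1 Mb | a taggable haplotype block at sequence-like local density |

Design notes, in the order they matter:

* **Dense QTL grid.** The genome backbone is array-density (about one
  SNP per 67 kb), at which the 50-SNP/50-kb-per-SNP ROH rules are
  unattainable by construction. Planted QTL regions therefore carry an
  extra dense grid (default 400 variants within ±1 Mb, one per ~5 kb),
  emulating the sequence-level density of an imputed fine-mapping region.
* **Carrier homogeneity, a non-recombining block, and tags.** All founder
  haplotypes carrying the causal minor allele share one local haplotype
  over the block (single-founder-mutation structure), and the block is
  non-recombining: each simulated haplotype copies the founder that
  donates the causal site across the whole ±600 kb. Without this, founder
  switching at 1/Mb fragments the homozygous runs and the strict
  "shared by all top-k" ROH rule fails sporadically — the IBD argument
  presumes an intact founder haplotype, so the generator makes that
  presumption true rather than approximately true. The nearest 8 variants
  are additionally forced into complete LD with the causal site so the
  block is taggable whatever the random founder frequencies do.
* **Exact variance bookkeeping.** Fixed-effect contributions are centred
  (they move individuals, not the population mean); the polygenic part
  assigns i.i.d. normal effects to all variants *outside* planted blocks
  and windows and is rescaled so the realized genetic variance matches
  $h^2 \sigma^2$ exactly; frac-specified causal effects are derived from
  the realized dosage variance. Planted shares are therefore true by
  construction, and recovery error measures the estimator, not the
  generator.
* **Two planting modes.** `causal_variant()` concentrates a window's
  share in one large-effect SNV (what GWAS, BLUP-ranking, ROH and
  fine-mapping need); `region_effect()` spreads it as i.i.d. effects over
  all window variants (the architecture a window/rest GRM partition
  assumes, used for the variance-partition calibrations). A single
  huge-effect SNV pushed through a GRM with equal per-SNP weights is
  deliberately misspecified — single-GRM heritability then overestimates
  and a window GRM underestimates, which is a property of the estimator
  worth knowing, not a bug in either.
* **Pleiotropy.** Causal specs carry a named trait→scaling map; shared
  window effects are fully concordant across traits, polygenic
  backgrounds are independent. The default secondary-trait scaling (0.3
  of the primary per-allele effect for a unit-SD ordinal-style trait)
  keeps the implied causal share inside the secondary trait's
  heritability budget.
* **Ordinal scores.** A latent Gaussian is cut at 6 symmetric thresholds
  (±0.5, ±1.5, ±2.5 SD around the mean) into $-3..+3$, or at 3 thresholds
  into $0..+3$ for defect traits.
* **Ages** are uniform on 2–10 years (in days); age class is derived from
  age. **Seeds**: every output is a pure function of the configuration
  including its seed; the phenotype stage uses `seed + 1` so phenotype
  replicates can be drawn on fixed genotypes.

What the generator does *not* emulate: realistic demography or LD decay
calibrated to any particular cohort (the founder switch rate is a free
knob, documented as such), genotyping or imputation error, X chromosomes,
missing genotype calls, and selection. Passing recovery tests on these
cohorts shows the estimators are correct under their assumed model at
study scale — not that any particular field data set satisfies those
assumptions.

## Problem sizes and replicate counts

The calibration checks run 10 replicates at n = 2000 with ~5000 backbone
SNPs for heritability, window-partition and effect-size recovery; 10
replicates for the bivariate local correlation; and 20 replicates for the
end-to-end candidate-recovery rate. These are the package's chosen
study-scale conditions: large enough that REML and GWAS sampling error is
small against the tolerances, small enough to run on a laptop.

## Known limitations

* Variance components are floored, so a truly zero component reports the
  floor, and its SE from the AI matrix is not meaningful at the boundary.
* The bivariate clamp caps $|r_G|$ at ~0.99 during iteration; boundary
  correlations are reported after a final clamp to $[-1, 1]$.
* Window-component genetic correlations are attenuated when most window
  variants are uncorrelated with the causal signal: each trait's window
  variance estimate then carries misspecification noise that is
  independent between traits, pulling $\hat r_G$ below a true value of 1
  (on the default synthetic cohort, whose causal-aligned LD spans only the
  ±600 kb block of a 6-Mb window, single-replicate estimates range
  roughly 0.6–1.0 around a true correlation of 1). Real sequence-level
  fine-mapping windows, drawn to match the observed LD extent, are far
  less affected. Multi-start checks confirm these are properties of the
  REML optimum itself, not of the optimizer.
* The GWAS two-stage approximation reuses null variance components for
  every SNP of a chromosome; for variants of very large effect the Wald
  beta is mildly conservative relative to exact per-SNP REML.
* The annotator handles SNVs on toy gene models only.
* PLINK text round-trips cannot preserve which of two equally frequent
  alleles was "minor" (the orientation rule is deterministic but format
  information is lost at exact 0.5), and monomorphic variants re-read
  from .ped files get a placeholder second allele.
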