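# Example qtlfine pipeline configuration: simulate a desk-scale cohort
# with a planted nonsense QTL and run the full analysis chain.
#   Rscript inst/cli/qtlfine.R --config inst/extdata/pipeline-example.yaml --out out/
seed: 1
trait: height
covariates: age_days
qtl:
  chrom: "3"
  center: 107373887
  window_halfwidth: 3.0e6
  exclusion_halfwidth: 7.0e6
thresholds:
  min_maf: 0.01
  alpha: 0.05
  r2: 0.8
  updown: 100000
  k_extremes: 10
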