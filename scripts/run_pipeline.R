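#!/usr/bin/env Rscript
# Thin command-line wrapper around leatsubtype::run_pipeline().
#
# Simulated cohort:   Rscript scripts/run_pipeline.R --seed 1 --outdir out/
# File-based cohort:  Rscript scripts/run_pipeline.R --expr expr.tsv \
#                       --clinical clinical.tsv [--gmt sets.gmt] --outdir out/

suppressMessages({
  library(optparse)
  library(leatsubtype)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--expr", type = "character", default = NULL,
              help = "expression TSV (gene_id + one column per sample)"),
  make_option("--clinical", type = "character", default = NULL,
              help = "clinical TSV with a 'batch' column"),
  make_option("--gmt", type = "character", default = NULL,
              help = "gene sets in GMT format"),
  make_option("--top-n", type = "integer", default = 1000, dest = "top_n"),
  make_option("--k-min", type = "integer", default = 2, dest = "k_min"),
  make_option("--k-max", type = "integer", default = 10, dest = "k_max"),
  make_option("--metric", type = "character", default = "pearson"),
  make_option("--folds", type = "integer", default = 5),
  make_option("--nperm", type = "integer", default = 1000),
  make_option("--consensus-reps", type = "integer", default = 100,
              dest = "consensus_reps"),
  make_option("--seed", type = "integer", default = 1),
  make_option("--outdir", type = "character", default = "leat_out")
)))

cfg <- pipeline_config(
  simulation = if (is.null(opts$expr)) cohort_config(seed = opts$seed),
  expression_path = opts$expr, clinical_path = opts$clinical,
  gmt_path = opts$gmt, top_n = opts$top_n, k_min = opts$k_min,
  k_max = opts$k_max, metric = opts$metric, n_folds = opts$folds,
  gsea_n_perm = opts$nperm, consensus_reps = opts$consensus_reps,
  seed = opts$seed, outdir = opts$outdir)

report <- run_pipeline(cfg)
print(report)
cat("stage outputs written to", opts$outdir, "\n")
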