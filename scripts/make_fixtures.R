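#!/usr/bin/env Rscript
# Regenerates the packaged example data under inst/extdata/. The files are
# synthetic: a small two-sample summary-statistic set drawn from the
# package's own data-generating model (25 correlated variants, 3 traits,
# true effects +0.4 / 0 / -0.6), written in the package's TSV dialects.
library(mvmrpca)

set.seed(20260911)
cfg <- sim_config(n_exposure_sample = 4000, n_outcome_sample = 4000,
                  J = 25, K = 3, causal_variants_per_trait = 5,
                  alpha_mean = 0.15)
dat <- simulate_individual_data(cfg)
ss <- summarize_two_sample(dat)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_summary_data(ss$summary, "inst/extdata/synthetic_summary.tsv")
write_ld_matrix(ss$ld, "inst/extdata/synthetic_ld.tsv")
cat("fixtures written to inst/extdata/\n")
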