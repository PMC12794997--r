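#!/usr/bin/env Rscript

## Step 1 — simulate the study corpus.
##
## Generates a FAERS-like quarterly extract spanning 2004Q1-2024Q3 with
## 60,000 cases, 20 background drugs and three planted depression signals
## whose onset-time laws follow the early-failure Weibull profiles reported
## for varenicline-, isotretinoin- and adalimumab-like exposures. The
## planted reporting odds ratios are analytically exact, so every later
## step can be checked against results/simdata/planted_truth.tsv.

suppressPackageStartupMessages(library(faersdpa))

outdir <- "results/simdata"

config <- sim_config(
  n_cases = 60000,
  background_drugs = data.frame(name = sprintf("DRUG%02d", 1:20),
                                prob = rep(0.05, 20)),
  signal_drugs = data.frame(
    name  = c("VARENICLINE", "ISOTRETINOIN", "ADALIMUMAB"),
    ror   = c(10, 6, 4),
    alpha = c(80.97, 296.23, 334.57),
    beta  = c(0.68, 0.53, 0.65)),
  signal_prob = 0.02,
  target_event_rate = 0.0143,
  duplicate_rate = 0.10,
  date_range = c("2004Q1", "2024Q3"),
  seed = 20240101
)

summary <- generate_dataset(config, outdir)
print(summary)
cat(sprintf("planted truth:\n"))
print(planted_truth(config))
cat(sprintf("wrote %d quarters under %s\n", nrow(summary), outdir))
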