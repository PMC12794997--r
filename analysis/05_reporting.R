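#!/usr/bin/env Rscript

## Step 5 — descriptive outputs.
##
## Cohort characteristics of the target-event population, the annual
## reporting trend with a cubic polynomial fit, top-drug rankings by count
## and by signal strength, and a cross-database overlap against a second,
## independently simulated reporting corpus.

suppressPackageStartupMessages({library(faersdpa); library(data.table)})

clean <- readRDS("results/clean.rds")
target <- filter_target_event(clean, "Depression")
cat(sprintf("target-event cohort: %d reports\n", n_reports(target)))

cohort <- summarize_cohort(target)
export_cohort_summary(cohort, "results/cohort_summary.csv")
print(cohort$by_sex)

trend <- annual_trend(target)
fit <- fit_trend(trend, degree = 3)
fwrite(data.table(year = trend$year, count = trend$count,
                  fitted = fit$fitted), "results/annual_trend.csv")
jsonlite::write_json(list(degree = fit$degree, r_squared = fit$r_squared,
                          coefficients = fit$coefficients),
                     "results/trend_fit.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("cubic trend R^2 = %.4f\n", fit$r_squared))

signals <- fread("results/signal_table.csv")
fwrite(top_drugs(signals, 20, "by_count"), "results/top20_by_count.csv")
fwrite(top_drugs(signals, 20, "by_signal"), "results/top20_by_signal.csv")
print(top_drugs(signals, 5, "by_signal"))

## second database: an independent corpus with partially overlapping drugs
cfg_b <- sim_config(
  n_cases = 30000,
  background_drugs = data.frame(name = c(sprintf("DRUG%02d", 11:30),
                                         "QUETIAPINE", "BUPROPION"),
                                prob = rep(1 / 22, 22)),
  signal_drugs = data.frame(name = c("VARENICLINE", "ISOTRETINOIN"),
                            ror = c(8, 5), alpha = c(80, 300),
                            beta = c(0.7, 0.55)),
  signal_prob = 0.02, date_range = c("2010Q1", "2024Q3"), seed = 77001)
corpus_b <- normalize_names(deduplicate(simulate_reports(cfg_b)),
                            synthetic_synonyms(cfg_b))
sig_b <- signal_table(corpus_b, "Depression")

drugs_a <- signals[a > 0, drug]
drugs_b <- sig_b[a > 0, drug]
ov <- database_overlap(drugs_a, drugs_b,
                       setNames(signals$a, signals$drug),
                       setNames(sig_b$a, sig_b$drug), k = 20)
jsonlite::write_json(list(n_a = ov$n_a, n_b = ov$n_b,
                          n_overlap = ov$n_overlap),
                     "results/database_overlap.json", auto_unbox = TRUE)
fwrite(ov$shared, "results/database_overlap_top.csv")
cat(sprintf("database overlap: %d vs %d drugs, %d shared\n",
            ov$n_a, ov$n_b, ov$n_overlap))
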