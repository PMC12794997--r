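#!/usr/bin/env Rscript

## Step 2 — ingest the quarterly extract and clean it.
##
## Reads every quarter written by step 1, records the ingest warning tally,
## deduplicates to one report per case (latest version wins) and normalizes
## drug names against the generator's synonym table. The cleaned collection
## is cached under results/ for the later steps.

suppressPackageStartupMessages(library(faersdpa))

simdir <- "results/simdata"
config <- read_sim_config(file.path(simdir, "sim_config.yaml"))
quarters <- sub("^DEMO(.*)\\.txt$", "\\1",
                list.files(simdir, pattern = "^DEMO.*\\.txt$"))
quarters <- paste0("20", quarters)   # file suffix yyQq -> yyyyQq

raw <- read_quarters(simdir, sort(quarters))
write_ingest_tally(raw, "results/ingest_tally.json")
cat(sprintf("ingested %d report versions across %d quarters\n",
            n_reports(raw), length(quarters)))

clean <- deduplicate(raw)
cat(sprintf("deduplicated to %d cases (%d versions removed)\n",
            n_reports(clean), n_reports(raw) - n_reports(clean)))

syn <- read_synonym_table(file.path(simdir, "synonyms.tsv"))
clean <- normalize_names(clean, syn)
unmapped <- attr(clean, "unmapped")
cat(sprintf("normalized drug names; %d distinct unmapped raw names\n",
            nrow(unmapped)))

saveRDS(clean, "results/clean.rds")
cat("cached cleaned collection at results/clean.rds\n")
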