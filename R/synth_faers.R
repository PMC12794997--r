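## Synthetic spontaneous-report generator with planted structure.
##
## The generator emulates the features of FAERS quarterly extracts that the
## downstream pipeline must survive: multiple report versions per case,
## raw drug-name variants, MedDRA-style preferred-term strings, demographic
## missingness, therapy start/event dates with Weibull-distributed onset
## intervals, and per-drug planted reporting-rate elevations whose true
## reporting odds ratio is analytically known.

noise_pts <- c("Nausea", "Headache", "Dizziness", "Rash", "Fatigue",
               "Insomnia", "Vomiting", "Pruritus", "Anxiety", "Pyrexia")
indication_pool <- c("Multiple sclerosis", "Depression",
                     "Rheumatoid arthritis", "Smoking cessation therapy",
                     "Contraception", "Hypertension", "Pain", "Psoriasis")

#' Default demographic mixture
#'
#' Category proportions for the four demographic axes, each including a
#' missing category. The sex, age-band, weight-band and country proportions
#' default to the composition observed in the drug-induced-depression
#' reporting population (fractions of all reports, missing included).
#'
#' @return a named list of named probability vectors summing to 1 per axis.
#' @export
default_demographic_mix <- function() {
  list(
    sex = c(F = 0.612, M = 0.322, missing = 0.066),
    age_band = c("<18" = 0.0359, "18-65" = 0.4777, "65-85" = 0.1155,
                 ">85" = 0.0110, missing = 0.3599),
    weight_band = c("<50" = 0.0099, "50-69" = 0.0632, "70-89" = 0.1569,
                    ">=90" = 0.1191, missing = 0.6509),
    country = c(US = 0.6709, GB = 0.0633, CA = 0.0498, FR = 0.0275,
                BR = 0.0159, other = 0.1226, missing = 0.05)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic report
#' generator. Defaults reflect the reporting conditions the pipeline is
#' designed for: a background target-event reporting rate of 1.43% (the
#' share of depression reports in the full reporting corpus), report
#' versions duplicated at 10%, and quarterly extracts spanning 2004Q1
#' through 2024Q3.
#'
#' @param n_cases number of distinct cases (>= 1).
#' @param background_drugs data.frame with columns `name`, `prob`: candidate
#'   primary-suspect drugs and their relative reporting weights (normalized
#'   internally).
#' @param signal_drugs data.frame with columns `name`, `ror`, `alpha`,
#'   `beta`: drugs planted with a target reporting odds ratio versus the
#'   background event odds, and a Weibull(`alpha` days, `beta`) onset-time
#'   law for their target-event cases. May have zero rows.
#' @param target_event_rate probability in (0,1) that a background report
#'   lists the target event.
#' @param duplicate_rate probability in \[0,1) that a case emits an extra,
#'   strictly earlier-dated report version.
#' @param demographic_mix list as returned by [default_demographic_mix()];
#'   per-axis proportions must sum to 1 (tolerance 1e-9) and include a
#'   `missing` category.
#' @param date_range length-2 character vector of year-quarter labels,
#'   start and end inclusive.
#' @param seed integer RNG seed; identical configurations produce
#'   byte-identical output files.
#' @param signal_prob per-signal-drug probability weight of being a case's
#'   primary suspect (the signal-drug analogue of `background_drugs$prob`).
#' @param name_variant_rate probability that a drug mention carries a raw
#'   name variant (case change or brand alias) instead of the canonical
#'   name.
#' @param target_pt preferred-term string used for the target event.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cases,
                       background_drugs = data.frame(
                         name = sprintf("DRUG%02d", 1:20),
                         prob = rep(0.05, 20)),
                       signal_drugs = data.frame(
                         name = character(), ror = numeric(),
                         alpha = numeric(), beta = numeric()),
                       target_event_rate = 0.0143,
                       duplicate_rate = 0.10,
                       demographic_mix = default_demographic_mix(),
                       date_range = c("2004Q1", "2024Q3"),
                       seed = 1L,
                       signal_prob = 0.005,
                       name_variant_rate = 0.30,
                       target_pt = "Depression") {
  fail <- function(field, msg) {
    stop("invalid sim_config: field '", field, "' ", msg, call. = FALSE)
  }
  if (!is.numeric(n_cases) || length(n_cases) != 1L || is.na(n_cases) ||
      n_cases < 1 || n_cases != floor(n_cases)) {
    fail("n_cases", "must be a positive integer")
  }
  background_drugs <- as.data.table(background_drugs)
  if (!all(c("name", "prob") %in% names(background_drugs)) ||
      nrow(background_drugs) == 0L) {
    fail("background_drugs", "needs columns 'name' and 'prob' and >= 1 row")
  }
  if (any(background_drugs$prob < 0) || sum(background_drugs$prob) <= 0) {
    fail("background_drugs", "probabilities must be >= 0 with positive sum")
  }
  signal_drugs <- as.data.table(signal_drugs)
  if (!all(c("name", "ror", "alpha", "beta") %in% names(signal_drugs))) {
    fail("signal_drugs", "needs columns name, ror, alpha, beta")
  }
  if (nrow(signal_drugs)) {
    if (any(signal_drugs$ror <= 0)) fail("signal_drugs", "ror must be > 0")
    if (any(signal_drugs$alpha <= 0)) fail("signal_drugs", "alpha must be > 0")
    if (any(signal_drugs$beta <= 0)) fail("signal_drugs", "beta must be > 0")
    if (anyDuplicated(signal_drugs$name)) {
      fail("signal_drugs", "names must be unique")
    }
  }
  if (!is.numeric(target_event_rate) || target_event_rate <= 0 ||
      target_event_rate >= 1) {
    fail("target_event_rate", "must lie in (0,1)")
  }
  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 ||
      duplicate_rate >= 1) {
    fail("duplicate_rate", "must lie in [0,1)")
  }
  if (!is.numeric(signal_prob) || signal_prob <= 0 || signal_prob >= 1) {
    fail("signal_prob", "must lie in (0,1)")
  }
  if (!is.numeric(name_variant_rate) || name_variant_rate < 0 ||
      name_variant_rate > 1) {
    fail("name_variant_rate", "must lie in [0,1]")
  }
  if (!is.list(demographic_mix) ||
      !all(c("sex", "age_band", "weight_band", "country") %in%
           names(demographic_mix))) {
    fail("demographic_mix", "must list sex, age_band, weight_band, country")
  }
  for (axis in names(demographic_mix)) {
    p <- demographic_mix[[axis]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      fail("demographic_mix", paste0("axis '", axis,
                                     "' must sum to 1 with entries >= 0"))
    }
    if (!"missing" %in% names(p)) {
      fail("demographic_mix", paste0("axis '", axis,
                                     "' needs a 'missing' category"))
    }
  }
  if (length(date_range) != 2L) fail("date_range", "must have length 2")
  quarter_seq(date_range[1], date_range[2])  # validates labels and order
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    fail("seed", "must be a single integer")
  }
  if (!is.character(target_pt) || !nzchar(target_pt)) {
    fail("target_pt", "must be a nonempty string")
  }
  structure(list(
    n_cases = as.integer(n_cases),
    background_drugs = background_drugs,
    signal_drugs = signal_drugs,
    target_event_rate = target_event_rate,
    duplicate_rate = duplicate_rate,
    demographic_mix = demographic_mix,
    date_range = as.character(date_range),
    seed = as.integer(seed),
    signal_prob = signal_prob,
    name_variant_rate = name_variant_rate,
    target_pt = target_pt
  ), class = "sim_config")
}

#' Planted ground truth of a configuration
#'
#' Deterministic readback of the per-drug planted parameters, for recovery
#' tests: the target reporting odds ratio and the Weibull onset-time
#' parameters of each signal drug, in input order.
#'
#' @param config a [sim_config()] object.
#' @return data.table with columns `drug`, `ror`, `alpha`, `beta`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sd <- config$signal_drugs
  data.table(drug = as.character(sd$name), ror = as.numeric(sd$ror),
             alpha = as.numeric(sd$alpha), beta = as.numeric(sd$beta))
}

## sample one category per row from a named probability vector
sample_axis <- function(p, n) {
  sample(names(p), n, replace = TRUE, prob = p)
}

age_from_band <- function(band) {
  n <- length(band)
  lo <- c("<18" = 1, "18-65" = 18, "65-85" = 65, ">85" = 86)[band]
  hi <- c("<18" = 17, "18-65" = 64, "65-85" = 84, ">85" = 100)[band]
  out <- rep(NA_real_, n)
  ok <- !is.na(lo)
  out[ok] <- floor(runif(sum(ok), lo[ok], hi[ok] + 1))
  out
}

weight_from_band <- function(band) {
  n <- length(band)
  lo <- c("<50" = 30, "50-69" = 50, "70-89" = 70, ">=90" = 90)[band]
  hi <- c("<50" = 49, "50-69" = 69, "70-89" = 89, ">=90" = 150)[band]
  out <- rep(NA_real_, n)
  ok <- !is.na(lo)
  out[ok] <- round(runif(sum(ok), lo[ok], hi[ok] + 1), 1)
  out
}

## raw-name variants: lower case, title case, or a brand alias that only the
## synonym table can resolve
variant_name <- function(name, rate) {
  n <- length(name)
  u <- runif(n)
  out <- name
  title <- function(x) paste0(substr(x, 1, 1), tolower(substring(x, 2)))
  i1 <- u < rate / 3
  i2 <- u >= rate / 3 & u < 2 * rate / 3
  i3 <- u >= 2 * rate / 3 & u < rate
  out[i1] <- tolower(name[i1])
  out[i2] <- title(name[i2])
  out[i3] <- paste0("BRAND-", name[i3])
  out
}

#' Synonym table resolving the generator's name variants
#'
#' Maps the brand aliases emitted by the generator (`BRAND-<NAME>`) back to
#' their canonical ingredient names. Case variants need no entry because
#' normalization upper-cases unmapped names.
#'
#' @param config a [sim_config()] object.
#' @return data.table with columns `raw`, `canonical`.
#' @export
synthetic_synonyms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nm <- c(config$background_drugs$name, config$signal_drugs$name)
  data.table(raw = paste0("BRAND-", nm), canonical = toupper(nm))
}

#' Simulate a report collection in memory
#'
#' Draws the full synthetic corpus described by a configuration without
#' touching disk: each case receives one primary-suspect drug (background
#' drugs by their weights, signal drugs by `signal_prob`), lists the target
#' event with the background probability or, for signal drugs, with the
#' probability solved from the planted reporting odds ratio against the
#' background event odds; onset intervals for signal-drug target-event cases
#' follow the planted Weibull law (other therapy starts use a
#' Weibull(120 days, 1) background). A fraction `duplicate_rate` of cases
#' emits an extra, strictly earlier-dated report version whose reaction list
#' is a noise placeholder, so deduplication has a unique correct answer.
#'
#' @param config a [sim_config()] object.
#' @return a `faers_reports` collection (raw names unnormalized).
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_reports_impl(config))
}

simulate_reports_impl <- function(config) {
  n <- config$n_cases
  bg <- config$background_drugs
  sg <- config$signal_drugs
  n_bg <- nrow(bg); n_sg <- nrow(sg)

  caseid <- sprintf("C%07d", seq_len(n))

  ## report-version dates, uniform within a uniformly chosen quarter
  quarters <- quarter_seq(config$date_range[1], config$date_range[2])
  qi <- sample(length(quarters), n, replace = TRUE)
  qs <- quarter_start(quarters)[qi]
  qe <- quarter_end(quarters)[qi]
  fda_dt <- qs + floor(runif(n) * (as.numeric(qe - qs) + 1))
  event_dt <- fda_dt - sample(0:90, n, replace = TRUE)

  ## primary-suspect assignment and planted event probabilities
  wts <- c(bg$prob / sum(bg$prob), rep(config$signal_prob, n_sg))
  all_names <- toupper(c(bg$name, sg$name))
  ps_idx <- sample(length(all_names), n, replace = TRUE, prob = wts)
  ps_drug <- all_names[ps_idx]
  sig_j <- ps_idx - n_bg            # > 0 for signal drugs
  is_sig <- sig_j > 0L

  p0 <- config$target_event_rate
  odds0 <- p0 / (1 - p0)
  p_event <- rep(p0, n)
  if (n_sg) {
    p_sig <- sg$ror * odds0 / (1 + sg$ror * odds0)
    p_event[is_sig] <- p_sig[sig_j[is_sig]]
  }
  is_event <- runif(n) < p_event

  ## onset interval (days) for the primary-suspect drug
  onset <- rweibull(n, shape = 1, scale = 120)
  planted <- is_sig & is_event
  if (any(planted)) {
    j <- sig_j[planted]
    onset[planted] <- rweibull(sum(planted), shape = sg$beta[j],
                               scale = sg$alpha[j])
  }
  onset <- pmax(1, ceiling(onset))
  ps_start <- event_dt - onset

  ## demographics
  mix <- config$demographic_mix
  sex_cat <- sample_axis(mix$sex, n)
  age_band <- sample_axis(mix$age_band, n)
  wt_band <- sample_axis(mix$weight_band, n)
  ctry_cat <- sample_axis(mix$country, n)
  demo <- data.table(
    primaryid = paste0(caseid, "-1"),
    caseid = caseid,
    fda_dt = fda_dt, fda_dt_prec = "day",
    event_dt = event_dt, event_dt_prec = "day",
    sex = fifelse(sex_cat == "missing", NA_character_, sex_cat),
    age_years = age_from_band(age_band),
    weight_kg = weight_from_band(wt_band),
    country = fifelse(ctry_cat == "missing", NA_character_, ctry_cat)
  )

  ## drug rows: the primary suspect plus 0-3 concomitant mentions
  ps_rows <- data.table(
    primaryid = demo$primaryid, caseid = caseid, drug_seq = 1L,
    role_cod = "PS",
    drugname = variant_name(ps_drug, config$name_variant_rate),
    normalized_name = NA_character_,
    indi_pt = fifelse(runif(n) < 0.3, NA_character_,
                      sample(indication_pool, n, replace = TRUE)),
    start_dt = ps_start, start_dt_prec = "day"
  )
  n_extra <- pmin(rpois(n, 0.8), 3L)
  idx <- rep(seq_len(n), n_extra)
  extra_rows <- if (length(idx)) {
    nm <- toupper(sample(bg$name, length(idx), replace = TRUE))
    keep <- nm != ps_drug[idx]
    idx <- idx[keep]; nm <- nm[keep]
    data.table(
      primaryid = demo$primaryid[idx], caseid = caseid[idx],
      drug_seq = 0L,  # renumbered below
      role_cod = sample(c("SS", "C", "I"), length(idx), replace = TRUE,
                        prob = c(0.5, 0.4, 0.1)),
      drugname = variant_name(nm, config$name_variant_rate),
      normalized_name = NA_character_,
      indi_pt = fifelse(runif(length(idx)) < 0.5, NA_character_,
                        sample(indication_pool, length(idx), replace = TRUE)),
      start_dt = event_dt[idx] -
        pmax(1, ceiling(rweibull(length(idx), 1, 120))),
      start_dt_prec = "day"
    )
  } else NULL
  drugs <- rbindlist(list(ps_rows, extra_rows))
  setorder(drugs, caseid, role_cod)            # PS sorts before SS/C? no:
  drugs <- drugs[order(caseid, -(role_cod == "PS"))]
  drugs[, drug_seq := seq_len(.N), by = caseid]
  ## a fraction of therapy starts is missing, as in real extracts
  miss_st <- runif(nrow(drugs)) < 0.15 & drugs$role_cod != "PS"
  drugs[miss_st, `:=`(start_dt = as.Date(NA), start_dt_prec = NA_character_)]

  ## reactions: target PT for event cases plus 0-2 noise PTs; 1-3 noise PTs
  ## otherwise
  n_noise <- fifelse(is_event, pmin(rpois(n, 0.7), 2L),
                     pmin(1L + rpois(n, 0.8), 3L))
  ridx <- rep(seq_len(n), n_noise)
  reac <- rbindlist(list(
    data.table(primaryid = demo$primaryid[is_event],
               caseid = caseid[is_event], pt = config$target_pt),
    data.table(primaryid = demo$primaryid[ridx], caseid = caseid[ridx],
               pt = sample(noise_pts, length(ridx), replace = TRUE))
  ))
  setorder(reac, caseid, pt)

  ## duplicate earlier-dated versions with placeholder reaction lists
  dup <- runif(n) < config$duplicate_rate
  if (any(dup)) {
    dd <- demo[dup]
    dd[, `:=`(primaryid = paste0(caseid, "-0"),
              fda_dt = fda_dt - sample(1:180, .N, replace = TRUE))]
    dg <- drugs[caseid %chin% dd$caseid]
    dg[, primaryid := paste0(caseid, "-0")]
    dr <- data.table(primaryid = dd$primaryid, caseid = dd$caseid,
                     pt = sample(noise_pts, nrow(dd), replace = TRUE))
    demo <- rbindlist(list(demo, dd))
    drugs <- rbindlist(list(drugs, dg))
    reac <- rbindlist(list(reac, dr))
  }
  setorder(demo, caseid, primaryid)
  setorder(drugs, caseid, primaryid, drug_seq)
  setorder(reac, caseid, primaryid, pt)

  faers_reports(demo, drugs, reac)
}

#' Generate a synthetic quarterly dataset on disk
#'
#' Simulates the corpus described by `config` and writes it as one
#' DEMO/DRUG/REAC/THER file set per quarter (grouped by each report
#' version's `fda_dt`), dollar-delimited with header rows. Identical
#' configurations (including the seed) produce byte-identical files.
#'
#' @param config a [sim_config()] object.
#' @param outdir output directory (created if needed).
#' @return a `generation_summary`: data.table of per-quarter row counts with
#'   attributes `cases` (distinct cases) and `report_versions` (total DEMO
#'   rows); also serialized config (`sim_config.yaml`), planted truth
#'   (`planted_truth.tsv`) and synonym table (`synonyms.tsv`) in `outdir`.
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  reports <- simulate_reports(config)
  qlab <- date_quarter(reports$demo$fda_dt)
  summary <- rbindlist(lapply(sort(unique(qlab)), function(q) {
    sub <- subset_reports(reports, reports$demo$primaryid[qlab == q])
    write_quarter(sub, outdir, q)
    data.table(quarter = q, demo_rows = nrow(sub$demo),
               drug_rows = nrow(sub$drugs), reac_rows = nrow(sub$reactions),
               ther_rows = sum(!is.na(sub$drugs$start_dt)))
  }))
  write_sim_config(config, file.path(outdir, "sim_config.yaml"))
  fwrite(planted_truth(config), file.path(outdir, "planted_truth.tsv"),
         sep = "\t")
  fwrite(synthetic_synonyms(config), file.path(outdir, "synonyms.tsv"),
         sep = "\t")
  setattr(summary, "cases", length(unique(reports$demo$caseid)))
  setattr(summary, "report_versions", nrow(reports$demo))
  setattr(summary, "class", c("generation_summary", class(summary)))
  summary
}

#' @export
print.generation_summary <- function(x, ...) {
  cat(sprintf("<generation_summary> %d case(s), %d report version(s), %d quarter(s)\n",
              attr(x, "cases"), attr(x, "report_versions"), nrow(x)))
  print(as.data.table(x))
  invisible(x)
}

#' Serialize / read a simulation configuration
#'
#' The configuration is stored as YAML key/value pairs; drug tables are
#' stored as lists of records.
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$background_drugs <- as.list(as.data.frame(x$background_drugs))
  x$signal_drugs <- as.list(as.data.frame(x$signal_drugs))
  x$demographic_mix <- lapply(x$demographic_mix, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$background_drugs <- as.data.frame(x$background_drugs)
  sd <- as.data.frame(x$signal_drugs)
  if (nrow(sd) == 0L) {
    sd <- data.frame(name = character(), ror = numeric(),
                     alpha = numeric(), beta = numeric())
  }
  x$signal_drugs <- sd
  x$demographic_mix <- lapply(x$demographic_mix, unlist)
  do.call(sim_config, x)
}
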