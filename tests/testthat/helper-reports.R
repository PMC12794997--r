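## Builders for small in-code report fixtures.

library(data.table)

as_date <- function(x) {
  if (length(x) == 0) return(as.Date(character()))
  as.Date(x, format = "%Y%m%d")
}

## One report version. drugs: list of lists with fields name, role
## (default "PS"), start (YYYYMMDD or NA), indi.
report_spec <- function(pid, cid = pid, fda = NA, evt = NA, sex = NA,
                        age = NA, wt = NA, country = NA,
                        drugs = list(list(name = "DRUGA")),
                        pts = "Depression") {
  list(pid = pid, cid = cid, fda = fda, evt = evt, sex = sex, age = age,
       wt = wt, country = country, drugs = drugs, pts = pts)
}

## Assemble report_spec()s into a faers_reports collection.
empty_demo <- function() data.table(
  primaryid = character(), caseid = character(),
  fda_dt = as.Date(character()), fda_dt_prec = character(),
  event_dt = as.Date(character()), event_dt_prec = character(),
  sex = character(), age_years = numeric(), weight_kg = numeric(),
  country = character())

report_set <- function(...) {
  specs <- list(...)
  if (!length(specs)) {
    return(faers_reports(empty_demo(), empty_drugs(), empty_reac()))
  }
  demo <- rbindlist(lapply(specs, function(s) data.table(
    primaryid = s$pid, caseid = s$cid,
    fda_dt = as_date(s$fda), fda_dt_prec = ifelse(is.na(s$fda), NA, "day"),
    event_dt = as_date(s$evt), event_dt_prec = ifelse(is.na(s$evt), NA, "day"),
    sex = as.character(s$sex), age_years = as.numeric(s$age),
    weight_kg = as.numeric(s$wt), country = as.character(s$country))))
  drugs <- rbindlist(lapply(specs, function(s) {
    if (!length(s$drugs)) return(NULL)
    rbindlist(lapply(seq_along(s$drugs), function(i) {
      d <- s$drugs[[i]]
      data.table(primaryid = s$pid, caseid = s$cid, drug_seq = i,
                 role_cod = d$role %||% "PS", drugname = d$name,
                 normalized_name = NA_character_,
                 indi_pt = as.character(d$indi %||% NA),
                 start_dt = as_date(d$start %||% NA),
                 start_dt_prec = ifelse(is.na(d$start %||% NA), NA, "day"))
    }))
  }))
  reac <- rbindlist(lapply(specs, function(s) {
    if (!length(s$pts) || all(is.na(s$pts))) return(NULL)
    data.table(primaryid = s$pid, caseid = s$cid, pt = s$pts)
  }))
  empty_drugs <- data.table(primaryid = character(), caseid = character(),
                            drug_seq = integer(), role_cod = character(),
                            drugname = character(),
                            normalized_name = character(),
                            indi_pt = character(),
                            start_dt = as.Date(character()),
                            start_dt_prec = character())
  empty_reac <- data.table(primaryid = character(), caseid = character(),
                           pt = character())
  faers_reports(demo,
                if (nrow(drugs)) drugs else empty_drugs,
                if (nrow(reac)) reac else empty_reac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_drugs <- function() data.table(
  primaryid = character(), caseid = character(), drug_seq = integer(),
  role_cod = character(), drugname = character(),
  normalized_name = character(), indi_pt = character(),
  start_dt = as.Date(character()), start_dt_prec = character())

empty_reac <- function() data.table(
  primaryid = character(), caseid = character(), pt = character())

## small simulation config used across tests
test_config <- function(n = 500, seed = 42, ...) {
  sim_config(n_cases = n, seed = seed,
             background_drugs = data.frame(name = sprintf("BG%02d", 1:8),
                                           prob = rep(0.125, 8)),
             date_range = c("2020Q1", "2020Q4"), ...)
}
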