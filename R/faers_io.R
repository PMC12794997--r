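## Quarterly ASCII table IO and the in-memory report model.
##
## A report collection is held as three keyed tables rather than a list of
## per-report objects: `demo` (one row per report version), `drugs` (one row
## per drug mention) and `reactions` (one row per reported preferred term),
## all linked by `primaryid`. Therapy start dates live on the drug rows and
## are serialized to/from the THER table.

#' Construct a report collection
#'
#' Bundles the three component tables of a FAERS-style report set into a
#' `faers_reports` object. Most users obtain one from [simulate_reports()]
#' or [read_quarter()] rather than calling this directly.
#'
#' @param demo data.frame with columns `primaryid`, `caseid`, `fda_dt`
#'   (Date, the report-version date), `fda_dt_prec`, `event_dt`,
#'   `event_dt_prec`, `sex` ("F"/"M"/NA), `age_years`, `weight_kg`,
#'   `country`.
#' @param drugs data.frame with columns `primaryid`, `caseid`, `drug_seq`,
#'   `role_cod` (one of PS/SS/C/I), `drugname`, `normalized_name`,
#'   `indi_pt`, `start_dt`, `start_dt_prec`.
#' @param reactions data.frame with columns `primaryid`, `caseid`, `pt`.
#' @return a `faers_reports` object (a list of three `data.table`s).
#' @export
faers_reports <- function(demo, drugs, reactions) {
  demo <- as.data.table(demo)
  drugs <- as.data.table(drugs)
  reactions <- as.data.table(reactions)
  need <- function(dt, cols, what) {
    miss <- setdiff(cols, names(dt))
    if (length(miss)) {
      stop(what, " table is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  need(demo, c("primaryid", "caseid", "fda_dt", "fda_dt_prec", "event_dt",
               "event_dt_prec", "sex", "age_years", "weight_kg", "country"),
       "demo")
  need(drugs, c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
                "normalized_name", "indi_pt", "start_dt", "start_dt_prec"),
       "drugs")
  need(reactions, c("primaryid", "caseid", "pt"), "reactions")
  if (anyNA(demo$primaryid) || any(!nzchar(demo$primaryid))) {
    stop("demo: primaryid must be nonempty", call. = FALSE)
  }
  if (anyNA(demo$caseid) || any(!nzchar(demo$caseid))) {
    stop("demo: caseid must be nonempty", call. = FALSE)
  }
  bad_role <- setdiff(unique(drugs$role_cod), c("PS", "SS", "C", "I"))
  if (length(bad_role)) {
    stop("drugs: invalid role_cod value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  structure(list(demo = demo, drugs = drugs, reactions = reactions),
            class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf(
    "<faers_reports> %d report version(s), %d case(s), %d drug row(s), %d reaction row(s)\n",
    nrow(x$demo), length(unique(x$demo$caseid)), nrow(x$drugs),
    nrow(x$reactions)))
  invisible(x)
}

#' Number of report versions in a collection
#' @param x a `faers_reports` object.
#' @export
n_reports <- function(x) nrow(x$demo)

## Subset a collection to a set of primaryids, preserving order of `demo`.
subset_reports <- function(x, ids) {
  keep <- x$demo$primaryid %in% ids
  faers_reports(x$demo[keep],
                x$drugs[primaryid %chin% ids],
                x$reactions[primaryid %chin% ids])
}

## Row-bind collections (used when assembling quarters).
bind_reports <- function(lst) {
  faers_reports(rbindlist(lapply(lst, `[[`, "demo")),
                rbindlist(lapply(lst, `[[`, "drugs")),
                rbindlist(lapply(lst, `[[`, "reactions")))
}

quarter_file <- function(dir, table, quarter) {
  file.path(dir, paste0(table, quarter_suffix(quarter), ".txt"))
}

read_faers_table <- function(path, table, expected) {
  if (!file.exists(path)) {
    stop("missing ", table, " file: ", path, call. = FALSE)
  }
  dt <- fread(path, sep = "$", colClasses = "character", header = TRUE,
              na.strings = NULL, quote = "", encoding = "UTF-8")
  if (!identical(names(dt), expected)) {
    stop("malformed ", table, " header in ", path, ": expected ",
         paste(expected, collapse = "$"), call. = FALSE)
  }
  dt
}

demo_cols <- c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
               "age_cod", "wt", "wt_cod", "reporter_country")
drug_cols <- c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
               "indi_pt")
reac_cols <- c("primaryid", "caseid", "pt")
ther_cols <- c("primaryid", "caseid", "drug_seq", "start_dt")

## Age unit codes handled: YR as-is, MON /12, WK /52.18, DY /365.25; DEC and
## unknown codes are passed through unconverted. Weight: KG as-is, LBS
## converted at 0.453592 kg/lb.
convert_age <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  div <- rep(1, length(v))
  div[cod == "MON"] <- 12
  div[cod == "WK"] <- 52.18
  div[cod == "DY"] <- 365.25
  v / div
}

convert_weight <- function(wt, wt_cod) {
  v <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(wt_cod))
  v[cod == "LBS"] <- v[cod == "LBS"] * 0.453592
  v
}

#' Read one quarter of FAERS-dialect ASCII tables
#'
#' Reads the DEMO/DRUG/REAC/THER files for a quarter (dollar-delimited,
#' header row first) and assembles them into a [faers_reports()] collection,
#' one report version per DEMO row. Child rows (DRUG/REAC/THER) whose
#' `primaryid` does not appear in DEMO are dropped and counted; unparseable
#' dates are left absent and counted. The tally is attached as attribute
#' `"tally"` (a named list, serializable with [write_ingest_tally()]).
#'
#' @param dir directory holding the quarter's files.
#' @param quarter year-quarter label, e.g. `"2020Q1"`.
#' @return a `faers_reports` object with a `"tally"` attribute.
#' @export
read_quarter <- function(dir, quarter) {
  demo <- read_faers_table(quarter_file(dir, "DEMO", quarter), "DEMO", demo_cols)
  drug <- read_faers_table(quarter_file(dir, "DRUG", quarter), "DRUG", drug_cols)
  reac <- read_faers_table(quarter_file(dir, "REAC", quarter), "REAC", reac_cols)
  ther <- read_faers_table(quarter_file(dir, "THER", quarter), "THER", ther_cols)

  ids <- demo$primaryid
  orphan_drug <- sum(!(drug$primaryid %chin% ids))
  orphan_reac <- sum(!(reac$primaryid %chin% ids))
  orphan_ther <- sum(!(ther$primaryid %chin% ids))
  drug <- drug[primaryid %chin% ids]
  reac <- reac[primaryid %chin% ids]
  ther <- ther[primaryid %chin% ids]

  fda <- parse_faers_date(demo$fda_dt)
  evt <- parse_faers_date(demo$event_dt)
  demo_out <- data.table(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = fda$date, fda_dt_prec = fda$prec,
    event_dt = evt$date, event_dt_prec = evt$prec,
    sex = fifelse(toupper(trimws(demo$sex)) %in% c("F", "M"),
                  toupper(trimws(demo$sex)), NA_character_),
    age_years = convert_age(demo$age, demo$age_cod),
    weight_kg = convert_weight(demo$wt, demo$wt_cod),
    country = fifelse(nzchar(trimws(demo$reporter_country)),
                      trimws(demo$reporter_country), NA_character_)
  )

  st <- parse_faers_date(ther$start_dt)
  ther_out <- data.table(primaryid = ther$primaryid,
                         drug_seq = as.integer(ther$drug_seq),
                         start_dt = st$date, start_dt_prec = st$prec)
  ## several therapy episodes may share one drug mention: keep the earliest
  ## dated episode (absent dates lose)
  ther_out <- ther_out[order(primaryid, drug_seq, is.na(start_dt), start_dt)]
  ther_out <- ther_out[, .SD[1L], by = .(primaryid, drug_seq)]
  drug_out <- data.table(
    primaryid = drug$primaryid,
    caseid = drug$caseid,
    drug_seq = as.integer(drug$drug_seq),
    role_cod = drug$role_cod,
    drugname = drug$drugname,
    normalized_name = NA_character_,
    indi_pt = fifelse(nzchar(trimws(drug$indi_pt)), trimws(drug$indi_pt),
                      NA_character_)
  )
  drug_out <- ther_out[drug_out, on = c("primaryid", "drug_seq")]
  setcolorder(drug_out, c("primaryid", "caseid", "drug_seq", "role_cod",
                          "drugname", "normalized_name", "indi_pt",
                          "start_dt", "start_dt_prec"))

  reac_out <- data.table(primaryid = reac$primaryid, caseid = reac$caseid,
                         pt = reac$pt)

  out <- faers_reports(demo_out, drug_out, reac_out)
  attr(out, "tally") <- list(
    quarter = quarter,
    demo_rows = nrow(demo_out),
    orphan_drug_rows = orphan_drug,
    orphan_reac_rows = orphan_reac,
    orphan_ther_rows = orphan_ther,
    unparseable_dates = fda$n_bad + evt$n_bad + st$n_bad
  )
  out
}

#' Read several quarters into one collection
#'
#' @inheritParams read_quarter
#' @param quarters character vector of year-quarter labels.
#' @return a `faers_reports` object; per-quarter tallies in attribute
#'   `"tally"` (a list).
#' @export
read_quarters <- function(dir, quarters) {
  parts <- lapply(quarters, function(q) read_quarter(dir, q))
  out <- bind_reports(parts)
  attr(out, "tally") <- lapply(parts, attr, "tally")
  out
}

#' Write one quarter of FAERS-dialect ASCII tables
#'
#' Serializes a report collection as the four dollar-delimited files for the
#' given quarter (`DEMOyyQq.txt` etc.). Ages are written in years
#' (`age_cod = "YR"`), weights in kilograms (`wt_cod = "KG"`); partial dates
#' keep their precision. THER rows are emitted only for drug mentions with a
#' therapy start date. `read_quarter()` on the result reproduces the input
#' collection field-for-field (normalized names, which are derived, are not
#' serialized).
#'
#' @param reports a `faers_reports` collection.
#' @param dir output directory (created if needed).
#' @param quarter year-quarter label used in the file names.
#' @return invisibly, a named character vector of the four file paths.
#' @export
write_quarter <- function(reports, dir, quarter) {
  stopifnot(inherits(reports, "faers_reports"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  d <- reports$demo
  demo_out <- data.table(
    primaryid = d$primaryid, caseid = d$caseid,
    fda_dt = format_faers_date(d$fda_dt, d$fda_dt_prec),
    event_dt = format_faers_date(d$event_dt, d$event_dt_prec),
    sex = fifelse(is.na(d$sex), "", d$sex),
    age = fifelse(is.na(d$age_years), "",
                  format(d$age_years, trim = TRUE, scientific = FALSE)),
    age_cod = fifelse(is.na(d$age_years), "", "YR"),
    wt = fifelse(is.na(d$weight_kg), "",
                 format(d$weight_kg, trim = TRUE, scientific = FALSE)),
    wt_cod = fifelse(is.na(d$weight_kg), "", "KG"),
    reporter_country = fifelse(is.na(d$country), "", d$country)
  )
  g <- reports$drugs
  drug_out <- data.table(
    primaryid = g$primaryid, caseid = g$caseid, drug_seq = g$drug_seq,
    role_cod = g$role_cod, drugname = g$drugname,
    indi_pt = fifelse(is.na(g$indi_pt), "", g$indi_pt)
  )
  ther_out <- g[!is.na(start_dt),
                .(primaryid, caseid, drug_seq,
                  start_dt = format_faers_date(start_dt, start_dt_prec))]
  reac_out <- reports$reactions

  has_dollar <- function(dt) any(vapply(dt, function(col)
    any(grepl("$", as.character(col), fixed = TRUE)), logical(1)))
  if (has_dollar(demo_out) || has_dollar(drug_out) || has_dollar(reac_out) ||
      has_dollar(ther_out)) {
    stop("field values must not contain the '$' delimiter", call. = FALSE)
  }

  paths <- c(DEMO = quarter_file(dir, "DEMO", quarter),
             DRUG = quarter_file(dir, "DRUG", quarter),
             REAC = quarter_file(dir, "REAC", quarter),
             THER = quarter_file(dir, "THER", quarter))
  fwrite(demo_out, paths[["DEMO"]], sep = "$", quote = FALSE, na = "")
  fwrite(drug_out, paths[["DRUG"]], sep = "$", quote = FALSE, na = "")
  fwrite(reac_out, paths[["REAC"]], sep = "$", quote = FALSE, na = "")
  fwrite(ther_out, paths[["THER"]], sep = "$", quote = FALSE, na = "")
  invisible(paths)
}

#' Write an ingest warning tally as JSON
#'
#' @param reports a collection returned by [read_quarter()] or
#'   [read_quarters()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_ingest_tally <- function(reports, path) {
  tally <- attr(reports, "tally")
  if (is.null(tally)) stop("reports carry no ingest tally", call. = FALSE)
  jsonlite::write_json(tally, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
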