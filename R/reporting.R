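## Descriptive outputs: cohort characteristics, annual reporting trend with
## polynomial fit, top-drug rankings, and cross-database overlap.

age_band_levels <- c("<18", "18-65", "65-85", ">85", "missing")
weight_band_levels <- c("<50", "50-69", "70-89", ">=90", "missing")

## closed-open bands; the "<18 / 18-65 / 65-85 / >85" labels overlap at
## their printed edges, so band membership is [lo, hi)
age_band_of <- function(age) {
  band <- rep("missing", length(age))
  ok <- !is.na(age)
  band[ok & age < 18] <- "<18"
  band[ok & age >= 18 & age < 65] <- "18-65"
  band[ok & age >= 65 & age < 85] <- "65-85"
  band[ok & age >= 85] <- ">85"
  factor(band, levels = age_band_levels)
}

weight_band_of <- function(wt) {
  band <- rep("missing", length(wt))
  ok <- !is.na(wt)
  band[ok & wt < 50] <- "<50"
  band[ok & wt >= 50 & wt < 70] <- "50-69"
  band[ok & wt >= 70 & wt < 90] <- "70-89"
  band[ok & wt >= 90] <- ">=90"
  factor(band, levels = weight_band_levels)
}

axis_summary <- function(cat, total, digits) {
  tab <- table(cat)
  data.table(category = names(tab), count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / total, digits))
}

#' Summarize the cohort of target-event reports
#'
#' Tabulates the deduplicated target-event collection by sex, age band,
#' weight band, reporting country and primary-suspect indication. Per-axis
#' counts (including the missing category) always sum to the report total.
#' Percentages are of the total, rounded half-up at the axis's export
#' precision: 1 decimal for sex and indication, 2 decimals for age, weight
#' and country. Country and indication tables are complete here; top-5
#' truncation happens in [export_cohort_summary()].
#'
#' @param reports a deduplicated `faers_reports` collection.
#' @return a `cohort_summary`: list with `total`, `median_age`, and the
#'   five per-axis data.tables (`by_sex`, `by_age_band`, `by_weight_band`,
#'   `by_country`, `by_indication`).
#' @export
summarize_cohort <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  d <- reports$demo
  total <- nrow(d)
  if (total == 0L) stop("empty report collection", call. = FALSE)

  sex_cat <- factor(fcase(is.na(d$sex), "missing", d$sex == "F", "female",
                          d$sex == "M", "male"),
                    levels = c("female", "male", "missing"))
  ctry_cat <- fifelse(is.na(d$country), "missing", d$country)

  ## indication of the first primary-suspect drug record per report
  ps <- reports$drugs[role_cod == "PS"][order(primaryid, drug_seq)]
  ps1 <- ps[!duplicated(primaryid), .(primaryid, indi_pt)]
  ind <- ps1[data.table(primaryid = d$primaryid), on = "primaryid"]$indi_pt
  ind_cat <- fifelse(is.na(ind), "missing", ind)

  structure(list(
    total = total,
    median_age = stats::median(d$age_years, na.rm = TRUE),
    by_sex = axis_summary(sex_cat, total, 1),
    by_age_band = axis_summary(age_band_of(d$age_years), total, 2),
    by_weight_band = axis_summary(weight_band_of(d$weight_kg), total, 2),
    by_country = axis_summary(ctry_cat, total, 2),
    by_indication = axis_summary(ind_cat, total, 1)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d report(s), median age %.0f\n", x$total,
              x$median_age))
  for (axis in c("by_sex", "by_age_band", "by_weight_band")) {
    cat("--", sub("^by_", "", axis), "--\n")
    print(x[[axis]])
  }
  invisible(x)
}

#' Export a cohort summary as CSV
#'
#' One long table (axis, category, count, percent); country and indication
#' axes are truncated to their top 5 categories by count (missing category
#' excluded from the ranking but kept in the output).
#'
#' @param summary a [summarize_cohort()] result.
#' @param path output CSV path.
#' @return invisibly, the exported data.table.
#' @export
export_cohort_summary <- function(summary, path) {
  top5 <- function(dt) {
    named <- dt[category != "missing"][order(-count, category)][
      seq_len(min(5L, .N))]
    rbind(named, dt[category == "missing"])
  }
  out <- rbindlist(list(
    data.table(axis = "total", category = "all", count = summary$total,
               percent = 100),
    cbind(axis = "sex", summary$by_sex),
    cbind(axis = "age_band", summary$by_age_band),
    cbind(axis = "weight_band", summary$by_weight_band),
    cbind(axis = "country", top5(summary$by_country)),
    cbind(axis = "indication", top5(summary$by_indication))
  ), use.names = TRUE)
  fwrite(out, path)
  invisible(out)
}

#' Annual report counts
#'
#' Counts deduplicated reports per calendar year, taking the year from the
#' event date when present, else from the report-version date; reports with
#' neither are dropped. Years inside the observed range are zero-filled.
#'
#' @param reports a `faers_reports` collection.
#' @return data.table with columns `year`, `count` (empty for empty input).
#' @export
annual_trend <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  d <- reports$demo
  dt <- fifelse(is.na(d$event_dt), d$fda_dt, d$event_dt)
  yr <- as.integer(format(dt, "%Y"))
  yr <- yr[!is.na(yr)]
  if (!length(yr)) return(data.table(year = integer(), count = integer()))
  rng <- min(yr):max(yr)
  counts <- tabulate(yr - min(yr) + 1L, nbins = length(rng))
  data.table(year = rng, count = as.integer(counts))
}

#' Fit a polynomial trend to annual counts
#'
#' Ordinary least-squares polynomial of the given degree (raw basis) fitted
#' to counts over years, with the coefficient of determination
#' R^2 = 1 - SSres/SStot. A constant series (SStot = 0) is assigned
#' R^2 = 0 with a warning. The default degree 3 accommodates one
#' rise-plateau inflection; the choice is cosmetic to the pipeline.
#'
#' @param yearly data.table with columns `year`, `count`.
#' @param degree polynomial degree; needs at least `degree + 2` years.
#' @return a `trend_fit`: list with `yearly_counts`, `degree`,
#'   `coefficients` (intercept first), `fitted`, `r_squared`.
#' @export
fit_trend <- function(yearly, degree = 3) {
  yearly <- as.data.table(yearly)
  if (!all(c("year", "count") %in% names(yearly))) {
    stop("yearly counts need columns 'year' and 'count'", call. = FALSE)
  }
  if (nrow(yearly) < degree + 2) {
    stop("need at least degree + 2 = ", degree + 2, " years, got ",
         nrow(yearly), call. = FALSE)
  }
  fit <- stats::lm(count ~ poly(year, degree, raw = TRUE), data = yearly)
  fitted <- unname(stats::fitted(fit))
  ss_res <- sum((yearly$count - fitted)^2)
  ss_tot <- sum((yearly$count - mean(yearly$count))^2)
  if (ss_tot == 0) {
    warning("constant series: R^2 defined as 0")
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  structure(list(yearly_counts = yearly, degree = degree,
                 coefficients = unname(stats::coef(fit)), fitted = fitted,
                 r_squared = r2),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> degree %d over %d years, R^2 = %.4f\n",
              x$degree, nrow(x$yearly_counts), x$r_squared))
  invisible(x)
}

#' Rank drugs by report count or signal strength
#'
#' `by_count` ranks on the target-event report count `n` descending;
#' `by_signal` ranks on the ROR descending among composite-positive drugs.
#' Ties break alphabetically. When a `novel` column is present (from
#' [flag_novel()]) novel signals are marked with a trailing `*` in `label`.
#'
#' @param signals a [signal_table()] result (optionally novelty-flagged).
#' @param n number of rows to keep.
#' @param mode `"by_count"` or `"by_signal"`.
#' @return data.table with columns `rank`, `drug`, `n`, `ror`, `novel`,
#'   `label`.
#' @export
top_drugs <- function(signals, n = 20, mode = c("by_count", "by_signal")) {
  mode <- match.arg(mode)
  n_keep <- n
  s <- copy(as.data.table(signals))
  if (!"novel" %in% names(s)) s[, novel := NA]
  if (mode == "by_signal") {
    s <- s[composite == TRUE][order(-ror, drug)]
  } else {
    s <- s[order(-n, drug)]
  }
  keep <- seq_len(min(n_keep, nrow(s)))
  s <- s[keep]
  s[, label := paste0(drug, fifelse(!is.na(novel) & novel, "*", ""))]
  cbind(data.table(rank = seq_len(nrow(s))),
        s[, .(drug, n, ror, novel, label)])
}

#' Overlap between two databases' signal-drug sets
#'
#' Exact cardinalities of two canonical-name sets and their intersection,
#' plus the shared top-k drugs ranked by combined report count when counts
#' are supplied. Both sets must be canonicalized under the same synonym
#' table.
#'
#' @param drugs_a,drugs_b character vectors of canonical drug names.
#' @param counts_a,counts_b optional named numeric vectors of per-drug
#'   report counts, used to rank the shared drugs.
#' @param k number of shared drugs to report.
#' @return list with `n_a`, `n_b`, `n_overlap`, and `shared` (data.table of
#'   the top-k shared drugs with combined counts).
#' @export
database_overlap <- function(drugs_a, drugs_b, counts_a = NULL,
                             counts_b = NULL, k = 20) {
  A <- unique(toupper(drugs_a))
  B <- unique(toupper(drugs_b))
  shared <- sort(intersect(A, B))
  comb <- data.table(drug = shared,
                     count_a = if (is.null(counts_a)) NA_real_ else
                       unname(counts_a[shared]),
                     count_b = if (is.null(counts_b)) NA_real_ else
                       unname(counts_b[shared]))
  comb[, count := fifelse(is.na(count_a), 0, count_a) +
         fifelse(is.na(count_b), 0, count_b)]
  setorder(comb, -count, drug)
  list(n_a = length(A), n_b = length(B), n_overlap = length(shared),
       shared = comb[seq_len(min(k, nrow(comb)))])
}
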