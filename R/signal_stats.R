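## Four-algorithm disproportionality analysis on 2x2 contingency tables.
##
## The drug-event 2x2 table:
##                     target event   other events
##   target drug (PS)       a              b
##   other drugs            c              d
##
## Statistics (N = a+b+c+d):
##   ROR  = ad/(bc),            95% CI exp(ln ROR +/- 1.96 * sqrt(1/a+1/b+1/c+1/d))
##   PRR  = a(c+d) / (c(a+b)),  chi2 = (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d))
##   IC   = log2(aN / ((a+c)(a+b))), IC025 = IC - 2*sqrt(V(IC))
##   EBGM = aN / ((a+c)(a+b)),  EBGM05 = exp(ln EBGM - 1.96 * sqrt(1/a+1/b+1/c+1/d))
##
## Here EBGM is the unshrunk observed-to-expected ratio (no Gamma-Poisson
## empirical-Bayes shrinkage is fitted); the conventional name is kept. The
## IC variance uses a delta-method approximation,
## V(IC) = (1/ln 2)^2 (1/a - 1/(a+b) - 1/(a+c) + 1/N), clipped at 0.
## Identically, IC == log2(EBGM).
##
## Positivity criteria: ROR CI lower > 1 & N>=3; PRR>=2 & chi2>=4 & N>=3;
## IC025 > 0; EBGM05 > 2. The composite signal requires all four. Tables
## with a zero cell yield non-evaluable (NA) CIs and false flags; no
## continuity correction is applied.

#' Construct a 2x2 drug-event contingency table
#'
#' @param a reports with the target drug (primary suspect) and target event.
#' @param b reports with the target drug and other events.
#' @param c reports with other drugs and the target event.
#' @param d reports with other drugs and other events.
#' @return a `contingency` object. Arguments may be equal-length vectors.
#' @export
contingency <- function(a, b, c, d) {
  ## cells are stored as doubles: N can exceed .Machine$integer.max in the
  ## chi-squared product terms
  cells <- cbind(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d))
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(cells) < 1)) {
    stop("contingency table must contain at least one report", call. = FALSE)
  }
  structure(as.data.table(cells), class = c("contingency", "data.table",
                                            "data.frame"))
}

as_contingency <- function(tab) {
  if (inherits(tab, "contingency")) return(tab)
  if (is.data.frame(tab) && all(c("a", "b", "c", "d") %in% names(tab))) {
    return(contingency(tab$a, tab$b, tab$c, tab$d))
  }
  if (is.numeric(tab) && length(tab) == 4L) {
    return(contingency(tab[1], tab[2], tab[3], tab[4]))
  }
  stop("not a contingency table", call. = FALSE)
}

#' Reporting odds ratio with log-normal 95% CI
#'
#' @param tab a [contingency()] table (or data.frame with columns a,b,c,d,
#'   or a length-4 numeric vector); vectorized over rows.
#' @return data.table with columns `ror`, `ror_lower`, `ror_upper`. Any
#'   zero cell makes the row non-evaluable (all NA), without error.
#' @export
ror <- function(tab) {
  t <- as_contingency(tab)
  ok <- t$a > 0 & t$b > 0 & t$c > 0 & t$d > 0
  est <- ifelse(ok, (t$a * t$d) / (t$b * t$c), NA_real_)
  se <- ifelse(ok, sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d), NA_real_)
  data.table(ror = est,
             ror_lower = exp(log(est) - 1.96 * se),
             ror_upper = exp(log(est) + 1.96 * se))
}

#' Proportional reporting ratio and chi-squared statistic
#'
#' The chi-squared statistic is Pearson's, computed from the closed form
#' without continuity correction.
#'
#' @inheritParams ror
#' @return data.table with columns `prr`, `chi2`; rows with an empty drug
#'   margin (`a+b == 0`), `c == 0`, or any empty margin for `chi2` are
#'   non-evaluable (NA).
#' @export
prr <- function(tab) {
  t <- as_contingency(tab)
  N <- t$a + t$b + t$c + t$d
  ok_prr <- (t$a + t$b) > 0 & t$c > 0
  est <- ifelse(ok_prr, t$a * (t$c + t$d) / (t$c * (t$a + t$b)), NA_real_)
  ok_chi <- ok_prr & (t$a + t$c) > 0 & (t$b + t$d) > 0 & (t$c + t$d) > 0
  chi <- ifelse(ok_chi,
                (t$a * t$d - t$b * t$c)^2 * N /
                  ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d)),
                NA_real_)
  data.table(prr = est, chi2 = chi)
}

#' BCPNN information component with delta-method lower bound
#'
#' @inheritParams ror
#' @return data.table with columns `ic` (bits), `ic025`. Rows with `a == 0`
#'   are non-evaluable.
#' @export
bcpnn_ic <- function(tab) {
  t <- as_contingency(tab)
  N <- t$a + t$b + t$c + t$d
  ok <- t$a > 0
  ic <- ifelse(ok, log2(t$a * N / ((t$a + t$c) * (t$a + t$b))), NA_real_)
  v <- ifelse(ok,
              pmax(0, (1 / log(2))^2 *
                     (1 / t$a - 1 / (t$a + t$b) - 1 / (t$a + t$c) + 1 / N)),
              NA_real_)
  data.table(ic = ic, ic025 = ic - 2 * sqrt(v))
}

#' Observed-to-expected ratio (EBGM form) with log-normal lower bound
#'
#' @inheritParams ror
#' @return data.table with columns `ebgm`, `ebgm05`. The estimate requires
#'   `a > 0`; the lower bound additionally requires all cells positive.
#' @export
ebgm <- function(tab) {
  t <- as_contingency(tab)
  N <- t$a + t$b + t$c + t$d
  est <- ifelse(t$a > 0, t$a * N / ((t$a + t$c) * (t$a + t$b)), NA_real_)
  ok_ci <- t$a > 0 & t$b > 0 & t$c > 0 & t$d > 0
  se <- ifelse(ok_ci, sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d), NA_real_)
  data.table(ebgm = est, ebgm05 = exp(log(est) - 1.96 * se))
}

#' Evaluate per-algorithm positivity flags and the composite rule
#'
#' Applies the four positivity criteria (see the module header) to computed
#' statistics; a non-evaluable statistic yields a `FALSE` flag. The
#' composite flag is the conjunction of all four.
#'
#' @inheritParams ror
#' @return data.table with the statistics plus logical columns `ror_pos`,
#'   `prr_pos`, `bcpnn_pos`, `mgps_pos`, `composite` and the report count
#'   `n` (= a).
#' @export
evaluate_signal <- function(tab) {
  t <- as_contingency(tab)
  res <- cbind(data.table(n = t$a), ror(t), prr(t), bcpnn_ic(t), ebgm(t))
  flag <- function(x) !is.na(x) & x
  res[, ror_pos := flag(ror_lower > 1 & n >= 3)]
  res[, prr_pos := flag(prr >= 2 & chi2 >= 4 & n >= 3)]
  res[, bcpnn_pos := flag(ic025 > 0)]
  res[, mgps_pos := flag(ebgm05 > 2)]
  res[, composite := ror_pos & prr_pos & bcpnn_pos & mgps_pos]
  res[]
}

#' Build the contingency table for one drug
#'
#' Each report in the (deduplicated, name-normalized) collection is counted
#' in exactly one cell: the drug axis is membership of `drug` among the
#' report's primary-suspect drug names; the event axis is membership of
#' `target_pt` among its reactions (case-insensitive exact PT match).
#'
#' @param reports a deduplicated `faers_reports` collection.
#' @param drug canonical drug name.
#' @param target_pt preferred-term string.
#' @return a [contingency()] table (one row).
#' @export
build_contingency <- function(reports, drug, target_pt) {
  stopifnot(inherits(reports, "faers_reports"))
  ps <- primary_suspect_drugs(reports)
  exposed <- unique(ps$primaryid[ps$drug == toupper(drug)])
  event <- reports$reactions[tolower(pt) == tolower(target_pt),
                             unique(primaryid)]
  ids <- reports$demo$primaryid
  de <- ids %chin% exposed
  ev <- ids %chin% event
  contingency(sum(de & ev), sum(de & !ev), sum(!de & ev), sum(!de & !ev))
}

#' Per-drug signal table across a corpus
#'
#' Builds the 2x2 table of every distinct primary-suspect drug against the
#' full deduplicated corpus and evaluates all four disproportionality
#' statistics and flags. A drug's "other drugs" cells include reports that
#' mention it only in non-primary-suspect roles (exposure is PS-only).
#'
#' @param reports a deduplicated, name-normalized `faers_reports`
#'   collection.
#' @param target_pt preferred-term string of the target event.
#' @return data.table keyed by `drug` with cells `a`,`b`,`c`,`d`, all
#'   statistics and flags, sorted by drug name.
#' @export
signal_table <- function(reports, target_pt) {
  stopifnot(inherits(reports, "faers_reports"))
  ps <- primary_suspect_drugs(reports)
  event_ids <- reports$reactions[tolower(pt) == tolower(target_pt),
                                 unique(primaryid)]
  N <- nrow(reports$demo)
  n_event <- length(event_ids)
  if (nrow(ps) == 0L) {
    return(data.table(drug = character()))
  }
  cells <- ps[, .(margin = .N, a = sum(primaryid %chin% event_ids)),
              by = drug]
  cells[, b := margin - a]
  cells[, c := n_event - a]
  cells[, d := N - margin - c]
  setorder(cells, drug)
  out <- cbind(cells[, .(drug, a, b, c, d)],
               evaluate_signal(cells[, .(a, b, c, d)]))
  out
}

#' Flag label-novel signals
#'
#' A signal is novel when it is composite-positive and the target event is
#' absent from the drug's approved labeling. Drugs missing from the label
#' table are treated as unlabelled for the event (novel if composite) and
#' tallied in attribute `"unlabelled"`.
#'
#' @param signals a [signal_table()] result (needs `drug`, `composite`).
#' @param labels data.table from [read_label_table()].
#' @param target_pt preferred-term string.
#' @return `signals` with a logical `novel` column added.
#' @export
flag_novel <- function(signals, labels, target_pt) {
  signals <- copy(as.data.table(signals))
  labels <- as.data.table(labels)
  labelled_drugs <- unique(toupper(labels$drug))
  covered <- unique(toupper(labels$drug[tolower(labels$pt) ==
                                          tolower(target_pt)]))
  signals[, novel := composite & !(toupper(drug) %in% covered)]
  missing_drugs <- setdiff(unique(toupper(signals$drug)), labelled_drugs)
  attr(signals, "unlabelled") <- missing_drugs
  signals[]
}

#' Venn structure of the four algorithms
#'
#' Counts drugs positive under each of the 15 non-empty subsets of the four
#' algorithms (exact Venn regions: a drug contributes to the region of the
#' exact set of algorithms flagging it). The all-four region equals the
#' number of composite signals.
#'
#' @param signals a [signal_table()] result.
#' @return named integer vector of length 15; names are `+`-joined subsets
#'   of `ror`, `prr`, `bcpnn`, `mgps`.
#' @export
algorithm_overlap <- function(signals) {
  signals <- as.data.table(signals)
  algs <- c("ror", "prr", "bcpnn", "mgps")
  subsets <- unlist(lapply(1:4, function(k)
    combn(algs, k, paste, collapse = "+", simplify = FALSE)), use.names = FALSE)
  out <- setNames(integer(15), subsets)
  if (nrow(signals)) {
    flags <- as.matrix(signals[, .(ror = ror_pos, prr = prr_pos,
                                   bcpnn = bcpnn_pos, mgps = mgps_pos)])
    key <- apply(flags, 1, function(r) paste(algs[r], collapse = "+"))
    tab <- table(key[nzchar(key)])
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Export a forest-plot-ready signal table
#'
#' Writes the per-drug signal table with all statistics rounded half-up to
#' two decimals (internal values stay full precision) as a delimited file.
#'
#' @param signals a [signal_table()] (optionally [flag_novel()]-annotated)
#'   result.
#' @param path output CSV path.
#' @return invisibly, the rounded table.
#' @export
export_signal_table <- function(signals, path) {
  out <- copy(as.data.table(signals))
  num <- intersect(c("ror", "ror_lower", "ror_upper", "prr", "chi2", "ic",
                     "ic025", "ebgm", "ebgm05"), names(out))
  out[, (num) := lapply(.SD, round_half_up, 2), .SDcols = num]
  fwrite(out, path)
  invisible(out)
}
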