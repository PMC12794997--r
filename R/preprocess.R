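## Report cleaning: case-level deduplication, drug-name normalization,
## target-event filtering and primary-suspect restriction. All operations
## are pure: they return new collections and never mutate their input.

#' Read a drug-name synonym table
#'
#' Two-column delimited text (header `raw<TAB>canonical`, tab- or
#' comma-separated) mapping raw drug-name strings, matched
#' case-insensitively after trimming, to canonical ingredient names.
#'
#' @param path file path.
#' @return data.table with columns `raw`, `canonical`.
#' @export
read_synonym_table <- function(path) {
  dt <- fread(path, colClasses = "character")
  if (!all(c("raw", "canonical") %in% names(dt))) {
    stop("synonym table needs columns 'raw' and 'canonical'", call. = FALSE)
  }
  dt <- dt[, .(raw, canonical)]
  if (any(!nzchar(dt$canonical))) {
    stop("synonym table: canonical names must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(tolower(trimws(dt$raw)))) {
    stop("synonym table: raw keys must be unique (case-insensitive)",
         call. = FALSE)
  }
  dt
}

#' Read a drug labelling table
#'
#' Long-format delimited text (header `drug<TAB>pt`) listing, per canonical
#' drug name, the preferred terms mentioned in its approved labeling. Used
#' by [flag_novel()].
#'
#' @param path file path.
#' @return data.table with columns `drug`, `pt`.
#' @export
read_label_table <- function(path) {
  dt <- fread(path, colClasses = "character")
  if (!all(c("drug", "pt") %in% names(dt))) {
    stop("label table needs columns 'drug' and 'pt'", call. = FALSE)
  }
  dt[, .(drug, pt)]
}

#' Deduplicate report versions to one report per case
#'
#' FAERS cases accumulate report versions; analyses use only the most
#' recent submission. Per `caseid` the version with the latest version date
#' (`fda_dt`) is retained. Ties, and versions without a date, are resolved
#' deterministically: an absent date loses to any present date, and within
#' equal dates the larger `primaryid` (numeric-aware string comparison)
#' wins. Output is sorted by `caseid`. Idempotent.
#'
#' @param reports a `faers_reports` collection.
#' @return a `faers_reports` collection with one report version per case.
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  d <- reports$demo
  dnum <- as.numeric(d$fda_dt)              # absent date loses to any date
  dnum[is.na(dnum)] <- -Inf
  pnum <- suppressWarnings(as.numeric(gsub("[^0-9]", "", d$primaryid)))
  pnum[is.na(pnum)] <- -Inf
  ord <- order(d$caseid, dnum, pnum, d$primaryid)
  keep_id <- d$primaryid[ord][!duplicated(d$caseid[ord], fromLast = TRUE)]
  out <- subset_reports(reports, keep_id)
  setorder(out$demo, caseid)
  out
}

#' Normalize drug names against a synonym table
#'
#' Sets `normalized_name` on every drug row: the synonym table's canonical
#' name when the trimmed, lower-cased raw name has an entry, otherwise the
#' raw name upper-cased verbatim. Unmapped names are tallied in attribute
#' `"unmapped"` (a data.table of raw name / count). Idempotent in its
#' effect: re-normalizing changes nothing.
#'
#' @param reports a `faers_reports` collection.
#' @param synonyms data.table from [read_synonym_table()] or
#'   [synthetic_synonyms()].
#' @return the collection with `normalized_name` filled in.
#' @export
normalize_names <- function(reports, synonyms) {
  stopifnot(inherits(reports, "faers_reports"))
  synonyms <- as.data.table(synonyms)
  key <- tolower(trimws(reports$drugs$drugname))
  m <- match(key, tolower(trimws(synonyms$raw)))
  norm <- ifelse(is.na(m), toupper(trimws(reports$drugs$drugname)),
                 synonyms$canonical[m])
  drugs <- copy(reports$drugs)[, normalized_name := norm]
  out <- faers_reports(reports$demo, drugs, reports$reactions)
  unmapped <- data.table(raw = key[is.na(m)])[, .N, by = raw]
  setnames(unmapped, "N", "count")
  attr(out, "unmapped") <- unmapped
  out
}

#' Keep only reports listing a target event
#'
#' Retains report versions whose reaction list contains `target_pt` under
#' exact, case-insensitive preferred-term matching (no substring matching:
#' PTs are a controlled vocabulary). Idempotent; output is a subset of the
#' input.
#'
#' @param reports a `faers_reports` collection.
#' @param target_pt nonempty preferred-term string.
#' @return the filtered collection.
#' @export
filter_target_event <- function(reports, target_pt) {
  stopifnot(inherits(reports, "faers_reports"))
  if (!is.character(target_pt) || length(target_pt) != 1L ||
      !nzchar(target_pt)) {
    stop("target_pt must be a nonempty string", call. = FALSE)
  }
  hit <- reports$reactions[tolower(pt) == tolower(target_pt),
                           unique(primaryid)]
  subset_reports(reports, hit)
}

#' Primary-suspect drug names per report
#'
#' Returns, for each report version, its distinct primary-suspect (role
#' `PS`) drug names in drug-sequence order. Uses `normalized_name` when
#' normalization has been applied, otherwise the upper-cased raw name.
#'
#' @param reports a `faers_reports` collection.
#' @return data.table with columns `primaryid`, `drug` (one row per
#'   distinct PS drug per report).
#' @export
primary_suspect_drugs <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  ps <- reports$drugs[role_cod == "PS"]
  if (nrow(ps) == 0L) {
    return(data.table(primaryid = character(), drug = character()))
  }
  ps <- ps[order(primaryid, drug_seq)]
  ps[, drug := fifelse(is.na(normalized_name), toupper(trimws(drugname)),
                       normalized_name)]
  unique(ps[, .(primaryid, drug)])
}
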