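## Shared helpers: commercial rounding, year-quarter arithmetic, partial dates.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published pharmacovigilance tables
#' round half up. Used for every exported/rounded statistic.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- year-quarter labels ("2004Q1") -------------------------------------

parse_quarter <- function(q) {
  m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", q))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop("invalid year-quarter label(s): ", paste(q[bad], collapse = ", "),
         call. = FALSE)
  }
  data.table(
    year = as.integer(vapply(m, `[`, "", 2L)),
    q    = as.integer(vapply(m, `[`, "", 3L))
  )
}

quarter_label <- function(year, q) sprintf("%04dQ%d", year, q)

## inclusive sequence of quarter labels
quarter_seq <- function(from, to) {
  a <- parse_quarter(from); b <- parse_quarter(to)
  ia <- a$year * 4L + a$q; ib <- b$year * 4L + b$q
  if (ia > ib) stop("date_range start is after its end", call. = FALSE)
  idx <- ia:ib
  quarter_label((idx - 1L) %/% 4L, (idx - 1L) %% 4L + 1L)
}

quarter_start <- function(label) {
  pq <- parse_quarter(label)
  as.Date(sprintf("%04d-%02d-01", pq$year, (pq$q - 1L) * 3L + 1L))
}

quarter_end <- function(label) {
  pq <- parse_quarter(label)
  nxt <- ifelse(pq$q == 4L,
                sprintf("%04d-01-01", pq$year + 1L),
                sprintf("%04d-%02d-01", pq$year, pq$q * 3L + 1L))
  as.Date(nxt) - 1L
}

## quarter label of a Date vector
date_quarter <- function(d) {
  y <- as.integer(format(d, "%Y"))
  q <- (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  out[ok] <- quarter_label(y[ok], q[ok])
  out
}

## file suffix used in quarterly file names: "2004Q1" -> "04Q1"
quarter_suffix <- function(label) sub("^[0-9]{2}", "", label)

## ---- FAERS dates (YYYYMMDD, possibly partial) ---------------------------

## Returns list(date = Date, prec = "day"/"month"/"year"/NA, n_bad = count).
## Partial dates are floored to the first day of their period and flagged
## with a precision so day-level analyses can exclude them.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  n <- nchar(x)
  date <- rep(as.Date(NA), length(x))
  prec <- rep(NA_character_, length(x))
  digits <- !is.na(x) & grepl("^[0-9]+$", x)

  i8 <- digits & n == 8L
  date[i8] <- as.Date(x[i8], format = "%Y%m%d")
  prec[i8][!is.na(date[i8])] <- "day"
  i6 <- digits & n == 6L
  date[i6] <- as.Date(paste0(x[i6], "01"), format = "%Y%m%d")
  prec[i6][!is.na(date[i6])] <- "month"
  i4 <- digits & n == 4L
  date[i4] <- as.Date(paste0(x[i4], "0101"), format = "%Y%m%d")
  prec[i4][!is.na(date[i4])] <- "year"

  n_bad <- sum(!is.na(x) & is.na(date))
  list(date = date, prec = prec, n_bad = n_bad)
}

format_faers_date <- function(date, prec) {
  out <- rep("", length(date))
  ok <- !is.na(date) & !is.na(prec)
  fmt <- c(day = "%Y%m%d", month = "%Y%m", year = "%Y")
  for (p in names(fmt)) {
    i <- ok & prec == p
    out[i] <- format(date[i], fmt[[p]])
  }
  out
}
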