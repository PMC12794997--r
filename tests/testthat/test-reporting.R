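## demo-only collection builder for cohort arithmetic at scale
demo_only <- function(n, sex = NA, age = NA, wt = NA, country = NA) {
  data.table::data.table(
    primaryid = sprintf("P%07d", seq_len(n)), caseid = sprintf("C%07d", seq_len(n)),
    fda_dt = as.Date("2020-01-15"), fda_dt_prec = "day",
    event_dt = as.Date(NA), event_dt_prec = NA_character_,
    sex = as.character(sex), age_years = as.numeric(age),
    weight_kg = as.numeric(wt), country = as.character(country))
}

test_that("cohort axis counts conserve the total and percents follow half-up rounding", {
  demo <- rbind(demo_only(7, sex = "F"), demo_only(2, sex = "M"),
                demo_only(3))
  demo$primaryid <- sprintf("P%03d", 1:12); demo$caseid <- demo$primaryid
  r <- faers_reports(demo, empty_drugs(), empty_reac())
  cs <- summarize_cohort(r)
  expect_identical(cs$total, 12L)
  expect_identical(sum(cs$by_sex$count), 12L)
  expect_identical(sum(cs$by_age_band$count), 12L)
  expect_identical(sum(cs$by_weight_band$count), 12L)
  expect_equal(cs$by_sex$percent[cs$by_sex$category == "female"],
               round(100 * 7 / 12, 1))  # 58.3
  ## single female report
  r1 <- faers_reports(demo_only(1, sex = "F"), empty_drugs(), empty_reac())
  cs1 <- summarize_cohort(r1)
  expect_equal(cs1$by_sex$percent[cs1$by_sex$category == "female"], 100)
})

test_that("band classification matches a brute-force scan on synthetic data", {
  cfg <- test_config(800, seed = 41)
  r <- deduplicate(simulate_reports(cfg))
  cs <- summarize_cohort(r)
  age <- r$demo$age_years
  expected <- c(sum(age < 18, na.rm = TRUE),
                sum(age >= 18 & age < 65, na.rm = TRUE),
                sum(age >= 65 & age < 85, na.rm = TRUE),
                sum(age >= 85, na.rm = TRUE),
                sum(is.na(age)))
  expect_identical(cs$by_age_band$count, as.integer(expected))
  wt <- r$demo$weight_kg
  expected_wt <- c(sum(wt < 50, na.rm = TRUE),
                   sum(wt >= 50 & wt < 70, na.rm = TRUE),
                   sum(wt >= 70 & wt < 90, na.rm = TRUE),
                   sum(wt >= 90, na.rm = TRUE), sum(is.na(wt)))
  expect_identical(cs$by_weight_band$count, as.integer(expected_wt))
  ## export truncates country to top 5 plus missing
  p <- withr::local_tempfile(fileext = ".csv")
  out <- export_cohort_summary(cs, p)
  expect_lte(nrow(out[out$axis == "country" & out$category != "missing", ]), 5L)
})

test_that("annual counts zero-fill the year range and match brute force", {
  expect_identical(nrow(annual_trend(report_set())), 0L)
  r <- report_set(
    report_spec("P1", evt = "20100601"), report_spec("P2", evt = "20100701"),
    report_spec("P3", evt = "20101201"), report_spec("P4", evt = "20120301"))
  tr <- annual_trend(r)
  expect_identical(tr$year, 2010:2012)
  expect_identical(tr$count, c(3L, 0L, 1L))
  ## event date preferred, version date as fallback
  r2 <- report_set(report_spec("P1", fda = "20150101"),
                   report_spec("P2", fda = "20150601", evt = "20140601"))
  expect_identical(annual_trend(r2)$count, c(1L, 1L))
  cfg <- test_config(700, seed = 51)
  rr <- deduplicate(simulate_reports(cfg))
  tr2 <- annual_trend(rr)
  yr <- as.integer(format(data.table::fifelse(is.na(rr$demo$event_dt),
                                              rr$demo$fda_dt,
                                              rr$demo$event_dt), "%Y"))
  expect_identical(sum(tr2$count), length(yr))
  expect_identical(tr2$count[tr2$year == min(yr)], sum(yr == min(yr)))
})

test_that("polynomial trend fitting reproduces exact fits and the R2 definition", {
  years <- 2001:2012
  exact <- data.frame(year = years, count = 3 + 2 * (years - 2000) +
                        0.5 * (years - 2000)^2)
  f <- fit_trend(exact, degree = 2)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  ## constant series: R2 defined as 0 with a warning, slope ~ 0
  const <- data.frame(year = years, count = rep(7, 12))
  expect_warning(fc <- fit_trend(const, degree = 1), "constant")
  expect_equal(fc$r_squared, 0)
  expect_equal(fc$coefficients[2], 0, tolerance = 1e-10)
  expect_error(fit_trend(exact[1:3, ], degree = 2), "at least")
})

test_that("trend R2 matches an independent normal-equations solver", {
  years <- 2000 + 1:15
  y <- withr::with_seed(61, 10 + 3 * (1:15) + 0.4 * (1:15)^2 +
                          stats::rnorm(15, 0, 5))
  f <- fit_trend(data.frame(year = years, count = y), degree = 2)
  X <- outer(years - 2007, 0:2, `^`)   # centered basis; R2 is basis-invariant
  beta <- solve(crossprod(X), crossprod(X, y))
  r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
  expect_equal(f$r_squared, r2, tolerance = 1e-10)
  ## R2 is non-decreasing in the degree
  r2s <- vapply(1:4, function(d)
    fit_trend(data.frame(year = years, count = y), d)$r_squared, numeric(1))
  expect_true(all(diff(r2s) > -1e-12))
})

test_that("drug rankings sort per mode with alphabetical tie-break and stars", {
  sig <- data.table::data.table(
    drug = c("A", "B", "C", "D"), n = c(5, 9, 1, 5),
    ror = c(12, 3, 50, 8), composite = c(TRUE, TRUE, FALSE, TRUE),
    novel = c(TRUE, FALSE, FALSE, FALSE))
  byc <- top_drugs(sig, n = 3, mode = "by_count")
  expect_identical(byc$drug, c("B", "A", "D"))   # tie 5/5 -> A before D
  expect_identical(byc$label[2], "A*")
  bys <- top_drugs(sig, n = 10, mode = "by_signal")
  expect_identical(bys$drug, c("A", "D", "B"))   # composite only, ror desc
  ## deterministic under permutation of the input rows
  perm <- sig[c(3, 1, 4, 2)]
  expect_identical(top_drugs(perm, n = 3, mode = "by_count")$drug, byc$drug)
  ## brute-force order oracle on a random table
  rnd <- withr::with_seed(71, data.table::data.table(
    drug = sprintf("D%02d", 1:30), n = sample(1:10, 30, TRUE),
    ror = runif(30, 0.5, 40), composite = sample(c(TRUE, FALSE), 30, TRUE)))
  got <- top_drugs(rnd, n = 30, mode = "by_count")$drug
  expect_identical(got, rnd$drug[order(-rnd$n, rnd$drug)])
})

test_that("database overlap returns exact cardinalities and shared ranking", {
  ov <- database_overlap(c("X", "Y"), c("Y", "Z"))
  expect_identical(c(ov$n_a, ov$n_b, ov$n_overlap), c(2L, 2L, 1L))
  expect_identical(database_overlap(c("A"), c("B"))$n_overlap, 0L)
  ## case-canonicalized and deduplicated
  expect_identical(database_overlap(c("x", "X", "y"), c("Y"))$n_a, 2L)
  a <- sprintf("D%02d", 1:20); b <- sprintf("D%02d", 11:25)
  ca <- stats::setNames(1:20, a); cb <- stats::setNames(rep(5, 15), b)
  ov2 <- database_overlap(a, b, ca, cb, k = 3)
  expect_identical(ov2$n_overlap, length(intersect(a, b)))
  expect_identical(ov2$shared$drug[1], "D20")    # largest combined count
})
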