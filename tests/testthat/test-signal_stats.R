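## independent direct-formula oracle used across the property tests
oracle_stats <- function(a, b, c, d) {
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(
    ror = a * d / (b * c),
    ror_l = exp(log(a * d / (b * c)) - 1.96 * se),
    ror_u = exp(log(a * d / (b * c)) + 1.96 * se),
    prr = a * (c + d) / (c * (a + b)),
    chi2 = (a * d - b * c)^2 * N / ((a + b) * (c + d) * (a + c) * (b + d)),
    ic = log2(a * N / ((a + c) * (a + b))),
    ebgm = a * N / ((a + c) * (a + b)),
    ebgm05 = exp(log(a * N / ((a + c) * (a + b))) - 1.96 * se)
  )
}

random_tables <- function(n, seed) {
  withr::with_seed(seed, data.frame(   # doubles: the oracle products overflow ints
    a = as.numeric(sample(1:50, n, TRUE)), b = as.numeric(sample(1:500, n, TRUE)),
    c = as.numeric(sample(1:5000, n, TRUE)),
    d = as.numeric(sample(1000:100000, n, TRUE))))
}

test_that("the unit table is the independence fixed point", {
  t1 <- contingency(1, 1, 1, 1)
  expect_equal(ror(t1)$ror, 1)
  p <- prr(t1)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  expect_equal(bcpnn_ic(t1)$ic, 0)
  expect_equal(ebgm(t1)$ebgm, 1)
  s <- evaluate_signal(t1)
  expect_false(any(s$ror_pos, s$prr_pos, s$bcpnn_pos, s$mgps_pos,
                   s$composite))
})

test_that("statistics match the direct closed forms on random tables", {
  tabs <- random_tables(200, 99)
  o <- oracle_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  ct <- contingency(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(ror(ct)$ror, o$ror, tolerance = 1e-12)
  expect_equal(ror(ct)$ror_lower, o$ror_l, tolerance = 1e-12)
  expect_equal(prr(ct)$prr, o$prr, tolerance = 1e-12)
  expect_equal(prr(ct)$chi2, o$chi2, tolerance = 1e-12)
  expect_equal(ebgm(ct)$ebgm, o$ebgm, tolerance = 1e-12)
  expect_equal(ebgm(ct)$ebgm05, o$ebgm05, tolerance = 1e-12)
  ## algebraic identity: the information component is log2 of the
  ## observed-to-expected ratio
  expect_equal(bcpnn_ic(ct)$ic, log2(ebgm(ct)$ebgm), tolerance = 1e-12)
})

test_that("ROR and chi-squared are invariant under table transposition", {
  tabs <- random_tables(100, 7)
  ct <- contingency(tabs$a, tabs$b, tabs$c, tabs$d)
  sw <- contingency(tabs$a, tabs$c, tabs$b, tabs$d)   # swap b <-> c
  expect_equal(ror(ct)$ror, ror(sw)$ror, tolerance = 1e-12)
  expect_equal(ror(ct)$ror_lower, ror(sw)$ror_lower, tolerance = 1e-12)
  expect_equal(prr(ct)$chi2, prr(sw)$chi2, tolerance = 1e-12)
})

test_that("CI ordering holds and widths shrink as cells scale up", {
  tabs <- random_tables(50, 17)
  ct <- contingency(tabs$a, tabs$b, tabs$c, tabs$d)
  ci <- ror(ct)
  expect_true(all(ci$ror_lower < ci$ror & ci$ror < ci$ror_upper))
  widths <- sapply(c(1, 2, 4, 8), function(k) {
    cik <- ror(contingency(tabs$a * k, tabs$b * k, tabs$c * k, tabs$d * k))
    log(cik$ror_upper) - log(cik$ror_lower)
  })
  expect_true(all(widths[, 2] < widths[, 1]))
  expect_true(all(widths[, 3] < widths[, 2]))
  expect_true(all(widths[, 4] < widths[, 3]))
})

test_that("zero cells yield non-evaluable statistics and false flags", {
  z <- contingency(0, 10, 5, 100)
  expect_true(is.na(ror(z)$ror))
  expect_true(is.na(bcpnn_ic(z)$ic))
  expect_true(is.na(ebgm(z)$ebgm))
  s <- evaluate_signal(z)
  expect_false(any(s$ror_pos, s$prr_pos, s$bcpnn_pos, s$mgps_pos))
  ## a > 0 but another zero cell: estimate kept, CI non-evaluable
  z2 <- contingency(3, 0, 5, 100)
  expect_false(is.na(ebgm(z2)$ebgm))
  expect_true(is.na(ebgm(z2)$ebgm05))
  expect_true(is.na(ror(z2)$ror))
  expect_error(contingency(-1, 1, 1, 1), "non-negative")
  expect_error(contingency(0, 0, 0, 0), "at least one")
})

test_that("positivity flags follow the four published criteria", {
  ## strong signal: hand-evaluate all four criteria from the closed forms
  o <- oracle_stats(10, 10, 100, 10000)
  expect_true(o$ror_l > 1)                       # ROR criterion
  expect_true(o$prr >= 2 && o$chi2 >= 4)         # PRR criterion
  expect_true(o$ebgm05 > 2)                      # MGPS criterion
  s <- evaluate_signal(contingency(10, 10, 100, 10000))
  expect_true(s$ror_pos && s$prr_pos && s$bcpnn_pos && s$mgps_pos)
  expect_true(s$composite)
  ## n = 2 fails the N >= 3 gate regardless of ratio strength
  s2 <- evaluate_signal(contingency(2, 2, 262101, 18016823))
  expect_false(s2$ror_pos)
  expect_false(s2$prr_pos)
  expect_false(s2$composite)
  expect_identical(s2$composite,
                   s2$ror_pos & s2$prr_pos & s2$bcpnn_pos & s2$mgps_pos)
})

test_that("contingency construction matches brute-force report classification", {
  r <- report_set(
    report_spec("P1", drugs = list(list(name = "X")), pts = "Depression"),
    report_spec("P2", drugs = list(list(name = "X")), pts = "Nausea"),
    report_spec("P3", drugs = list(list(name = "Y")), pts = "Depression"),
    report_spec("P4", drugs = list(list(name = "Y")), pts = "Nausea")
  )
  expect_equal(unclass(as.data.frame(build_contingency(r, "X", "Depression"))),
               list(a = 1, b = 1, c = 1, d = 1), ignore_attr = TRUE)
  ## absent drug: a = b = 0
  t0 <- build_contingency(r, "Z", "Depression")
  expect_equal(t0$a + t0$b, 0)
  ## random corpus against a per-report loop
  cfg <- test_config(500, seed = 19, signal_drugs = data.frame(
    name = "SIG", ror = 10, alpha = 80, beta = 0.7), signal_prob = 0.1)
  rr <- normalize_names(deduplicate(simulate_reports(cfg)),
                        synthetic_synonyms(cfg))
  tab <- build_contingency(rr, "SIG", "Depression")
  demo <- as.data.frame(rr$demo)
  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (pid in demo$primaryid) {
    dg <- rr$drugs[rr$drugs$primaryid == pid & rr$drugs$role_cod == "PS", ]
    exposed <- "SIG" %in% dg$normalized_name
    event <- any(tolower(rr$reactions$pt[rr$reactions$primaryid == pid]) ==
                   "depression")
    cell <- if (exposed && event) "a" else if (exposed) "b"
            else if (event) "c" else "d"
    cells[cell] <- cells[cell] + 1
  }
  expect_equal(as.numeric(as.data.frame(tab)), unname(cells))
  ## per-drug table agrees with the single-drug path and sums to the corpus
  st <- signal_table(rr, "Depression")
  expect_equal(as.numeric(st[st$drug == "SIG", c("a", "b", "c", "d")]),
               unname(cells))
  expect_true(all(st$a + st$b + st$c + st$d == nrow(demo)))
})

test_that("novelty flags require a composite signal and an unlabelled event", {
  sig <- data.table::data.table(
    drug = c("A", "B", "C"), composite = c(TRUE, TRUE, FALSE))
  labels <- data.table::data.table(
    drug = c("A", "C"), pt = c("Depression", "Depression"))
  out <- flag_novel(sig, labels, "Depression")
  expect_identical(out$novel, c(FALSE, TRUE, FALSE))
  expect_identical(attr(out, "unlabelled"), "B")
})

test_that("algorithm overlap counts match brute-force subset enumeration", {
  expect_identical(sum(algorithm_overlap(data.table::data.table(
    drug = character(), ror_pos = logical(), prr_pos = logical(),
    bcpnn_pos = logical(), mgps_pos = logical()))), 0L)
  one <- data.table::data.table(drug = "A", ror_pos = TRUE, prr_pos = TRUE,
                                bcpnn_pos = TRUE, mgps_pos = TRUE)
  expect_identical(algorithm_overlap(one)[["ror+prr+bcpnn+mgps"]], 1L)
  flags <- withr::with_seed(5, data.table::data.table(
    drug = sprintf("D%02d", 1:40),
    ror_pos = sample(c(TRUE, FALSE), 40, TRUE),
    prr_pos = sample(c(TRUE, FALSE), 40, TRUE),
    bcpnn_pos = sample(c(TRUE, FALSE), 40, TRUE),
    mgps_pos = sample(c(TRUE, FALSE), 40, TRUE)))
  ov <- algorithm_overlap(flags)
  algs <- c("ror", "prr", "bcpnn", "mgps")
  for (nm in names(ov)) {
    members <- strsplit(nm, "+", fixed = TRUE)[[1]]
    expected <- sum(apply(flags[, paste0(algs, "_pos"), with = FALSE], 1,
                          function(r) identical(algs[r], members)))
    expect_identical(unname(ov[nm]), as.integer(expected))
  }
  expect_identical(sum(ov), sum(rowSums(
    flags[, paste0(algs, "_pos"), with = FALSE]) > 0))
})

test_that("exported signal tables are rounded half-up at 2 decimals", {
  st <- evaluate_signal(contingency(2, 2, 262101, 18016823))
  st$drug <- "ESTRONE"
  p <- withr::local_tempfile(fileext = ".csv")
  out <- export_signal_table(st, p)
  expect_equal(out$ror, 68.74)
  expect_equal(out$chi2, 66.75)
  expect_equal(out$ic, 5.12)
  expect_true(file.exists(p))
})
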