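test_that("FPKM arithmetic and detection counting follow the definitions", {
  expect_equal(compute_fpkm(1000, 2000, 1e7), 50)
  expect_equal(compute_fpkm(0, 2000, 1e7), 0)
  expect_equal(compute_fpkm(1, 1000, 1e6), 1)
  expect_error(compute_fpkm(1, 0, 1e6), "length")
  expect_error(compute_fpkm(1, 1000, 0), "total")

  tab <- data.frame(transcript_id = c("a", "b", "c"),
                    sample = "s1", fpkm = c(5.0, 4.9, 6.0))
  expect_equal(unname(detect_expressed(tab, 5)), 2L)
  expect_equal(length(detect_expressed(tab[0, ], 5)), 0L)
  tab$fpkm <- 0
  expect_equal(unname(detect_expressed(tab, 0)), 3L)
})

test_that("base-level CV matches its sampling behaviour", {
  expect_equal(base_cv(rep(10, 50)), 0)
  expect_true(is.na(base_cv(numeric(100))))
  d <- rep(c(5, 15), 5000)
  expect_true(abs(base_cv(d) - 0.5) < 1e-3)
})

test_that("within-transcript fold change implements trim, exclusion and bins", {
  expect_equal(within_transcript_fold_change(rep(7, 1000)), 1)
  expect_true(is.na(within_transcript_fold_change(rep(7, 499))))
  # 1,000 bases; after trimming 200 each side: 540 bases at 10, 60 at 100
  d <- c(rep(5, 200), rep(10, 540), rep(100, 60), rep(5, 200))
  expect_equal(within_transcript_fold_change(d), 10)
  # zero bottom decile -> infinity sentinel, counted at every threshold
  dz <- c(rep(5, 200), rep(0, 100), rep(10, 500), rep(5, 200))
  expect_equal(within_transcript_fold_change(dz), Inf)
  expect_equal(unname(fold_change_summary(c(1.5, 3, 15, 150, Inf, NA))),
               c(4L, 3L, 2L))
  expect_equal(unname(fold_change_summary(rep(1, 10))), c(0L, 0L, 0L))
})

test_that("fold change and CV are scale invariant; fold change >= 1", {
  set.seed(31)
  for (i in 1:25) {
    d <- stats::rpois(sample(500:1500, 1), 50)
    k <- stats::runif(1, 0.1, 30)
    fc <- within_transcript_fold_change(d)
    expect_gte(fc, 1)
    expect_equal(within_transcript_fold_change(d * k), fc)
    expect_equal(base_cv(d * k), base_cv(d))
  }
})

test_that("decile-bin means agree with a brute-force extraction oracle", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(500:2000, 1)
    d <- stats::rpois(n, sample(c(2, 20, 200), 1)) +
      stats::runif(n, 0, 0.1)
    expect_equal(within_transcript_fold_change(d), oracle_fold_change(d))
  }
})

test_that("processivity ratio uses fractional windows and the FPKM filter", {
  expect_equal(processivity_ratio(rep(4, 1000), fpkm = 50), 1)
  # linear ramp 100 -> 0: closed-form window means ~90.05 and ~9.96
  d <- 100 * (1 - (0:999) / 999)
  r <- processivity_ratio(d, fpkm = 50)
  expect_true(abs(r - 0.1106) < 0.005)
  expect_true(is.na(processivity_ratio(rep(4, 1000), fpkm = 5)))
  expect_true(is.na(processivity_ratio(c(rep(0, 200), rep(5, 800)),
                                       fpkm = 50)))
})

test_that("read-end nucleotide frequencies normalize per position", {
  f <- read_end_nt_frequencies(rep("ACGTAC", 5))
  expect_equal(unname(f[1, "A"]), 1)
  expect_equal(unname(rowSums(f)), rep(1, 6))
  f2 <- read_end_nt_frequencies(c("AA", "CC", "GG", "TT"))
  expect_equal(unname(f2[1, ]), rep(0.25, 4))
  # N excluded from the denominator
  f3 <- read_end_nt_frequencies(c("NA", "AA", "TA"))
  expect_equal(unname(f3[1, c("A", "T")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(f3)), c(1, 1))
  expect_error(read_end_nt_frequencies(character()), "no read prefixes")
  expect_error(read_end_nt_frequencies(c("AC", "A")), "same length")
})

test_that("the metrics table assembles statistics with exclusion reasons", {
  cov <- list(a = rep(10, 1000), b = rep(10, 400), c = rep(10, 1000))
  fpkm <- c(a = 50, b = 50, c = 2)
  m <- coverage_metrics_table(cov, fpkm)
  expect_equal(m$excluded_reason, c("", "short_transcript", "low_fpkm"))
  expect_equal(m$fold_change[1], 1)
  expect_true(is.na(m$fold_change[2]))
  expect_true(is.na(m$processivity[3]))
})
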