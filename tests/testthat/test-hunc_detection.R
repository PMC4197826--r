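# small builder: a two-replicate series with given per-condition coverage
# generators, bypassing the simulator
manual_series <- function(cov_fun, ids, L) {
  reps <- lapply(1:2, function(r) {
    conds <- lapply(names(dilution_conditions()), function(cond) {
      out <- lapply(ids, function(id) cov_fun(id, cond, r))
      names(out) <- ids
      out
    })
    names(conds) <- names(dilution_conditions())
    conds
  })
  structure(list(replicates = reps,
                 mouse_fpkm = data.frame(transcript_id = ids, rep1 = 0,
                                         rep2 = 0)),
            class = "dilution_series")
}

test_that("MAD with constant 1 matches the hand oracle", {
  expect_equal(mad_constant1(c(1, 2, 3, 4, 5)), 1)
  expect_equal(mad_constant1(rep(3.3, 9)), 0)
  expect_equal(mad_constant1(42), 0)
  expect_error(mad_constant1(numeric()), "at least one")
  set.seed(17)
  for (i in 1:100) {
    x <- stats::rnorm(sample(1:30, 1))
    expect_equal(mad_constant1(x), oracle_mad(x))
  }
})

test_that("min-max normalization maps constants to zero and is scale-free", {
  expect_equal(minmax_normalize(rep(4, 10)), numeric(10))
  expect_equal(minmax_normalize(numeric(5)), numeric(5))
  x <- c(2, 8, 5, 2, 11)
  expect_equal(range(minmax_normalize(x)), c(0, 1))
  # proportional profiles normalize to exactly equal vectors
  expect_identical(minmax_normalize(x / 11), minmax_normalize(x))
  expect_identical(minmax_normalize(x / 3), minmax_normalize(x))
})

test_that("windowed MAD scores match a naive loop oracle", {
  cfg <- hunc_config(window = 10, trim_head = 5, trim_tail = 7,
                     min_contiguous = 3)
  set.seed(23)
  for (i in 1:100) {
    L <- sample(60:140, 1)
    cc <- replicate(5, stats::rpois(L, 20) + stats::runif(L),
                    simplify = FALSE)
    got <- windowed_mad_scores(cc, cfg)
    want <- oracle_windowed_mad(cc, 10, 5, 7)
    expect_equal(got$scores, want$scores)
    expect_equal(got$centers, want$centers)
  }
})

test_that("windowed MAD scoring handles degenerate and short inputs", {
  cc <- replicate(5, rep(c(1, 5, 2), 400), simplify = FALSE)
  s <- windowed_mad_scores(cc, hunc_config())
  expect_equal(max(abs(s$scores)), 0)
  expect_equal(length(s$scores), (1200 - 99) - 300 - 250)
  # a 600-base transcript retains no window under default trims
  short <- replicate(5, stats::rpois(600, 10), simplify = FALSE)
  expect_null(windowed_mad_scores(short, hunc_config()))
})

test_that("scores are invariant to scaling any single condition", {
  set.seed(29)
  cc <- replicate(5, stats::rpois(900, 30) + stats::runif(900),
                  simplify = FALSE)
  cfg <- hunc_config(trim_head = 20, trim_tail = 20)
  base <- windowed_mad_scores(cc, cfg)
  cc2 <- cc
  cc2[[3]] <- cc2[[3]] * 7.3
  expect_equal(windowed_mad_scores(cc2, cfg)$scores, base$scores)
})

test_that("the caller finds replicate-consistent anomalies and only those", {
  cfg <- sim_config(n_transcripts = 10, length_range = c(1700, 2300),
                    n_fragments = 5e4, seed = 41)
  tx <- generate_transcriptome(cfg)
  truth <- make_sim_truth(tx$models, n_hunc = 3, hunc_width = 160,
                          amplitude = 5, seed = 42)
  ser <- simulate_dilution_experiment(tx$models, truth, cfg)
  s1 <- score_dilution_replicate(ser, 1)
  s2 <- score_dilution_replicate(ser, 2)
  m1 <- ser$replicates[[1]]$mouse_only
  m2 <- ser$replicates[[2]]$mouse_only
  calls <- call_hunc_regions(s1, s2, ser$mouse_fpkm, m1, m2)
  rec <- score_recovery(calls$regions, truth)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$false_positive_regions, 0)
  expect_true(all(rec$jaccard >= 0.5))

  # null series: no injection -> no calls
  truth0 <- make_sim_truth(tx$models, n_hunc = 0, seed = 43)
  ser0 <- simulate_dilution_experiment(tx$models, truth0, cfg)
  calls0 <- call_hunc_regions(score_dilution_replicate(ser0, 1),
                              score_dilution_replicate(ser0, 2),
                              ser0$mouse_fpkm,
                              ser0$replicates[[1]]$mouse_only,
                              ser0$replicates[[2]]$mouse_only)
  expect_equal(nrow(calls0$regions), 0L)
})

test_that("background filters drop planted decoys with provenance", {
  cfg <- sim_config(n_transcripts = 10, length_range = c(1700, 2300),
                    n_fragments = 5e4, seed = 51)
  tx <- generate_transcriptome(cfg)
  truth <- make_sim_truth(tx$models, n_hunc = 2, n_decoys_fpkm = 1,
                          n_decoys_cov = 1, hunc_width = 160,
                          amplitude = 5, seed = 52)
  ser <- simulate_dilution_experiment(tx$models, truth, cfg)
  s1 <- score_dilution_replicate(ser, 1)
  s2 <- score_dilution_replicate(ser, 2)
  calls <- call_hunc_regions(s1, s2, ser$mouse_fpkm,
                             ser$replicates[[1]]$mouse_only,
                             ser$replicates[[2]]$mouse_only)
  d <- truth$decoys
  fp_id <- d$transcript_id[d$type == "fpkm"]
  cov_id <- d$transcript_id[d$type == "cov"]
  expect_false(any(calls$regions$transcript_id %in% c(fp_id, cov_id)))
  expect_true("mouse_fpkm" %in%
                calls$dropped$filter[calls$dropped$transcript_id == fp_id])
  expect_true("mouse_coverage" %in%
                calls$dropped$filter[calls$dropped$transcript_id == cov_id])
})

test_that("a replicate must carry all five dilution conditions", {
  cfg <- sim_config(n_transcripts = 4, length_range = c(1700, 1900),
                    n_fragments = 1e4, seed = 61)
  tx <- generate_transcriptome(cfg)
  ser <- simulate_dilution_experiment(tx$models,
                                      make_sim_truth(tx$models, seed = 62),
                                      cfg)
  ser$replicates[[2]]$mix_1_2 <- NULL
  expect_error(score_dilution_replicate(ser, 2), "mix_1_2")
})

test_that("difference regions flag replicate-divergent anomalies", {
  set.seed(71)
  ids <- sprintf("D%02d", 1:6)
  L <- 1800L
  base <- lapply(ids, function(id) stats::rpois(L, 60) + stats::runif(L))
  names(base) <- ids
  anom <- c(0.15, 0.45, 1, 0.7)
  names(anom) <- setdiff(names(dilution_conditions()), "mouse_only")
  # anomaly on D1 at [800, 1000) in replicate 1 only
  cov_fun <- function(id, cond, r) {
    v <- base[[id]] * dilution_conditions()[[cond]]
    if (r == 1 && id == "D01" && cond != "mouse_only") {
      v[801:1000] <- v[801:1000] * anom[[cond]]
    }
    v
  }
  ser <- manual_series(cov_fun, ids, L)
  s1 <- score_dilution_replicate(ser, 1)
  s2 <- score_dilution_replicate(ser, 2)
  m1 <- ser$replicates[[1]]$mouse_only
  m2 <- ser$replicates[[2]]$mouse_only
  hunc <- call_hunc_regions(s1, s2, ser$mouse_fpkm, m1, m2)
  expect_equal(nrow(hunc$regions), 0L)  # not replicate-consistent
  diffs <- difference_regions(s1, s2, hunc, ser$mouse_fpkm, m1, m2)
  expect_equal(unique(diffs$regions$transcript_id), "D01")
  expect_true(any(diffs$regions$start < 1000 & diffs$regions$end > 800))

  # identical replicates -> no difference regions
  ser0 <- manual_series(function(id, cond, r) {
    base[[id]] * dilution_conditions()[[cond]]
  }, ids, L)
  s01 <- score_dilution_replicate(ser0, 1)
  s02 <- score_dilution_replicate(ser0, 2)
  d0 <- difference_regions(s01, s02, hunc, ser0$mouse_fpkm,
                           ser0$replicates[[1]]$mouse_only,
                           ser0$replicates[[2]]$mouse_only)
  expect_equal(nrow(d0$regions), 0L)

  # a difference region within 200 bases of a hunc region is suppressed
  fake_hunc <- hunc
  fake_hunc$regions <- data.frame(transcript_id = "D01", start = 1050L,
                                  end = 1150L, mean_mad = 0.2,
                                  filter = "pass")
  d2 <- difference_regions(s1, s2, fake_hunc, ser$mouse_fpkm, m1, m2)
  expect_false(any(d2$regions$transcript_id == "D01"))
  expect_true("near_hunc" %in% d2$dropped$filter)
})
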