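test_that("transcriptome generation is deterministic and honors GC target", {
  cfg <- sim_config(n_transcripts = 5, length_range = c(700, 900), seed = 3)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth$weights, b$truth$weights)

  gc1 <- generate_transcriptome(sim_config(n_transcripts = 3,
                                           length_range = c(700, 700),
                                           gc_target = 1, seed = 1))
  expect_true(all(grepl("^[GC]+$", as.character(gc1$sequences))))

  half <- generate_transcriptome(sim_config(n_transcripts = 1,
                                            length_range = c(10000, 10000),
                                            gc_target = 0.5, seed = 2))
  gc_obs <- gc_fraction(as.character(half$sequences[[1]]))
  expect_true(abs(gc_obs - 0.5) < 0.02)

  expect_error(sim_config(gc_target = 1.2), "gc_target")
  empty <- generate_transcriptome(sim_config(n_transcripts = 0))
  expect_length(empty$models, 0)
})

test_that("planted low-complexity segments are recorded in the truth", {
  cfg <- sim_config(n_transcripts = 6, length_range = c(800, 1000), seed = 9)
  tx <- generate_transcriptome(cfg, n_low_complexity = 2,
                               low_complexity_width = 120)
  lc <- tx$truth$low_complexity
  expect_equal(nrow(lc), 2L)
  for (i in 1:2) {
    seg <- substr(as.character(tx$sequences[[lc$transcript_id[i]]]),
                  lc$start[i] + 1, lc$end[i])
    expect_equal(length(unique(strsplit(seg, "")[[1]])),
                 nchar(lc$motif[i]))
  }
  # planted repeats depress hexamer entropy relative to random sequence
  ids <- names(tx$sequences)
  ent <- vapply(as.character(tx$sequences), hexamer_entropy, 0)
  expect_lt(mean(ent[ids %in% lc$transcript_id]),
            mean(ent[!(ids %in% lc$transcript_id)]))
})

test_that("fragment simulation conserves totals and matches its expectation", {
  # one transcript takes every fragment
  models <- single_exon_models(1000L)
  cfg <- sim_config(n_transcripts = 1, length_range = c(1000, 1000),
                    n_fragments = 10000, seed = 7)
  r <- simulate_fragment_coverage(models, 1, cfg)
  expect_equal(unname(r$counts), 10000L)
  # mean depth over the transcript ~ n * 2 * read_length / L
  expect_true(abs(mean(r$coverage[[1]]) - 2000) / 2000 < 0.05)

  expect_error(simulate_fragment_coverage(models, 0, cfg),
               "weights are zero")

  # multinomial consistency of per-transcript counts with weights
  models4 <- single_exon_models(rep(1000L, 4))
  w <- c(1, 2, 3, 4)
  cfg4 <- sim_config(n_transcripts = 4, length_range = c(1000, 1000),
                     n_fragments = 1e5, seed = 11)
  r4 <- simulate_fragment_coverage(models4, w, cfg4)
  expect_equal(sum(r4$counts), 1e5)
  gof <- stats::chisq.test(r4$counts, p = w / sum(w))
  expect_gt(gof$p.value, 0.001)
})

test_that("fragment coverage determinism holds for fixed config and seed", {
  models <- single_exon_models(rep(1200L, 3))
  cfg <- sim_config(n_transcripts = 3, length_range = c(1200, 1200),
                    n_fragments = 5000, seed = 21)
  expect_identical(simulate_fragment_coverage(models, 1, cfg),
                   simulate_fragment_coverage(models, 1, cfg))
})

test_that("dilution series scales conditions and injects recorded truth", {
  cfg <- sim_config(n_transcripts = 6, length_range = c(1700, 2000),
                    n_fragments = 4e4, seed = 5)
  tx <- generate_transcriptome(cfg)
  truth <- make_sim_truth(tx$models, n_hunc = 2, seed = 6)
  ser <- simulate_dilution_experiment(tx$models, truth, cfg)

  ratios <- dilution_conditions()
  clean <- setdiff(names(tx$models), truth$hunc$transcript_id)
  id <- clean[1]
  base <- ser$replicates[[1]]$ivt_only[[id]]
  for (cond in c("mix_1_1", "mix_1_2", "mix_1_10")) {
    expect_equal(ser$replicates[[1]][[cond]][[id]], base * ratios[[cond]])
  }
  expect_equal(ser$replicates[[1]]$mouse_only[[id]],
               numeric(length(base)))

  # injected interval carries the per-condition multipliers
  h <- truth$hunc[1, ]
  hv <- ser$replicates[[2]]$mix_1_1[[h$transcript_id]]
  bv <- ser$replicates[[2]]$ivt_only[[h$transcript_id]]
  inside <- (h$start + 1):h$end
  expect_equal(hv[inside],
               bv[inside] * ratios[["mix_1_1"]] * h$mix_1_1 / h$ivt_only)

  # out-of-bounds injection is a config error
  bad <- truth
  bad$hunc$end[1] <- tx$models[[bad$hunc$transcript_id[1]]]$length + 50L
  expect_error(simulate_dilution_experiment(tx$models, bad, cfg),
               "out of transcript bounds")
})

test_that("decoy transcripts get the recorded background signal", {
  cfg <- sim_config(n_transcripts = 8, length_range = c(1700, 2000),
                    n_fragments = 4e4, seed = 15)
  tx <- generate_transcriptome(cfg)
  truth <- make_sim_truth(tx$models, n_hunc = 1, n_decoys_fpkm = 1,
                          n_decoys_cov = 1, seed = 16)
  ser <- simulate_dilution_experiment(tx$models, truth, cfg)
  d <- truth$decoys
  fp <- d[d$type == "fpkm", ]
  cv <- d[d$type == "cov", ]
  expect_equal(ser$mouse_fpkm$rep1[ser$mouse_fpkm$transcript_id ==
                                     fp$transcript_id], 20)
  mcov <- ser$replicates[[1]]$mouse_only
  expect_true(all(mcov[[fp$transcript_id]] == fp$depth))
  spike <- mcov[[cv$transcript_id]]
  expect_true(all(spike[(cv$spike_start + 1):cv$spike_end] == cv$depth))
  expect_true(all(spike[-((cv$spike_start + 1):cv$spike_end)] == 0))
})
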