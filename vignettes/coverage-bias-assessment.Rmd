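---
title: "Assessing technical coverage bias with IVT control transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing technical coverage bias with IVT control transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtbias)
```

## The measurement problem

A pool of transcripts produced by in vitro transcription (IVT) from
fully sequenced cDNA templates has three properties that no biological
sample has: the sequence of every molecule is known, the splicing
structure is fixed, and every base of every transcript is present at the
same molarity. After library preparation and sequencing, the expected
read coverage along each transcript is therefore uniform up to
fragmentation randomness; any reproducible structure in the observed
coverage — peaks, valleys, end bias, sample-dependent swings — is a
technical artifact of library construction or sequencing. `ivtbias`
implements the statistics that quantify those artifacts, the detector
that localizes the most erratic ones, and a simulator that supplies the
fragmentation-only null and ground-truthed bias for validation.

The intended experimental design is a *dilution series*: the IVT pool is
sequenced alone and mixed with a complex background RNA from another
species (here called "mouse", after the common choice of mouse liver
total RNA behind human control transcripts) at decreasing IVT fractions,
plus a background-only library, in two replicates. Cross-species mixing
lets background reads that misalign to the control sequences be
recognized and filtered.

## Per-transcript uniformity statistics

All statistics operate on transcript-space coverage: genome-space
bedGraph tracks are projected through BED12 transcript models
(`project_to_transcript()`), walking exons 5′→3′ and ignoring introns.

* **FPKM** — fragments per kilobase of exon per million mapped
  fragments, `count / ((L/1000) · (total/10^6))`. Fragments (read
  pairs) are counted, not reads, and only uniquely mapped data should be
  supplied. A transcript counts as *detected* at FPKM ≥ 5.
* **Base-level CV** — sample standard deviation of per-base depths over
  their mean. The denominator `n − 1` convention is used; with thousands
  of bases per transcript the distinction from `n` is negligible.
* **Within-transcript fold change** — after trimming 200 bases from each
  end (fragmentation edge effects) and discarding transcripts shorter
  than 500 bases, per-base depths are sorted and the mean of the top
  decile bin is divided by the mean of the bottom decile bin
  (`floor(n/10)` bases each). A perfectly uniform transcript scores 1; a
  transcript whose 10% least-covered bases average zero scores `Inf`,
  which deliberately counts in every threshold bucket of
  `fold_change_summary()`. "Decile bin" is one of two defensible
  readings of averaging "across the 10th/90th percentile"; the other —
  means of all bases at or below/above the percentile cutoffs — is
  available as `fc_method = "percentile_cutoff"` and coincides with the
  default on the worked examples used in the tests.
* **Processivity ratio** — mean depth over the 85–95% span of the
  transcript divided by mean depth over the 5–15% span, computed on
  half-open base windows `[floor(0.85·L), floor(0.95·L))` and
  `[floor(0.05·L), floor(0.15·L))`; a 1,000-base transcript uses bases
  `[850, 950)` and `[50, 150)`. A fully processive polymerase yields a
  ratio near 1; premature termination depresses it. Transcripts at or
  below 5 FPKM are excluded.

## The hunc detector

A *hunc region* (high, unpredictable coverage) is an interval whose
depth, relative to the rest of its transcript, swings across the
dilution conditions far more than the transcript as a whole. The
detector (`score_dilution_replicate()` + `call_hunc_regions()`) works
per replicate:

1. Each condition's coverage vector is min-max normalized to `[0, 1]`
   so conditions at different sequencing depths are comparable; a
   constant (including all-zero) vector maps to all zeros.
2. At every base, the median absolute deviation (MAD, scale constant 1)
   is taken across the five conditions. The MAD is used for its
   outlier resistance; with five samples it ignores up to two
   discordant values.
3. MAD values are averaged over a 100-base window centered on each base
   (full windows only; the window at center `c` covers `[c−50, c+50)`).
   The first 300 and last 250 window scores of each transcript are
   trimmed as end/fragmentation artifacts, so only transcripts with
   more than `100 − 1 + 300 + 250` usable positions are scored.
4. The cutoff is the 95th percentile (type-7 quantile, the R default)
   of the window scores pooled over all transcripts of the replicate —
   one number per replicate, logged by the pipeline.
5. Runs of at least 20 contiguous above-cutoff windows become candidate
   intervals, spanning `[first_center − 50, last_center + 50)` clipped
   to the transcript.
6. Candidates are intersected across replicates: only intervals sharing
   at least one base in both replicates survive, and the emitted
   interval is the intersection. Abutting intervals do not count.
7. Two background filters remove misaligned background reads, with the
   failing filter recorded as provenance: transcripts with
   background-only FPKM ≥ 5 in either replicate lose all their
   candidates, and candidates whose mean background-only depth exceeds
   10 inside the region or in the 100 bases on either side are dropped.
   The strict `> 10` form is used (configurable), as the operational
   description of the filter.

`difference_regions()` searches for anomalies *not* shared between
replicates: per-window score differences (replicate 1 − replicate 2)
are pooled, the 2.5th/97.5th percentiles serve as cutoffs, runs of 20+
windows beyond either cutoff become candidates, the same background
filters apply, and candidates within 200 bases of a called hunc region
on the same transcript are discarded as mere extensions of it. On a
replicate-consistent experiment this list is empty.

Two design points deserve emphasis. The pooled (rather than
per-transcript) cutoff follows from the detector reporting a single
cutoff value per replicate. And the published procedure ends with a
manual inspection step; this package instead records per-region
provenance and emits score traces, making the calls reviewable without
pretending to automate judgement.

## The simulator and what it does (not) emulate

`simulate_fragment_coverage()` is a minimal fragmentation sampler: each
fragment picks a transcript with probability proportional to
`weight · length`, draws a Gaussian fragment length (default mean 250,
sd 25 — recorded in the config because the reference tooling does not
state its distribution) truncated to `[read_length, L]`, places its
start uniformly among eligible positions, and both 100-base read ends
increment depth. Sequencing error, intronic reads, polymorphisms,
quality values, polyA tails and GC-dependent amplification are all
deliberately absent: the null this simulator provides is *fragmentation
randomness only*. Per-transcript weights default to equal (an equimolar
pool); quantity-matched runs can seed them from a real FPKM table.

A consequence worth knowing: with starts uniform over the
`L − fl + 1` eligible positions, the interior plateau depth is
`2·rl·n/(L − fl + 1)`, slightly above the whole-transcript mean
`2·rl·n/L` that coverage conservation dictates; both ends ramp over
roughly a fragment length. The end-trimming built into the fold-change
and windowed-MAD statistics exists precisely because real fragmentation
produces the same ramps.

`simulate_dilution_experiment()` draws **one fragmentation realization
per replicate and shares it across the five conditions**, scaling by the
IVT fraction of each pool (1, 1/2, 1/3, 1/11, 0). This models the fact
that all conditions of a replicate derive from the same IVT RNA, and it
makes the null exact: conditions that are exact scalar multiples
normalize to identical vectors, the per-base MAD is identically zero,
and the detector provably calls nothing on un-injected transcripts.
Real data additionally carries independent per-condition sampling
noise, so a real-data MAD baseline is positive and the 95th-percentile
cutoff sits in a continuous score distribution. Passing the synthetic
recovery tests therefore demonstrates the machinery (normalization,
scoring, run detection, intersection, filters) end to end, but says
nothing about the false-positive rate under real between-library noise
— that is a property of the data, controlled in practice by the
replicate-intersection requirement.

Injected anomalies are multiplicative on depth (cheaper than
resampling reads and sufficient for detector testing): each anomaly
carries a per-condition multiplier ladder, geometric from 1 down to
`1/amplitude`, randomly assigned to the four IVT-containing conditions.
Two constraints shape this choice:

* With five conditions, one of which (background-only) is ~0 on control
  transcripts, a constant-1 MAD masks up to two deviating values. An
  anomaly expressed in a *single* condition is therefore mathematically
  invisible to this statistic — at least two IVT conditions must
  deviate, which matches the observed phenomenology of such regions
  (coverage swinging across *all* dilutions).
* Multipliers never exceed 1. An interval amplified above the
  transcript's maximum becomes the new min-max denominator, rescaling
  the whole profile of that condition and smearing the anomaly over the
  entire transcript; condition-specific local *suppression* — the
  depletion-type bias the detector targets — stays localized.

Decoy transcripts exercise the background filters: an "fpkm" decoy gets
uniform background coverage and a recorded background FPKM of 20
(tripping the FPKM ≥ 5 filter), a "cov" decoy gets a localized
background spike of depth 30 over its anomaly with transcript-level
background FPKM below 5 (tripping only the regional coverage filter).

## Numerical choices

* Min-max normalized profiles are quantized to 9 decimal places.
  Exactly proportional profiles then normalize to *exactly* equal
  vectors regardless of floating-point rounding of the scale factor.
  Without this, ~1e−16 rounding noise is smoothed by the 100-base
  window into long, correlated pseudo-runs above a degenerate cutoff.
  Genuine anomaly MADs are of order 0.1, nine orders above the grid.
* Quantiles use type 7 (R's default) everywhere a cutoff is defined.
* Extreme-set construction breaks metric ties lexicographically by
  transcript id, making the sets deterministic.
* The expression filters follow their stated inequalities exactly:
  detection is `≥ 5` FPKM, the association analysis *excludes* `≤ 5`,
  the processivity filter excludes `≤ 5`, and the background-region
  coverage filter drops `> 10`.
* `rank_sum_test()` is the unpaired Mann–Whitney test: the two extreme
  sets are disjoint transcript groups, not paired observations, so the
  unpaired form is correct even though box-plot conventions sometimes
  label such comparisons as signed-rank tests. Exact enumeration is
  used for `n + m ≤ 12` without ties; otherwise the normal
  approximation with continuity correction.
* Hexamer entropy is reported in bits (base-2 logarithm, maximum
  `log2(4^6) = 12`); any base preserves the ordering that the
  rank-based association tests consume.
* Local alignment to rRNA uses Smith–Waterman scores (match +2,
  mismatch −1, linear gap −2) rather than BLAST e-values: scores are
  exactly reproducible and oracle-verifiable, while e-values depend on
  external tool versions and database statistics. The comparison is
  strand-agnostic. The shipped references for testing are synthetic
  rRNA-like sequences; users should supply the real 45S and 5S rRNA
  FASTA for production use.
* The coverage-drop score normalizes each library so its pooled mean
  depth over all transcripts is 1 before comparing per-transcript
  means; this is a reconstruction of a library-size correction whose
  full published procedure is not available, and is flagged as such.

## Problem sizes in the test suite

The shipped tests validate at desk scale, chosen to finish in minutes:
null fold-change and processivity on 10 seeds × 200 transcripts
(lengths 600–3,000, 50-base reads so the shortest transcripts remain
valid configurations, ~1,000× mean depth, the depth at which the
reference simulated datasets were generated); detector recovery on
20 seeds × 12 transcripts with 3 anomalies and 2 decoys each
(amplitude 5, width 160); rank-sum calibration on 10,000 null pairs of
n = m = 100; oracle-equivalence suites on 100 random instances per
statistic. `scripts/acceptance.R` re-runs the same computations from an
installed copy of the package.

## Running on real data

The full-scale analysis consumes, per sample: a bedGraph coverage track
of uniquely aligned reads, BED12 models of the control transcripts, a
transcript-level FPKM table, and the control-transcript FASTA plus rRNA
references. The workflow is: read models (`read_gene_models()`),
exclude multi-locus and overlapping transcripts
(`exclude_transcripts()`, `overlapping_transcripts()`), project each
sample's track (`project_to_transcript()`), assemble the two replicate
dilution series, then run the metric, detection and association stages
exactly as `run_all()` chains them for simulated data. Alignment itself
is out of scope — any splice-aware aligner that emits unique-read
coverage in bedGraph works.

## Limitations

* The simulator's shared-noise dilution model understates
  between-condition variability of real libraries (see above).
* Coverage inputs are treated as raw unique-read depth; if normalized
  tracks are supplied, FPKM-dependent filters need externally computed
  FPKM values (fractional depths are accepted throughout).
* No motif analysis is attempted around called regions, and no
  correction of the measured biases is offered — the package measures
  associations, it does not remove them.
* No multiple-testing correction is applied in the association report;
  all raw p-values are emitted so users can adjust across whichever
  family of tests they assemble.
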