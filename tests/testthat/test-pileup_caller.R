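test_that("pileup tallies reads and resolves mate overlaps by quality", {
  ref <- toy_ref(1200, seed = 20)
  # 10 identical error-free reads covering 1..300
  aln <- mk_aln(ref, start = rep(1L, 10), seq = rep(ref_window(ref, 1, 300), 10))
  p <- build_pileup(aln, ref)
  expect_equal(p$depth[1:300], rep(10L, 300))
  expect_equal(p$depth[301:1200], rep(0L, 1200 - 300))
  ref_chars <- strsplit(ref_window(ref, 1, 300), "")[[1L]]
  expect_equal(p$counts[cbind(1:300, match(ref_chars, c("A", "C", "G", "T")))],
               rep(10L, 300))

  # overlapping mates disagreeing at position 150: Q35 base beats Q20 base,
  # and the fragment contributes exactly once in the overlap
  s1 <- ref_window(ref, 100, 100)
  s2 <- ref_window(ref, 120, 100)
  disagree <- other_base(substring(ref$sequence, 150, 150))
  s2 <- mutate_at(s2, 150 - 120 + 1, disagree)
  aln2 <- mk_aln(ref, start = c(100L, 120L), seq = c(s1, s2),
                 qual = c(qstr(100, 35), qstr(100, 20)),
                 strand = c("+", "-"), frag = c(1L, 1L), mate = c(1L, 2L))
  p2 <- build_pileup(aln2, ref, min_base_q = 15)
  col <- pileup_column(p2, 150)
  expect_equal(col$depth, 1L)
  expect_equal(unname(col$counts[substring(ref$sequence, 150, 150)]), 1L)
  expect_equal(unname(col$counts[disagree]), 0L)
  expect_equal(p2$depth[120:199], rep(1L, 80)) # whole overlap single-counted

  # low-quality bases are excluded entirely
  p3 <- build_pileup(aln2, ref, min_base_q = 25)
  expect_equal(p3$depth[110], 1L) # Q35 mate only
  expect_equal(p3$depth[205], 0L) # Q20 mate only region
})

test_that("pileup equals a naive per-read tally when no mates overlap", {
  ref <- toy_ref(1200, seed = 21)
  set.seed(22)
  starts <- sample(1:1100, 20)
  seqs <- ref_window(ref, starts, 80)
  # sprinkle a few mismatches
  for (i in 1:10) {
    off <- sample(80, 1)
    seqs[i] <- mutate_at(seqs[i], off,
                         other_base(substring(seqs[i], off, off)))
  }
  aln <- mk_aln(ref, starts, seqs)
  p <- build_pileup(aln, ref)
  naive <- matrix(0L, nrow = 1200, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(starts)) {
    for (o in 1:80) {
      b <- substring(seqs[i], o, o)
      naive[starts[i] + o - 1L, b] <- naive[starts[i] + o - 1L, b] + 1L
    }
  }
  expect_equal(unname(p$counts), unname(naive))

  # reads beyond the reference bounds are an upstream invariant breach
  expect_error(build_pileup(mk_aln(ref, 1190L, ref_window(ref, 1, 50)), ref),
               "exceeds reference bounds")
})

test_that("consensus takes the modal allele with reference tie-breaking", {
  ref <- toy_ref(1200, seed = 23)
  rb <- substring(ref$sequence, 50, 50)
  alt <- other_base(rb)
  reads <- c(rep(ref_window(ref, 1, 100), 2),
             rep(mutate_at(ref_window(ref, 1, 100), 50, alt), 2))
  # 2 ref / 2 alt at position 50: exact tie retains the reference base
  p <- build_pileup(mk_aln(ref, rep(1L, 4), reads), ref)
  cons <- call_consensus(p)
  expect_equal(substring(cons$sequence, 50, 50), rb)
  # zero-depth positions keep the reference with support 0
  expect_equal(substring(cons$sequence, 500, 500),
               substring(ref$sequence, 500, 500))
  expect_equal(cons$support[500], 0)
  expect_identical(cons$sequence == ref$sequence, TRUE)

  # an 82% alternative allele becomes the consensus base
  reads82 <- c(rep(mutate_at(ref_window(ref, 1, 100), 50, alt), 82),
               rep(ref_window(ref, 1, 100), 18))
  cons82 <- call_consensus(build_pileup(mk_aln(ref, rep(1L, 100), reads82),
                                        ref))
  expect_equal(substring(cons82$sequence, 50, 50), alt)
  expect_equal(cons82$support[50], 0.82)
})

test_that("call_variants enforces frequency, depth and count thresholds", {
  ref <- toy_ref(1200, seed = 24)
  window <- ref_window(ref, 1, 100)
  rb <- function(pos) substring(ref$sequence, pos, pos)
  alt10 <- other_base(rb(10))
  alt20 <- other_base(rb(20))
  alt30 <- other_base(rb(30))
  # 200 fragments over 1..100: pos 10 at 8%, pos 20 at 0.5%, pos 30 at 2%
  reads <- rep(window, 200)
  reads[1:16] <- mutate_at(reads[1:16], 10, alt10)
  reads[17] <- mutate_at(reads[17], 20, alt20)
  reads[18:21] <- mutate_at(reads[18:21], 30, alt30)
  p <- build_pileup(mk_aln(ref, rep(1L, 200), reads), ref)
  cons <- call_consensus(p)
  calls <- call_variants(p, cons)
  # manual evaluation: 16/200 = 8% and 4/200 = 2% pass; 1/200 = 0.5% fails
  expect_equal(calls$pos, c(10L, 30L))
  expect_equal(calls$alt, c(alt10, alt30))
  expect_equal(calls$freq, c(0.08, 0.02))
  expect_equal(calls$depth, c(200L, 200L))

  # depth 99 never qualifies under the 100x rule, even at 50% frequency
  half <- c(rep(mutate_at(window, 10, alt10), 50), rep(window, 49))
  p99 <- build_pileup(mk_aln(ref, rep(1L, 99), half), ref)
  expect_equal(nrow(call_variants(p99, call_consensus(p99))), 0L)

  # raising min_freq can only shrink the call set
  n_prev <- Inf
  for (mf in c(0.01, 0.05, 0.1, 0.5)) {
    n <- nrow(call_variants(p, cons, min_freq = mf))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_error(call_variants(p, cons, min_freq = 0), "strictly between")
})

test_that("the two-SD agreement filter matches direct computation", {
  # zero-SD: six identical values pass
  expect_true(consensus_filter(rep(0.05, 6)))
  # tight spread: all within mean +/- 2 sd by direct mean/SD computation
  x <- c(5.0, 5.1, 4.9, 5.05, 4.95, 5.0)
  expect_equal(all(abs(x - mean(x)) <= 2 * sd(x)), TRUE)
  expect_true(consensus_filter(x))
  # single missing (0) among five detections: 0 falls outside the band
  y <- c(5, 5, 5, 5, 5, 0)
  expect_equal(any(abs(y - mean(y)) > 2 * sd(y)), TRUE)
  expect_false(consensus_filter(y))
  # scale invariance
  set.seed(30)
  for (i in 1:20) {
    z <- runif(6)
    expect_identical(consensus_filter(z), consensus_filter(z * 137.5))
  }
  expect_error(consensus_filter(0.5), "at least 2")
})

test_that("multi-configuration calling reduces to single-config when degenerate", {
  ref <- toy_ref(1500, seed = 25)
  v <- make_planted_variants(ref, c(0.10, 0.30), positions = c(400, 800))
  set.seed(26)
  pop <- build_population_independent(ref, v, n_haplotypes = 100L)
  cfg <- sim_config(read_length = 100, insert_mean = 250, insert_sd = 20,
                    mean_coverage = 400, substitution_error_rate = 0,
                    seed = 27)
  aln <- align_read_set(simulate_reads(pop, cfg), ref)

  grid1 <- data.frame(min_base_q = 20L, min_alt_count = 2L)
  expect_message(single <- run_multi_config(aln, ref, grid = grid1),
                 "single configuration")
  dup6 <- grid1[rep(1L, 6L), ]
  six <- run_multi_config(aln, ref, grid = dup6)
  expect_equal(six$pos, single$pos)
  expect_equal(six$alt, single$alt)
  expect_equal(six$freq, single$freq)
  expect_true(all(six$filter == "PASS"))
  expect_true(all(six$nconf == 6L))

  # default grid recovers both planted sites
  calls <- run_multi_config(aln, ref)
  pass <- calls[calls$filter == "PASS", ]
  expect_equal(pass$pos, v$pos)
  expect_equal(pass$alt, v$alt)
  expect_equal(dim(attr(calls, "estimates")), c(nrow(calls), 6L))
})

test_that("sites detected by a minority of configurations are excluded", {
  ref <- toy_ref(1200, seed = 28)
  rb <- substring(ref$sequence, 60, 60)
  alt <- other_base(rb)
  window <- ref_window(ref, 1, 120)
  # 3 alt reads of 150: 2% -> passes min_alt_count 2 but fails 4, so the
  # six-value vector is {f,f,f,0,0,0}; with depth high the mean freq is f/2
  reads <- c(rep(mutate_at(window, 60, alt), 3), rep(window, 147))
  aln <- mk_aln(ref, rep(1L, 150), reads)
  calls <- run_multi_config(aln, ref)
  row <- calls[calls$pos == 60L, ]
  expect_equal(row$nconf, 3L)
  expect_equal(row$freq, mean(c(rep(3 / 150, 3), 0, 0, 0)))
  expect_equal(row$filter, "low_freq")
})

test_that("substitution classes follow transition/transversion rules", {
  cls <- classify_substitution(c("A", "G", "A", "T", "C", "C"),
                               c("G", "A", "C", "C", "T", "G"))
  expect_equal(cls$type, c("transition", "transition", "transversion",
                           "transition", "transition", "transversion"))
  expect_equal(cls$spectrum, c("AT_to_GC", "GC_to_AT", "other", "AT_to_GC",
                               "GC_to_AT", "other"))
  expect_error(classify_substitution("A", "A"), "must differ")
})

test_that("VCF output round-trips and parses as VCF 4.2", {
  ref <- toy_ref(1500, seed = 29)
  v <- make_planted_variants(ref, 0.2, positions = 700)
  set.seed(29)
  pop <- build_population_independent(ref, v, n_haplotypes = 100L)
  cfg <- sim_config(read_length = 100, insert_mean = 250, insert_sd = 20,
                    mean_coverage = 300, substitution_error_rate = 0,
                    seed = 30)
  aln <- align_read_set(simulate_reads(pop, cfg), ref)
  calls <- run_multi_config(aln, ref)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  back <- read_vcf_calls(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$freq, calls$freq, tolerance = 1e-6)
  expect_equal(back$filter, calls$filter)

  vcf <- VariantAnnotation::readVcf(path, genome = "toy")
  expect_equal(nrow(vcf), nrow(calls))
  expect_equal(unname(GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))),
               calls$pos)
  expect_equal(VariantAnnotation::info(vcf)$DP, calls$depth)
})
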