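test_that("reference and variant containers validate their invariants", {
  expect_error(reference_genome(strrep("A", 100)), "1000")
  expect_error(reference_genome(paste0(strrep("A", 1200), "N")), "A/C/G/T")
  ref <- toy_ref(2000)
  expect_equal(ref$length, 2000L)

  v <- make_planted_variants(ref, c(0.05, 0.2), positions = c(500, 900))
  expect_equal(v$pos, c(500L, 900L))
  expect_true(all(v$ref != v$alt))
  expect_equal(substring(ref$sequence, v$pos, v$pos), v$ref)

  # out-of-range position and weight-sum violations are rejected
  bad <- data.frame(pos = 99999L, ref = "A", alt = "G", freq = 0.1)
  expect_error(build_population(ref, bad, list(list(variants = 1L, weight = 1))),
               "out of reference range")
  expect_error(
    build_population(ref, v, list(list(variants = 1L, weight = 0.5))),
    "sum to 1")
})

test_that("population truth matches closed form and brute-force enumeration", {
  ref <- toy_ref(2000)
  v <- make_planted_variants(ref, c(0.05, 0.05, 0.1),
                             positions = c(400, 700, 1100))

  # single variant-free haplotype: all site frequencies 0
  empty <- build_population(ref, v[0, ], list(list(variants = integer(0),
                                                   weight = 1)))
  expect_equal(nrow(empty$truth$frequencies), 0L)

  # perfect linkage by construction: {v1,v2} w=0.05, {} w=0.95
  pop <- build_population(ref, v[1:2, ], list(
    list(variants = c(1L, 2L), weight = 0.05),
    list(variants = integer(0), weight = 0.95)))
  expect_equal(pop$truth$frequencies$freq, c(0.05, 0.05))
  expect_equal(pop$truth$cooccurrence$cooccurrence_pct, 100)

  # mutually exclusive variants of one codon: 8.31% / 1.44%, never together
  pop2 <- build_population(ref, v[1:2, ], list(
    list(variants = 1L, weight = 0.0831),
    list(variants = 2L, weight = 0.0144),
    list(variants = integer(0), weight = 0.9025)))
  expect_equal(pop2$truth$frequencies$freq, c(0.0831, 0.0144))
  expect_equal(pop2$truth$cooccurrence$p_both, 0)
  expect_equal(pop2$truth$cooccurrence$cooccurrence_pct, 0)

  # closed form equals brute-force enumeration over haplotypes
  set.seed(5)
  pop3 <- build_population_independent(ref, v, n_haplotypes = 200L)
  cc <- pop3$truth$cooccurrence
  for (r in seq_len(nrow(cc))) {
    expect_equal(cc$cooccurrence_pct[r], oracle_cooc(pop3, cc$i[r], cc$j[r]))
  }
  # realised marginals exact at pool resolution
  expect_equal(pop3$truth$frequencies$freq,
               round(c(0.05, 0.05, 0.1) * 200) / 200)
})

test_that("simulated reads are exact haplotype substrings at error rate 0", {
  ref <- toy_ref(3000, seed = 11)
  v <- make_planted_variants(ref, 0.999, positions = 1500)
  pop <- build_population(ref, v, list(
    list(variants = 1L, weight = 0.999),
    list(variants = integer(0), weight = 0.001)))
  cfg <- sim_config(read_length = 100, insert_mean = 260, insert_sd = 20,
                    mean_coverage = 30, substitution_error_rate = 0, seed = 3)
  reads <- simulate_reads(pop, cfg)
  alt_genome <- ref$sequence
  substr(alt_genome, 1500, 1500) <- v$alt
  for (i in seq_along(reads$id)) {
    hapseq <- if (pop$carriers[1L, reads$truth$haplotype[i]])
      alt_genome else ref$sequence
    s <- reads$truth$start[i]
    ins <- reads$truth$insert[i]
    expect_identical(reads$r1_seq[i], substring(hapseq, s, s + 99))
    expect_identical(
      reads$r2_seq[i],
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substring(hapseq, s + ins - 100, s + ins - 1)))))
  }
})

test_that("sequenced base mass and planted-site allele counts match truth", {
  ref <- toy_ref(10000, seed = 21)
  v <- make_planted_variants(ref, 0.40, positions = 5000)
  set.seed(21)
  pop <- build_population_independent(ref, v, n_haplotypes = 1000L)
  cfg <- sim_config(read_length = 300, insert_mean = 600, insert_sd = 60,
                    mean_coverage = 1000, substitution_error_rate = 0,
                    seed = 13)
  reads <- simulate_reads(pop, cfg)
  total_bases <- sum(nchar(reads$r1_seq)) + sum(nchar(reads$r2_seq))
  expect_lt(abs(total_bases - 1000 * 10000), 0.05 * 1000 * 10000)

  # fragments covering the site from carrier haplotypes must show the alt;
  # binomial check at 3 SDs against the truth table
  covers <- reads$truth$start <= 5000 &
    reads$truth$start + reads$truth$insert - 1L >= 5000
  n_cov <- sum(covers)
  n_alt <- sum(covers & pop$carriers[1L, reads$truth$haplotype])
  expect_lt(abs(n_alt - 0.4 * n_cov), 3 * sqrt(n_cov * 0.4 * 0.6))

  # and the emitted read bases agree with the truth labels
  off <- 5000 - reads$truth$start[covers] + 1L
  base1 <- substr(reads$r1_seq[covers], off, off)
  is_alt_hap <- pop$carriers[1L, reads$truth$haplotype[covers]]
  first_mate_covers <- off <= 300
  expect_true(all(base1[first_mate_covers & is_alt_hap] == v$alt))
  expect_true(all(base1[first_mate_covers & !is_alt_hap] == v$ref))
})

test_that("read simulation is byte-identical under a fixed seed", {
  ref <- toy_ref(2000, seed = 31)
  v <- make_planted_variants(ref, 0.1, positions = 1000)
  set.seed(31)
  pop <- build_population_independent(ref, v, n_haplotypes = 100L)
  cfg <- sim_config(read_length = 80, insert_mean = 200, insert_sd = 15,
                    mean_coverage = 50, substitution_error_rate = 0.01,
                    seed = 99)
  a <- simulate_reads(pop, cfg)
  b <- simulate_reads(pop, cfg)
  expect_identical(a$r1_seq, b$r1_seq)
  expect_identical(a$r2_seq, b$r2_seq)
  expect_identical(a$truth, b$truth)

  d1 <- tempfile(); d2 <- tempfile()
  write_read_set(a, d1, "x"); write_read_set(b, d2, "x")
  expect_identical(readLines(file.path(d1, "x_R1.fastq")),
                   readLines(file.path(d2, "x_R1.fastq")))
})

test_that("co-infection pools label sources and reject degenerate mixtures", {
  ref_a <- toy_ref(1200, seed = 41, id = "A")
  ref_b <- toy_ref(1200, seed = 42, id = "B")
  pop_a <- build_population(ref_a, make_planted_variants(ref_a, numeric(0)),
                            list(list(variants = integer(0), weight = 1)))
  pop_b <- build_population(ref_b, make_planted_variants(ref_b, numeric(0)),
                            list(list(variants = integer(0), weight = 1)))
  cfg <- sim_config(read_length = 60, insert_mean = 150, insert_sd = 10,
                    mean_coverage = 500, substitution_error_rate = 0,
                    seed = 5)
  pool <- simulate_coinfection_pool(pop_a, pop_b, 0.5, cfg)
  n <- length(pool$id)
  expect_equal(n, round(500 * 2400 / 120))
  n_a <- sum(pool$truth$source == "A")
  expect_lt(abs(n_a - 0.5 * n), 3 * sqrt(n * 0.25))

  expect_error(simulate_coinfection_pool(pop_a, pop_b, 1.0, cfg),
               "strictly between")
  expect_error(simulate_coinfection_pool(pop_a, pop_a, 0.5, cfg),
               "distinct ids")
})

test_that("truth tables round-trip through TSV", {
  ref <- toy_ref(1500, seed = 51)
  v <- make_planted_variants(ref, c(0.2, 0.3), positions = c(300, 800))
  pop <- build_population(ref, v, list(
    list(variants = 1L, weight = 0.2),
    list(variants = 2L, weight = 0.3),
    list(variants = integer(0), weight = 0.5)))
  d <- tempfile()
  write_population_truth(pop, d)
  tv <- data.table::fread(file.path(d, "truth_variants.tsv"),
                          data.table = FALSE)
  expect_equal(tv$freq, c(0.2, 0.3))
  hap <- data.table::fread(file.path(d, "truth_haplotypes.tsv"),
                           data.table = FALSE)
  expect_equal(hap$weight, c(0.2, 0.3, 0.5))
})
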