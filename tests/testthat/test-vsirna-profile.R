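# shared mid-size fixture: linear genome + 20k-read Dicer-like population
vs_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- gen_viral_genome(10002, 0.45, "linear", "nyamivirus",
                             c(987, 1428, 2001), seed = 7)
      p <- srna_sim_params(n_viral = 20000, n_background = 5000,
                           sense_fraction = 0.5, au5_fraction = 0.8, seed = 11)
      sim <- gen_vsirna_reads(tr, p)
      m <- map_reads(build_index(tr$genome), length_filter(sim$reads))
      cache <<- list(tr = tr, p = p, sim = sim, mapped = m)
    }
    cache
  }
})

test_that("length filtering keeps the inclusive 18-30 nt window in order", {
  reads <- seq_set(c("a", "b", "c", "d"),
                   vapply(c(17, 18, 30, 31), random_dna, ""))
  kept <- length_filter(reads)
  expect_identical(kept$id, c("b", "c"))
  expect_identical(nrow(length_filter(seq_set(character(0), character(0)))), 0L)
  only21 <- length_filter(seq_set(c("x", "y"), c(random_dna(21), random_dna(22))),
                          lo = 21, hi = 21)
  expect_identical(only21$id, "x")
})

test_that("size distribution counts by length and strand with smallest-length tie-break", {
  g <- genome(random_dna(300), "linear")
  idx <- build_index(g)
  read19 <- rev_comp(substr(g$seq, 50, 68))
  m <- map_reads(idx, seq_set("r", read19))
  sd1 <- size_strand_distribution(m)
  expect_identical(sum(sd1$counts), 1)
  expect_identical(unname(sd1$counts["19", "-"]), 1)
  expect_identical(sd1$mode_length, 19L)
  # tie: one 20-mer and one 22-mer -> mode resolves to 20
  m2 <- map_reads(idx, seq_set(c("a", "b"),
                               c(substr(g$seq, 10, 29), substr(g$seq, 100, 121))))
  expect_identical(size_strand_distribution(m2)$mode_length, 20L)
})

test_that("simulated population recovers mode 21, strand balance and A/U bias", {
  fx <- vs_fixture()
  m <- fx$mapped
  sdist <- size_strand_distribution(m)
  expect_identical(sdist$mode_length, 21L)
  # sense fraction within 3 binomial sigma of the planted 0.5
  n <- sum(sdist$counts)
  sense <- sum(sdist$counts[, "+"]) / n
  expect_lt(abs(sense - 0.5), 3 * sqrt(0.25 / n))
  # per-length class weights match the planted size distribution
  marg <- rowSums(sdist$counts) / n
  expect_true(all(abs(marg - unname(fx$p$size_probs)) < 0.01))
  # 5' A/U at 21 nt: equals the truth table exactly, and sits within 3
  # sigma of the resampling mechanism's expectation au5 + (1-au5)*baseline
  fp <- five_prime_preference(m, 21)
  truth21 <- fx$sim$truth[fx$sim$truth$viral & fx$sim$truth$length == 21, ]
  expect_equal(fp$au_fraction, mean(truth21$first_base %in% c("A", "U")),
               tolerance = 1e-12)
  base_at <- mean(strsplit(fx$tr$genome$seq, "")[[1]] %in% c("A", "T"))
  expected <- 0.8 + 0.2 * base_at
  expect_lt(abs(fp$au_fraction - expected),
            3 * sqrt(expected * (1 - expected) / nrow(truth21)) + 0.01)
  expect_equal(sum(fp$fractions), 1, tolerance = 1e-9)
})

test_that("5' preference uses the read's own first base and flags empty classes", {
  g <- genome(paste0("GG", random_dna(298)), "linear")
  idx <- build_index(g)
  m <- map_reads(idx, seq_set("r", substr(g$seq, 1, 21)))
  fp <- five_prime_preference(m, 21)
  expect_identical(unname(fp$fractions["G"]), 1)
  # minus-strand read: first base is the complement of the genome base at
  # position + length - 1
  read <- rev_comp(substr(g$seq, 40, 60))
  m2 <- map_reads(idx, seq_set("r2", read))
  fp2 <- five_prime_preference(m2, 21)
  b <- chartr("ACGT", "UGCA", substr(g$seq, 60, 60))
  expect_identical(unname(fp2$fractions[b]), 1)
  # no reads of the focal length
  fp0 <- five_prime_preference(m2, 25)
  expect_true(all(is.na(fp0$fractions)))
  expect_identical(fp0$n, 0)
})

test_that("positional profile deposits weight at strand-resolved 5' ends", {
  g <- genome(random_dna(300), "linear")
  idx <- build_index(g)
  m <- map_reads(idx, seq_set("plus", substr(g$seq, 100, 120)))
  pp <- positional_profile(m)
  expect_identical(pp$plus[100], 1)
  expect_identical(sum(pp$plus), 1)
  m2 <- map_reads(idx, seq_set("minus", rev_comp(substr(g$seq, 100, 120))))
  pp2 <- positional_profile(m2)
  expect_identical(pp2$minus[120], 1)
  # circular wrap: a minus read wrapping the origin has its 5' end modulo L
  gc <- genome(random_dna(300), "circular")
  idxc <- build_index(gc)
  wrap <- rev_comp(genome_substr(gc, 290, 21))  # covers 290..300,1..10
  ppw <- positional_profile(map_reads(idxc, seq_set("w", wrap)))
  expect_identical(ppw$minus[10], 1)
})

test_that("profile totals are conserved across summaries", {
  fx <- vs_fixture()
  m <- fx$mapped
  sdist <- size_strand_distribution(m)
  pp <- positional_profile(m)
  expect_equal(sum(sdist$counts), sum(m$placements$weight))
  expect_equal(pp$total, sum(m$placements$weight))
})

test_that("relabeling strands by complementing the genome leaves marginals invariant", {
  tr <- gen_viral_genome(4002, 0.5, "linear", "nyamivirus",
                         c(450, 450, 450), seed = 15)
  sim <- gen_vsirna_reads(tr, srna_sim_params(n_viral = 2000, n_background = 0,
                                              sense_fraction = 0.4, seed = 8))
  m1 <- map_reads(build_index(tr$genome), sim$reads)
  flipped <- genome(rev_comp(tr$genome$seq), "linear")
  m2 <- map_reads(build_index(flipped), sim$reads)
  s1 <- size_strand_distribution(m1)
  s2 <- size_strand_distribution(m2)
  expect_equal(rowSums(s1$counts), rowSums(s2$counts))
  expect_equal(unname(s1$counts[, "+"]), unname(s2$counts[, "-"]))
  f1 <- five_prime_preference(m1)
  f2 <- five_prime_preference(m2)
  expect_equal(f1$fractions, f2$fractions)
})

test_that("planted hotspots are called and flat profiles are not", {
  tr <- gen_viral_genome(4002, 0.5, "linear", "nyamivirus",
                         c(450, 450, 450), seed = 15)
  hs <- data.frame(position = 500L, weight = 200)
  sim <- gen_vsirna_reads(tr, srna_sim_params(n_viral = 20000, n_background = 0,
                                              hotspots = hs, seed = 21))
  m <- map_reads(build_index(tr$genome), sim$reads)
  pp <- positional_profile(m)
  expect_gt(pp$plus[500] + pp$minus[500],
            5 * (pp$total / length(pp$plus)))
  called <- call_hotspots(pp, window = 50, z = 3)
  expect_true(any(called$window_start <= 500 & called$window_start > 450))
  # all-zero profile
  empty <- positional_profile(map_reads(build_index(tr$genome),
                                        seq_set(character(0), character(0))))
  expect_identical(nrow(call_hotspots(empty)), 0L)
})

test_that("flat multinomial profiles rarely trigger hotspot calls", {
  # null calibration on synthetic uniform profiles (no mapping involved):
  # with ~200 windows per run, a mean + 3*sd threshold admits an occasional
  # upper-tail window, so the null is characterized as rare-and-small at
  # z = 3 and essentially silent at z = 4
  L <- 5000L
  calls3 <- integer(100)
  calls4 <- integer(100)
  for (s in 1:100) {
    set.seed(s)
    prof <- structure(list(plus = as.numeric(tabulate(sample.int(L, 5000, TRUE), L)),
                           minus = as.numeric(tabulate(sample.int(L, 5000, TRUE), L)),
                           total = 10000),
                      class = "positional_profile")
    calls3[s] <- nrow(call_hotspots(prof, window = 50, z = 3))
    calls4[s] <- nrow(call_hotspots(prof, window = 50, z = 4))
  }
  expect_lt(mean(calls3), 1)
  expect_gte(sum(calls3 == 0L), 60L)
  expect_lte(max(calls3), 5L)
  expect_gte(sum(calls4 == 0L), 95L)
})

test_that("the vsiRNA report is complete, consistent and byte-deterministic", {
  fx <- vs_fixture()
  rep <- summarize_vsirna(fx$sim$reads, fx$mapped)
  expect_lte(rep$totals$mapped_reads, rep$totals$in_range_reads)
  expect_lte(rep$totals$in_range_reads, rep$totals$input_reads)
  expect_identical(rep$totals$mapped_reads, 20000L)
  expect_identical(rep$size_distribution$mode_length, 21L)
  d1 <- tempfile(); d2 <- tempfile()
  write_vsirna_report(rep, d1)
  write_vsirna_report(rep, d2)
  expect_identical(readLines(file.path(d1, "vsirna_report.json")),
                   readLines(file.path(d2, "vsirna_report.json")))
  expect_true(all(c("size_dist.tsv", "fiveprime.tsv", "positional_plus.tsv",
                    "positional_minus.tsv", "hotspots.tsv") %in% list.files(d1)))
  # empty input does not crash
  g <- genome(random_dna(300), "linear")
  e <- seq_set(character(0), character(0))
  rep0 <- summarize_vsirna(e, map_reads(build_index(g), e))
  expect_identical(rep0$totals$input_reads, 0L)
  expect_true(is.na(rep0$sense_fraction))
})
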