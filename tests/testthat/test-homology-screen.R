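test_that("self-alignment scores the BLOSUM62 diagonal at 100% identity", {
  sc <- scoring_matrix()
  set.seed(2)
  p <- random_aa(50)
  al <- smith_waterman(p, p, sc)
  expect_equal(al$identity_pct, 100)
  diag_sum <- sum(vapply(strsplit(p, "")[[1]],
                         function(a) sc$matrix[a, a], 0))
  expect_equal(al$score, diag_sum)
  expect_identical(al$q_start, 1L)
  expect_identical(al$q_end, 50L)
})

test_that("local alignment equals an independent affine DP on random pairs", {
  sc <- scoring_matrix()
  set.seed(14)
  for (i in 1:60) {
    a <- random_aa(sample(8:45, 1))
    b <- random_aa(sample(8:45, 1))
    expect_equal(smith_waterman(a, b, sc)$score,
                 affine_dp_score(a, b, sc$matrix, 11, 1, local = TRUE))
  }
  # score symmetry under a symmetric matrix
  for (i in 1:20) {
    a <- random_aa(30); b <- random_aa(30)
    expect_equal(smith_waterman(a, b, sc)$score, smith_waterman(b, a, sc)$score)
  }
})

test_that("alignment identity recovers planted mutation levels", {
  sc <- scoring_matrix()
  set.seed(5)
  p <- random_aa(300)
  for (ti in c(0.30, 0.47, 0.80)) {
    q <- mutate_protein(p, ti, seed = 31)
    al <- smith_waterman(p, q, sc)
    expect_lt(abs(al$identity_pct - 100 * ti), 3)
  }
})

test_that("Karlin-Altschul statistics follow the closed form", {
  # raw score chosen so the bit score is exactly 40
  s40 <- (40 * log(2) + log(0.041)) / 0.267
  ka <- karlin_altschul_evalue(s40, 1000, 1000)
  expect_equal(ka$bit_score, 40)
  expect_equal(ka$e_value, 1e6 * 2^-40, tolerance = 1e-12)
  # doubling n doubles E at fixed S
  expect_equal(karlin_altschul_evalue(100, 500, 800)$e_value * 2,
               karlin_altschul_evalue(100, 500, 1600)$e_value)
  # monotone decreasing in S
  expect_lt(karlin_altschul_evalue(120, 500, 500)$e_value,
            karlin_altschul_evalue(100, 500, 500)$e_value)
  expect_error(karlin_altschul_evalue(50, 0, 10), "positive")
  expect_error(karlin_altschul_evalue(50, 10, 10, lambda = -1), "positive")
})

# shared screen fixture: a genome-slice contig carrying the polymerase ORF
# and a panel with one 47%-identity homolog and one unrelated protein
screen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- synthetic_aiclv1_genome()
      lprot <- find_orfs(tr$genome, 300)$protein[1]
      set.seed(40)
      panel <- seq_set(c("unrelated_ref", "viral_L_ref"),
                       c(random_aa(400), mutate_protein(lprot, 0.47, seed = 4)))
      contig <- seq_set("contig_viral", genome_substr(tr$genome, 1, 6800))
      cache <<- list(tr = tr, panel = panel, contig = contig, lprot = lprot)
    }
    cache
  }
})

test_that("a planted 47%-identity homolog passes the screen with strong E-value", {
  fx <- screen_fixture()
  res <- screen_contigs(fx$contig, fx$panel)
  expect_identical(nrow(res$hits), 1L)
  h <- res$hits[1, ]
  expect_identical(h$sseqid, "viral_L_ref")
  expect_lte(h$evalue, 1e-20)
  expect_lt(abs(h$pident - 47), 3)
  expect_identical(h$frame, 1L)
  # aligned span maps back into the planted ORF's nucleotide interval
  expect_gte(h$qstart, 70L)
  expect_lte(h$qend, 6708L)
})

test_that("contigs at or below 1000 bp are rejected as short, even with a perfect hit", {
  fx <- screen_fixture()
  perfect_panel <- seq_set("self", substr(fx$lprot, 1, 300))
  short999 <- seq_set("c999", genome_substr(fx$tr$genome, 70, 999))
  res <- screen_contigs(short999, perfect_panel)
  expect_identical(nrow(res$hits), 0L)
  expect_identical(res$rejected$short_contig, 1L)
  # the boundary: exactly 1000 bp is NOT 'exceeding 1000 bp'
  at1000 <- seq_set("c1000", genome_substr(fx$tr$genome, 70, 1000))
  res2 <- screen_contigs(at1000, perfect_panel)
  expect_identical(res2$rejected$short_contig, 1L)
  at1001 <- seq_set("c1001", genome_substr(fx$tr$genome, 70, 1001))
  res3 <- screen_contigs(at1001, perfect_panel)
  expect_identical(res3$rejected$short_contig, 0L)
  expect_identical(nrow(res3$hits), 1L)
})

test_that("weak hits are rejected by E-value with a machine-readable reason", {
  fx <- screen_fixture()
  # a short, weakly similar peptide region: alignable but far above cutoff
  set.seed(9)
  weak_panel <- seq_set("weak_ref", random_aa(150))
  contig2k <- seq_set("c2k", genome_substr(fx$tr$genome, 70, 2169))
  res <- screen_contigs(contig2k, weak_panel)
  expect_identical(nrow(res$hits), 0L)
  expect_identical(res$rejected$weak_evalue, 1L)
  # every kept hit satisfies both thresholds (filter soundness)
  res_all <- screen_contigs(rbind(fx$contig, contig2k), fx$panel)
  expect_true(all(res_all$hits$evalue <= 1e-20))
  expect_true(all(nchar(fx$contig$seq) > 1000))
})

test_that("screening an empty contig set or unrelated contigs yields no hits", {
  fx <- screen_fixture()
  empty <- screen_contigs(seq_set(character(0), character(0)), fx$panel)
  expect_identical(nrow(empty$hits), 0L)
  set.seed(77)
  rnd <- seq_set("rand2k", random_dna(2000))
  res <- screen_contigs(rnd, fx$panel)
  expect_identical(nrow(res$hits), 0L)
  expect_error(screen_contigs(rnd, seq_set(character(0), character(0))), "non-empty")
})

test_that("screen output order and serialization are deterministic", {
  fx <- screen_fixture()
  r1 <- screen_contigs(fx$contig, fx$panel)
  r2 <- screen_contigs(fx$contig, fx$panel)
  expect_identical(r1$hits, r2$hits)
  d <- tempfile()
  write_screen_result(r1, d)
  expect_true(file.exists(file.path(d, "screen_hits.tsv")))
  tab <- read.delim(file.path(d, "screen_hits.tsv"))
  expect_identical(names(tab)[1:6],
                   c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore"))
})

test_that("reverse-orientation contigs are found in minus frames with flipped coordinates", {
  fx <- screen_fixture()
  rc_contig <- seq_set("contig_rc", rev_comp(fx$contig$seq))
  res <- screen_contigs(rc_contig, fx$panel)
  expect_identical(nrow(res$hits), 1L)
  expect_lt(res$hits$frame[1], 0L)
  expect_gt(res$hits$qstart[1], res$hits$qend[1])
})
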