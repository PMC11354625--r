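test_that("index construction validates k and is deterministic", {
  g <- genome("ACGTACGT", "linear")
  idx <- build_index(g, k = 8)
  pl <- map_read(idx, "ACGTACGT")   # palindromic: one hit on each strand
  expect_identical(pl$position, c(1L, 1L))
  expect_identical(pl$strand, c("+", "-"))
  expect_error(build_index(g, k = 9), "exceeds")
  expect_error(build_index(g, k = 4), "at least 8")
  # rebuild gives identical query results on random probes
  set.seed(5)
  g2 <- genome(random_dna(1500), "circular")
  i1 <- build_index(g2)
  i2 <- build_index(g2)
  for (n in 1:50) {
    r <- random_dna(21)
    expect_identical(map_read(i1, r), map_read(i2, r))
  }
})

test_that("circular indexes answer queries across the origin", {
  g <- genome(random_dna(400), "circular")
  idx <- build_index(g)
  wrap_read <- genome_substr(g, 395, 20)   # spans the origin
  pl <- map_read(idx, wrap_read)
  expect_true(395L %in% pl$position)
  expect_true(pl$wraps_origin[pl$position == 395L])
})

test_that("single reads map by construction on both strands, N never maps", {
  set.seed(8)
  g <- genome(random_dna(3000), "linear")
  idx <- build_index(g)
  read <- substr(g$seq, 100, 120)
  pl <- map_read(idx, read)
  expect_true(all(c(100L) %in% pl$position[pl$strand == "+"]))
  plm <- map_read(idx, rev_comp(read))
  expect_true(100L %in% plm$position[plm$strand == "-"])
  expect_identical(nrow(map_read(idx, paste0(substr(read, 1, 20), "N"))), 0L)
  expect_error(map_read(idx, "ACGTACGTACGT"), "seed length")
})

test_that("mapping equals the naive full-scan oracle on 200 random cases", {
  set.seed(42)
  for (case in 1:200) {
    L <- sample(300:5000, 1)
    topo <- sample(c("linear", "circular"), 1)
    g <- genome(random_dna(L), topo)
    idx <- build_index(g)
    kind <- case %% 4
    if (kind == 0) {          # planted sense read (may wrap on circular)
      pos <- sample(L, 1)
      len <- sample(18:30, 1)
      if (topo == "linear") pos <- min(pos, L - len + 1)
      read <- genome_substr(g, pos, len)
    } else if (kind == 1) {   # planted antisense read
      pos <- sample(L, 1)
      len <- sample(18:30, 1)
      if (topo == "linear") pos <- min(pos, L - len + 1)
      read <- rev_comp(genome_substr(g, pos, len))
    } else if (kind == 2) {   # wrap-spanning read on circular genomes
      len <- sample(18:30, 1)
      pos <- if (topo == "circular") L - sample(1:(len - 1), 1) + 1 else 1
      read <- genome_substr(g, pos, len)
    } else {                  # random read, usually unmapped
      read <- random_dna(sample(18:30, 1))
    }
    mine <- map_read(idx, read)
    oracle <- naive_map_oracle(g, read)
    expect_identical(mine$position, oracle$position)
    expect_identical(mine$strand, oracle$strand)
  }
})

test_that("mapping a read mirrors mapping its reverse complement", {
  set.seed(77)
  g <- genome(random_dna(2000), "circular")
  idx <- build_index(g)
  for (i in 1:25) {
    read <- genome_substr(g, sample(2000, 1), 21)
    a <- map_read(idx, read)
    b <- map_read(idx, rev_comp(read))
    swap <- c("+" = "-", "-" = "+")
    expect_identical(a$position, b$position)
    expect_identical(a$strand, unname(swap[b$strand]))
  }
})

test_that("rotating a circular genome rotates all placements", {
  set.seed(31)
  g <- genome(random_dna(800), "circular")
  off <- 123L
  rot <- genome(paste0(substr(g$seq, off + 1, 800), substr(g$seq, 1, off)),
                "circular")
  i1 <- build_index(g)
  i2 <- build_index(rot)
  for (i in 1:20) {
    read <- genome_substr(g, sample(800, 1), 24)
    p1 <- map_read(i1, read)
    p2 <- map_read(i2, read)
    expect_identical(sort(((p1$position - off - 1L) %% 800L) + 1L),
                     sort(p2$position))
  }
})

test_that("multimap policies weight, keep or drop multi-placed reads", {
  # duplicate a 40-mer so a read drawn from it places exactly twice
  set.seed(6)
  block <- random_dna(40)
  g <- genome(paste0(random_dna(200), block, random_dna(200), block,
                     random_dna(100)), "linear")
  idx <- build_index(g)
  reads <- seq_set(c("dup", "uniq"),
                   c(substr(block, 5, 28), substr(g$seq, 10, 33)))
  frac <- map_reads(idx, reads, "fractional")
  expect_identical(nrow(frac$placements[frac$placements$read_id == "dup", ]), 2L)
  expect_equal(frac$placements$weight[frac$placements$read_id == "dup"],
               c(0.5, 0.5))
  all_p <- map_reads(idx, reads, "all")
  expect_true(all(all_p$placements$weight == 1))
  uniq <- map_reads(idx, reads, "unique")
  expect_identical(uniq$n_multi_dropped, 1L)
  expect_false("dup" %in% uniq$placements$read_id)
})

test_that("all simulated viral reads are recovered and background never maps", {
  tr <- gen_viral_genome(10000, 0.45, "linear", "nyamivirus",
                         c(900, 1200, 1500), seed = 5)
  sim <- gen_vsirna_reads(tr, srna_sim_params(n_viral = 5000, n_background = 500,
                                              seed = 19))
  m <- map_reads(build_index(tr$genome), sim$reads)
  tv <- sim$truth[sim$truth$viral, ]
  got <- paste(m$placements$read_id, m$placements$position, m$placements$strand)
  expect_true(all(paste(tv$read_id, tv$origin, tv$strand) %in% got))
  expect_false(any(grepl("^bg_", m$placements$read_id)))
  expect_identical(m$n_unmapped, 500L)
})

test_that("coverage accumulates placement weight and respects conservation", {
  g <- genome(random_dna(100), "linear")
  idx <- build_index(g)
  one <- map_reads(idx, seq_set("r1", substr(g$seq, 30, 50)))
  cov <- coverage_profile(one)
  expect_equal(cov$mean_coverage, 0.21)
  expect_equal(sum(cov$depth), 21)
  # empty set
  cov0 <- coverage_profile(map_reads(idx, seq_set(character(0), character(0))))
  expect_identical(cov0$mean_coverage, 0)
  expect_true(all(cov0$depth == 0))
  # fractional conservation: total depth equals summed mapped read length
  tr <- gen_viral_genome(4000, 0.45, "linear", "nyamivirus",
                         c(450, 450, 450), seed = 23)
  sim <- gen_vsirna_reads(tr, srna_sim_params(n_viral = 1000, n_background = 0,
                                              seed = 3))
  m <- map_reads(build_index(tr$genome), sim$reads, "fractional")
  covf <- coverage_profile(m)
  expect_equal(sum(covf$depth), sum(sim$truth$length))
})

test_that("simulated RNA-seq recovers the planted mean coverage at 50x", {
  tr <- gen_viral_genome(11590, 0.40, "circular", "chuvirus",
                         c(6639, 2031, 1341, 450), seed = 3)
  rna <- gen_rnaseq_reads(tr$genome, mean_coverage = 50, read_len = 150, seed = 9)
  cov <- coverage_profile(map_reads(build_index(tr$genome), rna$reads, "all"))
  expect_lt(abs(cov$mean_coverage - 50) / 50, 0.02)
})

test_that("SAM emission round-trips through a SAM parser", {
  g <- genome(random_dna(500), "linear")
  g$id <- "ref1"
  idx <- build_index(g)
  reads <- seq_set(c("a", "b"),
                   c(substr(g$seq, 11, 35), rev_comp(substr(g$seq, 101, 122))))
  m <- map_reads(idx, reads)
  f <- tempfile(fileext = ".sam")
  write_sam(m, reads, f)
  lines <- readLines(f)
  expect_true(any(grepl("^@SQ\tSN:ref1\tLN:500$", lines)))
  body <- read.delim(text = lines[!grepl("^@", lines)], header = FALSE)
  expect_identical(body$V2, c(0L, 16L))       # FLAG encodes strand
  expect_identical(body$V4, c(11L, 101L))     # POS is 1-based leftmost
  expect_identical(body$V6, c("25M", "22M"))  # CIGAR full-length match
})
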