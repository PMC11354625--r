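#!/usr/bin/env Rscript
# Discovery stage: screen an assembled contig set (two viral contigs
# hidden among host-like background contigs) against a small viral
# protein panel, with the published thresholds: E-value <= 1e-20 and
# contig length strictly greater than 1000 bp.
# Requires: results/fixtures (01_simulate.R). Outputs: results/discovery/

suppressMessages(library(vsikit))
set.seed(7L)
fx <- "results/fixtures"
if (!dir.exists(fx)) stop("run analysis/01_simulate.R first")

a1 <- read_fasta(file.path(fx, "ainlv1", "genome.fasta"))
c1 <- read_fasta(file.path(fx, "aiclv1", "genome.fasta"))
g_a <- genome(a1$seq[1], "linear", id = a1$id[1])
g_c <- genome(c1$seq[1], "circular", id = c1$id[1])

# viral contigs: near-full-length slices of the two genomes (the assembler
# view); background: random host-like contigs of assorted sizes
aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
contigs <- seq_set(
  c("contig_nyami", "contig_chu", sprintf("host_%02d", 1:8)),
  c(substr(g_a$seq, 1, 9802), genome_substr(g_c, 60, 9009),
    vapply(sample(500:3000, 8), rand_dna, "")))

# panel: diverged homologs (47% / 45% identity) of the two L proteins,
# emulating the closest relatives a RefSeq search would surface
l_a <- find_orfs(g_a, 300)$protein[3]
l_c <- find_orfs(g_c, 300)$protein[1]
panel <- seq_set(c("orinovirus_like_L", "scarabeuvirus_like_L", "decoy_protein"),
                 c(mutate_protein(l_a, 0.47, seed = 31),
                   mutate_protein(l_c, 0.45, seed = 32),
                   paste(sample(aa20, 500, TRUE), collapse = "")))

res <- run_discover(contigs, panel, "results/discovery")
message(sprintf("%d candidate hit(s); rejections: %d short, %d weak E-value, %d unalignable",
                nrow(res$hits), res$rejected$short_contig,
                res$rejected$weak_evalue, res$rejected$no_alignment))
print(res$hits[, c("qseqid", "sseqid", "pident", "length", "evalue", "frame")])
message("hit table and rejection summary written under results/discovery")
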