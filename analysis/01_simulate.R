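#!/usr/bin/env Rscript
# Build the study's synthetic data: stand-in genomes for the two
# negative-sense viruses (a linear nyamivirus-like genome and a circular
# chuvirus-like genome with their published ORF coordinates), plus
# simulated RNA-seq and small-RNA populations with ground truth.
# Outputs: results/fixtures/<virus>/

suppressMessages(library(vsikit))
seed <- 2024L
out <- "results/fixtures"

message("nyamivirus-like stand-in: 9873 nt linear, N/G/L ORFs, 90-nt leading UTR")
a1 <- synthetic_ainlv1_genome()
dir.create(file.path(out, "ainlv1"), recursive = TRUE, showWarnings = FALSE)
write_fasta(seq_set(a1$genome$id, a1$genome$seq, desc = "linear synthetic stand-in"),
            file.path(out, "ainlv1", "genome.fasta"))
write.table(a1$orfs, file.path(out, "ainlv1", "orf_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("chuvirus-like stand-in: 11590 nt circular, L-G-N-(x) ORFs")
c1 <- synthetic_aiclv1_genome()
dir.create(file.path(out, "aiclv1"), recursive = TRUE, showWarnings = FALSE)
write_fasta(seq_set(c1$genome$id, c1$genome$seq, desc = "circular synthetic stand-in"),
            file.path(out, "aiclv1", "genome.fasta"))
write.table(c1$orfs, file.path(out, "aiclv1", "orf_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("RNA-seq: 147x over the nyamivirus-like genome, 50x over the chuvirus-like genome")
rna1 <- gen_rnaseq_reads(a1$genome, mean_coverage = 147, read_len = 147, seed = seed)
write_fastq(rna1$reads, file.path(out, "ainlv1", "rnaseq_reads.fastq"))
rna2 <- gen_rnaseq_reads(c1$genome, mean_coverage = 50, read_len = 150, seed = seed + 1L)
write_fastq(rna2$reads, file.path(out, "aiclv1", "rnaseq_reads.fastq"))

message("small RNA: 20k Dicer-like vsiRNAs + 5k host background per virus")
for (v in list(list(tag = "ainlv1", tr = a1, s = seed + 2L),
               list(tag = "aiclv1", tr = c1, s = seed + 3L))) {
  sim <- gen_vsirna_reads(v$tr, srna_sim_params(n_viral = 20000L,
                                                n_background = 5000L,
                                                sense_fraction = 0.5,
                                                au5_fraction = 0.8,
                                                seed = v$s))
  write_fastq(sim$reads, file.path(out, v$tag, "srna_reads.fastq"))
  write.table(sim$truth, file.path(out, v$tag, "srna_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("fixtures written under ", out)
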