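#!/usr/bin/env Rscript
# Annotation stage: ORF prediction (min span 300 nt), terminal UTRs on the
# linear genome, and gene-order typing against the family templates.
# Requires: results/fixtures. Outputs: results/annotation/

suppressMessages(library(vsikit))
fx <- "results/fixtures"
if (!dir.exists(fx)) stop("run analysis/01_simulate.R first")

for (v in list(list(tag = "ainlv1", topo = "linear", labels = c("N", "G", "L")),
               list(tag = "aiclv1", topo = "circular", labels = c("L", "G", "N", "x")))) {
  out <- run_characterize(file.path(fx, v$tag, "genome.fasta"),
                          file.path("results/annotation", v$tag),
                          topology = v$topo, labels = v$labels)
  ann <- out$annotation
  message(sprintf("%s: %d ORFs, gene order %s", v$tag, nrow(ann$orfs), out$gene_order))
  if (v$topo == "linear") {
    u <- utr_lengths(ann)
    message(sprintf("  terminal UTRs: %d nt before the first ORF, %d nt after the last",
                    u["utr5"], u["utr3"]))
  }
  print(ann$orfs[, c("orf_id", "start", "end", "strand", "span_nt", "label")])
}
message("GFF3 and ORF tables written under results/annotation")
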