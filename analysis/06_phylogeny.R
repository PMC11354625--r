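#!/usr/bin/env Rscript
# Phylogeny stage: pairwise RdRP identity matrices (global alignment,
# identity over all columns) and a neighbor-joining tree on
# d = 1 - identity/100, for a simulated polymerase family with two genera
# around each focal virus. NJ on identity distances stands in for
# maximum-likelihood inference throughout this package.
# Requires: results/fixtures. Outputs: results/phylogeny/

suppressMessages(library(vsikit))
fx <- "results/fixtures"
if (!dir.exists(fx)) stop("run analysis/01_simulate.R first")
dir.create("results/phylogeny", recursive = TRUE, showWarnings = FALSE)
set.seed(9L)

rec <- read_fasta(file.path(fx, "aiclv1", "genome.fasta"))
g_c <- genome(rec$seq[1], "circular", id = rec$id[1])
rdrp <- substr(find_orfs(g_c, 300)$protein[1], 1, 400)  # polymerase core

# simulated family: the focal virus, a close relative (~45% identity, the
# 'nearest neighbour' regime), a within-genus pair, and distant outliers
fam <- seq_set(
  c("focal_virus", "nearest_relative", "genus_member_1", "genus_member_2",
    "outlier_1", "outlier_2"),
  c(rdrp,
    mutate_protein(rdrp, 0.45, seed = 61),
    mutate_protein(mutate_protein(rdrp, 0.45, seed = 61), 0.80, seed = 62),
    mutate_protein(mutate_protein(rdrp, 0.45, seed = 61), 0.75, seed = 63),
    mutate_protein(rdrp, 0.28, seed = 64),
    paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 400, TRUE),
          collapse = "")))

im <- pairwise_identity_matrix(fam)
write_identity_tsv(im, "results/phylogeny/rdrp_identity.tsv")
message("pairwise RdRP identities (%):")
print(round(im$identity, 1))

tree <- neighbor_joining(im)
write_newick(tree, "results/phylogeny/rdrp_nj.nwk")
message("NJ tree: ", ape::write.tree(tree))
if (attr(tree, "clamped_edges") > 0)
  message(attr(tree, "clamped_edges"), " negative branch estimate(s) clamped to 0")
message("identity matrix and Newick tree written under results/phylogeny")
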