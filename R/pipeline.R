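#' Pipeline orchestration
#'
#' Three thin drivers tie the stages together and write their outputs
#' under a run directory with a machine-readable run report:
#' `run_simulate()` (fixture generation), `run_discover()` (contigs ->
#' candidate viral hits) and `run_characterize()` (genome + reads ->
#' annotation, coverage, vsiRNA report). All randomness flows from a
#' single seed; stages derive independent sub-streams deterministically.
#' Re-running with identical inputs and configuration produces identical
#' report bodies.
#'
#' @name pipeline
NULL

run_report <- function(out_dir, stage, config, inputs = character(0),
                       summaries = list(), warnings = character(0)) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  rep <- list(tool = "vsikit",
              version = as.character(utils::packageVersion("vsikit")),
              stage = stage, config = config, input_md5 = checksums,
              summaries = summaries, warnings = warnings)
  jsonlite::write_json(rep, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rep
}

#' Simulate a full fixture directory
#'
#' Writes a planted genome (FASTA), vsiRNA reads (FASTQ), RNA-seq reads
#' (FASTQ), truth tables (TSV) and a parameter sidecar (JSON) under
#' `out_dir`. Regenerating with the same parameters reproduces identical
#' files.
#'
#' @param out_dir output directory (created).
#' @param genome_length,gc,topology,architecture,orf_lengths arguments to
#'   [gen_viral_genome()].
#' @param srna an [srna_sim_params()] (its own seed is overridden by
#'   `seed`).
#' @param rnaseq_coverage,rnaseq_read_len RNA-seq simulation settings.
#' @param seed master seed.
#' @return invisibly, a list with the generated objects.
#' @export
run_simulate <- function(out_dir,
                         genome_length = 10002L, gc = 0.45,
                         topology = "linear", architecture = "nyamivirus",
                         orf_lengths = c(987L, 1428L, 2001L),
                         srna = srna_sim_params(),
                         rnaseq_coverage = 50, rnaseq_read_len = 150L,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- gen_viral_genome(genome_length, gc, topology, architecture,
                            orf_lengths, seed = derive_seed(seed, 11L))
  srna$seed <- derive_seed(seed, 12L)
  sim <- gen_vsirna_reads(truth, srna)
  rna <- gen_rnaseq_reads(truth$genome, rnaseq_coverage, rnaseq_read_len,
                          seed = derive_seed(seed, 13L))
  g <- truth$genome
  write_fasta(seq_set(g$id, g$seq, desc = g$topology),
              file.path(out_dir, "genome.fasta"))
  write_fastq(sim$reads, file.path(out_dir, "srna_reads.fastq"))
  write_fastq(rna$reads, file.path(out_dir, "rnaseq_reads.fastq"))
  write.table(truth$orfs, file.path(out_dir, "orf_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(out_dir, "srna_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rna$truth, file.path(out_dir, "rnaseq_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(genome_length = genome_length, gc = gc, topology = topology,
              architecture = architecture, orf_lengths = orf_lengths,
              srna = srna[setdiff(names(srna), "hotspots")],
              rnaseq_coverage = rnaseq_coverage,
              rnaseq_read_len = rnaseq_read_len, seed = seed)
  jsonlite::write_json(cfg, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_report(out_dir, "simulate", cfg,
             summaries = list(n_srna = nrow(sim$reads), n_rnaseq = nrow(rna$reads)))
  invisible(list(truth = truth, srna = sim, rnaseq = rna, dir = out_dir))
}

#' Run the discovery workflow (contigs vs viral protein panel)
#'
#' @param contigs path to a contig FASTA or a [seq_set()].
#' @param panel path to a panel protein FASTA or a [seq_set()].
#' @param out_dir output directory.
#' @param e_cutoff,min_contig_len screen thresholds (defaults 1e-20 and
#'   1000 bp, exclusive).
#' @return the [screen_contigs()] result, invisibly.
#' @export
run_discover <- function(contigs, panel, out_dir, e_cutoff = 1e-20,
                         min_contig_len = 1000L) {
  input_paths <- character(0)
  if (is.character(contigs)) {
    if (!file.exists(contigs)) stop("contigs file not found: ", contigs, call. = FALSE)
    input_paths <- c(input_paths, contigs)
    contigs <- read_fasta(contigs, "dna")
  }
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("panel file not found: ", panel, call. = FALSE)
    input_paths <- c(input_paths, panel)
    panel <- read_fasta(panel, "aa")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- screen_contigs(contigs, panel, e_cutoff, min_contig_len)
  write_screen_result(res, out_dir)
  run_report(out_dir, "discover",
             list(e_cutoff = e_cutoff, min_contig_len = min_contig_len),
             inputs = input_paths,
             summaries = list(n_contigs = nrow(contigs),
                              n_hits = nrow(res$hits),
                              rejected = res$rejected))
  invisible(res)
}

#' Run the characterization workflow (annotation, coverage, vsiRNA)
#'
#' Annotates ORFs and UTRs, classifies the gene order, maps RNA-seq reads
#' for a coverage profile, and maps/profiles small RNAs; writes GFF3,
#' depth TSV, the vsiRNA report tables and a run report.
#'
#' @param genome path to a genome FASTA (single record) or a [genome()].
#' @param out_dir output directory.
#' @param topology `"linear"` or `"circular"`; required when `genome` is
#'   a path (topology cannot be inferred from FASTA).
#' @param rnaseq optional RNA-seq reads: FASTQ path or [seq_set()].
#' @param srna optional small-RNA reads: FASTQ/FASTA path or [seq_set()].
#' @param min_orf_len ORF length threshold (default 300 nt).
#' @param labels optional character vector labeling the annotated ORFs in
#'   genome order (N/G/L/x/unknown) for gene-order typing.
#' @param srna_lo,srna_hi small-RNA length window (default 18-30).
#' @param focal_length 5'-preference focal length (default 21).
#' @param policy mapper multimap policy (default `"fractional"`; noted in
#'   the run report because the choice affects multi-mapped weight).
#' @param hotspot_window,hotspot_z hotspot parameters.
#' @return invisibly, list with `annotation`, `gene_order`, `coverage`,
#'   `vsirna`.
#' @export
run_characterize <- function(genome, out_dir, topology = NULL,
                             rnaseq = NULL, srna = NULL,
                             min_orf_len = 300L, labels = NULL,
                             srna_lo = 18L, srna_hi = 30L,
                             focal_length = 21L,
                             policy = "fractional",
                             hotspot_window = 50L, hotspot_z = 3.0) {
  input_paths <- character(0)
  if (is.character(genome)) {
    if (is.null(topology))
      stop("topology must be given explicitly ('linear' or 'circular') when reading a genome from FASTA",
           call. = FALSE)
    input_paths <- c(input_paths, genome)
    rec <- read_fasta(genome, "dna")
    genome <- genome(rec$seq[1], topology, id = rec$id[1])
  }
  stopifnot(inherits(genome, "genome"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  orfs <- find_orfs(genome, min_len = min_orf_len)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(orfs))
    orfs$label <- labels
  }
  ann <- annotate_genome(genome, orfs)
  write_gff3(ann, file.path(out_dir, "annotation.gff3"))
  write_orf_tsv(orfs, file.path(out_dir, "orfs.tsv"))
  gene_order <- if (!is.null(labels) && any(labels != "unknown")) {
    classify_gene_order(orfs, circular = genome$topology == "circular")
  } else NA_character_

  cov <- NULL
  if (!is.null(rnaseq)) {
    if (is.character(rnaseq)) {
      input_paths <- c(input_paths, rnaseq)
      rnaseq <- read_fastq(rnaseq)
    }
    idx_long <- build_index(genome, k = 18L)
    cov <- coverage_profile(map_reads(idx_long, rnaseq, policy = policy))
    write_depth_tsv(cov, file.path(out_dir, "rnaseq_depth.tsv"))
  }

  vrep <- NULL
  if (!is.null(srna)) {
    if (is.character(srna)) {
      input_paths <- c(input_paths, srna)
      srna <- if (grepl("\\.f(ast)?a$", srna)) read_fasta(srna, "dna")
              else read_fastq(srna)
    }
    kept <- length_filter(srna, srna_lo, srna_hi)
    idx <- build_index(genome, k = min(18L, srna_lo))
    mapped <- map_reads(idx, kept, policy = policy)
    vrep <- summarize_vsirna(srna, mapped, srna_lo, srna_hi, focal_length,
                             hotspot_window, hotspot_z)
    write_vsirna_report(vrep, file.path(out_dir, "vsirna"))
  }

  cfg <- list(topology = genome$topology, min_orf_len = min_orf_len,
              srna_lo = srna_lo, srna_hi = srna_hi,
              focal_length = focal_length, policy = policy,
              hotspot_window = hotspot_window, hotspot_z = hotspot_z)
  run_report(out_dir, "characterize", cfg, inputs = input_paths,
             summaries = list(
               n_orfs = nrow(orfs), gene_order = gene_order,
               utr5 = ann$utr5, utr3 = ann$utr3,
               mean_coverage = if (!is.null(cov)) cov$mean_coverage else NULL,
               srna_mapped = if (!is.null(vrep)) vrep$totals$mapped_reads else NULL),
             warnings = c(
               sprintf("multimap policy '%s': fractional weighting is the deterministic default", policy),
               "trees produced by this package use neighbor joining on identity distances, not maximum likelihood"))
  invisible(list(annotation = ann, gene_order = gene_order,
                 coverage = cov, vsirna = vrep))
}
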