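#' Protein scoring scheme for the homology screen
#'
#' BLOSUM62 (from Biostrings' shipped substitution matrices) with affine
#' gap penalties in the BLAST 11/1 convention: a gap of length n costs
#' `gap_open + gap_extend * (n - 1)`.
#'
#' @param name substitution matrix name available in Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters used for E-values; defaults
#'   are the standard gapped BLOSUM62 11/1 calibration (0.267, 0.041).
#' @return list of class `scoring_matrix`.
#' @export
scoring_matrix <- function(name = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  structure(list(name = name, matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_matrix")
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' Deterministic traceback (ties resolve diagonal, then up, then left).
#' Identity is computed over all aligned columns, gap columns included.
#'
#' @param query,subject protein strings.
#' @param scoring a [scoring_matrix()].
#' @return list of class `local_alignment`: `score`, `identity_pct`,
#'   `matches`, `columns`, aligned spans `q_start`/`q_end`/`s_start`/
#'   `s_end` (1-based), and the aligned strings `q_aln`/`s_aln`.
#' @export
smith_waterman <- function(query, subject, scoring = scoring_matrix()) {
  r <- .sw_align_cpp(normalize_aa(query), normalize_aa(subject),
                     scoring$matrix, scoring$gap_open, scoring$gap_extend)
  structure(list(score = r$score,
                 identity_pct = if (r$columns > 0) 100 * r$matches / r$columns else 0,
                 matches = r$matches, columns = r$columns,
                 q_start = r$a_start, q_end = r$a_end,
                 s_start = r$b_start, s_end = r$b_end,
                 q_aln = r$a_aln, s_aln = r$b_aln),
            class = "local_alignment")
}

#' Karlin-Altschul bit score and E-value
#'
#' `bit = (lambda * S - ln K) / ln 2`; `E = m * n * 2^(-bit)`. E is
#' monotone decreasing in the raw score and linear in either search-space
#' length.
#'
#' @param raw_score raw alignment score S.
#' @param m,n query and subject lengths (residues); must be positive.
#' @param lambda,K Karlin-Altschul parameters.
#' @return list with `bit_score` and `e_value`.
#' @export
karlin_altschul_evalue <- function(raw_score, m, n, lambda = 0.267, K = 0.041) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive", call. = FALSE)
  if (m <= 0 || n <= 0) stop("sequence lengths must be positive", call. = FALSE)
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bit, e_value = m * n * 2^(-bit))
}

# six-frame peptides of a contig: frame translations split at stops,
# keeping peptides of at least min_pep aa with their coordinates
contig_peptides <- function(seq, min_pep = 20L) {
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rev_comp(seq)
    for (f in 0:2) {
      prot <- translate_seq(s, f)
      if (!nchar(prot)) next
      # split at stops, keeping 1-based aa offsets within the frame
      pieces <- strsplit(prot, "*", fixed = TRUE)[[1]]
      off <- 1L
      for (p in pieces) {
        if (nchar(p) >= min_pep) {
          out[[length(out) + 1L]] <- list(strand = strand, frame = f,
                                          aa_offset = off, peptide = p)
        }
        off <- off + nchar(p) + 1L
      }
    }
  }
  out
}

# map an aligned aa interval of a frame translation back to 1-based
# nucleotide coordinates on the original contig (qstart > qend on "-")
aa_to_nt <- function(L, strand, frame, aa_start, aa_end) {
  nt_start <- frame + 3L * (aa_start - 1L) + 1L
  nt_end <- frame + 3L * aa_end
  if (strand == "+") c(nt_start, nt_end)
  else c(L - nt_start + 1L, L - nt_end + 1L)
}

#' Screen assembled contigs against a viral protein panel
#'
#' The discovery stage: every contig is translated in six frames, frame
#' translations are split at stop codons into peptides of at least
#' `min_pep` residues, each peptide is locally aligned against each panel
#' protein, and the best hit per (contig, panel protein) is kept (lowest
#' E-value, ties to higher identity, then lexicographic panel id).
#' Filters are applied in order: contig length strictly greater than
#' `min_contig_len` (a 1000-bp contig does not pass the default), then
#' E-value at most `e_cutoff`. Rejections are counted by reason.
#'
#' @param contigs a [seq_set()] of nucleotide contigs.
#' @param panel a [seq_set()] of panel proteins.
#' @param e_cutoff E-value threshold (default 1e-20).
#' @param min_contig_len minimum contig length, exclusive (default 1000).
#' @param min_pep minimum peptide length aligned (default 20 aa).
#' @param scoring a [scoring_matrix()].
#' @return list of class `screen_result`: `hits` (data frame in BLAST
#'   outfmt-6-like column order: qseqid, sseqid, pident, length, evalue,
#'   bitscore, qstart, qend, sstart, send, frame), `rejected` (named list
#'   of counts: `short_contig`, `weak_evalue`, `no_alignment`), and the
#'   parameters used.
#' @export
screen_contigs <- function(contigs, panel, e_cutoff = 1e-20,
                           min_contig_len = 1000L, min_pep = 20L,
                           scoring = scoring_matrix()) {
  stopifnot(inherits(contigs, "seq_set"))
  if (!inherits(panel, "seq_set") || nrow(panel) == 0)
    stop("panel must be a non-empty seq_set of proteins", call. = FALSE)
  rejected <- list(short_contig = 0L, weak_evalue = 0L, no_alignment = 0L)
  hit_rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    cid <- contigs$id[ci]
    cseq <- contigs$seq[ci]
    L <- nchar(cseq)
    if (L <= min_contig_len) {
      rejected$short_contig <- rejected$short_contig + 1L
      next
    }
    peps <- contig_peptides(cseq, min_pep)
    if (!length(peps)) {
      rejected$no_alignment <- rejected$no_alignment + 1L
      next
    }
    any_kept <- FALSE
    any_hit <- FALSE
    for (pi in order(panel$id)) {
      sid <- panel$id[pi]
      sseq <- normalize_aa(panel$seq[pi])
      best <- NULL
      for (pep in peps) {
        al <- smith_waterman(pep$peptide, sseq, scoring)
        if (al$score <= 0) next
        ka <- karlin_altschul_evalue(al$score, nchar(pep$peptide), nchar(sseq),
                                     scoring$lambda, scoring$K)
        cand <- list(al = al, pep = pep, ka = ka)
        if (is.null(best) ||
            ka$e_value < best$ka$e_value ||
            (ka$e_value == best$ka$e_value && al$identity_pct > best$al$identity_pct)) {
          best <- cand
        }
      }
      if (is.null(best)) next
      any_hit <- TRUE
      if (best$ka$e_value > e_cutoff) next
      any_kept <- TRUE
      q_aa_start <- best$pep$aa_offset + best$al$q_start - 1L
      q_aa_end <- best$pep$aa_offset + best$al$q_end - 1L
      qnt <- aa_to_nt(L, best$pep$strand, best$pep$frame, q_aa_start, q_aa_end)
      frame_blast <- (best$pep$frame + 1L) * (if (best$pep$strand == "+") 1L else -1L)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        qseqid = cid, sseqid = sid,
        pident = round(best$al$identity_pct, 2),
        length = best$al$columns,
        evalue = best$ka$e_value, bitscore = best$ka$bit_score,
        qstart = qnt[1], qend = qnt[2],
        sstart = best$al$s_start, send = best$al$s_end,
        frame = frame_blast, stringsAsFactors = FALSE)
    }
    if (any_hit && !any_kept)
      rejected$weak_evalue <- rejected$weak_evalue + 1L
    if (!any_hit)
      rejected$no_alignment <- rejected$no_alignment + 1L
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
          else data.frame(qseqid = character(0), sseqid = character(0),
                          pident = numeric(0), length = integer(0),
                          evalue = numeric(0), bitscore = numeric(0),
                          qstart = integer(0), qend = integer(0),
                          sstart = integer(0), send = integer(0),
                          frame = integer(0), stringsAsFactors = FALSE)
  # deterministic order: contig input order, then E ascending
  if (nrow(hits) > 0) {
    hits <- hits[order(match(hits$qseqid, contigs$id), hits$evalue, hits$sseqid), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(hits = hits, rejected = rejected,
                 params = list(e_cutoff = e_cutoff,
                               min_contig_len = min_contig_len,
                               min_pep = min_pep, scoring = scoring$name,
                               gap_open = scoring$gap_open,
                               gap_extend = scoring$gap_extend,
                               lambda = scoring$lambda, K = scoring$K)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d hit(s); rejected: %d short, %d weak E, %d no alignment\n",
              nrow(x$hits), x$rejected$short_contig, x$rejected$weak_evalue,
              x$rejected$no_alignment))
  invisible(x)
}

#' Write screen hits as a BLAST outfmt-6-like table plus rejection summary
#'
#' @param result a [screen_contigs()] result.
#' @param dir output directory.
#' @export
write_screen_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$hits, file.path(dir, "screen_hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rejected = result$rejected, params = result$params),
                       file.path(dir, "screen_rejections.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
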