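#' @useDynLib vsikit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames runif sd
#' @importFrom utils write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Normalize and validate a nucleotide sequence
#'
#' Uppercases, converts RNA U to T, and errors on any character outside
#' `A,C,G,T,N`. Negative-sense RNA virus sequences are deposited as DNA;
#' RNA input is accepted and normalized.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_dna <- function(x) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- stringi::stri_detect_regex(x, "[^ACGTN]")
  if (any(bad)) {
    ch <- stringi::stri_extract_first_regex(x[bad][1], "[^ACGTN]")
    stop("non-nucleotide character '", ch, "' in sequence", call. = FALSE)
  }
  x
}

normalize_aa <- function(x) {
  x <- toupper(x)
  bad <- !stringi::stri_detect_regex(x, paste0("^[", paste(AA_ALPHABET[AA_ALPHABET != "*"], collapse = ""), "*]*$"))
  if (any(bad)) stop("non-amino-acid character in sequence", call. = FALSE)
  x
}

#' Construct a set of sequence records
#'
#' A `seq_set` is the light container used throughout the package for
#' contigs, reads and proteins: a data frame with columns `id`, `desc`
#' and `seq`.
#'
#' @param id character vector of record identifiers (must be unique).
#' @param seq character vector of sequences.
#' @param desc optional character vector of descriptions.
#' @return a data frame of class `seq_set`.
#' @export
seq_set <- function(id, seq, desc = "") {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) stop("duplicate record ids", call. = FALSE)
  if (length(seq) > 0 && any(!nzchar(seq)))
    stop("empty sequence for record ", id[!nzchar(seq)][1], call. = FALSE)
  out <- data.frame(id = as.character(id), desc = rep_len(as.character(desc), length(id)),
                    seq = as.character(seq), stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Read a FASTA file
#'
#' @param path file path.
#' @param alphabet `"dna"` (normalized: uppercase, U->T) or `"aa"`.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- as.character(x)
  if (any(!nzchar(seqs))) {
    stop("malformed FASTA: record '", names(x)[!nzchar(seqs)][1],
         "' has a header but no sequence in ", path, call. = FALSE)
  }
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- if (alphabet == "dna") normalize_dna(seqs) else normalize_aa(seqs)
  seq_set(id, unname(seqs), desc)
}

#' Write a FASTA file (60-column wrap)
#'
#' @param records a [seq_set()].
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- ifelse(nzchar(records$desc), paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file (qualities discarded)
#'
#' Reads arrive quality-trimmed; base qualities are parsed and dropped.
#'
#' @param path file path.
#' @return a [seq_set()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  seq_set(sub("\\s.*$", "", names(x)), normalize_dna(as.character(x)))
}

#' Write a FASTQ file with uniform placeholder qualities
#'
#' @param records a [seq_set()].
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records) > 0) {
    qual <- vapply(nchar(records$seq), function(n) strrep("I", n), "")
    writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized over input; `N` is self-complementary.
#'
#' @param x character vector of nucleotide sequences over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  x <- normalize_dna(x)
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

#' Translate a nucleotide sequence in a given frame
#'
#' Translates codons from offset `frame` up to the last complete codon,
#' under the standard genetic code. Stop codons are rendered `*`; codons
#' containing `N` are rendered `X`. A sequence shorter than one codon in
#' frame yields the empty protein.
#'
#' @param seq nucleotide string.
#' @param frame integer offset 0, 1 or 2.
#' @return protein string.
#' @export
translate_seq <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  seq <- normalize_dna(seq)
  L <- nchar(seq)
  n_codon <- (L - frame) %/% 3
  if (n_codon <= 0) return("")
  starts <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Construct a genome object
#'
#' @param seq nucleotide sequence (single string).
#' @param topology `"linear"` or `"circular"`. Circular genomes use
#'   modulo-length position arithmetic; ORFs and read placements may wrap
#'   the origin.
#' @param id genome identifier.
#' @param polya_trimmed logical flag recording that a terminal poly(A)
#'   tract was removed upstream.
#' @return an object of class `genome`.
#' @export
genome <- function(seq, topology = c("linear", "circular"), id = "genome",
                   polya_trimmed = FALSE) {
  topology <- match.arg(topology)
  seq <- normalize_dna(seq)
  if (nchar(seq) < 1) stop("genome must be non-empty", call. = FALSE)
  structure(list(id = id, seq = seq, topology = topology,
                 polya_trimmed = polya_trimmed),
            class = "genome")
}

#' @export
length.genome <- function(x) nchar(x$seq)

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d nt, %s\n", x$id, nchar(x$seq), x$topology))
  invisible(x)
}

#' Extract a (possibly wrapping) genome substring
#'
#' For circular genomes positions past the end wrap to the start.
#'
#' @param g a [genome()].
#' @param start 1-based start.
#' @param len substring length.
#' @return nucleotide string.
#' @export
genome_substr <- function(g, start, len) {
  L <- nchar(g$seq)
  if (g$topology == "circular") {
    if (start + len - 1L <= L) return(substr(g$seq, start, start + len - 1L))
    if (len > L) stop("substring longer than circular genome", call. = FALSE)
    paste0(substr(g$seq, start, L), substr(g$seq, 1L, start + len - 1L - L))
  } else {
    if (start < 1L || start + len - 1L > L)
      stop("substring out of range on linear genome", call. = FALSE)
    substr(g$seq, start, start + len - 1L)
  }
}

#' Six-frame translations of a genome
#'
#' Three forward and three reverse frames. For circular topology each
#' strand is translated on the doubled sequence and the protein truncated
#' to `floor(L/3)` codons so that every genomic codon start is used
#' exactly once (origin-spanning codons included, none double-counted).
#'
#' @param g a [genome()].
#' @return data frame with columns `strand`, `frame`, `protein` (6 rows).
#' @export
six_frame_translations <- function(g) {
  stopifnot(inherits(g, "genome"))
  L <- nchar(g$seq)
  one_strand <- function(s) {
    vapply(0:2, function(f) {
      if (g$topology == "circular") {
        p <- translate_seq(paste0(s, s), f)
        substr(p, 1L, L %/% 3L)
      } else {
        translate_seq(s, f)
      }
    }, "")
  }
  data.frame(strand = rep(c("+", "-"), each = 3),
             frame = rep(0:2, 2),
             protein = c(one_strand(g$seq), one_strand(rev_comp(g$seq))),
             stringsAsFactors = FALSE)
}

# deterministic 32-bit sub-seed derivation so independent stages get
# independent streams from one user seed
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}
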