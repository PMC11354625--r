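#' Build a k-mer index of a genome for zero-mismatch mapping
#'
#' Indexes every plus-strand k-mer start position (1..L). On circular
#' genomes k-mers spanning the origin are included, so wrap-spanning reads
#' are queryable. Reverse-strand hits are found at query time by looking
#' up the read's reverse complement, so only one strand is stored.
#'
#' @param g a [genome()].
#' @param k seed length; the minimum queryable read length (default 18,
#'   the lower bound of the small-RNA size window).
#' @return list of class `genome_index`.
#' @export
build_index <- function(g, k = 18L) {
  stopifnot(inherits(g, "genome"))
  L <- nchar(g$seq)
  if (k > L) stop("k exceeds the genome length", call. = FALSE)
  if (k < 8) stop("k must be at least 8", call. = FALSE)
  circ <- g$topology == "circular"
  s <- if (circ) paste0(g$seq, substr(g$seq, 1L, k - 1L)) else g$seq
  n_pos <- if (circ) L else L - k + 1L
  kmers <- substring(s, seq_len(n_pos), seq_len(n_pos) + k - 1L)
  env <- new.env(hash = TRUE, parent = emptyenv(), size = n_pos)
  tab <- split(seq_len(n_pos), kmers)
  list2env(tab, envir = env)
  structure(list(genome = g, k = k, positions = env), class = "genome_index")
}

# exhaustive exact placements of one read sequence on the plus strand
match_plus <- function(index, read) {
  g <- index$genome
  L <- nchar(g$seq)
  len <- nchar(read)
  cand <- index$positions[[substr(read, 1L, index$k)]]
  if (is.null(cand)) return(integer(0))
  if (g$topology == "linear") cand <- cand[cand + len - 1L <= L]
  if (!length(cand)) return(integer(0))
  Sd <- if (g$topology == "circular") paste0(g$seq, g$seq) else g$seq
  cand[substring(Sd, cand, cand + len - 1L) == read]
}

#' Map a single read with zero mismatches
#'
#' Exhaustive exact placements of the read on both strands. `N` matches
#' nothing (strict zero-mismatch semantics), so a read containing `N`
#' never maps. Reads shorter than the index seed length are rejected.
#'
#' @param index a [build_index()] result.
#' @param read read sequence (string) or single-row [seq_set()].
#' @return data frame of placements: `position` (1-based 5'-most
#'   plus-strand coordinate of the matched interval), `strand`, `length`,
#'   `wraps_origin`; sorted by position then strand.
#' @export
map_read <- function(index, read) {
  if (inherits(read, "seq_set")) read <- read$seq[1]
  len <- nchar(read)
  if (len < index$k)
    stop("read shorter than the index seed length (", index$k, " nt)", call. = FALSE)
  L <- nchar(index$genome$seq)
  if (len > L) stop("read longer than the genome", call. = FALSE)
  empty <- data.frame(position = integer(0), strand = character(0),
                      length = integer(0), wraps_origin = logical(0),
                      stringsAsFactors = FALSE)
  if (grepl("N", read, fixed = TRUE)) return(empty)
  pos_p <- match_plus(index, read)
  pos_m <- match_plus(index, rev_comp(read))
  out <- rbind(
    if (length(pos_p)) data.frame(position = pos_p, strand = "+", length = len,
                                  wraps_origin = pos_p + len - 1L > L),
    if (length(pos_m)) data.frame(position = pos_m, strand = "-", length = len,
                                  wraps_origin = pos_m + len - 1L > L))
  if (is.null(out)) return(empty)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a batch of reads with a multimapping policy
#'
#' Policies: `"all"` keeps every placement with weight 1; `"unique"`
#' drops reads with more than one placement (counted separately);
#' `"fractional"` (default) weights each placement `1/n_placements` —
#' deterministic, with the same expectation as random-best assignment.
#'
#' @param index a [build_index()] result.
#' @param reads a [seq_set()].
#' @param policy `"fractional"`, `"all"` or `"unique"`.
#' @return list of class `mapped_read_set`: `placements` (read_id,
#'   position, strand, length, wraps_origin, n_placements, weight,
#'   first_base — the read's own 5' base as sequenced), `policy`,
#'   `genome`, totals `n_reads`, `n_mapped`, `n_unmapped`,
#'   `n_multi_dropped`.
#' @export
map_reads <- function(index, reads, policy = c("fractional", "all", "unique")) {
  policy <- match.arg(policy)
  stopifnot(inherits(reads, "seq_set"))
  g <- index$genome
  L <- nchar(g$seq)
  k <- index$k
  circ <- g$topology == "circular"
  Sd <- if (circ) paste0(g$seq, g$seq) else g$seq
  env <- index$positions

  n <- nrow(reads)
  seqs <- reads$seq
  lens <- nchar(seqs)
  if (any(lens < k))
    stop("read shorter than the index seed length (", k, " nt)", call. = FALSE)
  if (any(lens > L)) stop("read longer than the genome", call. = FALSE)
  rc <- rev_comp(seqs)
  has_n <- grepl("N", seqs, fixed = TRUE)
  pre_f <- substr(seqs, 1L, k)
  pre_r <- substr(rc, 1L, k)

  lookup <- function(query, prefix, len) {
    cand <- env[[prefix]]
    if (is.null(cand)) return(integer(0))
    if (!circ) cand <- cand[cand + len - 1L <= L]
    if (!length(cand)) return(integer(0))
    cand[substring(Sd, cand, cand + len - 1L) == query]
  }

  pos_l <- vector("list", n)
  str_l <- vector("list", n)
  np_all <- integer(n)
  for (i in seq_len(n)) {
    if (has_n[i]) next
    pp <- lookup(seqs[i], pre_f[i], lens[i])
    pm <- lookup(rc[i], pre_r[i], lens[i])
    np <- length(pp) + length(pm)
    if (np == 0L) next
    np_all[i] <- np
    pos_l[[i]] <- c(pp, pm)
    str_l[[i]] <- rep(c("+", "-"), c(length(pp), length(pm)))
  }
  n_unmapped <- sum(np_all == 0L)
  keep <- np_all > 0L
  if (policy == "unique") {
    n_multi_dropped <- sum(np_all > 1L)
    keep <- np_all == 1L
  } else n_multi_dropped <- 0L
  mapped_ids <- sum(keep)

  ki <- which(keep)
  if (length(ki)) {
    reps <- np_all[ki]
    position <- unlist(pos_l[ki], use.names = FALSE)
    strand <- unlist(str_l[ki], use.names = FALSE)
    placements <- data.frame(
      position = position, strand = strand,
      length = rep(lens[ki], reps),
      wraps_origin = position + rep(lens[ki], reps) - 1L > L,
      read_id = rep(reads$id[ki], reps),
      n_placements = rep(np_all[ki], reps),
      weight = if (policy == "fractional") rep(1 / np_all[ki], reps) else 1,
      first_base = rep(chartr("T", "U", substr(seqs[ki], 1L, 1L)), reps),
      stringsAsFactors = FALSE)
    # within-read placements sorted by (position, strand)
    placements <- placements[order(match(placements$read_id, reads$id),
                                   placements$position, placements$strand), ,
                             drop = FALSE]
    rownames(placements) <- NULL
  } else {
    placements <- data.frame(position = integer(0), strand = character(0),
                             length = integer(0), wraps_origin = logical(0),
                             read_id = character(0), n_placements = integer(0),
                             weight = numeric(0), first_base = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(genome = index$genome, placements = placements,
                 policy = policy, n_reads = nrow(reads),
                 n_mapped = mapped_ids, n_unmapped = n_unmapped,
                 n_multi_dropped = n_multi_dropped),
            class = "mapped_read_set")
}

#' @export
print.mapped_read_set <- function(x, ...) {
  cat(sprintf("<mapped_read_set> %d/%d reads mapped (%s policy, %d placements)\n",
              x$n_mapped, x$n_reads, x$policy, nrow(x$placements)))
  invisible(x)
}

#' Per-base coverage profile of a mapped read set
#'
#' Each placement adds its weight to every position it covers (modulo the
#' genome length when wrapping). Under the fractional policy total depth
#' mass equals the summed length of mapped reads.
#'
#' @param mapped a [map_reads()] result.
#' @return list of class `coverage_profile`: `depth` (length-L numeric),
#'   `mean_coverage`.
#' @export
coverage_profile <- function(mapped) {
  stopifnot(inherits(mapped, "mapped_read_set"))
  L <- nchar(mapped$genome$seq)
  depth <- numeric(L)
  pl <- mapped$placements
  if (nrow(pl) > 0) {
    idx <- sequence(pl$length, from = pl$position)
    idx <- ((idx - 1L) %% L) + 1L
    w <- rep(pl$weight, pl$length)
    agg <- rowsum(w, idx)
    depth[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(list(depth = depth, mean_coverage = sum(depth) / L),
            class = "coverage_profile")
}

#' Write placements as a SAM file
#'
#' Minimal SAM v1.6 emission for interoperability: FLAG 0/16, 1-based POS,
#' CIGAR `<len>M`, MAPQ 255. Wrapping placements on circular genomes are
#' emitted at their start position with a full-length match CIGAR.
#'
#' @param mapped a [map_reads()] result.
#' @param reads the [seq_set()] that was mapped (for sequences).
#' @param path output path.
#' @export
write_sam <- function(mapped, reads, path) {
  g <- mapped$genome
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", g$id, nchar(g$seq))), con)
  pl <- mapped$placements
  if (nrow(pl) > 0) {
    seqs <- setNames(reads$seq, reads$id)[pl$read_id]
    out_seq <- ifelse(pl$strand == "+", seqs, rev_comp(seqs))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       pl$read_id, ifelse(pl$strand == "+", 0L, 16L), g$id,
                       pl$position, pl$length, out_seq), con)
  }
  invisible(path)
}

#' Write a per-base depth table
#'
#' @param profile a [coverage_profile()] result.
#' @param path output path (TSV: position, depth).
#' @export
write_depth_tsv <- function(profile, path) {
  write.table(data.frame(position = seq_along(profile$depth),
                         depth = profile$depth),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
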