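#' Find maximal ORFs on a linear or circular genome
#'
#' A maximal ORF runs from the first in-frame ATG after the previous
#' in-frame stop through the next in-frame stop (the stop codon is part of
#' the reported span, matching the convention in which a 6639-nt ORF
#' encodes 2212 residues plus the stop). Circular genomes are scanned on
#' the doubled sequence with duplicates removed and spans capped at the
#' genome length; an ORF crossing the origin is reported with
#' `wraps_origin = TRUE` and `end < start` (end taken modulo length).
#'
#' All coordinates are 1-based, fully closed. For `strand = "-"` ORFs the
#' reported `start`/`end` are plus-strand coordinates of the leftmost/
#' rightmost base; `frame` is the offset on the ORF's own strand.
#'
#' @param g a [genome()].
#' @param min_len minimum ORF span in nt (including the stop codon);
#'   must be divisible by 3 and at least 6. Default 300.
#' @param strand_policy `"coding_only"` (scan the deposited orientation
#'   only, the default — for negative-sense viruses annotation is done on
#'   the deposited antigenome sense) or `"both"`.
#' @return data frame of class `orf_table` with columns `orf_id`, `start`,
#'   `end`, `strand`, `frame`, `wraps_origin`, `span_nt`, `label`,
#'   `protein`, sorted by start then strand.
#' @export
find_orfs <- function(g, min_len = 300L, strand_policy = c("coding_only", "both")) {
  stopifnot(inherits(g, "genome"))
  strand_policy <- match.arg(strand_policy)
  if (min_len %% 3 != 0) stop("min_len must be divisible by 3", call. = FALSE)
  if (min_len < 6) stop("min_len must be at least 6", call. = FALSE)
  L <- nchar(g$seq)
  circ <- g$topology == "circular"

  scan_strand <- function(seq_plus_coords, strand) {
    # seq_plus_coords: sequence in the orientation being scanned. Circular
    # genomes are scanned on the doubled sequence; an open region whose
    # upstream boundary is the chain start (not a real stop) is skipped
    # there, because the same region reappears later in the chain with its
    # true upstream context — this keeps maximality origin-independent.
    s <- if (circ) paste0(seq_plus_coords, seq_plus_coords) else seq_plus_coords
    res <- list()
    for (f in 0:2) {
      n_codon <- (nchar(s) - f) %/% 3
      if (n_codon < 2) next
      starts <- f + 1L + 3L * (seq_len(n_codon) - 1L)
      cod <- substring(s, starts, starts + 2L)
      stop_i <- which(cod %in% STOP_CODONS)
      atg_i <- which(cod == "ATG")
      prev <- 0L
      for (si in stop_i) {
        a <- atg_i[atg_i > prev & atg_i < si]
        skip_region <- circ && prev == 0L
        prev <- si
        if (skip_region || !length(a)) next
        a <- a[1]
        span <- (si - a + 1L) * 3L
        if (span > L) span <- L   # circular cap: never report more than one lap
        if (span < min_len) next
        nt_start <- f + 3L * (a - 1L) + 1L
        nt_start <- ((nt_start - 1L) %% L) + 1L   # map second-lap starts back
        prot <- paste(Biostrings::GENETIC_CODE[cod[a:(si - 1L)]], collapse = "")
        res[[length(res) + 1L]] <- list(start = nt_start, span = span,
                                        frame = (nt_start - 1L) %% 3L,
                                        strand = strand, protein = prot)
      }
    }
    res
  }

  hits <- scan_strand(g$seq, "+")
  if (strand_policy == "both") {
    rc_hits <- scan_strand(rev_comp(g$seq), "-")
    # map reverse-strand coordinates back to plus-strand space
    rc_hits <- lapply(rc_hits, function(h) {
      rc_start <- h$start
      rc_end_raw <- h$start + h$span - 1L           # may exceed L when wrapping
      # leftmost plus-strand base corresponds to the ORF's last base on rc
      h$start_plus <- ((L - rc_end_raw) %% L) + 1L
      h
    })
    hits <- c(hits, rc_hits)
  }
  if (!length(hits)) {
    out <- data.frame(orf_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      wraps_origin = logical(0), span_nt = integer(0),
                      label = character(0), protein = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("orf_table", "data.frame")
    return(out)
  }

  rows <- lapply(hits, function(h) {
    left <- if (h$strand == "+") h$start else h$start_plus
    end_raw <- left + h$span - 1L
    wraps <- circ && end_raw > L
    end <- if (wraps) end_raw - L else end_raw
    data.frame(start = left, end = end, strand = h$strand, frame = h$frame,
               wraps_origin = wraps, span_nt = h$span, label = "unknown",
               protein = h$protein, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out <- cbind(orf_id = sprintf("ORF%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  class(out) <- c("orf_table", "data.frame")
  out
}

#' Assemble a genome annotation (ORFs plus terminal UTRs)
#'
#' @param g a [genome()].
#' @param orfs an `orf_table` from [find_orfs()] (optionally with labels
#'   filled in).
#' @return list of class `genome_annotation` with `genome`, `orfs`,
#'   `utr5`, `utr3` (UTRs are `NA` on circular genomes, where termini are
#'   undefined).
#' @export
annotate_genome <- function(g, orfs = find_orfs(g)) {
  stopifnot(inherits(g, "genome"))
  L <- nchar(g$seq)
  if (g$topology == "linear" && nrow(orfs) > 0) {
    utr5 <- min(orfs$start) - 1L
    utr3 <- L - max(orfs$end)
  } else {
    utr5 <- NA_integer_
    utr3 <- NA_integer_
  }
  structure(list(genome = g, orfs = orfs, utr5 = utr5, utr3 = utr3),
            class = "genome_annotation")
}

#' Terminal UTR lengths of a linear genome annotation
#'
#' The leading UTR is `first_orf$start - 1`; the trailing UTR is
#' `L - last_orf$end`. Undefined (error) for circular genomes or for
#' annotations without ORFs.
#'
#' @param ann a `genome_annotation`.
#' @return named integer vector `c(utr5 = ..., utr3 = ...)`.
#' @export
utr_lengths <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (ann$genome$topology == "circular")
    stop("UTRs are undefined on a circular genome", call. = FALSE)
  if (nrow(ann$orfs) == 0)
    stop("UTRs are undefined without at least one ORF", call. = FALSE)
  c(utr5 = min(ann$orfs$start) - 1L,
    utr3 = nchar(ann$genome$seq) - max(ann$orfs$end))
}

#' Construct a gene-order template
#'
#' @param id template identifier, e.g. `"L-G-N-(x)"`.
#' @param labels character vector of tokens in genome order. A plain label
#'   (`"N"`, `"G"`, `"L"`, ...) must be matched; a parenthesized token like
#'   `"(x)"` optionally matches zero or one ORF labeled `x` or `unknown`.
#' @param allow_extra_unlabeled may unlabeled/unknown ORFs be interspersed
#'   between the template's labels (default TRUE).
#' @return list of class `gene_order_template`.
#' @export
gene_order_template <- function(id, labels, allow_extra_unlabeled = TRUE) {
  core <- labels[!grepl("^\\(.*\\)$", labels)]
  if (!length(core)) stop("template needs at least one non-wildcard label", call. = FALSE)
  structure(list(id = id, labels = labels,
                 allow_extra_unlabeled = allow_extra_unlabeled),
            class = "gene_order_template")
}

#' Built-in family gene-order templates
#'
#' The chuvirus `L-G-N-(x)` order (with an optional extra ORF) and the
#' mononegavirus-style `N...G...L` order with unassigned ORFs permitted
#' between the core genes.
#'
#' @return list of [gene_order_template()]s, in matching priority order.
#' @export
default_gene_order_templates <- function() {
  list(gene_order_template("L-G-N-(x)", c("L", "G", "N", "(x)")),
       gene_order_template("N...G...L", c("N", "G", "L")))
}

match_label_seq <- function(lab, tpl) {
  # subsequence match of template tokens against the ordered ORF labels
  i <- 1L
  for (tok in tpl$labels) {
    optional <- grepl("^\\(.*\\)$", tok)
    want <- sub("^\\((.*)\\)$", "\\1", tok)
    matched <- FALSE
    j <- i
    while (j <= length(lab)) {
      ok <- if (optional) lab[j] %in% c(want, "unknown") else lab[j] == want
      if (ok) { i <- j + 1L; matched <- TRUE; break }
      if (!tpl$allow_extra_unlabeled && !optional) return(FALSE)
      if (!optional && lab[j] %in% c("N", "G", "L")) return(FALSE)  # core label out of order
      j <- j + 1L
    }
    if (!matched && !optional) return(FALSE)
  }
  TRUE
}

#' Classify a labeled ORF set against gene-order templates
#'
#' Returns the id of the first template whose non-wildcard labels appear,
#' in order, among the labeled ORFs. On circular genomes every rotation of
#' the ORF list is tried (gene order on a circle is defined up to
#' rotation). Template priority is input order.
#'
#' @param orfs an `orf_table` with a `label` column, or a character vector
#'   of labels in genome order.
#' @param templates list of [gene_order_template()]s (default
#'   [default_gene_order_templates()]).
#' @param circular logical; may the label sequence be rotated?
#' @return the matching template id, or `"unclassified"`.
#' @export
classify_gene_order <- function(orfs, templates = default_gene_order_templates(),
                                circular = FALSE) {
  if (!length(templates)) stop("empty template list", call. = FALSE)
  lab <- if (is.character(orfs)) orfs else orfs$label
  if (!length(lab) || all(lab == "unknown"))
    stop("at least one labeled ORF is required", call. = FALSE)
  rotations <- if (circular && length(lab) > 1) {
    lapply(seq_along(lab) - 1L, function(r) c(lab[-seq_len(r)], lab[seq_len(r)][r > 0]))
  } else list(lab)
  for (tpl in templates) {
    for (rot in rotations) {
      if (match_label_seq(rot, tpl)) return(tpl$id)
    }
  }
  "unclassified"
}

#' Write a genome annotation as GFF3
#'
#' One CDS feature per ORF; an origin-wrapping ORF is emitted as two CDS
#' parts sharing one `ID` attribute. Coordinates are 1-based inclusive.
#'
#' @param ann a `genome_annotation`.
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  orfs <- ann$orfs
  L <- nchar(ann$genome$seq)
  if (nrow(orfs) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  parts <- lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    if (isTRUE(o$wraps_origin)) {
      data.frame(start = c(o$start, 1L), end = c(L, o$end),
                 strand = o$strand, ID = o$orf_id, label = o$label)
    } else {
      data.frame(start = o$start, end = o$end, strand = o$strand,
                 ID = o$orf_id, label = o$label)
    }
  })
  pt <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$genome$id,
    ranges = IRanges::IRanges(start = pt$start, end = pt$end),
    strand = pt$strand)
  gr$source <- "vsikit"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- pt$ID
  gr$Name <- pt$label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write an ORF table as TSV
#'
#' @param orfs an `orf_table`.
#' @param path output path.
#' @export
write_orf_tsv <- function(orfs, path) {
  df <- orfs
  df$protein_len <- nchar(df$protein)
  df$protein <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
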