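#' Synthetic viral genomes, reads and protein families
#'
#' These generators plant known structure (ORF architecture, read origins,
#' size/strand/5'-nucleotide composition, coverage) and return it as ground
#' truth, so that every downstream stage of the pipeline can be validated
#' without external data. All generators are bit-reproducible for a fixed
#' seed.
#'
#' @name synthetic_data
NULL

# Stop-dense, start-free spacer fill. Each 24-nt unit is an 11-nt stop
# cassette ("TAAT" tiled: TAA stops at offsets 0, 4, 8 cover all three
# frames) followed by 13 random bases drawn from {C,G,T}. The cassette
# has no G and the filler no A, so a spacer contains no ATG anywhere
# (junctions included): spacers can never start an ORF, and any reading
# frame entering a spacer hits a stop within one unit. The random filler
# keeps spacers non-repetitive, so reads drawn from them do not multimap
# across spacer copies.
spacer_fill <- function(n, gc = 0.45) {
  if (n <= 0) return("")
  cassette <- "TAATTAATTAA"
  p <- c(C = gc / 2, G = gc / 2, T = 1 - gc)
  n_unit <- n %/% 24 + 1L
  filler <- matrix(sample(names(p), 13L * n_unit, replace = TRUE, prob = p),
                   nrow = n_unit)
  units <- paste0(cassette, apply(filler, 1L, paste, collapse = ""))
  substr(paste(units, collapse = ""), 1L, n)
}

random_codons <- function(n, gc) {
  if (n <= 0) return(character(0))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(k) {
    b <- matrix(sample(names(p), 3L * k, replace = TRUE, prob = p), ncol = 3L)
    paste0(b[, 1], b[, 2], b[, 3])
  }
  cod <- draw(n)
  bad <- cod %in% STOP_CODONS
  while (any(bad)) {
    cod[bad] <- draw(sum(bad))
    bad <- cod %in% STOP_CODONS
  }
  cod
}

# Coding-strand maximal-ORF scan used by the generator to reject interiors
# that spawn spurious ORFs in shifted frames. Independent of find_orfs().
orf_scan_coding <- function(seq, min_len, circular = FALSE) {
  L <- nchar(seq)
  s <- if (circular) paste0(seq, seq) else seq
  hits <- list()
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
      skip_region <- circular && prev == 0L   # context incomplete; seen again next lap
      prev <- si
      if (skip_region || !length(a)) next
      a <- a[1]
      span <- (si - a + 1L) * 3L
      nt_start <- ((f + 3L * (a - 1L)) %% L) + 1L
      if (span >= min_len && span <= L)
        hits[[length(hits) + 1L]] <- c(nt_start, span)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(0), span = integer(0)))
  m <- unique(do.call(rbind, hits))
  data.frame(start = m[, 1], span = m[, 2])
}

#' Generate a viral genome with a planted gene architecture
#'
#' Builds a genome whose coding regions are planted at known coordinates
#' with functional labels following a family template: `"nyamivirus"`
#' (linear, N ... G ... L gene order) or `"chuvirus"` (circular,
#' L-G-N-(x) gene order). Each planted ORF begins with ATG and ends with a
#' stop codon; inter-ORF spacers are stop-codon-dense in every frame so
#' the planted set is exactly the set of coding-strand ORFs at or above
#' `min_spurious_len`.
#'
#' @param length total genome length in nt.
#' @param gc approximate GC fraction of ORF interiors and spacer filler
#'   (the fixed stop cassettes in spacers are A/T-only, so realized
#'   spacer GC runs below the target).
#' @param topology `"linear"` or `"circular"`.
#' @param architecture `"nyamivirus"` or `"chuvirus"`; controls the label
#'   order assigned to the planted ORFs.
#' @param orf_lengths integer vector of ORF spans in nt (each divisible by
#'   3, at least 2 codons), in genome order.
#' @param seed integer seed; the generator is deterministic given it.
#' @param orf_starts optional explicit 1-based start coordinates (same
#'   length as `orf_lengths`, non-overlapping, in increasing order). When
#'   `NULL` the ORFs are spaced evenly.
#' @param labels optional character vector of labels; defaults follow the
#'   architecture template.
#' @param min_spurious_len no unplanted coding-strand ORF of at least this
#'   span (nt) will exist in the output (default 300).
#' @return an object of class `genome_truth`: list with elements `genome`
#'   (a [genome()]), `orfs` (data frame of planted coordinates and
#'   labels), `architecture`, and `params`.
#' @export
gen_viral_genome <- function(length, gc = 0.45,
                             topology = c("linear", "circular"),
                             architecture = c("nyamivirus", "chuvirus"),
                             orf_lengths, seed,
                             orf_starts = NULL, labels = NULL,
                             min_spurious_len = 300L) {
  topology <- match.arg(topology)
  architecture <- match.arg(architecture)
  k <- base::length(orf_lengths)
  if (any(orf_lengths %% 3 != 0) || any(orf_lengths < 6))
    stop("each orf_length must be divisible by 3 and span at least 2 codons", call. = FALSE)
  if (min_spurious_len > min(orf_lengths))
    stop("min_spurious_len exceeds the shortest planted ORF", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (architecture == "nyamivirus") {
      if (k < 3) stop("nyamivirus template needs >= 3 ORFs", call. = FALSE)
      c("N", rep("unknown", k - 3L), "G", "L")
    } else {
      if (k < 3) stop("chuvirus template needs >= 3 ORFs", call. = FALSE)
      c("L", "G", "N", rep("x", k - 3L))
    }
  }
  stopifnot(base::length(labels) == k)

  length <- as.integer(length)
  orf_lengths <- as.integer(orf_lengths)
  if (!is.null(orf_starts)) orf_starts <- as.integer(orf_starts)
  if (is.null(orf_starts)) {
    slack <- length - sum(orf_lengths)
    if (slack < 12L * (k + 1L))
      stop("infeasible packing: genome too short for requested ORFs and spacers", call. = FALSE)
    gap <- slack %/% (k + 1L)
    orf_starts <- integer(k)
    pos <- gap + 1L
    for (i in seq_len(k)) {
      orf_starts[i] <- pos
      pos <- pos + orf_lengths[i] + gap
    }
  }
  ends <- orf_starts + orf_lengths - 1L
  if (any(orf_starts < 1L) || any(ends > length) ||
      (k > 1 && any(orf_starts[-1] <= ends[-k])))
    stop("infeasible packing: ORF coordinates overlap or exceed the genome", call. = FALSE)
  # each inter-ORF spacer must hold at least one full stop cassette so a
  # frame running out of one ORF is terminated before the next
  gaps <- if (k > 1) orf_starts[-1] - ends[-k] - 1L else integer(0)
  if (topology == "circular")
    gaps <- c(gaps, (length - ends[k]) + (orf_starts[1] - 1L))
  if (any(gaps < 12L))
    stop("infeasible packing: inter-ORF spacers must be at least 12 nt", call. = FALSE)

  withr::with_seed(seed, {
    for (attempt in 1:25) {
      chunks <- character(0)
      cursor <- 1L
      for (i in seq_len(k)) {
        chunks <- c(chunks, spacer_fill(orf_starts[i] - cursor, gc))
        ncod <- orf_lengths[i] %/% 3L
        body <- paste(random_codons(ncod - 2L, gc), collapse = "")
        chunks <- c(chunks, paste0("ATG", body, sample(STOP_CODONS, 1L)))
        cursor <- ends[i] + 1L
      }
      chunks <- c(chunks, spacer_fill(length - cursor + 1L, gc))
      seq <- paste(chunks, collapse = "")
      stopifnot(nchar(seq) == length)
      found <- orf_scan_coding(seq, min_spurious_len, circular = topology == "circular")
      planted <- data.frame(start = orf_starts, span = orf_lengths)
      extras <- nrow(merge(found, planted)) < nrow(found)
      if (!extras) break
      if (attempt == 25) stop("could not avoid spurious ORFs; relax min_spurious_len", call. = FALSE)
    }
  })

  g <- genome(seq, topology, id = sprintf("synthetic_%s", architecture))
  orfs <- data.frame(start = orf_starts, end = ends, strand = "+",
                     frame = (orf_starts - 1L) %% 3L,
                     wraps_origin = FALSE, label = labels,
                     span_nt = orf_lengths, stringsAsFactors = FALSE)
  structure(list(genome = g, orfs = orfs, architecture = architecture,
                 params = list(length = length, gc = gc, topology = topology,
                               orf_lengths = orf_lengths, seed = seed,
                               min_spurious_len = min_spurious_len)),
            class = "genome_truth")
}

#' Simulation parameters for a Dicer-like small-RNA population
#'
#' @param n_viral number of virus-derived reads.
#' @param n_background number of host-background reads (rejection-sampled
#'   so they occur nowhere on either genome strand).
#' @param size_probs named numeric vector mapping read length (18..30 nt)
#'   to probability; must sum to 1. The default peaks at 21 nt, the
#'   canonical Dicer-2 product size in insects.
#' @param sense_fraction probability a viral read derives from the sense
#'   strand.
#' @param au5_fraction probability the 5'-terminal A/U bias event fires
#'   for a read (see [gen_vsirna_reads()]).
#' @param hotspots optional data frame with columns `position` and
#'   `weight`: origin positions whose sampling weight is multiplied.
#' @param seed integer seed.
#' @return a list of class `srna_sim_params`.
#' @export
srna_sim_params <- function(n_viral = 20000L, n_background = 5000L,
                            size_probs = default_size_probs(),
                            sense_fraction = 0.5, au5_fraction = 0.8,
                            hotspots = NULL, seed = 1L) {
  if (abs(sum(size_probs) - 1) > 1e-9) stop("size_probs must sum to 1", call. = FALSE)
  if (sense_fraction < 0 || sense_fraction > 1) stop("sense_fraction out of [0,1]", call. = FALSE)
  if (au5_fraction < 0 || au5_fraction > 1) stop("au5_fraction out of [0,1]", call. = FALSE)
  if (is.null(names(size_probs))) stop("size_probs must be named by length", call. = FALSE)
  structure(list(n_viral = n_viral, n_background = n_background,
                 size_probs = size_probs, sense_fraction = sense_fraction,
                 au5_fraction = au5_fraction, hotspots = hotspots, seed = seed),
            class = "srna_sim_params")
}

#' Default vsiRNA size distribution (peaked at 21 nt)
#'
#' 19:0.05, 20:0.15, 21:0.45, 22:0.25, 23:0.05, remainder uniform over the
#' rest of 18..30.
#'
#' @return named numeric vector over lengths 18..30.
#' @export
default_size_probs <- function() {
  p <- setNames(rep(0, 13), 18:30)
  p[c("19", "20", "21", "22", "23")] <- c(0.05, 0.15, 0.45, 0.25, 0.05)
  rest <- names(p)[p == 0]
  p[rest] <- (1 - sum(p)) / base::length(rest)
  p
}

#' Generate a virus-derived small-RNA population with ground truth
#'
#' Viral reads are exact substrings of the genome (sense) or of its
#' reverse complement (antisense), as required by zero-mismatch mapping.
#' The 5'-A/U bias is imposed by origin resampling, never by editing the
#' read: when the bias event fires (probability `au5_fraction`) the origin
#' is redrawn until the read's first base as sequenced is A or T (up to 50
#' attempts, then accepted as-is and flagged in the truth table).
#' Background reads are i.i.d. random sequences rejection-sampled against
#' both genome strands, so "background maps nowhere" is a hard invariant.
#'
#' @param truth a `genome_truth` from [gen_viral_genome()], or a [genome()].
#' @param params an [srna_sim_params()].
#' @return list of class `srna_sim`: `reads` (a [seq_set()] of viral then
#'   background reads), `truth` (data frame: read_id, origin, strand,
#'   length, viral, first_base, au_forced, au_failed), `params`.
#' @export
gen_vsirna_reads <- function(truth, params) {
  g <- if (inherits(truth, "genome_truth")) truth$genome else truth
  stopifnot(inherits(g, "genome"), inherits(params, "srna_sim_params"))
  L <- nchar(g$seq)
  lens_avail <- as.integer(names(params$size_probs))
  if (any(lens_avail[params$size_probs > 0] > L))
    stop("sampled read lengths exceed the genome length", call. = FALSE)
  Sd <- paste0(g$seq, g$seq)   # wrap-capable extraction buffer
  circ <- g$topology == "circular"
  w <- rep(1, L)
  if (!is.null(params$hotspots))
    w[params$hotspots$position] <- w[params$hotspots$position] * params$hotspots$weight

  withr::with_seed(derive_seed(params$seed, 1L), {
    n <- params$n_viral
    out_reads <- character(0)
    tr <- NULL
    if (n > 0) {
      len <- sample(lens_avail, n, replace = TRUE, prob = params$size_probs)
      strand <- ifelse(runif(n) < params$sense_fraction, "+", "-")
      au <- runif(n) < params$au5_fraction

      draw_origin <- function(m, ln) {
        pos <- sample.int(L, m, replace = TRUE, prob = w)
        if (!circ) {
          bad <- pos + ln - 1L > L
          while (any(bad)) {
            pos[bad] <- sample.int(L, sum(bad), replace = TRUE, prob = w)
            bad <- pos + ln - 1L > L
          }
        }
        pos
      }
      first_base_at <- function(pos, ln, strand) {
        ifelse(strand == "+",
               substring(Sd, pos, pos),
               chartr("ACGT", "TGCA", substring(Sd, pos + ln - 1L, pos + ln - 1L)))
      }

      pos <- draw_origin(n, len)
      fb <- first_base_at(pos, len, strand)
      au_failed <- rep(FALSE, n)
      need <- au & !(fb %in% c("A", "T"))
      attempts <- 0L
      while (any(need) && attempts < 50L) {
        idx <- which(need)
        pos[idx] <- draw_origin(base::length(idx), len[idx])
        fb[idx] <- first_base_at(pos[idx], len[idx], strand[idx])
        need <- au & !(fb %in% c("A", "T"))
        attempts <- attempts + 1L
      }
      au_failed[need] <- TRUE

      fwd <- substring(Sd, pos, pos + len - 1L)
      out_reads <- ifelse(strand == "+", fwd, rev_comp(fwd))
      tr <- data.frame(read_id = sprintf("vsir_%05d", seq_len(n)),
                       origin = pos, strand = strand, length = len,
                       viral = TRUE, first_base = chartr("T", "U", fb),
                       au_forced = au, au_failed = au_failed,
                       stringsAsFactors = FALSE)
    }

    nb <- params$n_background
    bg <- character(0)
    if (nb > 0) {
      blen <- sample(lens_avail, nb, replace = TRUE, prob = params$size_probs)
      search_space <- if (circ) c(Sd, rev_comp(Sd)) else c(g$seq, rev_comp(g$seq))
      gen_bg <- function(ln) {
        paste(sample(c("A", "C", "G", "T"), ln, replace = TRUE), collapse = "")
      }
      bg <- vapply(blen, gen_bg, "")
      occurs <- function(x) {
        vapply(x, function(r) any(stringi::stri_detect_fixed(search_space, r)), NA)
      }
      bad <- occurs(bg)
      while (any(bad)) {
        bg[bad] <- vapply(blen[bad], gen_bg, "")
        bad <- occurs(bg)
      }
      btr <- data.frame(read_id = sprintf("bg_%05d", seq_len(nb)),
                        origin = NA_integer_, strand = NA_character_,
                        length = blen, viral = FALSE, first_base = NA_character_,
                        au_forced = FALSE, au_failed = FALSE,
                        stringsAsFactors = FALSE)
      tr <- rbind(tr, btr)
    }
    reads <- seq_set(tr$read_id, c(out_reads, bg))
    structure(list(reads = reads, truth = tr, params = params, genome = g),
              class = "srna_sim")
  })
}

#' Generate uniform-coverage RNA-seq reads
#'
#' Draws `round(mean_coverage * L / read_len)` reads with uniform origins;
#' on a circular genome origins near the end wrap past the origin, on a
#' linear genome origins are uniform over `1..L-read_len+1`.
#'
#' @param g a [genome()].
#' @param mean_coverage target mean per-base depth.
#' @param read_len read length in nt.
#' @param seed integer seed.
#' @return list of class `rnaseq_sim`: `reads` (a [seq_set()]), `truth`
#'   (read_id, origin, wraps_origin).
#' @export
gen_rnaseq_reads <- function(g, mean_coverage, read_len, seed) {
  stopifnot(inherits(g, "genome"))
  L <- nchar(g$seq)
  if (read_len > L) stop("read_len exceeds genome length", call. = FALSE)
  n <- round(mean_coverage * L / read_len)
  withr::with_seed(derive_seed(seed, 2L), {
    if (n == 0) {
      return(structure(list(reads = seq_set(character(0), character(0)),
                            truth = data.frame(read_id = character(0),
                                               origin = integer(0),
                                               wraps_origin = logical(0))),
                       class = "rnaseq_sim"))
    }
    pos <- if (g$topology == "circular") sample.int(L, n, replace = TRUE)
           else sample.int(L - read_len + 1L, n, replace = TRUE)
    Sd <- paste0(g$seq, g$seq)
    reads <- substring(Sd, pos, pos + read_len - 1L)
    tr <- data.frame(read_id = sprintf("rna_%06d", seq_len(n)),
                     origin = pos, wraps_origin = pos + read_len - 1L > L,
                     stringsAsFactors = FALSE)
    structure(list(reads = seq_set(tr$read_id, reads), truth = tr,
                   params = list(mean_coverage = mean_coverage,
                                 read_len = read_len, seed = seed)),
              class = "rnaseq_sim")
  })
}

#' Mutate a protein to a target pairwise identity
#'
#' Substitutes exactly `round((1 - target_identity) * nchar(protein))`
#' positions, chosen without replacement, each with a different residue;
#' no indels, so ungapped alignment recovers the target identity exactly.
#'
#' @param protein protein string.
#' @param target_identity fraction in (0, 1].
#' @param seed integer seed.
#' @return mutated protein string.
#' @export
mutate_protein <- function(protein, target_identity, seed) {
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]", call. = FALSE)
  n <- nchar(protein)
  k <- round((1 - target_identity) * n)
  if (k == 0) return(protein)
  aa20 <- AA_ALPHABET[1:20]
  withr::with_seed(derive_seed(seed, 3L), {
    pos <- sample.int(n, k)
    chars <- strsplit(protein, "")[[1]]
    chars[pos] <- vapply(chars[pos], function(a) sample(setdiff(aa20, a), 1L), "")
    paste(chars, collapse = "")
  })
}

#' Synthetic stand-in for the AINlV1 nyamivirus genome
#'
#' A 9873-nt linear genome reproducing the published coordinate
#' architecture of Aulacophora indica nyami-like virus 1 (GenBank
#' PP888187): nucleoprotein ORF at 91-1077 (hence a 90-nt leading UTR),
#' glycoprotein ORF at 2674-4101, and polymerase ORF at 4185-4955. The
#' sequence itself is synthetic (planted, not the deposited record) and is
#' intended for offline regression of the annotation stack.
#'
#' @param seed integer seed.
#' @return a `genome_truth`.
#' @export
synthetic_ainlv1_genome <- function(seed = 101L) {
  gen_viral_genome(length = 9873L, gc = 0.45, topology = "linear",
                   architecture = "nyamivirus",
                   orf_lengths = c(987L, 1428L, 771L),
                   orf_starts = c(91L, 2674L, 4185L),
                   labels = c("N", "G", "L"), seed = seed)
}

#' Synthetic stand-in for the AIClV1 chuvirus genome
#'
#' An 11590-nt circular genome reproducing the published coordinate
#' architecture of Aulacophora indica chu-like virus 1 (GenBank PP888188):
#' L protein ORF at 70-6708, glycoprotein at 7242-9272, nucleoprotein at
#' 9631-10971, and an unassigned ORF at 11079-11528 — the chuvirus
#' L-G-N-(x) gene order on a circular replicon. The sequence itself is
#' synthetic (planted, not the deposited record).
#'
#' @param seed integer seed.
#' @return a `genome_truth`.
#' @export
synthetic_aiclv1_genome <- function(seed = 102L) {
  gen_viral_genome(length = 11590L, gc = 0.40, topology = "circular",
                   architecture = "chuvirus",
                   orf_lengths = c(6639L, 2031L, 1341L, 450L),
                   orf_starts = c(70L, 7242L, 9631L, 11079L),
                   labels = c("L", "G", "N", "x"), seed = seed,
                   min_spurious_len = 300L)
}
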