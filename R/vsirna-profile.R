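#' Filter small-RNA reads by length
#'
#' Keeps reads with `lo <= length <= hi` (bounds inclusive), preserving
#' input order. Defaults to the 18-30 nt small-RNA window.
#'
#' @param reads a [seq_set()].
#' @param lo,hi inclusive length bounds in nt.
#' @return a [seq_set()].
#' @export
length_filter <- function(reads, lo = 18L, hi = 30L) {
  stopifnot(inherits(reads, "seq_set"), lo <= hi)
  out <- reads[nchar(reads$seq) >= lo & nchar(reads$seq) <= hi, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Size-by-strand distribution of mapped small RNAs
#'
#' Counts (or fractional weights, under the fractional policy) by read
#' length and strand. The modal length maximizes the length marginal;
#' ties resolve to the smallest length.
#'
#' @param mapped a [map_reads()] result.
#' @param lo,hi length range of the table (default 18-30 nt).
#' @return list of class `size_distribution`: `counts` (matrix lengths x
#'   strands), `mode_length`, `total`.
#' @export
size_strand_distribution <- function(mapped, lo = 18L, hi = 30L) {
  stopifnot(inherits(mapped, "mapped_read_set"))
  lens <- lo:hi
  counts <- matrix(0, nrow = length(lens), ncol = 2,
                   dimnames = list(as.character(lens), c("+", "-")))
  pl <- mapped$placements
  pl <- pl[pl$length >= lo & pl$length <= hi, , drop = FALSE]
  if (nrow(pl) > 0) {
    agg <- rowsum(pl$weight, paste(pl$length, pl$strand))
    key <- do.call(rbind, strsplit(rownames(agg), " "))
    counts[cbind(key[, 1], key[, 2])] <- agg[, 1]
  }
  marg <- rowSums(counts)
  mode_length <- as.integer(names(marg)[which.max(marg)])  # which.max: first = smallest on ties
  structure(list(counts = counts, mode_length = mode_length,
                 total = sum(counts)),
            class = "size_distribution")
}

#' 5'-terminal nucleotide preference at a focal length
#'
#' Computed over mapped reads of exactly `focal_length` nt, using the
#' read's own first nucleotide as sequenced (for a minus-strand placement
#' this is the complement of the genome base at `position + length - 1`)
#' — the convention under which Dicer/Argonaute 5' bias is defined.
#' T is reported as U.
#'
#' @param mapped a [map_reads()] result.
#' @param focal_length read length analyzed (default 21 nt, the dominant
#'   Dicer-2 product).
#' @return list of class `five_prime_preference`: `focal_length`,
#'   `fractions` (named over A,C,G,U), `au_fraction`, `n` (weight used).
#'   With no focal-length reads the fractions are `NA` and `n` is 0.
#' @export
five_prime_preference <- function(mapped, focal_length = 21L) {
  stopifnot(inherits(mapped, "mapped_read_set"))
  pl <- mapped$placements
  pl <- pl[pl$length == focal_length, , drop = FALSE]
  fr <- setNames(rep(NA_real_, 4), c("A", "C", "G", "U"))
  n <- 0
  if (nrow(pl) > 0) {
    agg <- rowsum(pl$weight, pl$first_base)
    n <- sum(agg)
    fr[] <- 0
    fr[rownames(agg)] <- agg[, 1] / n
  }
  structure(list(focal_length = focal_length, fractions = fr,
                 au_fraction = if (n > 0) unname(fr["A"] + fr["U"]) else NA_real_,
                 n = n),
            class = "five_prime_preference")
}

#' Positional profile of small-RNA 5' ends along the genome
#'
#' Deposits each placement's weight at the genome coordinate of the
#' read's 5' end, strand-resolved: `position` for plus-strand reads,
#' `position + length - 1` (modulo L when wrapping) for minus-strand
#' reads.
#'
#' @param mapped a [map_reads()] result.
#' @return list of class `positional_profile`: `plus` and `minus`
#'   (length-L numeric vectors of 5'-end weight), `total`.
#' @export
positional_profile <- function(mapped) {
  stopifnot(inherits(mapped, "mapped_read_set"))
  L <- nchar(mapped$genome$seq)
  plus <- numeric(L)
  minus <- numeric(L)
  pl <- mapped$placements
  if (nrow(pl) > 0) {
    p5 <- ifelse(pl$strand == "+", pl$position,
                 ((pl$position + pl$length - 2L) %% L) + 1L)
    for (s in c("+", "-")) {
      sel <- pl$strand == s
      if (!any(sel)) next
      agg <- rowsum(pl$weight[sel], p5[sel])
      v <- numeric(L)
      v[as.integer(rownames(agg))] <- agg[, 1]
      if (s == "+") plus <- v else minus <- v
    }
  }
  structure(list(plus = plus, minus = minus, total = sum(plus) + sum(minus)),
            class = "positional_profile")
}

#' Call positional hotspots by windowed z-score
#'
#' Tiles the genome in non-overlapping windows and reports, per strand,
#' windows whose total 5'-end weight exceeds `mean + z * sd` of the
#' window weights on that strand. This is an operational definition of
#' "regions preferred by Dicer targeting"; window size and z threshold
#' are stamped into the result.
#'
#' @param profile a [positional_profile()] result.
#' @param window window size in nt (default 50).
#' @param z z-score threshold (default 3).
#' @return data frame of class `hotspot_table`: `window_start`, `strand`,
#'   `weight`, `zscore`; attributes `window` and `z`.
#' @export
call_hotspots <- function(profile, window = 50L, z = 3.0) {
  stopifnot(inherits(profile, "positional_profile"))
  L <- length(profile$plus)
  if (window > L) stop("window exceeds genome length", call. = FALSE)
  starts <- seq(1L, L, by = window)
  bin <- findInterval(seq_len(L), starts)
  rows <- list()
  for (s in c("+", "-")) {
    v <- if (s == "+") profile$plus else profile$minus
    wsum <- as.numeric(rowsum(v, bin))
    mu <- mean(wsum)
    sdev <- sd(wsum)
    if (!is.finite(sdev) || sdev == 0) next
    zs <- (wsum - mu) / sdev
    hit <- which(wsum > mu + z * sdev)
    for (h in hit)
      rows[[length(rows) + 1L]] <- data.frame(window_start = starts[h],
                                              strand = s, weight = wsum[h],
                                              zscore = zs[h])
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(window_start = integer(0), strand = character(0),
                         weight = numeric(0), zscore = numeric(0))
  out <- out[order(out$window_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "z") <- z
  class(out) <- c("hotspot_table", "data.frame")
  out
}

#' Full vsiRNA report
#'
#' Runs the profiling stages on an input read set and its mapping and
#' collects totals (input, in-range, mapped, multimapped), the sense-strand
#' weight fraction, the size-by-strand distribution, the 5'-terminal
#' preference at the focal length, the positional profile and called
#' hotspots, together with the parameters used.
#'
#' @param reads the raw input [seq_set()] (before length filtering).
#' @param mapped the [map_reads()] result for the length-filtered reads.
#' @param lo,hi small-RNA length window (default 18-30 nt).
#' @param focal_length 5'-preference focal length (default 21 nt).
#' @param hotspot_window,hotspot_z hotspot-calling parameters.
#' @return list of class `vsirna_report`.
#' @export
summarize_vsirna <- function(reads, mapped, lo = 18L, hi = 30L,
                             focal_length = 21L,
                             hotspot_window = 50L, hotspot_z = 3.0) {
  stopifnot(inherits(reads, "seq_set"), inherits(mapped, "mapped_read_set"))
  in_range <- sum(nchar(reads$seq) >= lo & nchar(reads$seq) <= hi)
  sizes <- size_strand_distribution(mapped, lo, hi)
  pos <- positional_profile(mapped)
  plus_w <- sum(mapped$placements$weight[mapped$placements$strand == "+"])
  total_w <- sum(mapped$placements$weight)
  structure(list(
    totals = list(input_reads = nrow(reads), in_range_reads = in_range,
                  mapped_reads = mapped$n_mapped,
                  multimapped_dropped = mapped$n_multi_dropped,
                  mapped_weight = total_w),
    sense_fraction = if (total_w > 0) plus_w / total_w else NA_real_,
    size_distribution = sizes,
    five_prime = five_prime_preference(mapped, focal_length),
    positional = pos,
    hotspots = call_hotspots(pos, hotspot_window, hotspot_z),
    params = list(lo = lo, hi = hi, focal_length = focal_length,
                  hotspot_window = hotspot_window, hotspot_z = hotspot_z,
                  mapper_policy = mapped$policy)),
    class = "vsirna_report")
}

#' @export
print.vsirna_report <- function(x, ...) {
  cat(sprintf(paste0("<vsirna_report> %d input, %d in 18-30 nt range, %d mapped\n",
                     "  mode length %d nt; sense fraction %.3f; 5' A/U fraction (%d nt) %.3f\n",
                     "  %d hotspot window(s)\n"),
              x$totals$input_reads, x$totals$in_range_reads, x$totals$mapped_reads,
              x$size_distribution$mode_length, x$sense_fraction,
              x$five_prime$focal_length, x$five_prime$au_fraction,
              nrow(x$hotspots)))
  invisible(x)
}

#' Serialize a vsiRNA report to JSON and per-panel TSV tables
#'
#' Writes `vsirna_report.json` plus `size_dist.tsv`, `fiveprime.tsv`,
#' `positional_plus.tsv`, `positional_minus.tsv` and `hotspots.tsv` under
#' `dir`. Output is deterministic: two runs on identical input are
#' byte-identical.
#'
#' @param report a [summarize_vsirna()] result.
#' @param dir output directory (created if needed).
#' @export
write_vsirna_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sd <- report$size_distribution
  js <- list(totals = report$totals,
             sense_fraction = report$sense_fraction,
             mode_length = sd$mode_length,
             size_counts = as.data.frame.table(sd$counts, responseName = "weight"),
             five_prime = list(focal_length = report$five_prime$focal_length,
                               fractions = as.list(report$five_prime$fractions),
                               au_fraction = report$five_prime$au_fraction),
             hotspots = report$hotspots,
             params = report$params)
  jsonlite::write_json(js, file.path(dir, "vsirna_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(as.data.frame.table(sd$counts, responseName = "weight",
                                  stringsAsFactors = FALSE),
              file.path(dir, "size_dist.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- report$five_prime
  write.table(data.frame(base = names(fp$fractions), fraction = fp$fractions),
              file.path(dir, "fiveprime.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(position = seq_along(report$positional$plus),
                         weight = report$positional$plus),
              file.path(dir, "positional_plus.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(position = seq_along(report$positional$minus),
                         weight = report$positional$minus),
              file.path(dir, "positional_minus.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$hotspots, file.path(dir, "hotspots.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
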