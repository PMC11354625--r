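# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
random_aa <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, TRUE), collapse = "")
}

# full-scan exact mapper: try every start position on both strands by
# direct (modular) substring comparison
naive_map_oracle <- function(g, read) {
  L <- nchar(g$seq)
  len <- nchar(read)
  circ <- g$topology == "circular"
  Sd <- if (circ) paste0(g$seq, g$seq) else g$seq
  n_start <- if (circ) L else L - len + 1L
  if (n_start < 1 || grepl("N", read, fixed = TRUE))
    return(data.frame(position = integer(0), strand = character(0)))
  windows <- substring(Sd, seq_len(n_start), seq_len(n_start) + len - 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out <- rbind(
    data.frame(position = which(windows == read),
               strand = rep("+", sum(windows == read))),
    data.frame(position = which(windows == rc),
               strand = rep("-", sum(windows == rc))))
  out[order(out$position, out$strand), , drop = FALSE]
}

# naive maximal-ORF scan: every position, every strand, walk codons
# forward to the stop and backward to verify the ATG is the first one in
# its open region
orf_brute_oracle <- function(g, min_len, both_strands = FALSE) {
  L <- nchar(g$seq)
  circ <- g$topology == "circular"
  stops <- c("TAA", "TAG", "TGA")
  codon_at <- function(s, p, Ls) {
    if (p + 2L <= Ls) substr(s, p, p + 2L)
    else paste0(substr(s, p, Ls), substr(s, 1L, p + 2L - Ls))  # circular wrap
  }
  scan1 <- function(s, strand) {
    res <- list()
    for (p in seq_len(L)) {
      if (circ) {
        if (codon_at(s, p, L) != "ATG") next
      } else {
        if (p + 2L > L || substr(s, p, p + 2L) != "ATG") next
      }
      # walk forward to the stop
      q <- p
      span <- NA_integer_
      steps <- 0L
      while (steps <= L %/% 3L) {
        cod <- if (circ) codon_at(s, ((q - 1L) %% L) + 1L, L)
               else { if (q + 2L > L) break else substr(s, q, q + 2L) }
        if (cod %in% stops && steps > 0L) { span <- steps * 3L + 3L; break }
        if (cod %in% stops && steps == 0L) break
        q <- q + 3L
        steps <- steps + 1L
      }
      if (is.na(span) || span < min_len || span > L) next
      # maximality: walk backward; reaching a stop (or the linear start)
      # before another ATG means p is the first ATG of its region
      r <- p - 3L
      maximal <- TRUE
      back <- 0L
      while (back <= L %/% 3L) {
        if (!circ && r < 1L) break
        rp <- if (circ) ((r - 1L) %% L) + 1L else r
        if (!circ && rp + 2L > L) break
        cod <- codon_at(s, rp, L)
        if (cod %in% stops) break
        if (cod == "ATG") { maximal <- FALSE; break }
        r <- r - 3L
        back <- back + 1L
      }
      if (!maximal) next
      res[[length(res) + 1L]] <- data.frame(start_scan = p, span = span,
                                            strand = strand)
    }
    if (length(res)) do.call(rbind, res)
    else data.frame(start_scan = integer(0), span = integer(0),
                    strand = character(0))
  }
  out <- scan1(g$seq, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$seq)))
    rev_hits <- scan1(rc, "-")
    if (nrow(rev_hits)) {
      # leftmost plus-strand coordinate of the reverse ORF
      rc_end <- rev_hits$start_scan + rev_hits$span - 1L
      rev_hits$start_scan <- ((L - rc_end) %% L) + 1L
    }
    out <- rbind(out, rev_hits)
  }
  # normalize: plus-strand leftmost start, span
  names(out)[1] <- "start"
  unique(out[order(out$start, out$strand), , drop = FALSE])
}

# plain-R affine-gap DP, score only (no traceback, no pointer tricks)
affine_dp_score <- function(a, b, submat, open, extend, local = TRUE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- -(open + extend * (i - 2))
    for (j in 2:(m + 1)) Y[1, j] <- -(open + extend * (j - 2))
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- if (local) s + max(prev, 0) else s + prev
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open, Y[i, j - 1] - extend)
      if (local && M[i, j] > best) best <- M[i, j]
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive topology-enumeration oracle for 4- and 5-taxon distance
# matrices: pick the unrooted binary topology whose least-squares path
# fit has the smallest residual
enumerate_topologies <- function(taxa) {
  n <- length(taxa)
  if (n == 4) {
    combn(4, 2, simplify = FALSE)[1:3]  # {1,2},{1,3},{1,4} pair with complement
  } else if (n == 5) {
    prs <- combn(5, 2, simplify = FALSE)
    tops <- list()
    for (i in seq_along(prs)) for (j in seq_along(prs)) {
      if (i < j && !any(prs[[i]] %in% prs[[j]]))
        tops[[length(tops) + 1L]] <- list(prs[[i]], prs[[j]])
    }
    tops
  } else stop("only 4 or 5 taxa supported")
}

topology_newick <- function(taxa, top) {
  if (length(taxa) == 4) {
    p <- top; q <- setdiff(1:4, p)
    sprintf("((%s,%s),(%s,%s));", taxa[p[1]], taxa[p[2]], taxa[q[1]], taxa[q[2]])
  } else {
    p1 <- top[[1]]; p2 <- top[[2]]; z <- setdiff(1:5, c(p1, p2))
    sprintf("((%s,%s),%s,(%s,%s));", taxa[p1[1]], taxa[p1[2]], taxa[z],
            taxa[p2[1]], taxa[p2[2]])
  }
}

ls_topology_fit <- function(d, taxa, top) {
  tr <- ape::unroot(ape::read.tree(text = topology_newick(taxa, top)))
  tr$edge.length <- rep(1, nrow(tr$edge))
  # design matrix: which edges lie on the path between each leaf pair
  n <- length(taxa)
  pairs <- combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(tr$edge))
  dvec <- numeric(ncol(pairs))
  lab <- tr$tip.label
  for (kk in seq_len(ncol(pairs))) {
    t1 <- which(lab == taxa[pairs[1, kk]])
    t2 <- which(lab == taxa[pairs[2, kk]])
    pth <- ape::nodepath(tr, t1, t2)
    for (e in seq_len(nrow(tr$edge))) {
      i1 <- match(tr$edge[e, 1], pth)
      i2 <- match(tr$edge[e, 2], pth)
      if (!is.na(i1) && !is.na(i2) && abs(i1 - i2) == 1) A[kk, e] <- 1
    }
    dvec[kk] <- d[taxa[pairs[1, kk]], taxa[pairs[2, kk]]]
  }
  fit <- qr.solve(crossprod(A) + diag(1e-9, ncol(A)), crossprod(A, dvec))
  sum((A %*% fit - dvec)^2)
}

best_topology_oracle <- function(d) {
  taxa <- rownames(d)
  tops <- enumerate_topologies(taxa)
  resid <- vapply(tops, function(tp) ls_topology_fit(d, taxa, tp), 0)
  ape::read.tree(text = topology_newick(taxa, tops[[which.min(resid)]]))
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
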