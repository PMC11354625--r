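#' Optimal global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Terminal gaps are penalized; traceback ties resolve diagonal, then up,
#' then left. Identity is computed over all alignment columns, gaps
#' included (stated here because identity conventions vary).
#'
#' @param a,b protein strings.
#' @param scoring a [scoring_matrix()].
#' @return list of class `global_alignment`: `score`, `identity_pct`,
#'   `matches`, `columns`, `a_aln`, `b_aln`.
#' @export
needleman_wunsch <- function(a, b, scoring = scoring_matrix()) {
  r <- .nw_align_cpp(normalize_aa(a), normalize_aa(b),
                     scoring$matrix, scoring$gap_open, scoring$gap_extend)
  structure(list(score = r$score,
                 identity_pct = if (r$columns > 0) 100 * r$matches / r$columns else 0,
                 matches = r$matches, columns = r$columns,
                 a_aln = r$a_aln, b_aln = r$b_aln),
            class = "global_alignment")
}

#' Pairwise identity and distance matrices for a protein set
#'
#' Identity of each pair is computed over all columns of its global
#' alignment (gap columns count in the denominator); the distance matrix
#' is `d = 1 - identity / 100`.
#'
#' @param seqs a [seq_set()] of at least 2 proteins with unique ids.
#' @param scoring a [scoring_matrix()].
#' @return list of class `identity_matrix`: `identity` (symmetric
#'   percentage matrix, diagonal 100) and `distance` (symmetric, zero
#'   diagonal).
#' @export
pairwise_identity_matrix <- function(seqs, scoring = scoring_matrix()) {
  stopifnot(inherits(seqs, "seq_set"))
  n <- nrow(seqs)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  if (anyDuplicated(seqs$id)) stop("duplicate sequence ids", call. = FALSE)
  id <- matrix(100, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- needleman_wunsch(seqs$seq[i], seqs$seq[j], scoring)
      id[i, j] <- id[j, i] <- al$identity_pct
    }
  }
  structure(list(identity = id, distance = 1 - id / 100),
            class = "identity_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via `ape::nj`), which reconstructs additive
#' distance matrices exactly. Negative branch-length estimates are
#' clamped to zero and flagged via the `clamped_edges` attribute. Note
#' this is a deterministic distance-based method intended for topology
#' comparison, not a maximum-likelihood inference.
#'
#' @param d square symmetric distance matrix with taxa as dimnames (or
#'   the `distance` element of an [pairwise_identity_matrix()] result),
#'   at least 3 taxa.
#' @return an `ape::phylo` tree (unrooted) with attribute
#'   `clamped_edges` giving the number of negative estimates clamped.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "identity_matrix")) d <- d$distance
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(d < 0) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_edges") <- clamped
  tr
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a Newick tree
#'
#' Malformed input (unbalanced parentheses) raises an error reporting the
#' 1-based character offset of the problem.
#'
#' @param path file path or a literal Newick string.
#' @return an `ape::phylo`.
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "")
         else path
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unmatched ')' at offset ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at offset ",
         length(chars), call. = FALSE)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("malformed Newick: could not parse tree", call. = FALSE)
  tr
}

#' Write an identity matrix as TSV (percentages, 2 decimals)
#'
#' @param im an [pairwise_identity_matrix()] result.
#' @param path output path.
#' @export
write_identity_tsv <- function(im, path) {
  m <- format(round(im$identity, 2), nsmall = 2, trim = TRUE)
  df <- data.frame(taxon = rownames(im$identity), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
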