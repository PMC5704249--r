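# scoring used for every percent-identity computation in the package:
# match +1, mismatch -1, gap open 5, gap extend 2 (penalties)
.submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE, type = "DNA")
    cache
  }
})

#' Percent identity between two nucleotide sequences
#'
#' Aligns the pair and returns `100 * matches / alignment columns`, where the
#' columns include internal gap positions but exclude end gaps. Global mode
#' is an end-gap-free Needleman-Wunsch ("overlap") alignment; local mode is
#' Smith-Waterman. Both use match +1, mismatch -1, gap-open 5, gap-extend 2.
#' Symmetric in its arguments.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @param mode `"global"` (end-gap-free) or `"local"`.
#' @return Percent identity in \[0, 100\].
#' @examples
#' percent_identity(strrep("ACGT", 50), strrep("ACGT", 50))  # 100
#' @export
percent_identity <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- .normalize_seq(a, "sequence a")
  b <- .normalize_seq(b, "sequence b")
  type <- if (mode == "global") "overlap" else "local"
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = .submat(), gapOpening = 5, gapExtension = 2)
  p <- Biostrings::pid(aln, type = "PID1")
  # sequences with no positively scoring overlap align to zero columns
  if (is.nan(p)) 0 else p
}

# identities of one query against many subjects (same scoring); vectorized
.identities_vs <- function(query, subjects, mode = "global") {
  type <- if (mode == "global") "overlap" else "local"
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(subjects), Biostrings::DNAString(query),
    type = type, substitutionMatrix = .submat(),
    gapOpening = 5, gapExtension = 2)
  Biostrings::pid(aln, type = "PID1")
}

# coverage-aware identity for best-hit classification: matches over the
# shorter sequence length. The end-gap-free alignment of two unrelated
# sequences is typically a few-bp perfect end overlap, which would score
# near 100% under the column-wise definition; dividing by the shorter
# sequence length instead keeps unrelated queries near zero.
.class_identities <- function(query, subjects) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(subjects), Biostrings::DNAString(query),
    type = "overlap", substitutionMatrix = .submat(),
    gapOpening = 5, gapExtension = 2)
  100 * Biostrings::nmatch(aln) / pmin(nchar(subjects), nchar(query))
}

#' Pairwise percent-identity matrix over a labeled sequence set
#'
#' Computes each unordered pair once with [percent_identity()] and mirrors it.
#' Diagonal is 100.
#'
#' @param seqs Named character vector (labels must be unique), a
#'   `DNAStringSet`, or a FASTA path; at least 2 records.
#' @param mode Alignment mode, see [percent_identity()].
#' @return Symmetric numeric matrix with the labels as dimnames, class
#'   `identity_matrix`.
#' @export
identity_matrix <- function(seqs, mode = c("global", "local")) {
  mode <- match.arg(mode)
  seqs <- .as_named_sequences(seqs)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate labels in sequence set")
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    vals <- .identities_vs(seqs[[i]], unname(seqs[(i + 1L):n]), mode)
    m[i, (i + 1L):n] <- vals
    m[(i + 1L):n, i] <- vals
  }
  class(m) <- c("identity_matrix", class(m))
  m
}

# unordered off-diagonal pairs of a symmetric matrix, lexicographic order
.matrix_pairs <- function(m) {
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  a <- labs[idx[, 1L]]
  b <- labs[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(label_a = a, label_b = b, identity = m[idx],
                   stringsAsFactors = FALSE)
  df[order(df$label_a, df$label_b), , drop = FALSE]
}

#' Summarize the resolving power of an identity matrix
#'
#' Minimum, unweighted mean, and maximum of the off-diagonal identities over
#' the n(n-1)/2 unordered pairs. Ties for the extreme pairs are broken
#' lexicographically by label pair.
#'
#' @param m An [identity_matrix()].
#' @return List with `min_pair`, `min`, `mean`, `max_pair`, `max`; pairs are
#'   length-2 character vectors.
#' @export
resolution_summary <- function(m) {
  if (nrow(m) < 2L) stop("matrix must have at least 2 labels")
  p <- .matrix_pairs(m)
  imin <- which(p$identity == min(p$identity))[1L]
  imax <- which(p$identity == max(p$identity))[1L]
  list(min_pair = c(p$label_a[imin], p$label_b[imin]), min = p$identity[imin],
       mean = mean(p$identity),
       max_pair = c(p$label_a[imax], p$label_b[imax]), max = p$identity[imax])
}

#' Compare the resolving power of two markers over shared taxa
#'
#' For each label in the intersection of the two matrices, the per-label
#' average identity against all other shared labels is computed for both
#' markers; marker A's averages are regressed on marker B's by ordinary least
#' squares.
#'
#' @param mA,mB [identity_matrix()] objects; label intersection must be >= 3.
#' @return List with `labels`, `avg_a`, `avg_b` (named numeric), `slope`,
#'   `intercept`, `correlation`.
#' @export
compare_markers <- function(mA, mB) {
  shared <- intersect(rownames(mA), rownames(mB))
  if (length(shared) < 3L)
    stop("markers share only ", length(shared), " labels; need >= 3")
  avg <- function(m) {
    sub <- m[shared, shared, drop = FALSE]
    (rowSums(sub) - diag(sub)) / (length(shared) - 1L)
  }
  a <- avg(mA)
  b <- avg(mB)
  fit <- stats::lm(a ~ b)
  list(labels = shared, avg_a = a, avg_b = b,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       correlation = stats::cor(a, b))
}

#' Label pairs at or above an identity threshold
#'
#' Pairs a marker cannot tell apart at the given identity level, sorted by
#' descending identity.
#'
#' @param m An [identity_matrix()].
#' @param threshold Percent identity in (0, 100].
#' @return `data.frame` with `label_a`, `label_b`, `identity`.
#' @export
indistinguishable_pairs <- function(m, threshold) {
  if (!(threshold > 0 && threshold <= 100))
    stop("threshold must be in (0, 100]")
  p <- .matrix_pairs(m)
  p <- p[p$identity >= threshold, , drop = FALSE]
  p <- p[order(-p$identity, p$label_a, p$label_b), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Neighbor-joining tree from an identity matrix
#'
#' Converts identities to distances `d = (100 - identity) / 100` and builds
#' an unrooted neighbor-joining tree. Negative branch lengths arising from
#' the NJ estimates are clamped to zero.
#'
#' @param m An [identity_matrix()] with >= 3 labels.
#' @return An `ape` `phylo` object; serialize with [write_newick()].
#' @export
nj_tree <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 labels for a tree")
  d <- stats::as.dist((100 - unclass(m)) / 100)
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}
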