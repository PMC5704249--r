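# IUPAC nucleotide alphabet: bitwise encoding A=1, C=2, G=4, T=8 so that a
# degenerate code is the OR of its member bases. "Template letter compatible
# with primer letter" is then the subset test bitwAnd(t, p) == t.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# letters of each code's base set, for expansion
.IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Normalize a nucleotide string: upper-case, U -> T. Errors name the first
# offending position when a non-IUPAC character is present.
.normalize_seq <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !is.character(sequence))
    stop(what, " must be a single character string")
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC_BITS))
  if (length(bad) > 0L)
    stop("invalid IUPAC character '", chars[bad[1L]], "' at position ",
         bad[1L], " of ", what)
  s
}

# integer bit codes of a normalized sequence
.encode_bits <- function(s) {
  unname(.IUPAC_BITS[strsplit(s, "", fixed = TRUE)[[1L]]])
}

#' Expand a degenerate IUPAC sequence into its unambiguous instances
#'
#' A degenerate oligonucleotide written over the 15-letter IUPAC alphabet
#' stands for the pool of all unambiguous A/C/G/T sequences obtained by
#' substituting each ambiguity code with one member of its base set.
#'
#' @param sequence Character scalar over the IUPAC alphabet
#'   (`ACGTRYSWKMBDHVN`; case-insensitive, `U` is read as `T`).
#' @return Character vector of all unambiguous expansions; its length equals
#'   [degeneracy()] of the input.
#' @examples
#' iupac_expand("Y")           # "C" "T"
#' iupac_expand("ACGT")        # "ACGT"
#' length(iupac_expand("TCCGATTACGAYCGYGAGAAGCT"))  # 4
#' @export
iupac_expand <- function(sequence) {
  s <- .normalize_seq(sequence)
  sets <- .IUPAC_SET[strsplit(s, "", fixed = TRUE)[[1L]]]
  n <- prod(vapply(sets, length, integer(1L)))
  if (n > 2^20)
    stop("refusing to expand: degeneracy ", n, " exceeds 2^20")
  Reduce(function(acc, set) as.vector(t(outer(acc, set, paste0))), sets,
         accumulate = FALSE, init = "")
}

#' Degeneracy of an IUPAC sequence
#'
#' The number of unambiguous sequences the degenerate oligo represents:
#' the product of the per-position base-set sizes. Computed without
#' materializing the expansion.
#'
#' @inheritParams iupac_expand
#' @return Numeric scalar (may exceed integer range for long degenerate
#'   sequences).
#' @examples
#' degeneracy("N")                       # 4
#' degeneracy("CSGCYTCGGTSGTCAGGAACAG")  # 8
#' @export
degeneracy <- function(sequence) {
  s <- .normalize_seq(sequence)
  prod(vapply(.IUPAC_SET[strsplit(s, "", fixed = TRUE)[[1L]]],
              length, integer(1L)))
}

#' Reverse complement of an IUPAC sequence
#'
#' Degenerate codes map to the code of the complemented base set
#' (Y to R, S to S, W to W, K to M, B to V, D to H, N to N). The operation
#' is an involution and preserves degeneracy.
#'
#' @inheritParams iupac_expand
#' @return Character scalar, the reverse complement.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("CSGCYTCGGTSGTCAGGAACAG")
#' @export
reverse_complement <- function(sequence) {
  s <- .normalize_seq(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}
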