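# Independent oracles used by the property tests. These deliberately take
# different routes than the package code: degenerate matching goes through
# explicit expansion + plain character comparison, and percent identity
# through a small hand-rolled affine-gap dynamic program.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-window Hamming distances of an unambiguous pattern on a template
.oracle_hamming_windows <- function(template, pattern) {
  t <- utf8ToInt(template)
  p <- utf8ToInt(pattern)
  nw <- length(t) - length(p) + 1L
  if (nw < 1L) return(integer(0L))
  m <- integer(nw)
  for (j in seq_along(p)) m <- m + (t[j:(j + nw - 1L)] != p[j])
  m
}

# union over iupac_expand(primer) of exact scans with the mismatch budget;
# mismatch count per site = min over expansions
oracle_binding_sites <- function(template, primer_seq, max_mismatch,
                                 strand = "+") {
  pat <- if (strand == "+") primer_seq else
    groELprofiler::reverse_complement(primer_seq)
  expansions <- groELprofiler::iupac_expand(pat)
  per_window <- sapply(expansions, function(p)
    .oracle_hamming_windows(template, p))
  if (length(per_window) == 0L)
    return(data.frame(start = integer(0L), mismatches = integer(0L)))
  m <- if (is.matrix(per_window)) apply(per_window, 1L, min) else min(per_window)
  ok <- which(m <= max_mismatch)
  data.frame(start = ok, mismatches = m[ok])
}

# End-gap-free global alignment (Gotoh affine gaps), match +1 / mismatch -1 /
# gap-open 5 / gap-extend 2 (gap of length k costs 5 + 2k). Returns the
# optimal score and the percent identity (matches / alignment columns,
# end gaps excluded) of one optimal path.
oracle_align_overlap <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(av); m <- length(bv)
  open <- 5; ext <- 2
  NEG <- -1e9
  # state matrices: score, matches along best path, columns along best path
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  Mm <- Xm <- Ym <- matrix(0L, n + 1L, m + 1L)   # match counts
  Mc <- Xc <- Yc <- matrix(0L, n + 1L, m + 1L)   # column counts
  for (i in 1:n) for (j in 1:m) {
    s <- if (av[i] == bv[j]) 1 else -1
    # predecessors of M: diagonal in any state, or a free start on an edge
    cand <- c(M[i, j], X[i, j], Y[i, j],
              if (i == 1L || j == 1L) 0 else NEG)
    k <- which.max(cand)
    M[i + 1L, j + 1L] <- cand[k] + s
    prevm <- switch(k, Mm[i, j], Xm[i, j], Ym[i, j], 0L)
    prevc <- switch(k, Mc[i, j], Xc[i, j], Yc[i, j], 0L)
    Mm[i + 1L, j + 1L] <- prevm + (s > 0)
    Mc[i + 1L, j + 1L] <- prevc + 1L
    # gap in b (consume a[i])
    cand <- c(M[i, j + 1L] - open - ext, X[i, j + 1L] - ext,
              Y[i, j + 1L] - open - ext)
    k <- which.max(cand)
    X[i + 1L, j + 1L] <- cand[k]
    Xm[i + 1L, j + 1L] <- switch(k, Mm[i, j + 1L], Xm[i, j + 1L], Ym[i, j + 1L])
    Xc[i + 1L, j + 1L] <- switch(k, Mc[i, j + 1L], Xc[i, j + 1L], Yc[i, j + 1L]) + 1L
    # gap in a (consume b[j])
    cand <- c(M[i + 1L, j] - open - ext, Y[i + 1L, j] - ext,
              X[i + 1L, j] - open - ext)
    k <- which.max(cand)
    Y[i + 1L, j + 1L] <- cand[k]
    Ym[i + 1L, j + 1L] <- switch(k, Mm[i + 1L, j], Ym[i + 1L, j], Xm[i + 1L, j])
    Yc[i + 1L, j + 1L] <- switch(k, Mc[i + 1L, j], Yc[i + 1L, j], Xc[i + 1L, j]) + 1L
  }
  # free trailing gaps: best over the last row and last column, any state;
  # the empty alignment (score 0, no columns) is always available
  best <- 0; bm <- 0L; bc <- 0L
  consider <- function(sc, mm, cc) {
    if (sc > best) { best <<- sc; bm <<- mm; bc <<- cc }
  }
  for (i in 2:(n + 1L)) {
    consider(M[i, m + 1L], Mm[i, m + 1L], Mc[i, m + 1L])
    consider(X[i, m + 1L], Xm[i, m + 1L], Xc[i, m + 1L])
    consider(Y[i, m + 1L], Ym[i, m + 1L], Yc[i, m + 1L])
  }
  for (j in 2:(m + 1L)) {
    consider(M[n + 1L, j], Mm[n + 1L, j], Mc[n + 1L, j])
    consider(X[n + 1L, j], Xm[n + 1L, j], Xc[n + 1L, j])
    consider(Y[n + 1L, j], Ym[n + 1L, j], Yc[n + 1L, j])
  }
  list(score = best,
       identity = if (bc == 0L) 0 else 100 * bm / bc)
}

# mutate a sequence at exactly k random positions (substitutions)
mutate_at <- function(s, k) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

# a constructed read pair covering both ends of `product` with reads of
# length `read_len`, perfect qualities
perfect_pair <- function(product, read_len, id = "p1") {
  L <- min(read_len, nchar(product))
  q <- strrep("I", L)
  data.frame(id = id,
             seq1 = substr(product, 1L, L), qual1 = q,
             seq2 = groELprofiler::reverse_complement(
               substr(product, nchar(product) - L + 1L, nchar(product))),
             qual2 = q, stringsAsFactors = FALSE)
}

# identity -> distance matrix for tree tests
identity_from_dist <- function(d) {
  m <- as.matrix(d)
  100 * (1 - m)
}
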