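# elementwise max of two equal-length Phred+33 quality strings
.max_qual <- function(q1, q2) {
  a <- utf8ToInt(q1)
  b <- utf8ToInt(q2)
  intToUtf8(pmax(a, b))
}

#' Merge paired-end reads by exact overlap
#'
#' Read 2 is reverse-complemented and the longest overlap with read 1 that is
#' strictly longer than `min_overlap` and contains at most
#' `max_overlap_mismatch` mismatches (default: none) is taken; pairs with no
#' qualifying overlap are discarded. In the overlap the consensus takes the
#' higher-quality base call (with zero mismatches allowed the bases agree
#' everywhere, so only the quality is consolidated).
#'
#' @param pairs `data.frame` with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, as from [read_fastq_pairs()].
#' @param min_overlap Overlaps must be strictly longer than this many bp
#'   (default 10).
#' @param max_overlap_mismatch Mismatches tolerated inside the overlap
#'   (default 0).
#' @return List with `merged` (`data.frame`: `id`, `sequence`, `qualities`,
#'   `overlap_len`) and `discarded` (character vector of pair ids).
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_overlap_mismatch = 0L) {
  n <- nrow(pairs)
  if (n == 0L)
    return(list(merged = data.frame(id = character(0L), sequence = character(0L),
                                    qualities = character(0L),
                                    overlap_len = integer(0L)),
                discarded = character(0L)))
  r2rc <- vapply(pairs$seq2, reverse_complement, character(1L), USE.NAMES = FALSE)
  q2r <- vapply(strsplit(pairs$qual2, "", fixed = TRUE),
                function(q) paste(rev(q), collapse = ""), character(1L))
  len1 <- nchar(pairs$seq1)
  len2 <- nchar(pairs$seq2)
  kmax <- pmin(len1, len2)
  overlap <- rep(NA_integer_, n)
  pending <- seq_len(n)
  for (k in seq(max(kmax), min_overlap + 1L, by = -1L)) {
    if (length(pending) == 0L) break
    cand <- pending[kmax[pending] >= k]
    if (length(cand) == 0L) next
    suf <- substring(pairs$seq1[cand], len1[cand] - k + 1L, len1[cand])
    pre <- substring(r2rc[cand], 1L, k)
    if (max_overlap_mismatch == 0L) {
      hit <- suf == pre
    } else {
      hit <- mapply(function(s, p) {
        sum(utf8ToInt(s) != utf8ToInt(p)) <= max_overlap_mismatch
      }, suf, pre, USE.NAMES = FALSE)
    }
    got <- cand[hit]
    overlap[got] <- k
    pending <- setdiff(pending, got)
  }
  ok <- which(!is.na(overlap))
  merged <- data.frame(id = character(0L), sequence = character(0L),
                       qualities = character(0L), overlap_len = integer(0L))
  if (length(ok) > 0L) {
    k <- overlap[ok]
    seqs <- paste0(pairs$seq1[ok], substring(r2rc[ok], k + 1L))
    quals <- character(length(ok))
    for (i in seq_along(ok)) {
      j <- ok[i]
      qa <- substring(pairs$qual1[j], len1[j] - k[i] + 1L, len1[j])
      qb <- substring(q2r[j], 1L, k[i])
      quals[i] <- paste0(substring(pairs$qual1[j], 1L, len1[j] - k[i]),
                         .max_qual(qa, qb), substring(q2r[j], k[i] + 1L))
    }
    merged <- data.frame(id = pairs$id[ok], sequence = seqs,
                         qualities = quals, overlap_len = k,
                         stringsAsFactors = FALSE)
  }
  list(merged = merged, discarded = pairs$id[is.na(overlap)])
}

#' Merge a single read pair
#'
#' Scalar convenience wrapper around [merge_pairs()].
#'
#' @param id Pair identifier.
#' @param seq1,qual1,seq2,qual2 Bases and Phred+33 qualities of the two mates.
#' @inheritParams merge_pairs
#' @return A one-row merged `data.frame`, or `NULL` when the pair is
#'   discarded.
#' @export
merge_pair <- function(id, seq1, qual1, seq2, qual2, min_overlap = 10L,
                       max_overlap_mismatch = 0L) {
  res <- merge_pairs(data.frame(id = id, seq1 = seq1, qual1 = qual1,
                                seq2 = seq2, qual2 = qual2,
                                stringsAsFactors = FALSE),
                     min_overlap, max_overlap_mismatch)
  if (nrow(res$merged) == 0L) NULL else res$merged
}

# mismatches of a primer (IUPAC) against a fixed window of each sequence;
# windows are (start, start+L-1); returns integer vector
.site_mismatches <- function(seqs, primer_seq, start_from_5p = TRUE) {
  enc_p <- .encode_bits(primer_seq)
  L <- length(enc_p)
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < L) return(L)
    win <- if (start_from_5p) substr(s, 1L, L) else substr(s, n - L + 1L, n)
    enc_t <- .encode_bits(win)
    sum(bitwAnd(enc_t, enc_p) != enc_t)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Quality- and primer-filter merged reads
#'
#' A merged read is retained iff its length is inside the window, its mean
#' Phred quality is at least `min_mean_quality`, it contains no ambiguous
#' (non-ACGT) base, and both primer sites match exactly (forward primer at
#' the 5' end, reverse complement of the reverse primer at the 3' end).
#' Rejection reasons are assigned in that order and tallied.
#'
#' @param merged `data.frame` from [merge_pairs()] (`id`, `sequence`,
#'   `qualities`).
#' @param pair [primer_pair()] whose sites must flank every read.
#' @param min_mean_quality Mean Phred threshold (default 20).
#' @param min_len,max_len Length window in bp (`NULL` disables a bound).
#' @return List with `retained` (subset of `merged` rows) and `tally` (named
#'   integer vector over `retained`, `length`, `low-quality`, `ambiguous`,
#'   `primer-mismatch`).
#' @export
filter_reads <- function(merged, pair, min_mean_quality = 20,
                         min_len = NULL, max_len = NULL) {
  n <- nrow(merged)
  reason <- rep(NA_character_, n)
  len <- nchar(merged$sequence)
  bad_len <- (!is.null(min_len) & len < (min_len %||% 0L)) |
             (!is.null(max_len) & len > (max_len %||% Inf))
  reason[bad_len] <- "length"
  meanq <- vapply(merged$qualities, function(q) mean(utf8ToInt(q)) - 33,
                  numeric(1L), USE.NAMES = FALSE)
  reason[is.na(reason) & meanq < min_mean_quality] <- "low-quality"
  ambig <- grepl("[^ACGT]", merged$sequence)
  reason[is.na(reason) & ambig] <- "ambiguous"
  idx <- which(is.na(reason))
  if (length(idx) > 0L) {
    fmm <- .site_mismatches(merged$sequence[idx], pair$forward$sequence, TRUE)
    rmm <- .site_mismatches(merged$sequence[idx],
                            reverse_complement(pair$reverse$sequence), FALSE)
    reason[idx[fmm > 0L | rmm > 0L]] <- "primer-mismatch"
  }
  keep <- is.na(reason)
  tally <- c(retained = sum(keep),
             length = sum(reason == "length", na.rm = TRUE),
             `low-quality` = sum(reason == "low-quality", na.rm = TRUE),
             ambiguous = sum(reason == "ambiguous", na.rm = TRUE),
             `primer-mismatch` = sum(reason == "primer-mismatch", na.rm = TRUE))
  list(retained = merged[keep, , drop = FALSE], tally = tally)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trim barcode and primer sites off merged reads
#'
#' Strips an exact barcode prefix (if any), the forward-primer site that
#' follows it, and the reverse-complemented reverse-primer site at the 3'
#' end, returning the inner amplicon sequence.
#'
#' @param seqs Character vector of merged read sequences (already primer-
#'   verified by [filter_reads()]).
#' @param pair [primer_pair()].
#' @param barcode Barcode string expected at the extreme 5' end (default
#'   none).
#' @return Character vector of inner sequences (possibly empty strings for
#'   degenerate zero-length inserts).
#' @export
trim_reads <- function(seqs, pair, barcode = "") {
  bl <- nchar(barcode)
  if (bl > 0L && !all(substr(seqs, 1L, bl) == barcode))
    stop("barcode not found at the 5' end of every read")
  fl <- nchar(pair$forward$sequence)
  rl <- nchar(pair$reverse$sequence)
  body <- substring(seqs, bl + 1L)
  if (any(.site_mismatches(body, pair$forward$sequence, TRUE) > 0L))
    stop("forward primer site not found; run filter_reads first")
  if (any(.site_mismatches(body, reverse_complement(pair$reverse$sequence),
                           FALSE) > 0L))
    stop("reverse primer site not found; run filter_reads first")
  substring(body, fl + 1L, nchar(body) - rl)
}

# identity between two sequences with a fast Hamming lower bound for
# equal-length inputs; falls back to alignment only when the bound is
# inconclusive for the threshold test
.identity_at_least <- function(a, b, threshold) {
  if (nchar(a) == nchar(b)) {
    h <- sum(utf8ToInt(a) != utf8ToInt(b))
    ham_id <- 100 * (1 - h / nchar(a))
    if (ham_id >= threshold) return(TRUE)
    # alignment identity can exceed the Hamming identity only via indels;
    # a generous slack avoids alignment for clearly distant pairs
    if (ham_id < threshold - 15) return(FALSE)
  }
  percent_identity(a, b, "global") >= threshold
}

#' Greedy centroid OTU clustering
#'
#' Sequences are visited by descending multiplicity (ties broken
#' lexicographically by sequence); each joins the first existing centroid
#' with percent identity at or above `radius`, else founds a new OTU.
#' Deterministic for a fixed input.
#'
#' @param seqs Character vector of (not necessarily unique) sequences, or
#'   unique sequences with `counts`.
#' @param counts Multiplicities (default 1 each); same length as `seqs`.
#' @param radius Identity threshold in percent, in (0, 100); default 97.
#' @param ids Optional list/vector of member identifiers parallel to `seqs`.
#' @return `data.frame` with columns `otu` (`OTU_1`, ...), `centroid`,
#'   `size`, and a list-column `members` of the member indices into `seqs`.
#' @export
cluster_otus <- function(seqs, counts = rep(1L, length(seqs)), radius = 97,
                         ids = NULL) {
  if (!(radius > 0 && radius < 100)) stop("radius must be in (0, 100)")
  seqs <- as.character(seqs %||% character(0L))
  if (length(seqs) == 0L) {
    out <- data.frame(otu = character(0L), centroid = character(0L),
                      size = integer(0L), stringsAsFactors = FALSE)
    out$members <- list()
    attr(out, "assignment") <- integer(0L)
    return(out)
  }
  stopifnot(length(seqs) == length(counts))
  ord <- order(-counts, seqs)
  centroids <- character(0L)
  members <- list()
  sizes <- integer(0L)
  assign <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (c in seq_along(centroids)) {
      if (.identity_at_least(seqs[i], centroids[c], radius)) {
        members[[c]] <- c(members[[c]], i)
        sizes[c] <- sizes[c] + counts[i]
        assign[i] <- c
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, seqs[i])
      members[[length(centroids)]] <- i
      sizes[length(centroids)] <- counts[i]
      assign[i] <- length(centroids)
    }
  }
  out <- data.frame(otu = paste0("OTU_", seq_along(centroids)),
                    centroid = centroids, size = sizes,
                    stringsAsFactors = FALSE)
  out$members <- members
  attr(out, "assignment") <- assign
  out
}

#' Build a taxonomy-labeled reference-amplicon database
#'
#' Runs [simulate_pcr()] over the reference sequences and keeps, per record,
#' the inner (primer-trimmed) amplicon, labeled with the record's taxonomy.
#' Records yielding no product are dropped with a warning; records yielding
#' several products contribute their first.
#'
#' @param references Named character vector, `DNAStringSet`, or FASTA path.
#' @param taxonomy `data.frame` as from [read_taxonomy()] (`id`, `genus`,
#'   `species`, `subspecies`, `strain`), or a path to such a TSV. Ids are
#'   matched against the first whitespace-delimited token of each reference
#'   name; species rank must be non-empty.
#' @param pair [primer_pair()] used to extract the amplicons.
#' @param max_mismatch Primer-site mismatch tolerance for the extraction.
#' @return Object of class `reference_db`: list with `sequences` (named inner
#'   amplicons), `taxonomy` (aligned rows), `marker`, `pair`.
#' @export
build_reference_db <- function(references, taxonomy, pair, max_mismatch = 0L) {
  seqs <- .as_named_sequences(references)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(taxonomy) && length(taxonomy) == 1L)
    taxonomy <- read_taxonomy(taxonomy)
  missing_tax <- setdiff(names(seqs), taxonomy$id)
  if (length(missing_tax) > 0L)
    stop("no taxonomy for reference(s): ", paste(missing_tax, collapse = ", "))
  res <- batch_pcr(seqs, pair, max_mismatch)
  none <- res$report$template_id[res$report$n_products == 0L]
  if (length(none) > 0L)
    warning("dropped ", length(none), " reference(s) without a product: ",
            paste(none, collapse = ", "))
  amps <- res$amplicons
  amps <- amps[!duplicated(amps$template_id), , drop = FALSE]
  tax <- taxonomy[match(amps$template_id, taxonomy$id), , drop = FALSE]
  if (any(!nzchar(tax$species)))
    stop("taxonomy must be non-empty at species rank for all db entries")
  structure(list(
    sequences = stats::setNames(amps$inner_sequence, amps$template_id),
    taxonomy = tax, marker = pair$forward$name, pair = pair),
    class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d entries, primer pair %s/%s\n",
              length(x$sequences), x$pair$forward$name, x$pair$reverse$name))
  invisible(x)
}

.RANKS <- c("genus", "species", "subspecies", "strain")

# human-readable label of a taxonomy row (non-empty ranks joined)
.taxon_label <- function(tax_row) {
  vals <- unlist(tax_row[.RANKS], use.names = FALSE)
  paste(vals[nzchar(vals)], collapse = " ")
}

#' Best-hit taxonomic classification against a reference database
#'
#' Each query is aligned against every database entry (same scoring as
#' [percent_identity()]); the best-hit identity decides the assignment. The
#' identity here is coverage-aware: matching columns over the shorter of the
#' two sequence lengths, so an unrelated query cannot reach a high identity
#' through a short perfect end overlap. Below `min_identity` the query is
#' `"unassigned"`. When several entries tie at the top identity the
#' assignment is truncated to the lowest rank shared by all tied entries
#' (e.g. a tie between two subspecies of one species yields a species-rank
#' call).
#'
#' @param seqs Character vector of query sequences (e.g. OTU centroids).
#' @param db [build_reference_db()] result.
#' @param min_identity Identity floor in percent (default 95).
#' @return `data.frame` with columns `query` (index), `taxonomy` (label or
#'   `"unassigned"`), `genus`, `species`, `subspecies`, `strain` (empty when
#'   truncated/unassigned), `identity`, `best_hit` (db entry id).
#' @export
classify_seqs <- function(seqs, db, min_identity = 95) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$sequences) == 0L) stop("reference database is empty")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ids <- .class_identities(seqs[i], unname(db$sequences))
    best <- max(ids)
    if (best < min_identity) {
      out[[i]] <- data.frame(query = i, taxonomy = "unassigned", genus = "",
                             species = "", subspecies = "", strain = "",
                             identity = best, best_hit = "",
                             stringsAsFactors = FALSE)
      next
    }
    tied <- which(ids >= best - 1e-9)
    tax <- db$taxonomy[tied, , drop = FALSE]
    ranks <- stats::setNames(rep("", 4L), .RANKS)
    for (r in .RANKS) {
      u <- unique(tax[[r]])
      if (length(u) == 1L) ranks[r] <- u else break
    }
    # a rank below a truncated rank is dropped too
    cut <- which(!nzchar(ranks))
    if (length(cut) > 0L) ranks[seq(min(cut), 4L)] <- ""
    label <- paste(ranks[nzchar(ranks)], collapse = " ")
    if (!nzchar(label)) label <- "unassigned"
    out[[i]] <- data.frame(query = i, taxonomy = label,
                           genus = ranks[["genus"]],
                           species = ranks[["species"]],
                           subspecies = ranks[["subspecies"]],
                           strain = ranks[["strain"]],
                           identity = best,
                           best_hit = names(db$sequences)[tied[1L]],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate classified OTUs into an abundance table
#'
#' @param samples Named list; each element is a `data.frame` with columns
#'   `taxonomy` (label, `"unassigned"` allowed), `genus`, and `size` (read
#'   count), e.g. a [classify_seqs()] result joined with OTU sizes.
#' @param target_genus Genus whose read fraction is reported per sample
#'   (default `"Bifidobacterium"`).
#' @return List of class `abundance_table`: `counts` (samples x taxa integer
#'   matrix, including an `unassigned` column when present), `rel_abundance`
#'   (rows sum to 1 over assigned + unassigned for non-empty samples),
#'   `genus_fraction` (named numeric, `NA` for empty samples),
#'   `target_genus`.
#' @export
profile_samples <- function(samples, target_genus = "Bifidobacterium") {
  if (length(samples) < 1L) stop("need at least one sample")
  if (is.null(names(samples)))
    names(samples) <- paste0("sample_", seq_along(samples))
  taxa <- sort(unique(unlist(lapply(samples, function(s)
    if (nrow(s) > 0L) s$taxonomy else character(0L)))))
  taxa <- c(setdiff(taxa, "unassigned"),
            if ("unassigned" %in% taxa) "unassigned")
  counts <- matrix(0L, length(samples), max(length(taxa), 1L),
                   dimnames = list(names(samples),
                                   if (length(taxa)) taxa else "unassigned"))
  gfrac <- stats::setNames(rep(NA_real_, length(samples)), names(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (nrow(s) == 0L) next
    agg <- tapply(s$size, s$taxonomy, sum)
    counts[i, names(agg)] <- as.integer(agg)
    total <- sum(s$size)
    gfrac[i] <- sum(s$size[s$genus == target_genus]) / total
  }
  rel <- counts / pmax(rowSums(counts), 1L)
  structure(list(counts = counts, rel_abundance = rel,
                 genus_fraction = gfrac, target_genus = target_genus),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d sample(s) x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  print(round(x$rel_abundance, 4))
  invisible(x)
}

#' Agglomerative clustering of samples by composition
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' the samples' relative-abundance vectors. Deterministic; merge heights are
#' invariant to sample input order.
#'
#' @param tab An [profile_samples()] result with >= 2 samples.
#' @return List with `order` (leaf order, sample names), `merge`, `height`
#'   (as in [stats::hclust()]), and the `hclust` object itself.
#' @export
cluster_samples <- function(tab) {
  rel <- tab$rel_abundance
  if (nrow(rel) < 2L) stop("need at least 2 samples")
  hc <- stats::hclust(stats::dist(rel, method = "euclidean"),
                      method = "average")
  list(order = rownames(rel)[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}

#' Run the full amplicon-profiling pipeline on paired reads
#'
#' Merge mates, quality/primer filter, trim to inner amplicons, dereplicate,
#' cluster into OTUs, classify centroids against the reference database, and
#' aggregate per-taxon read counts. A convenience wrapper tying the stage
#' functions together for a single sample.
#'
#' @param pairs Read-pair `data.frame` (see [read_fastq_pairs()]).
#' @param db [build_reference_db()] result; its primer pair is reused for
#'   filtering and trimming.
#' @param config [run_config()] overrides for thresholds.
#' @param expected_len Expected merged-read length in bp used for the length
#'   window (default: median merged length).
#' @param barcode Barcode prefix to strip (default none).
#' @return List with `otus` (with `taxonomy` columns merged in), `assignments`
#'   (per-OTU classification), `sample` (per-taxon `data.frame` suitable for
#'   [profile_samples()]), and `tally` (read-fate counts; stages sum exactly
#'   to the input pair count).
#' @export
profile_reads <- function(pairs, db, config = run_config(),
                          expected_len = NULL, barcode = "") {
  pair <- db$pair
  m <- merge_pairs(pairs, config$min_overlap, config$max_overlap_mismatch)
  if (is.null(expected_len) && nrow(m$merged) > 0L)
    expected_len <- stats::median(nchar(m$merged$sequence)) - nchar(barcode)
  lw <- if (is.null(expected_len)) c(NULL, NULL)
        else round(expected_len * c(1 - config$length_tolerance,
                                    1 + config$length_tolerance))
  body <- m$merged
  if (nchar(barcode) > 0L && nrow(body) > 0L) {
    has_bc <- substr(body$sequence, 1L, nchar(barcode)) == barcode
    body <- body[has_bc, , drop = FALSE]
    body$sequence <- substring(body$sequence, nchar(barcode) + 1L)
    body$qualities <- substring(body$qualities, nchar(barcode) + 1L)
    n_undetermined <- sum(!has_bc)
  } else n_undetermined <- 0L
  f <- filter_reads(body, pair, config$min_mean_quality,
                    min_len = lw[1L], max_len = lw[2L])
  inner <- trim_reads(f$retained$sequence, pair)
  tab <- table(inner)
  otus <- cluster_otus(names(tab), as.integer(tab), radius = config$otu_radius)
  cls <- if (nrow(otus) > 0L)
    classify_seqs(otus$centroid, db, config$min_identity)
  else data.frame(query = integer(0L), taxonomy = character(0L),
                  genus = character(0L), species = character(0L),
                  subspecies = character(0L), strain = character(0L),
                  identity = numeric(0L), best_hit = character(0L))
  sample_df <- data.frame(taxonomy = cls$taxonomy, genus = cls$genus,
                          size = otus$size, stringsAsFactors = FALSE)
  tally <- c(input_pairs = nrow(pairs), discarded_merge = length(m$discarded),
             undetermined_barcode = n_undetermined, f$tally)
  list(otus = cbind(otus, cls[, c("taxonomy", "identity", "best_hit")]),
       assignments = cls, sample = sample_df, tally = tally)
}
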