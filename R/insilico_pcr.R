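#' Construct a primer pair
#'
#' A forward and a reverse degenerate primer plus the product-length window
#' used by [simulate_pcr()]. The default window (100-2000 bp) comfortably
#' contains the ~490 bp groEL target product.
#'
#' @param forward,reverse [degenerate_primer()] objects, builtin primer names,
#'   or bare IUPAC sequences.
#' @param min_product_len,max_product_len Product length bounds in bp,
#'   primer-inclusive.
#' @return Object of class `primer_pair`.
#' @examples
#' groel_pair()
#' primer_pair("341F", "806R")
#' @export
primer_pair <- function(forward, reverse, min_product_len = 100L,
                        max_product_len = 2000L) {
  fwd <- .as_primer(forward, "forward")
  rev <- .as_primer(reverse, "reverse")
  fwd$orientation <- "forward"
  rev$orientation <- "reverse"
  if (!(min_product_len > 0L && min_product_len <= max_product_len))
    stop("need 0 < min_product_len <= max_product_len")
  structure(list(forward = fwd, reverse = rev,
                 min_product_len = as.integer(min_product_len),
                 max_product_len = as.integer(max_product_len)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s / %s, product window %d-%d bp\n",
              x$forward$name, x$reverse$name,
              x$min_product_len, x$max_product_len))
  invisible(x)
}

#' The builtin groEL primer pair
#'
#' Convenience constructor for the Bif-groEL-F/Bif-groEL-R pair.
#' @inheritParams primer_pair
#' @return A `primer_pair`.
#' @export
groel_pair <- function(min_product_len = 100L, max_product_len = 2000L) {
  primer_pair("Bif-groEL-F", "Bif-groEL-R", min_product_len, max_product_len)
}

# empty amplicon data.frame with the full column set
.empty_amplicons <- function() {
  data.frame(template_id = character(0L), start = integer(0L),
             end = integer(0L), strand = character(0L), length = integer(0L),
             sequence = character(0L), fwd_mismatches = integer(0L),
             rev_mismatches = integer(0L), inner_sequence = character(0L))
}

# products on the plus strand of an encoded template
.pcr_plus <- function(tpl, pair, max_mismatch, template_id, strand_label) {
  f <- find_binding_sites(tpl, pair$forward, max_mismatch, "+", template_id)
  if (nrow(f) == 0L) return(.empty_amplicons())
  r <- find_binding_sites(tpl, pair$reverse, max_mismatch, "-", template_id)
  if (nrow(r) == 0L) return(.empty_amplicons())
  out <- list()
  for (i in seq_len(nrow(f))) {
    cand <- r[r$start > f$end[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    len <- cand$end - f$start[i] + 1L
    keep <- len >= pair$min_product_len & len <= pair$max_product_len
    cand <- cand[keep, , drop = FALSE]
    len <- len[keep]
    if (nrow(cand) == 0L) next
    seqs <- substring(tpl, f$start[i], cand$end)
    out[[length(out) + 1L]] <- data.frame(
      template_id = template_id, start = f$start[i], end = cand$end,
      strand = strand_label, length = len, sequence = seqs,
      fwd_mismatches = f$mismatches[i], rev_mismatches = cand$mismatches,
      inner_sequence = substring(tpl, f$end[i] + 1L, cand$start - 1L))
  }
  if (length(out) == 0L) return(.empty_amplicons())
  do.call(rbind, out)
}

#' In-silico PCR: extract predicted amplicons for a primer pair
#'
#' Locates convergent forward / reverse-complemented-reverse binding sites on
#' both orientations of the template and reports every candidate product
#' whose primer-inclusive length falls inside the pair's length window.
#' Products are reported on the strand that begins with the forward primer;
#' minus-strand products carry coordinates on the given template with
#' `strand == "-"`. Overlapping or nested candidates are all reported.
#'
#' @param template Nucleotide string.
#' @param pair A [primer_pair()].
#' @param max_mismatch Maximum mismatches allowed per primer site (default 0).
#' @param template_id Identifier carried into the result.
#' @return `data.frame` with one row per amplicon: `template_id`, `start`,
#'   `end` (1-based inclusive, primer-inclusive), `strand`, `length`,
#'   `sequence` (forward-primer strand), `fwd_mismatches`, `rev_mismatches`,
#'   `inner_sequence` (product minus both primer sites). Sorted by `start`.
#'   No product gives a zero-row frame, not an error.
#' @examples
#' p <- groel_pair()
#' fwd <- iupac_expand(p$forward$sequence)[1]
#' rev <- iupac_expand(p$reverse$sequence)[1]
#' tpl <- paste0(strrep("A", 50), fwd, strrep("G", 300),
#'               reverse_complement(rev), strrep("C", 50))
#' simulate_pcr(tpl, p)
#' @export
simulate_pcr <- function(template, pair, max_mismatch = 0L,
                         template_id = "template") {
  stopifnot(inherits(pair, "primer_pair"))
  tpl <- .normalize_seq(template, what = "template")
  n <- nchar(tpl)
  plus <- .pcr_plus(tpl, pair, max_mismatch, template_id, "+")
  rc <- reverse_complement(tpl)
  minus <- .pcr_plus(rc, pair, max_mismatch, template_id, "-")
  if (nrow(minus) > 0L) {
    s <- minus$start
    minus$start <- n - minus$end + 1L
    minus$end <- n - s + 1L
  }
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico PCR over a FASTA collection
#'
#' Runs [simulate_pcr()] on every record and tallies, per record, how many
#' products were predicted (0, 1 or more than 1).
#'
#' @param references Named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param pair A [primer_pair()].
#' @param max_mismatch Maximum mismatches per primer site.
#' @return List with `amplicons` (row-bound [simulate_pcr()] results; the
#'   record identifier is inherited as `template_id`) and `report`
#'   (`data.frame` with `template_id`, `n_products`).
#' @export
batch_pcr <- function(references, pair, max_mismatch = 0L) {
  seqs <- .as_named_sequences(references)
  if (length(seqs) == 0L) stop("reference collection is empty")
  amps <- lapply(names(seqs), function(id)
    simulate_pcr(seqs[[id]], pair, max_mismatch, template_id = id))
  report <- data.frame(
    template_id = names(seqs),
    n_products = vapply(amps, nrow, integer(1L)))
  amplicons <- do.call(rbind, amps)
  rownames(amplicons) <- NULL
  list(amplicons = amplicons, report = report)
}

# accept named character / DNAStringSet / FASTA path
.as_named_sequences <- function(x) {
  if (methods::is(x, "DNAStringSet"))
    return(stats::setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x)))
    return(read_fasta(x))
  if (is.character(x)) {
    if (length(x) == 0L) return(stats::setNames(character(0L), character(0L)))
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("sequence collection must have unique names")
    return(x)
  }
  stop("cannot interpret references: pass a named character vector, ",
       "a DNAStringSet, or a FASTA path")
}
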