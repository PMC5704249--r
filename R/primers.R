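#' Construct a degenerate primer
#'
#' An oligonucleotide over the IUPAC alphabet with a name and an orientation.
#' The sequence is stored 5' to 3' as written; `orientation` records whether
#' the oligo is the forward or the reverse member of a pair.
#'
#' @param name Short identifier.
#' @param sequence IUPAC string (case-insensitive, `U` accepted), length >= 10.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `degenerate_primer` with fields `name`,
#'   `sequence`, `orientation`.
#' @examples
#' degenerate_primer("Bif-groEL-F", "TCCGATTACGAYCGYGAGAAGCT", "forward")
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  s <- .normalize_seq(sequence, what = paste0("primer '", name, "'"))
  if (nchar(s) < 10L)
    stop("primer '", name, "' is shorter than 10 nt")
  structure(list(name = name, sequence = s, orientation = orientation),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s)\n  5'-%s-3'  length %d, degeneracy %g\n",
              x$name, x$orientation, x$sequence, nchar(x$sequence),
              degeneracy(x$sequence)))
  invisible(x)
}

# coerce a primer argument that may be a bare sequence or a builtin name
.as_primer <- function(x, orientation = "forward") {
  if (inherits(x, "degenerate_primer")) return(x)
  builtins <- builtin_primers()
  if (is.character(x) && length(x) == 1L && x %in% names(builtins))
    return(builtins[[x]])
  degenerate_primer(name = as.character(x), sequence = x,
                    orientation = orientation)
}

#' Built-in primer fixtures
#'
#' The genus-specific degenerate groEL pair (Bif-groEL-F/Bif-groEL-R)
#' targeting a hypervariable region of the bifidobacterial groEL gene, and
#' the 16S rRNA V3-V4 pair 341F/806R used as the genus-level comparator.
#'
#' @return Named list of [degenerate_primer()] objects:
#'   `"Bif-groEL-F"`, `"Bif-groEL-R"`, `"341F"`, `"806R"`.
#' @examples
#' builtin_primers()[["Bif-groEL-F"]]
#' @export
builtin_primers <- function() {
  list(
    "Bif-groEL-F" = degenerate_primer("Bif-groEL-F", "TCCGATTACGAYCGYGAGAAGCT", "forward"),
    "Bif-groEL-R" = degenerate_primer("Bif-groEL-R", "CSGCYTCGGTSGTCAGGAACAG", "reverse"),
    "341F"        = degenerate_primer("341F", "CCTAYGGGRBGCASCAG", "forward"),
    "806R"        = degenerate_primer("806R", "GGACTACNNGGGTATCTAAT", "reverse")
  )
}

#' Load primer definitions from a TSV file
#'
#' Expects a header line `name	sequence	orientation` and one primer per row.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of [degenerate_primer()] objects.
#' @export
read_primer_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(df)))
    stop("primer TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    degenerate_primer(df$name[i], df$sequence[i], df$orientation[i]))
  stats::setNames(out, df$name)
}

# Per-window mismatch counts of a primer bit pattern against an encoded
# template. A position matches iff the template letter's base set is a subset
# of the primer letter's set (so N in the template only matches primer N).
.window_mismatches <- function(enc_t, enc_p) {
  n <- length(enc_t)
  L <- length(enc_p)
  nw <- n - L + 1L
  if (nw < 1L) return(integer(0L))
  m <- integer(nw)
  for (j in seq_len(L)) {
    tj <- enc_t[j:(j + nw - 1L)]
    m <- m + as.integer(bitwAnd(tj, enc_p[j]) != tj)
  }
  m
}

#' Find binding sites of a degenerate primer on a template
#'
#' Scans every window of the template on the requested strand(s) and reports
#' those with at most `max_mismatch` mismatching positions. A template
#' position counts as a match iff its IUPAC base set is a subset of the
#' primer position's set (an unambiguous template base matches when it is a
#' member of the primer's set; an ambiguous template base such as N matches
#' only a primer code at least as permissive). Substitutions only; no indels.
#'
#' @param template Nucleotide string (IUPAC letters permitted).
#' @param primer A [degenerate_primer()], a builtin primer name, or a bare
#'   IUPAC sequence.
#' @param max_mismatch Maximum mismatches per site (default 0).
#' @param search_strand `"+"`, `"-"` or `"both"`. Minus-strand hits are
#'   windows where the primer matches the reverse complement of the template;
#'   their coordinates are reported on the given (plus) template.
#' @param template_id Identifier copied into the result.
#' @return `data.frame` with columns `template_id`, `start`, `end` (1-based
#'   inclusive), `strand`, `mismatches`, sorted by `start`.
#' @examples
#' tpl <- paste0(strrep("A", 20), "TCCGATTACGATCGTGAGAAGCT", strrep("C", 20))
#' find_binding_sites(tpl, "Bif-groEL-F")
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 0L,
                               search_strand = c("both", "+", "-"),
                               template_id = "template") {
  search_strand <- match.arg(search_strand)
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  primer <- .as_primer(primer)
  tpl <- .normalize_seq(template, what = "template")
  enc_t <- .encode_bits(tpl)

  hits <- list()
  L <- nchar(primer$sequence)
  if (search_strand %in% c("both", "+")) {
    m <- .window_mismatches(enc_t, .encode_bits(primer$sequence))
    ok <- which(m <= max_mismatch)
    if (length(ok) > 0L)
      hits[["+"]] <- data.frame(start = ok, strand = "+", mismatches = m[ok])
  }
  if (search_strand %in% c("both", "-")) {
    m <- .window_mismatches(enc_t, .encode_bits(reverse_complement(primer$sequence)))
    ok <- which(m <= max_mismatch)
    if (length(ok) > 0L)
      hits[["-"]] <- data.frame(start = ok, strand = "-", mismatches = m[ok])
  }
  if (length(hits) == 0L) {
    return(data.frame(template_id = character(0L), start = integer(0L),
                      end = integer(0L), strand = character(0L),
                      mismatches = integer(0L)))
  }
  out <- do.call(rbind, hits)
  out$end <- out$start + L - 1L
  out <- data.frame(template_id = template_id, start = out$start,
                    end = out$end, strand = out$strand,
                    mismatches = out$mismatches)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
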