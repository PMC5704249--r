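#' Read a FASTA file into a named character vector
#'
#' Names keep the full header line (identifier plus description). Records
#' with an empty sequence are rejected.
#'
#' @param path Path to a FASTA file (may be gzipped).
#' @return Named character vector of sequences; zero-length for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0L), character(0L)))
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (any(Biostrings::width(ss) == 0L)) {
    bad <- which(Biostrings::width(ss) == 0L)[1L]
    stop("FASTA record ", bad, " ('", names(ss)[bad], "') in '", path,
         "' has a blank sequence")
  }
  stats::setNames(as.character(ss), names(ss))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) && length(seqs) > 0L)
    stop("sequences must be named")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param ids Read identifiers (without the leading `@`).
#' @param seqs Base strings.
#' @param quals Quality strings, Phred+33, same lengths as `seqs`.
#' @param path Output path; a `.gz` suffix gzips the file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  if (any(nchar(seqs) != nchar(quals)))
    stop("sequence/quality length mismatch")
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "wt")
         else file(path, open = "wt")
  on.exit(close(con))
  if (length(ids) > 0L)
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

# read one FASTQ into data.frame(id, seq, qual); Phred+64 rejected
.read_fastq <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTQ: ", path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e)))
  quals <- as.character(S4Vectors::mcols(ss)$qualities)
  if (length(quals) > 0L) {
    codes <- utf8ToInt(paste(quals, collapse = ""))
    if (length(codes) > 0L && max(codes) > 75L)
      stop("'", path, "' looks like Phred+64-scaled qualities ",
           "(codes above 'K' seen); only Phred+33 is supported")
  }
  data.frame(id = names(ss), seq = as.character(ss), qual = quals,
             stringsAsFactors = FALSE)
}

# strip pair suffixes like /1, /2, " 1:N:0:...", so mates can be compared
.core_read_id <- function(ids) {
  ids <- sub("\\s.*$", "", ids)
  sub("/[12]$", "", ids)
}

#' Read paired FASTQ files into a read-pair table
#'
#' Mates are matched by record order; identifiers must agree after stripping
#' `/1`,`/2` suffixes and any whitespace-delimited comment. Qualities are
#' Phred+33; apparent Phred+64 input is rejected.
#'
#' @param path1,path2 Paths to the R1 and R2 FASTQ files (optionally gzipped).
#' @return `data.frame` with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- .read_fastq(path1)
  r2 <- .read_fastq(path2)
  if (nrow(r1) != nrow(r2))
    stop("pairing error: ", nrow(r1), " reads in '", path1, "' vs ",
         nrow(r2), " in '", path2, "'")
  id1 <- .core_read_id(r1$id)
  id2 <- .core_read_id(r2$id)
  bad <- which(id1 != id2)
  if (length(bad) > 0L)
    stop("pairing error at record ", bad[1L], ": '", r1$id[bad[1L]],
         "' vs '", r2$id[bad[1L]], "'")
  if (any(nchar(r1$seq) != nchar(r1$qual)) || any(nchar(r2$seq) != nchar(r2$qual)))
    stop("base/quality length mismatch")
  data.frame(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Read a taxonomy table (TSV)
#'
#' Two tab-separated columns: sequence identifier and a semicolon-delimited
#' rank string. QIIME-style rank prefixes (`g__`, `s__`, `ssp__`, `st__`) are
#' accepted and stripped. Ranks beyond the fourth are ignored; missing ranks
#' are empty strings.
#'
#' @param path Path to the TSV (no header, or a header line starting with `#`).
#' @return `data.frame` with columns `id`, `genus`, `species`, `subspecies`,
#'   `strain`.
#' @export
read_taxonomy <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0L) stop("empty taxonomy file: ", path)
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1L)) < 2L))
    stop("taxonomy rows must be 'id<TAB>ranks'")
  ids <- vapply(parts, `[[`, character(1L), 1L)
  ranks <- lapply(strsplit(vapply(parts, `[[`, character(1L), 2L), ";"),
                  function(r) sub("^\\s*(g|s|ssp|st)__", "", trimws(r)))
  pick <- function(r, i) if (length(r) >= i) r[[i]] else ""
  data.frame(
    id = ids,
    genus = vapply(ranks, pick, character(1L), 1L),
    species = vapply(ranks, pick, character(1L), 2L),
    subspecies = vapply(ranks, pick, character(1L), 3L),
    strain = vapply(ranks, pick, character(1L), 4L),
    stringsAsFactors = FALSE)
}

#' Write a taxonomy table (TSV)
#'
#' @param tax `data.frame` as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  ranks <- apply(tax[, c("genus", "species", "subspecies", "strain")], 1L,
                 function(r) paste(r, collapse = ";"))
  ranks <- sub(";+$", "", ranks)
  writeLines(paste(tax$id, ranks, sep = "\t"), path)
  invisible(path)
}

#' Write an identity matrix as labeled TSV
#'
#' Values at one decimal place; first column holds the row labels.
#'
#' @param m Square numeric matrix with matching dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m),
                   formatC(m, format = "f", digits = 1L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("label", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an identity matrix written by [write_identity_matrix()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with dimnames.
#' @export
read_identity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Serialize a phylogenetic tree to newick text
#'
#' @param tree An `ape` `phylo` object.
#' @param path Optional output path; when `NULL` the newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write an abundance table to TSV
#'
#' One row per sample; counts as integers and relative abundances at four
#' decimals, column pairs per taxon.
#'
#' @param tab Abundance table from [profile_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(tab, path) {
  counts <- tab$counts
  rel <- tab$rel_abundance
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  relcols <- as.data.frame(formatC(rel, format = "f", digits = 4L))
  colnames(relcols) <- paste0("frac_", colnames(rel))
  df <- cbind(df, relcols,
              genus_fraction = formatC(tab$genus_fraction, format = "f",
                                       digits = 4L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunables of the toolkit with their defaults. `run_config()` validates
#' overrides and rejects unknown keys, so a typo in a config cannot silently
#' fall back to a default.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config` with a `config_hash` attribute.
#' @export
run_config <- function(...) {
  defaults <- list(
    max_mismatch = 0L,          # primer-site mismatch tolerance
    min_product_len = 100L,     # in-silico PCR product window, bp
    max_product_len = 2000L,
    alignment_mode = "global",  # percent-identity mode
    otu_radius = 97,            # OTU clustering identity threshold, percent
    min_identity = 95,          # classification best-hit floor, percent
    min_overlap = 10L,          # read-merge overlap must exceed this, bp
    max_overlap_mismatch = 0L,
    min_mean_quality = 20,      # mean Phred of merged reads
    length_tolerance = 0.10,    # +/- fraction around expected amplicon length
    min_detect_reads = 10L,     # dilution-series detection floor
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, ov)
  tf <- tempfile()
  writeLines(paste(names(cfg), vapply(cfg, format, character(1L)), sep = "="), tf)
  attr(cfg, "config_hash") <- unname(tools::md5sum(tf))
  unlink(tf)
  class(cfg) <- "run_config"
  cfg
}
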