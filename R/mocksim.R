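# run code under a fixed RNG seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# substitute exactly k positions of s with a different random base
.mutate_seq <- function(s, k) {
  if (k == 0L) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate a taxonomy-labeled reference set with planted divergence
#'
#' Generates `n_taxa` synthetic reference records, each an exact forward
#' primer instantiation + a divergent inner region + the reverse-complemented
#' reverse primer instantiation, flanked by random sequence, so that every
#' record yields exactly one product under [simulate_pcr()] at zero
#' mismatches. Inner regions descend from a common random ancestor with a
#' per-taxon substitution load solved so that realized pairwise inner
#' identities (measured by [percent_identity()]) fall inside
#' `target_identity_band`; the draw is repeated up to `max_retries` times and
#' fails with an error if the band cannot be realized. Deterministic per
#' `seed`.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param target_identity_band Length-2 numeric in (50, 100): the band the
#'   pairwise inner identities must fall in. Default `c(78, 92)`, emulating
#'   typical inter-species divergence of the groEL hypervariable region.
#' @param inner_len Inner (between-primer) length in bp; default 442, the
#'   inner length of a 487-bp primer-inclusive product with the builtin 23-bp
#'   and 22-bp groEL primers.
#' @param pair [primer_pair()] planted into every record.
#' @param seed RNG seed; recorded in the output.
#' @param flank_len Random flank length on each side (default 100 bp).
#' @param max_retries Redraw cap before giving up on the band.
#' @param out_fasta,out_tax Optional output paths (FASTA / taxonomy TSV).
#' @return List of class `mock_reference_set`: `sequences` (named full
#'   records), `inner` (named inner regions), `taxonomy` (`data.frame`),
#'   `pair`, `seed`.
#' @export
simulate_reference_set <- function(n_taxa, target_identity_band = c(78, 92),
                                   inner_len = 442L, pair = groel_pair(),
                                   seed = 1L, flank_len = 100L,
                                   max_retries = 20L,
                                   out_fasta = NULL, out_tax = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  band <- sort(target_identity_band)
  if (!(band[1L] > 50 && band[2L] < 100))
    stop("target_identity_band must lie within (50, 100)")
  # per-taxon divergence d so that two independent descendants have expected
  # identity (1-d)^2 + d^2/3 at the band midpoint
  mid <- mean(band) / 100
  d <- stats::uniroot(function(d) (1 - d)^2 + d^2 / 3 - mid,
                      c(0, 0.75))$root
  k <- round(d * inner_len)
  if (k < 1L)
    stop("target_identity_band infeasible for inner_len ", inner_len,
         ": required substitution count rounds to zero")
  .with_seed(seed, {
    fwd_opts <- iupac_expand(pair$forward$sequence)
    rev_opts <- iupac_expand(pair$reverse$sequence)
    inner <- NULL
    for (try in seq_len(max_retries)) {
      ancestor <- .random_seq(inner_len)
      cand <- vapply(seq_len(n_taxa), function(i) .mutate_seq(ancestor, k),
                     character(1L))
      ok <- TRUE
      for (i in seq_len(n_taxa - 1L)) {
        idv <- .identities_vs(cand[i], cand[(i + 1L):n_taxa], "global")
        if (any(idv < band[1L] | idv > band[2L])) { ok <- FALSE; break }
      }
      if (ok) { inner <- cand; break }
    }
    if (is.null(inner))
      stop("could not realize identity band [", band[1L], ", ", band[2L],
           "] for inner_len ", inner_len, " in ", max_retries, " draws")
    ids <- sprintf("taxon_%02d", seq_len(n_taxa))
    records <- character(n_taxa)
    for (i in seq_len(n_taxa)) {
      repeat {
        rec <- paste0(.random_seq(flank_len),
                      sample(fwd_opts, 1L),
                      inner[i],
                      reverse_complement(sample(rev_opts, 1L)),
                      .random_seq(flank_len))
        if (nrow(simulate_pcr(rec, pair, 0L)) == 1L) break
      }
      records[i] <- rec
    }
    names(records) <- ids
    names(inner) <- ids
    taxonomy <- data.frame(
      id = ids, genus = "Bifidobacterium",
      species = sprintf("synthspecies%02d", seq_len(n_taxa)),
      subspecies = "", strain = "", stringsAsFactors = FALSE)
    if (!is.null(out_fasta)) write_fasta(records, out_fasta)
    if (!is.null(out_tax)) write_taxonomy(taxonomy, out_tax)
    structure(list(sequences = records, inner = inner, taxonomy = taxonomy,
                   pair = pair, seed = seed),
              class = "mock_reference_set")
  })
}

#' Template copies from DNA mass
#'
#' Copy number of a template of `template_len` bp present at `mass_ng`
#' nanograms, at an average molecular mass of 650 Da per base pair:
#' `copies = mass_ng * 6.022e23 / (template_len * 1e9 * 650)`.
#'
#' @param mass_ng DNA mass in nanograms (>= 0; vectorized).
#' @param template_len Template length in bp (> 0).
#' @return Copy number (numeric, not rounded).
#' @examples
#' copies_from_mass(1, 1000)   # ~9.26e8
#' @export
copies_from_mass <- function(mass_ng, template_len) {
  if (any(template_len <= 0)) stop("template_len must be positive")
  if (any(mass_ng < 0)) stop("mass_ng must be >= 0")
  mass_ng * 6.022e23 / (template_len * 1e9 * 650)
}

#' Declare a mock community
#'
#' @param taxa Character vector of reference ids (must resolve in the
#'   reference set handed to [simulate_reads()]).
#' @param proportions Non-negative fractions summing to 1 (within 1e-9).
#' @param total_reads Total read pairs to draw (default 1e5).
#' @param error_rate Per-base substitution probability in \[0, 0.1\]
#'   (default 0.001).
#' @param read_len Read length in bp (default 250).
#' @param seed RNG seed, recorded in all outputs.
#' @return List of class `mock_spec`.
#' @export
mock_spec <- function(taxa, proportions, total_reads = 1e5L,
                      error_rate = 0.001, read_len = 250L, seed = 1L) {
  if (length(taxa) != length(proportions))
    stop("taxa and proportions must have equal length")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be >= 0 and sum to 1")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  structure(list(taxa = taxa, proportions = proportions,
                 total_reads = as.integer(total_reads),
                 error_rate = error_rate, read_len = as.integer(read_len),
                 seed = as.integer(seed)),
            class = "mock_spec")
}

# MiSeq-plausible quality string: constant Q37 with a linear decay to Q27
# over the final 20% of cycles
.quality_string <- function(len) {
  q <- rep(37L, len)
  tail_len <- max(1L, floor(len * 0.2))
  q[(len - tail_len + 1L):len] <- round(seq(37L, 27L, length.out = tail_len))
  intToUtf8(q + 33L)
}

# inject substitution errors at rate e into a character vector of
# equal-length reads; returns the mutated vector
.inject_errors <- function(reads, e) {
  if (e <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  n <- length(reads)
  n_err <- stats::rbinom(1L, n * L, e)
  if (n_err == 0L) return(reads)
  flat <- sample(n * L, n_err)
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  for (f in flat) {
    r <- (f - 1L) %% n + 1L
    c <- (f - 1L) %/% n + 1L
    mat[r, c] <- sample(setdiff(.BASES, mat[r, c]), 1L)
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Simulate paired amplicon reads from a mock community
#'
#' Per-taxon read counts are multinomial in the spec's proportions. Each pair
#' reads the two ends of the taxon's predicted amplicon (primer-inclusive
#' product of the reference under the pair): read 1 is the first `read_len`
#' bases of the product, read 2 the reverse complement of its last
#' `read_len` bases. Independent per-base substitution errors at the spec's
#' rate; qualities are a fixed MiSeq-plausible profile. Output order is a
#' seeded shuffle. Fully deterministic per `(spec, seed)`.
#'
#' @param spec A [mock_spec()].
#' @param references A [simulate_reference_set()] result, or a named
#'   character vector of reference sequences.
#' @param pair [primer_pair()] (default taken from `references` when
#'   available, else the builtin groEL pair).
#' @param out_r1,out_r2,out_truth Optional output paths (FASTQ x2, TSV).
#' @return List with `pairs` (read-pair `data.frame` as in
#'   [read_fastq_pairs()]), `truth` (`data.frame`: `id`, `taxon`), `spec`.
#' @export
simulate_reads <- function(spec, references, pair = NULL,
                           out_r1 = NULL, out_r2 = NULL, out_truth = NULL) {
  stopifnot(inherits(spec, "mock_spec"))
  if (inherits(references, "mock_reference_set")) {
    if (is.null(pair)) pair <- references$pair
    refs <- references$sequences
  } else {
    refs <- .as_named_sequences(references)
    if (is.null(pair)) pair <- groel_pair()
  }
  missing_ref <- setdiff(spec$taxa, names(refs))
  if (length(missing_ref) > 0L)
    stop("no reference sequence for taxon/taxa: ",
         paste(missing_ref, collapse = ", "))
  products <- character(length(spec$taxa))
  for (i in seq_along(spec$taxa)) {
    amp <- simulate_pcr(refs[[spec$taxa[i]]], pair, 0L)
    if (nrow(amp) == 0L)
      stop("no amplicon for taxon '", spec$taxa[i], "' under the primer pair")
    products[i] <- amp$sequence[1L]
  }
  .with_seed(spec$seed, {
    counts <- as.vector(stats::rmultinom(1L, spec$total_reads,
                                         spec$proportions))
    r1 <- character(0L); r2 <- character(0L); taxon <- character(0L)
    for (i in seq_along(spec$taxa)) {
      if (counts[i] == 0L) next
      prod <- products[i]
      L <- min(spec$read_len, nchar(prod))
      fwd <- substr(prod, 1L, L)
      rev <- reverse_complement(substr(prod, nchar(prod) - L + 1L,
                                       nchar(prod)))
      r1 <- c(r1, .inject_errors(rep(fwd, counts[i]), spec$error_rate))
      r2 <- c(r2, .inject_errors(rep(rev, counts[i]), spec$error_rate))
      taxon <- c(taxon, rep(spec$taxa[i], counts[i]))
    }
    ord <- sample(length(taxon))
    r1 <- r1[ord]; r2 <- r2[ord]; taxon <- taxon[ord]
    ids <- sprintf("read%06d", seq_along(taxon))
    q1 <- vapply(nchar(r1), .quality_string, character(1L))
    q2 <- vapply(nchar(r2), .quality_string, character(1L))
    pairs <- data.frame(id = ids, seq1 = r1, qual1 = q1, seq2 = r2, qual2 = q2,
                        stringsAsFactors = FALSE)
    truth <- data.frame(id = ids, taxon = taxon, seed = spec$seed,
                        stringsAsFactors = FALSE)
    if (!is.null(out_r1))
      write_fastq(paste0(ids, "/1"), r1, q1, out_r1)
    if (!is.null(out_r2))
      write_fastq(paste0(ids, "/2"), r2, q2, out_r2)
    if (!is.null(out_truth))
      utils::write.table(truth, out_truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    list(pairs = pairs, truth = truth, spec = spec)
  })
}

#' Simulate a dilution series and estimate the limit of detection
#'
#' Emulates a sensitivity experiment: a mock community is supplied at a range
#' of DNA masses; per point, template copies follow [copies_from_mass()] and
#' the number of community read pairs scales proportionally to copies
#' (`reads_per_copy`), optionally on top of a fixed count of background
#' (off-target, unclassifiable) read pairs. Each point is pushed through the
#' full profiling pipeline; a taxon is detected when at least
#' `min_detect_reads` reads are assigned to it, and the point is detected
#' when every taxon of the community with non-zero proportion is. The LOD is
#' the smallest mass with detection.
#'
#' @param base_spec A [mock_spec()]; its `total_reads` is overridden per
#'   point.
#' @param masses_ng Ascending DNA masses in nanograms.
#' @param references Reference set (see [simulate_reads()]).
#' @param template_len Genome length in bp used for the copy calculation
#'   (default 2.3e6, a typical bifidobacterial genome; one marker copy per
#'   genome).
#' @param reads_per_copy Sequencing yield per template copy (default 1e-3
#'   read pairs per copy).
#' @param background Number of background read pairs per point (default 0);
#'   background reads are random sequence and classify as unassigned.
#' @param min_detect_reads Per-taxon detection floor (default 10 reads).
#' @param config [run_config()] for the profiling stage.
#' @return List with `table` (`data.frame`: `mass_ng`, `copies`,
#'   `target_reads`, `min_assigned`, `detected`) and `lod_mass_ng` (`NA` when
#'   nothing is detected).
#' @export
dilution_series <- function(base_spec, masses_ng, references,
                            template_len = 2.3e6, reads_per_copy = 1e-3,
                            background = 0L, min_detect_reads = 10L,
                            config = run_config()) {
  if (is.unsorted(masses_ng)) stop("masses_ng must be sorted ascending")
  stopifnot(inherits(base_spec, "mock_spec"))
  refset <- references
  pair <- if (inherits(refset, "mock_reference_set")) refset$pair
          else groel_pair()
  db <- if (inherits(refset, "mock_reference_set"))
    build_reference_db(refset$sequences, refset$taxonomy, pair)
  else stop("dilution_series needs a mock_reference_set")
  rows <- vector("list", length(masses_ng))
  active <- base_spec$taxa[base_spec$proportions > 0]
  for (p in seq_along(masses_ng)) {
    copies <- copies_from_mass(masses_ng[p], template_len)
    n_target <- round(copies * reads_per_copy)
    assigned <- stats::setNames(rep(0, length(active)), active)
    if (n_target > 0L) {
      spec_p <- mock_spec(base_spec$taxa, base_spec$proportions,
                          total_reads = n_target,
                          error_rate = base_spec$error_rate,
                          read_len = base_spec$read_len,
                          seed = (base_spec$seed + p) %% .Machine$integer.max)
      sim <- simulate_reads(spec_p, refset, pair)
      reads <- sim$pairs
      if (background > 0L) {
        bg <- .with_seed(spec_p$seed + 10007L, {
          L <- base_spec$read_len
          data.frame(id = sprintf("bg%06d", seq_len(background)),
                     seq1 = vapply(seq_len(background),
                                   function(i) .random_seq(L), character(1L)),
                     qual1 = .quality_string(L),
                     seq2 = vapply(seq_len(background),
                                   function(i) .random_seq(L), character(1L)),
                     qual2 = .quality_string(L), stringsAsFactors = FALSE)
        })
        reads <- rbind(reads, bg)
      }
      prof <- profile_reads(reads, db, config)
      labmap <- stats::setNames(
        apply(db$taxonomy[, .RANKS], 1L,
              function(r) paste(r[nzchar(r)], collapse = " ")),
        db$taxonomy$id)
      for (tx in active) {
        lab <- labmap[[tx]]
        hit <- prof$sample$taxonomy == lab
        assigned[tx] <- sum(prof$sample$size[hit])
      }
    }
    rows[[p]] <- data.frame(mass_ng = masses_ng[p], copies = copies,
                            target_reads = n_target,
                            min_assigned = min(assigned),
                            detected = all(assigned >= min_detect_reads))
  }
  tab <- do.call(rbind, rows)
  lod <- if (any(tab$detected)) min(tab$mass_ng[tab$detected]) else NA_real_
  list(table = tab, lod_mass_ng = lod)
}
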