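groel <- groel_pair()

# a merged-read fixture: product with exact primer sites and a known inner
make_product <- function(inner_len = 200L, fwd_idx = 1L, rev_idx = 1L) {
  fwd <- iupac_expand(groel$forward$sequence)[fwd_idx]
  rev <- iupac_expand(groel$reverse$sequence)[rev_idx]
  inner <- random_dna(inner_len)
  list(product = paste0(fwd, inner, reverse_complement(rev)), inner = inner)
}

test_that("merge_pair takes the longest exact overlap and consolidates quality", {
  set.seed(31)
  left <- random_dna(80)
  right <- random_dna(80)
  ov <- substr(random_dna(20), 1, 20)
  full <- paste0(left, ov, right)
  seq1 <- substr(full, 1, 100)                      # left + overlap
  seq2 <- reverse_complement(substr(full, 81, 180)) # overlap + right, as R2
  m <- merge_pair("p", seq1, strrep("A", 100), seq2, strrep("J", 100))
  expect_false(is.null(m))
  expect_equal(m$overlap_len, 20L)
  expect_equal(nchar(m$sequence), 100L + 100L - 20L)
  expect_equal(m$sequence, full)
  # overlap bases take the higher quality ('J' from read 2 beats 'A')
  expect_equal(substr(m$qualities, 81, 100), strrep("J", 20))
})

test_that("overlaps of 10 bp or shorter, or with a mismatch, are discarded", {
  set.seed(32)
  core <- random_dna(8)
  seq1 <- paste0(random_dna(40), core)
  seq2 <- reverse_complement(paste0(core, random_dna(40)))
  expect_null(merge_pair("p", seq1, strrep("I", 48), seq2, strrep("I", 48)))

  # overlap of exactly 11 bp passes the strictly-greater-than-10 rule
  core11 <- random_dna(11)
  s1 <- paste0(random_dna(40), core11)
  s2 <- reverse_complement(paste0(core11, random_dna(40)))
  m <- merge_pair("p", s1, strrep("I", 51), s2, strrep("I", 51))
  expect_equal(m$overlap_len, 11L)

  # a 15-bp overlap with one mismatch is discarded at 0 tolerated mismatches
  core15 <- random_dna(15)
  s1 <- paste0(random_dna(40), core15)
  s2 <- reverse_complement(paste0(mutate_at(core15, 1L), random_dna(40)))
  expect_null(merge_pair("p", s1, strrep("I", 55), s2, strrep("I", 55)))
  # ... but accepted when one mismatch is allowed
  m1 <- merge_pair("p", s1, strrep("I", 55), s2, strrep("I", 55),
                   max_overlap_mismatch = 1L)
  expect_equal(m1$overlap_len, 15L)
})

test_that("read conservation: merged + discarded = input pairs", {
  set.seed(33)
  prods <- replicate(5, make_product(sample(160:240, 1))$product)
  pairs <- do.call(rbind, lapply(seq_along(prods), function(i)
    perfect_pair(prods[i], 150L, sprintf("r%02d", i))))
  # sabotage two pairs so they cannot merge
  pairs$seq2[2] <- random_dna(150)
  pairs$seq2[4] <- random_dna(150)
  res <- merge_pairs(pairs)
  expect_equal(nrow(res$merged) + length(res$discarded), nrow(pairs))
  expect_setequal(res$discarded, c("r02", "r04"))
})

test_that("filter_reads applies quality, ambiguity, length and primer rules", {
  set.seed(34)
  good <- make_product(200L)$product
  amb <- good
  substr(amb, 100, 100) <- "N"
  primer_broken <- good
  substr(primer_broken, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                         substr(good, 5, 5))[1]
  long <- paste0(good, random_dna(100))
  qn <- function(s, q = 40L) intToUtf8(rep(q + 33L, nchar(s)))
  merged <- data.frame(
    id = c("ok", "amb", "pm", "lowq", "long"),
    sequence = c(good, amb, primer_broken, good, long),
    qualities = c(qn(good), qn(amb), qn(primer_broken), qn(good, 10L), qn(long)),
    stringsAsFactors = FALSE)
  f <- filter_reads(merged, groel, min_mean_quality = 20,
                    min_len = 220, max_len = 260)
  expect_equal(f$retained$id, "ok")
  expect_equal(unname(f$tally["retained"]), 1L)
  expect_equal(unname(f$tally["ambiguous"]), 1L)
  expect_equal(unname(f$tally["primer-mismatch"]), 1L)
  expect_equal(unname(f$tally["low-quality"]), 1L)
  expect_equal(unname(f$tally["length"]), 1L)
  expect_equal(sum(f$tally), nrow(merged))  # tallies sum exactly
})

test_that("trim_reads strips barcode and both primer sites", {
  set.seed(35)
  mp <- make_product(180L)
  expect_equal(trim_reads(mp$product, groel), mp$inner)
  bc <- "ACGTACGT"
  expect_equal(trim_reads(paste0(bc, mp$product), groel, barcode = bc),
               mp$inner)
  # inner length of a 487-bp primer-inclusive product: 487 - 23 - 22 = 442
  mp487 <- make_product(442L)
  expect_equal(nchar(mp487$product), 487L)
  expect_equal(nchar(trim_reads(mp487$product, groel)), 442L)
  # zero-length insert trims to the empty string
  fwd <- iupac_expand(groel$forward$sequence)[1]
  rev <- iupac_expand(groel$reverse$sequence)[1]
  expect_equal(trim_reads(paste0(fwd, reverse_complement(rev)), groel), "")
  expect_error(trim_reads(random_dna(120), groel), "forward primer")
})

test_that("cluster_otus is greedy, deterministic, and respects the radius", {
  s <- random_dna(300)
  one <- cluster_otus(rep(s, 5))
  expect_equal(nrow(one), 1L)
  expect_equal(one$size, 5L)

  # two haplotypes at ~90% identity, radius 97 -> exactly 2 OTUs
  set.seed(36)
  h1 <- random_dna(300)
  h2 <- mutate_at(h1, 30L)
  otus <- cluster_otus(c(h1, h2), counts = c(8L, 3L), radius = 97)
  expect_equal(nrow(otus), 2L)
  expect_equal(otus$centroid[1], h1)  # highest multiplicity seeds first
  expect_equal(otus$size, c(8L, 3L))
  # same input as raw repeats, one sequence each: same partition
  otus_raw <- cluster_otus(c(rep(h1, 8), rep(h2, 3)), radius = 97)
  expect_equal(nrow(otus_raw), 2L)
  expect_equal(sort(otus_raw$size), c(3L, 8L))

  # brute-force: every member within the radius of its centroid
  set.seed(37)
  base <- random_dna(250)
  seqs <- c(replicate(10, mutate_at(base, sample(0:4, 1))),
            replicate(10, random_dna(250)))
  res <- cluster_otus(seqs, radius = 97)
  assign <- attr(res, "assignment")
  for (i in seq_along(seqs)) {
    cen <- res$centroid[assign[i]]
    if (seqs[i] != cen)
      expect_gte(percent_identity(seqs[i], cen), 97)
  }
  expect_equal(sum(res$size), length(seqs))
  expect_error(cluster_otus(seqs, radius = 101), "radius")
})

make_test_db <- function(n = 4L, seed = 38L, subspecies = NULL) {
  rs <- simulate_reference_set(n, c(80, 92), inner_len = 300L, seed = seed)
  tax <- rs$taxonomy
  if (!is.null(subspecies)) tax$subspecies <- subspecies
  build_reference_db(rs$sequences, tax, rs$pair)
}

test_that("classify_seqs assigns db entries to themselves at 100%", {
  db <- make_test_db()
  cls <- classify_seqs(unname(db$sequences), db)
  expect_equal(cls$identity, rep(100, 4))
  expect_equal(cls$species, db$taxonomy$species)
  expect_equal(cls$genus, rep("Bifidobacterium", 4))
})

test_that("classify_seqs leaves distant sequences unassigned", {
  db <- make_test_db()
  set.seed(39)
  cls <- classify_seqs(random_dna(300), db, min_identity = 95)
  expect_equal(cls$taxonomy, "unassigned")
})

test_that("ties between subspecies truncate to the shared species rank", {
  # two identical db entries that differ only at subspecies rank
  set.seed(40)
  rs <- simulate_reference_set(2, c(80, 92), inner_len = 300L, seed = 40L)
  tax <- rs$taxonomy
  tax$species <- "longum"
  tax$subspecies <- c("infantis", "longum")
  seqs <- rs$sequences
  seqs[2] <- seqs[1]  # make the two amplicons identical
  db <- build_reference_db(seqs, tax, rs$pair)
  cls <- classify_seqs(db$sequences[[1]], db)
  expect_equal(cls$species, "longum")
  expect_equal(cls$subspecies, "")
  expect_equal(cls$taxonomy, "Bifidobacterium longum")
})

test_that("profile_samples aggregates counts, fractions and genus fraction", {
  one <- data.frame(taxonomy = "Bifidobacterium breve",
                    genus = "Bifidobacterium", size = 50L)
  tab <- profile_samples(list(s1 = one))
  expect_equal(unname(tab$rel_abundance[1, "Bifidobacterium breve"]), 1.0)
  expect_equal(unname(tab$genus_fraction["s1"]), 1.0)

  mixed <- data.frame(
    taxonomy = c("Bifidobacterium breve", "Bifidobacterium longum", "unassigned"),
    genus = c("Bifidobacterium", "Bifidobacterium", ""),
    size = c(60L, 30L, 10L))
  empty <- mixed[0, ]
  tab2 <- profile_samples(list(a = mixed, b = empty))
  expect_equal(rowSums(tab2$rel_abundance)[["a"]], 1)  # incl. unassigned
  expect_equal(unname(tab2$genus_fraction["a"]), 0.9)
  expect_true(is.na(tab2$genus_fraction["b"]))
  expect_true(all(tab2$counts["b", ] == 0L))
})

test_that("cluster_samples separates planted blocks and ignores input order", {
  human <- c(0.7, 0.25, 0.05, 0, 0)
  rat <- c(0.02, 0.03, 0.05, 0.6, 0.3)
  jit <- function(v, seed) {
    set.seed(seed)
    p <- abs(v + rnorm(5, 0, 0.01)); p / sum(p)
  }
  taxa <- paste0("sp", 1:5)
  mk_sample <- function(p) data.frame(taxonomy = taxa, genus = "Bifidobacterium",
                                      size = round(p * 1000))
  samples <- list(H1 = mk_sample(jit(human, 1)), H2 = mk_sample(jit(human, 2)),
                  R1 = mk_sample(jit(rat, 3)), R2 = mk_sample(jit(rat, 4)))
  tab <- profile_samples(samples)
  cl <- cluster_samples(tab)
  # top split separates the two blocks: the leaf order keeps blocks contiguous
  ord <- cl$order
  expect_true(paste(substr(ord, 1, 1), collapse = "") %in% c("HHRR", "RRHH"))

  # duplicated samples merge first at height 0
  dup <- profile_samples(list(x = samples$H1, y = samples$H1, z = samples$R1))
  cld <- cluster_samples(dup)
  expect_equal(min(cld$height), 0)

  # permuting sample order leaves merge heights unchanged
  cl2 <- cluster_samples(profile_samples(samples[c(3, 1, 4, 2)]))
  expect_equal(sort(cl2$height), sort(cl$height))
})

test_that("error-free reads from db entries classify to their source taxon", {
  rs <- simulate_reference_set(4, c(80, 92), inner_len = 300L, seed = 41L)
  db <- build_reference_db(rs$sequences, rs$taxonomy, rs$pair)
  spec <- mock_spec(rs$taxonomy$id, rep(0.25, 4), total_reads = 400L,
                    error_rate = 0, read_len = 200L, seed = 42L)
  sim <- simulate_reads(spec, rs)
  prof <- profile_reads(sim$pairs, db)
  expect_equal(unname(prof$tally["retained"]), 400L)
  expect_true(all(prof$assignments$taxonomy != "unassigned"))
  expect_equal(unname(prof$tally["input_pairs"]),
               unname(prof$tally["retained"] + prof$tally["discarded_merge"] +
                        prof$tally["length"] + prof$tally["low-quality"] +
                        prof$tally["ambiguous"] + prof$tally["primer-mismatch"]))
  # species-level recovery of every read
  truth_counts <- table(sim$truth$taxon)
  labmap <- setNames(paste("Bifidobacterium", db$taxonomy$species),
                     db$taxonomy$id)
  agg <- tapply(prof$sample$size, prof$sample$taxonomy, sum)
  for (tx in names(truth_counts))
    expect_equal(unname(agg[[labmap[[tx]]]]), unname(truth_counts[[tx]]))
})

test_that("pipeline output is deterministic for identical inputs", {
  rs <- simulate_reference_set(3, c(80, 92), inner_len = 250L, seed = 43L)
  db <- build_reference_db(rs$sequences, rs$taxonomy, rs$pair)
  spec <- mock_spec(rs$taxonomy$id, c(0.5, 0.3, 0.2), total_reads = 300L,
                    error_rate = 0.002, read_len = 160L, seed = 44L)
  sim1 <- simulate_reads(spec, rs)
  sim2 <- simulate_reads(spec, rs)
  expect_identical(sim1$pairs, sim2$pairs)
  p1 <- profile_reads(sim1$pairs, db)
  p2 <- profile_reads(sim2$pairs, db)
  expect_identical(p1$sample, p2$sample)
  expect_identical(p1$tally, p2$tally)
})
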