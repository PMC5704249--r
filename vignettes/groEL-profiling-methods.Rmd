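---
title: "Species-level Bifidobacterium profiling with degenerate groEL primers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{groEL profiling methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groELprofiler)
```

## The problem

The 16S rRNA gene separates bifidobacteria poorly: across the genus its
pairwise identities sit above ~90%, well past the conventional ~97% species
boundary for several species pairs, so 16S amplicon surveys of gut samples
usually stop at genus rank for *Bifidobacterium*. The single-copy chaperonin
gene *groEL* (also called *cpn60*/*hsp60*) evolves faster; a hypervariable
window of roughly 490 bp, flanked by two conserved stretches, discriminates
all recognized *Bifidobacterium* species. A degenerate primer pair over that
window — Bif-groEL-F `TCCGATTACGAYCGYGAGAAGCT` and Bif-groEL-R
`CSGCYTCGGTSGTCAGGAACAG` — makes the region amplifiable genus-wide: the
forward pool holds 4 unambiguous oligos (two `Y` positions) and the reverse
pool 8 (`S`, `Y`, `S`). Because the gene is single-copy, read counts map to
genome (CFU-equivalent) counts without copy-number correction, unlike 16S
and ITS.

This package implements the in-silico side of that protocol: degenerate
primer matching and in-silico PCR, marker resolving-power analysis, an
amplicon-read profiling pipeline, and a seeded mock-community simulator for
sensitivity experiments. The 16S V3–V4 comparator pair 341F/806R ships as a
fixture and runs through the same generic machinery.

## Degenerate matching and in-silico PCR

Each IUPAC letter is encoded as the bit-set of its bases (A=1, C=2, G=4,
T=8; e.g. Y = C|T = 10). A template position matches a primer position iff
the template letter's base set is a **subset** of the primer letter's set.
For plain A/C/G/T templates this is ordinary membership; for ambiguous
template letters it is deliberately conservative — a template `N` matches
only a primer `N` — so runs of `N` in draft genomes cannot fabricate binding
sites. Annealing is modeled with substitutions only (no indels), matching
how short-oligo specificity screens treat primers, and it keeps the
expansion-based oracle exact. The default mismatch tolerance is 0, since the
published specificity screen reports clean single products; it is an
argument everywhere.

`simulate_pcr()` pairs every forward site with every downstream
reverse-complemented reverse site on both template orientations, keeps
products inside a length window (default 100–2000 bp, comfortably bracketing
the ~490 bp target), and reports **all** candidates — nested and overlapping
ones included — rather than applying a shortest-product heuristic; callers
can filter, and multi-product records are visible in `batch_pcr()`'s report.
Coordinates are 1-based and inclusive, and product lengths are
primer-inclusive: a product whose forward site starts at gene position 1066
and whose reverse site ends at 1552 is 487 bp, and its inner
(primer-trimmed) region is 487 − 23 − 22 = 442 bp. The package applies this
convention consistently, and the test suite pins it with a synthetic
full-length gene built to those coordinates.

## Percent identity and marker resolution

`percent_identity()` is 100 × matches / alignment columns, where columns
include internal gap positions but exclude end gaps. Global mode is an
end-gap-free Needleman–Wunsch ("overlap") alignment; local mode is
Smith–Waterman. Both score match +1, mismatch −1, gap-open 5, gap-extend 2.
The end-gap-free global form approximates what BLAST reports on
near-full-length homologous genes while staying deterministic; because the
exact alignment parameters behind published similarity tables are rarely
stated, both modes are exposed and accession-based checks accept a match in
either mode within ±0.5 points.

One consequence of end-gap-free alignment is worth spelling out: for two
**unrelated** sequences the optimal overlap alignment is typically a
few-base perfect end overlap, so the column-wise identity is uselessly high.
That is harmless when comparing homologous marker genes (the full-length
alignment dominates as soon as sequences are actually related), but it would
break best-hit classification. The classifier therefore uses a
coverage-aware identity — matching columns divided by the shorter sequence
length — which equals the column identity for gapless full-length matches
and collapses to near zero for unrelated queries.

`resolution_summary()` reports the minimum, unweighted mean and maximum over
the n(n−1)/2 unordered pairs, with lexicographic tie-breaks, the form in
which marker resolving power is usually quoted (e.g. *groEL* genus-wide
minima near 79% against 16S minima near 91%). `compare_markers()` computes
per-taxon average identities over the shared labels of two matrices and
regresses one marker on the other by ordinary least squares, the standard
scatter-plus-regression comparison of marker resolution.
`indistinguishable_pairs()` lists pairs above a chosen identity — the
practical "these two species cannot be told apart at this threshold" check.
`nj_tree()` converts identities to distances d = (100 − identity)/100 and
builds an unrooted neighbor-joining tree (negative NJ branch estimates are
clamped to zero). NJ is exact on additive distances, which the tests
exploit; it is a distance-based surrogate for likelihood phylogenetics,
which is out of scope here, so no substitution-model fitting and no
bootstrap support values.

## The profiling pipeline

The pipeline mirrors a conservative amplicon workflow:

1. **Merge** (`merge_pairs()`): read 2 is reverse-complemented and the
   longest exact overlap strictly longer than 10 bp is taken; any mismatch in
   the overlap (at the default tolerance 0) discards the pair. Discarding is
   a counted outcome, not an error, and the per-stage tallies always sum to
   the input pair count.
2. **Filter** (`filter_reads()`): a merged read is kept iff its length is
   within the window, mean Phred ≥ 20, it has no ambiguous base, and both
   primer sites match exactly. The quality floor and the length window
   (expected amplicon ± 10%) make explicit what "lower quality score and
   short-read length" filters leave implicit; both are `run_config()` keys.
3. **Trim** (`trim_reads()`): exact barcode prefix (if any) and both primer
   sites are stripped, leaving the inner amplicon. Demultiplexing is
   exact-match with unknown barcodes counted as undetermined.
4. **Cluster** (`cluster_otus()`): greedy centroid clustering; sequences are
   visited by descending multiplicity (ties lexicographic) and join the
   first centroid at ≥ the radius, else found a new OTU. Deterministic by
   construction. Equal-length comparisons use a Hamming bound before falling
   back to alignment, which is exact for the substitution-only error model
   and fast at depth.
5. **Classify** (`classify_seqs()`): best hit over the reference database at
   the coverage-aware identity. Ties at the top identity truncate the call
   to the lowest rank shared by all tied entries, so a tie between two
   subspecies yields an honest species-rank call — relevant because, e.g.,
   the *B. longum* subspecies sit near 98% identity even in this marker.
6. **Aggregate** (`profile_samples()`): counts per assigned taxon plus an
   `unassigned` category; relative abundances sum to 1 per non-empty sample;
   the per-sample fraction of reads assigned to the target genus (default
   *Bifidobacterium*) is reported, the quantity that separates a
   genus-specific assay from a universal one. `cluster_samples()` runs
   average-linkage clustering on Euclidean distances between composition
   vectors, the ordering used for composition heatmaps (rendering itself is
   out of scope).

The OTU radius (97%) and the classification floor (95%) are conventional
amplicon values, stated as defaults rather than derived ones: the source
protocol does not publish its thresholds, which is also why published
per-sample OTU counts are not treated as reproducible targets. All
thresholds live in `run_config()`, which rejects unknown keys and embeds an
MD5 of the effective configuration for provenance.

## The mock-community simulator

`simulate_reference_set()` builds synthetic reference genes: a random
ancestor inner region of 442 bp (the inner length of the 487-bp product) is
independently mutated per taxon so realized pairwise identities fall inside
a target band, then each taxon gets exact primer-site instantiations (a
random member of each degenerate pool) and random flanks, re-drawn in the
rare case a spurious extra product appears. The default band of 78–92%
emulates the inter-species spread reported for the *groEL* window (roughly
74–97%, mean ~85%). The divergence needed per taxon is solved from the
expected identity of two independent descendants, (1−d)² + d²/3, and
realized identities are verified by alignment with redraws up to a cap; an
unrealizable band is an error, not a silent approximation.

`simulate_reads()` draws per-taxon read counts multinomially, reads the two
ends of each taxon's predicted amplicon at the configured read length
(default 250 bp, a MiSeq 2×250-style design whose 13-bp overlap on the
487-bp product just clears the >10 bp merge rule), and applies independent
per-base substitution errors (default 10⁻³; MiSeq's dominant error mode —
indels are not simulated). Quality strings are a fixed plausible profile:
Q37 with a linear decay to Q27 over the final 20% of cycles. Everything is a
pure function of (spec, seed): identical seeds give byte-identical FASTQ,
and the generators save and restore the caller's RNG state.

`copies_from_mass()` is the standard template-copy calculator at 650 Da per
base pair: copies = mass_ng × 6.022×10²³ / (len × 10⁹ × 650).
`dilution_series()` emulates a sensitivity experiment over a mass range
(the published design spans 0.01–40 ng): per point, copies follow the
calculator with a genome-length template (default 2.3 Mb, a typical
bifidobacterial genome, one marker copy per genome so copies equal
CFU-equivalents), community read pairs scale proportionally to copies
(default 10⁻³ read pairs per copy, a plausible yield for a normalized run),
and the point is "detected" when the full pipeline assigns at least 10 reads
to every community member. The LOD is the smallest detected mass. Under
these defaults 0.05 ng of a two-taxon community sits right at the detection
boundary (~2×10⁴ copies, ~20 target read pairs), which reproduces the scale
of the published 0.05 ng / 10⁴ CFU sensitivity; whether that exact point or
the next one is the LOD depends on the multinomial draw, i.e. on the seed.

## What the synthetic data does and does not show

The generator emulates: genus-wide inner-region divergence, exact primer
sites, paired-end reads with overlap, uniform substitution errors, and
mass-to-copies dilution. It does not emulate: PCR amplification bias,
chimeras, indel/homopolymer errors, position- and context-dependent MiSeq
error profiles, barcode cross-talk, or real community composition. Green
property tests therefore demonstrate that the pipeline's logic is correct
and self-consistent under its stated error model — not that the protocol
achieves any particular accuracy on real fecal samples. Checks against the
published worked examples (amplicon coordinates on reference accessions,
genus-wide identity extremes) additionally require the GenBank sequences,
which are not redistributed with the package; the acceptance tests state
exactly which accessions to fetch and fail informatively without them.

## Numerical and degeneracy choices

- Coordinates 1-based inclusive everywhere; products reported on the strand
  beginning with the forward primer.
- Identities are printed at one decimal (half-up) in TSV writers; fractions
  at four decimals.
- Empty samples produce zero rows and an `NA` genus fraction rather than an
  error; zero-length inserts trim to empty strings; a template shorter than
  the primer yields an empty site list.
- `percent_identity()` returns 0 when no positively scoring overlap exists
  (the empty alignment), avoiding a NaN from a zero-column alignment.
- Tie-breaks are lexicographic (min/max pairs, OTU seeding order) so every
  result is reproducible byte-for-byte.
- Problem sizes used by the shipped checks — 500 random matching cases on
  2-kb templates, 10⁴-read mock communities, 100 NJ trials on 8 taxa — were
  chosen to exercise the full pipeline at realistic depth while completing
  in a few minutes.

## Command-line use

A thin Rscript front end ships at `exec/groelprofiler` inside the installed
package (`system.file("exec", "groelprofiler", package = "groELprofiler")`),
with subcommands `insilico-pcr`, `resolve`, `build-db`, `profile`, `mock`
and `lod` that delegate directly to the exported functions; the R API is the
primary interface.
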