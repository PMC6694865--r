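---
title: "Methods: consensus-corrected DNA metabarcoding of nanopore amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-corrected DNA metabarcoding of nanopore amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanometabar)
```

## The problem

DNA metabarcoding identifies the species in a mixed sample by amplifying a
taxonomically diagnostic locus (here the mitochondrial markers cytochrome b
and COI, as used for commercial fish) and sequencing the amplicon pool.
Long-read nanopore sequencers make this attractive for rapid, on-site food
authentication, but individual nanopore reads carry on the order of 13%
combined substitution/insertion/deletion error. At that error level a raw
read cannot be placed reliably at species rank, where congeners often differ
by only a few percent. The pipeline in this package therefore reduces a run
of noisy reads to a small set of error-corrected consensus barcodes before
any taxonomic comparison, and then combines two markers into one conclusion
per detected taxon.

The stages, in fixed order:

1. **Filtering** — keep reads with mean Phred ≥ 10 and length 500–800 nt
   (inclusive bounds; the window brackets a full-length barcode amplicon).
2. **Marker classification and trimming** — find marker primers with an
   error-tolerant, IUPAC-aware matcher (20% error rate, ≥ 15 nt overlap),
   assign each read to a marker, and trim the primers off.
3. **Greedy clustering at 80% identity** — longest-first, best-cluster
   joining against cluster representatives, both read strands considered.
4. **Consensus** — per cluster: subsample to 100 reads, orient all reads
   onto the representative strand, build a center-star multiple sequence
   alignment, and emit the 30% majority consensus; residual primer matches
   at the consensus termini are stripped.
5. **Taxonomy** — local alignment of each consensus against an annotated
   reference set; hits need ≥ 98% identity and ≥ 90% query coverage; the
   assignment is the lowest common rank of the score-tied top hits.
6. **Combination** — marker-level assignments merge into per-lineage final
   conclusions; a species call stands when the other marker agrees or is
   silent, and contradicting species calls retreat to genus with a conflict
   flag.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `min_mean_q` | 10 | arithmetic mean of per-base Phred scores; the convention of standard read filters |
| `min_len`, `max_len` | 500, 800 nt | inclusive bounds bracketing the amplicon |
| `max_error_rate` | 0.20 | primer edit budget, integerized as `floor(rate × matched_len)` |
| `min_overlap` | 15 nt | shortest primer stretch accepted at a read end |
| `cluster_threshold` | 80% | identity over the shorter sequence; two 13%-error reads of one template meet it (their pairwise identity centers near 83%), reads of species ≥ 5% apart do not |
| `min_cluster_size` | 5 | below this, column support is too thin for a meaningful consensus |
| `subsample_cap` | 100 | more reads do not improve the consensus; alignment cost grows linearly |
| `consensus_threshold` | 0.30, strict `>` | a column is emitted only when its winning base exceeds 30% frequency |
| `min_identity`, `min_coverage` | 98%, 90% | species-delimitation thresholds customary for fish barcodes |
| `score_margin` | 0 | only exactly score-tied hits are merged into a rank decision |

All of these live in one place, `pipeline_config()`, and every stage
function takes them as ordinary arguments.

## Design choices where the design was open

**Identity definition.** "80% identity" is operationalized as a global
alignment with unit mismatch/gap costs; identity = matched positions divided
by the shorter sequence length (the short-side denominator of greedy
clustering tools). Among minimum-cost alignments the one with the most
matches is counted, which makes the value well defined and reproducible.

**Best-cluster joining.** Classic greedy clustering joins the first
acceptable cluster; this implementation joins the best-identity one (ties to
the lowest cluster id). The result does not depend on the order in which
clusters were founded, and members sit at least as close to their
representative.

**Strand handling.** Amplicon molecules enter the pore in either
orientation, so half the reads are reverse complements. Clustering evaluates
both strands of a read against each representative; the consensus stage then
orients all members onto the representative strand — this is why a
direction-adjustment step precedes the alignment. Consensi (and reads, when
error rates are measured) are compared strand-insensitively downstream.

**Clustering prescreen.** Comparing every read with every representative by
full dynamic programming is the only exact semantics; to skip hopeless
comparisons the clusterer first computes the bit-parallel (Myers) edit
distance `e` and uses the bound `matches ≤ (|a| + |b| − e)/2`: when even that
ceiling falls below the threshold (or below the current best candidate), the
full alignment is provably unnecessary. A k-mer counting screen was
considered and rejected: at 80% identity and 13% read error, short k-mers
occur everywhere by chance and long k-mers are almost all broken, so no
k-mer bound can ever exclude anything at these scales. The prescreen is
switchable, and a test asserts the clustering is identical with it on or
off.

**Center-star MSA.** The per-cluster alignment is a center-star: the center
is the read with the maximal summed pairwise identity (estimated from edit
distances on a sampled subset of partners — only the argmax matters), every
read is pairwise-aligned to the center, and pairwise gaps are merged into
common columns ("once a gap, always a gap"), with insertions between the
same center positions left-aligned in their block. For ≤ 100 reads that are
all ≥ 80% identical to the center this is accurate and dependency-free;
iterative refinement aligners would add minutes per cluster for marginal
gains at the 30% majority threshold.

**Majority consensus.** Per column the frequencies of A, C, G, T and gap are
computed over non-N symbols. A winning gap, or a winner at or below 30%
frequency, drops the column — hence the consensus length tracks the true
template length (center-read insertions are voted out, center-read deletions
are restored through insertion columns that the other reads carry).
Base-vs-gap frequency ties favor the base, base-vs-base ties break
alphabetically; both rules are arbitrary but fixed and tested.

**Primer matcher tie-breaks.** Hits minimize edits, then prefer the leftmost
read start, then the longest matched primer stretch; residual exact ties
resolve toward the largest read end and the leftmost primer window. The
matcher is implemented as two anchored semi-global DPs (one on reversed
sequences) plus an exhaustive pass for the both-ends-overhanging case, and
is tested cell-for-cell against a brute-force oracle.

**Taxonomy without BLAST.** Reference sets here are desk-scale (tens to
thousands of barcodes), so each consensus is aligned to every reference with
exact Smith–Waterman (+1/−2/−2, both strands) and hits rank by raw score —
at fixed scoring parameters, bit-score ranking reduces to score ranking.
The rank decision is lowest-common-rank over score-tied, threshold-passing
hits: one species → species; several congeneric species → genus; several
genera in one family → family; anything broader → unassigned.

**Marker combination and conflicts.** Each species-rank call seeds a
lineage; genus- and family-rank calls attach to lineages they are ancestors
of, and stand alone otherwise. A genus is flagged as conflicted only when
two markers both make species calls in it and agree on none — the pattern of
two markers contradicting each other about one organism. Two congeners each
seen by only one marker (the dropout pattern) are two lineages, not a
conflict.

**Error metric.** Error percentages follow the pooled-counts formula
`100 × (mismatches + insertions + deletions) / (sum of read lengths)`, with
counts taken from a unit-cost global alignment (ties prefer fewer gaps; the
totals are tie-invariant). Both comparison modes are provided: against
consensus sequences (the observable in a real run) and against the true
template (available in simulations).

## What the simulator emulates — and what it does not

`simulate_reads()` walks the template base by base: deletion with
probability 0.025, substitution with 0.08 (to a uniformly chosen different
base), and a uniformly random inserted base with 0.025 — 13% combined, the
error level of the targeted instrument class; only the total is anchored to
observation, the apportionment (substitution-dominated) is a modeling
choice. Reads flip strand with probability 0.5 and carry i.i.d. qualities
around a mean of 12 (read filtering only uses the mean). The reference
generator produces substitution-only divergence: a root per family, genus
roots at twice the requested divergence from the family root, species at
half the divergence from the genus root, so congeners differ by
approximately the requested fraction.

Real nanopore data differ in ways the simulator deliberately ignores:
homopolymer-dependent indels, positional and pore-dependent quality
structure, chimeras and adapter remnants, length variation between
barcodes, and PCR abundance bias. Passing tests therefore demonstrate the
*logic* of the workflow — filtering, classification, clustering, consensus
arithmetic, threshold behavior, rank resolution — not robustness to every
artifact of a physical flow cell.

The bundled demonstration study (`fish_mixture()`, `demo_reference_set()`,
`simulate_demo_study()`) mirrors a two-mixture validation design: six
species at 75/5×5% and eleven species at 17/10×8.3% by weight, with known
amplification failures (no COI amplicon for *Scophthalmus rhombus* and
*S. maximus*, no cytb amplicon for *Osmerus eperlanus*), a read-quality
dropout (*Limanda aspera* cytb, emitted at mean Phred 6 so the filter
removes it), and two deliberate database pathologies: the *Agonus
cataphractus* cytb record is absent while two other Agonidae genera carry
its haplotype (database incompleteness → family-rank call), and a second
*Myoxocephalus* species shares the *M. scorpius* COI haplotype (no genetic
variability → genus-rank call). Weight fractions map to expected read
fractions one-to-one; real PCR would distort that mapping, which only makes
the 75%-dominated mixture easier than reality for the minority species.

## Numerical choices and degenerate inputs

* Seeds: every stochastic operation takes a seed or inherits the caller's
  RNG stream; `run_pipeline()` fans its single seed out to stage-local
  seeds by fixed offsets, and RNG state is always restored afterwards.
  Identical seeds give byte-identical outputs.
* Degenerate primer bases are resolved uniformly per simulated amplicon;
  read-side N matches nothing in any aligner (and never appears in a
  consensus, since N is excluded from column tallies).
* Empty inputs are reports with zero counts, not errors; a zero-length
  insert after primer trimming is dropped and counted; single-read clusters
  are emitted verbatim (support 1.0) only if they pass the minimum cluster
  size, which they do not at the default of 5.
* Problem sizes used in the shipped tests: the two study-scale simulations
  run at 8,000 reads per marker against 600 nt references at 5% within-genus
  divergence; consensus-accuracy checks use clusters of 100 reads over ten
  seeds. These sizes were chosen so the full pipeline behavior (dominant and
  5%-minority species alike) is exercised while a complete run of both
  studies stays within a few minutes on one CPU.

## Known limitations

* The center-star MSA is not an iterative refinement alignment; for clusters
  of highly divergent or chimeric reads its columns can be poorly defined.
  The 30% majority rule absorbs most of this at realistic error rates.
* Abundance is reported only as read and cluster counts; no attempt is made
  to convert read fractions into weight fractions.
* Taxonomy is limited to family/genus/species, and the reference set is a
  local FASTA — the assignment logic of a live full-scale nucleotide
  database (with its redundancy and mislabeled entries) is out of scope.
* The carry-over estimate counts primer-classified foreign-marker reads;
  molecules without recognizable primers are invisible to it, so it is a
  lower bound on physical contamination.
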