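# nanometabar

Species identification from noisy long-read amplicon sequencing, for DNA
metabarcoding of mixed-template samples — the typical use case being rapid
food authentication (e.g. "which fish are in this mixture?") with a
portable nanopore sequencer.

Individual nanopore reads carry roughly 13% combined
substitution/insertion/deletion error, far too much to call a species whose
nearest congener differs by 2–5%. The package implements the standard
remedy as one coherent, tested pipeline:

1. **filter** reads (mean Phred ≥ 10, length 500–800 nt),
2. **demultiplex** by barcode-marker primers with an error-tolerant,
   IUPAC-aware semi-global matcher (20% error rate, ≥ 15 nt overlap) and
   trim the primers,
3. **cluster** greedily at 80% identity (longest-first, best-cluster
   joining, both strands; identity = matches / shorter length under a
   unit-cost global alignment),
4. **error-correct** each cluster: subsample to 100 reads, orient onto the
   representative strand, center-star multiple alignment, and a 30%
   majority consensus — per column, emit the winning base only if its
   frequency exceeds 0.30; winning gaps drop the column,
5. **assign taxonomy** by exact Smith–Waterman (+1/−2/−2) against an
   annotated reference FASTA (`accession|marker|family|genus|species`
   headers), keeping hits with ≥ 98% identity and ≥ 90% query coverage and
   resolving the lowest common rank of score-tied top hits,
6. **combine markers** (cytb + COI) into one final conclusion per taxon,
   flagging genuine cross-marker conflicts.

Consensus accuracy is measured with the pooled error formula
`100 × (mismatches + insertions + deletions) / (sum of read lengths)` from
unit-cost global alignments; on simulated clusters of 100 reads the ~13%
per-read error drops below 2% (typically ≈ 0.2%) in the consensus.

A full read simulator (`simulate_reads()`, `simulate_mixture_run()`) with a
configurable error profile, strand flips, mixture weights, amplification
dropouts, read-quality dropouts and run-to-run carry-over makes every stage
verifiable without sequencing data.

## Worked example

The package bundles a demonstration study modeled on a two-mixture
validation design: mixture "a" holds six flatfish species (75% plus five at
5% by weight), with no COI amplicon for *Scophthalmus rhombus* and no
usable cytb reads for *Limanda aspera*.

```r
library(nanometabar)

study <- simulate_demo_study("a", reads_per_marker = 8000L, seed = 11)
report <- run_pipeline(study$reads, study$refs, study$primers,
                       pipeline_config(seed = 11))
print(report)
```

```
Pipeline run report
  run cytb: 8000 reads in, 7615 kept by filter
  run COI: 8000 reads in, 8000 kept by filter
  marker cytb: 7513 trimmed reads, 13 clusters, 9 consensi
  marker COI: 7889 trimmed reads, 15 clusters, 13 consensi
  run cytb carry-over: 0.0% of classified reads
  run COI carry-over: 0.0% of classified reads
Final conclusions:
                   cytb                   COI final_rank           final_taxon conflict
1 Pleuronectes platessa Pleuronectes platessa    species Pleuronectes platessa    FALSE
2      Microstomus kitt      Microstomus kitt    species      Microstomus kitt    FALSE
3       Limanda limanda       Limanda limanda    species       Limanda limanda    FALSE
4    Platichthys flesus    Platichthys flesus    species    Platichthys flesus    FALSE
5  Scophthalmus rhombus               no call    species  Scophthalmus rhombus    FALSE
6               no call        Limanda aspera    species        Limanda aspera    FALSE
```

Reading the table: each row is one detected lineage; the `cytb` and `COI`
columns show that marker's own call (the *L. aspera* cytb reads fell below
the quality filter, the *S. rhombus* COI amplicon never existed, hence
"no call"), and `final_taxon` is the combined conclusion — all six mixture
species at species rank, with nothing detected that is not in the mixture.
The cytb run lost 385 reads to the quality filter: exactly the low-quality
*L. aspera* read-dropout share (5% of 8000) plus regular quality noise.

The eleven-species mixture `"b"` exercises the harder cases: a
`cytb` reference missing from the database resolves *Agonus cataphractus*
only to family rank ("Agonidae") on that marker, and a COI haplotype shared
between *Myoxocephalus* species stops at genus rank — in both cases the
other marker still carries the identification to species, as
`simulate_demo_study("b", ...)` reproduces.

A thin command-line front end over the same functions ships in
`inst/cli/nanometabar.R` (subcommands `simulate`, `filter`, `demux`,
`cluster`, `consensus`, `classify`, `error-stats`, `run`, `summarize`).

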