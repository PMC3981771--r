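---
title: "Organellar SNP calling under plastid-to-mitochondrion DNA transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organellar SNP calling under plastid-to-mitochondrion DNA transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgsnp)
```

## The problem

Plant cells carry three genomes at wildly different copy numbers: many
plastids per cell, each with many genome copies; fewer mitochondria; one
nucleus. Total-DNA sequencing therefore yields plastid reads at several
times the mitochondrial depth and both far above nuclear depth. A second
complication is directional DNA transfer: large tracts of the plastid genome
are integrated into plant mitochondrial genomes (MTPT). In date palm
roughly a tenth of the mitochondrial genome is plastid-derived insertion,
corresponding to nearly half of the plastid genome.

When reads from total DNA are aligned to the mitochondrial reference, reads
of plastid origin co-assemble onto those insertions. At every site where
the insertion has diverged from its plastid source, the alignment shows two
alleles — the genuine mitochondrial base and the plastid base — at a read
depth inflated by the plastid copy number. A naive caller reports this as
*heteroplasmy* (intra-individual organellar polymorphism). The remedy
implemented here is blunt and effective: **remove every read that aligns to
both organellar genomes before calling SNPs**. `orgsnp` implements this
filter inside a complete, self-contained pipeline (simulation, mapping,
pileup calling, annotation, cohort statistics, phylogenetics) so the
artifact and its elimination can be demonstrated end-to-end and every stage
is testable offline.

## Pipeline and model choices

### Read mapping

The built-in mapper is deliberately minimal: ungapped seed-and-verify
alignment. Exact k-mer seeds (default `k = 15`) tile each read in disjoint
windows; candidate placements are verified by full-length Hamming
comparison on both strands, and the best placement (fewest mismatches,
up to `max_mismatch = 5`) is reported. Because a 100 bp read holds
`max_mismatch + 1` disjoint seed windows, any placement within the mismatch
budget leaves at least one seed exact (pigeonhole), so the search provably
equals an exhaustive Hamming scan — a property the test suite asserts
directly against a brute-force oracle.

Mapping quality is `0` when the best placement is tied, otherwise
`min(60, 20 * (second_best - best))`, with `second_best = max_mismatch + 1`
when no second candidate exists. This formula is fixed and documented
rather than borrowed from any production aligner; what matters downstream
is only its interaction with the MAPQ ≥ 20 retention gate, and ties
(ambiguous placements, e.g. repeats) reliably receive 0. Indels are out of
scope throughout: the simulator plants substitutions only and the analysis
concerns SNPs.

### Cross-mapping filter

Each library is aligned separately to the mitochondrial and plastid
references; read identifiers mapped in both alignments are collected and
removed from each. Filtering is by read, not by pair — a mate that
cross-maps removes only itself (pair-level removal is available as an
option). A read counts as "mapped" regardless of MAPQ: mapping-quality
thresholds belong to SNP retention, not to the filter. Re-mapping the
surviving reads is unnecessary for ungapped single-best placements, so the
filter is implemented as record subtraction; it is idempotent and leaves
record order unchanged.

### SNP calling and retention

Pileups count each aligned base into one column; reads below MAPQ 20 are
excluded at this point. A site becomes a SNP when

* total depth ≥ 10,
* the top non-reference base has binomial-tail variant quality ≥ 15.

The variant quality is a defined, reproducible stand-in for a caller QUAL:
with per-base error `e = 10^(-mean_baseq/10)` and `k` alternate reads out
of depth `d`, the score is `min(99, -10 log10 P(X >= k))`,
`X ~ Binomial(d, e)` — the phred-scaled probability of that much alternate
evidence arising from sequencing error alone. No attempt is made to
reproduce the QUAL numbers printed in the source tables, which come from a
different (unspecified) model; no acceptance check depends on them.

Zygosity classification is the rule the printed tables force: a SNP is
**heteroplasmic** exactly when reference-supporting and
alternate-supporting depths are both positive, homoplasmic when the
reference depth is zero. Applied to the transcribed tables this reproduces
the polymorphism marks exactly (15 of 188 mitochondrial records; 30 of 30
plastid records). Reads showing a third base count toward total depth but
toward neither allele depth, matching the printed arithmetic; a secondary
alternate with ≥ 2 reads and ≥ 10% of the site depth is recorded on the
same record, mirroring the one multi-allelic printed row.

### Annotation

Location labels follow the compact grammar of the source tables
(`S-atpA`, `NS-matR`, `I-petD`, `IGS`, `IGS-petA:psbJ`), with overlap
resolved coding > intron > intergenic. Synonymous/nonsynonymous status
translates the affected codon before and after substitution on the coding
strand, using NCBI translation table 11 for both organelles (configurable;
the source names no code). RNA editing is ignored — effect prediction is
strictly genomic. Context partitions are counted over distinct genome
positions, not cultivar × position records, because the published totals
(13 genic + 2 intron + 5 IGS = 20 positions) use that unit.

### Cohort statistics

Sharing is keyed on (position, primary alternate), so the one printed
"T, G" record matches the other cultivars' "T" at its position. The
reference accession contributes no records — it *is* the reference — and
re-enters only as the reference taxon of the character matrices.

### Phylogenetics

Character matrices code each cultivar by its alternate allele at each SNP
site and the reference allele elsewhere, with the reference accession as an
extra all-reference taxon. With at most 57 sites across ten taxa nothing
richer than Jukes–Cantor is identifiable, so ML trees use JC69 with
Felsenstein pruning, Brent branch-length optimisation (tolerance 1e-8,
branch lengths in [1e-9, 10]), and NNI rearrangement from a parsimony
starting tree; candidate rearrangements are screened by optimising only
their newly created edges, and accepted moves are fully re-optimised, so
the likelihood never decreases along the search. Two-taxon matrices are
optimised directly on the single path, whose MLE the tests check against
the closed-form JC distance `-(3/4) ln(1 - 4p/3)` to 1e-6. Bootstrap
support resamples sites with replacement and repeats the whole search per
replicate.

Parsimony uses Fitch state-set operations over bit-encoded bases with
pattern compression; the heuristic search is stepwise addition from five
addition orders followed by NNI, and equals exhaustive enumeration over all
945 seven-taxon topologies in the tests. The ILD congruence test uses
`D = L(A+B) - L(A) - L(B)` with heuristic lengths (two addition orders per
search, applied identically to observed and permuted partitions), null
partitions of the original sizes drawn from the pooled sites, and
`p = (1 + #{D_perm >= D_obs}) / (1 + n_permutations)`. The replicate count
of the original analysis is unstated; 1000 is the default here, and the
published p-value (0.63, "not significantly incongruent") is treated as
qualitative only — the analysis scripts reproduce its *conclusion*, not the
number, which depends on unavailable real libraries and search settings.

## The synthetic-data generator

The generator emulates exactly the features the analysis depends on:

* **Genomes**: random plastid (20 kb), mitochondrial (50 kb) and nuclear
  (100 kb) sequences — miniatures, since every tested property scales with
  coverage and fraction, not genome size. Five transfer segments totalling
  10.3% of the mitochondrial genome are copied from the plastid and
  diverged at 2% per site (the copies diverge; the plastid source does
  not), matching the direction of transfer and giving cross-mapping reads
  their ~2 mismatches.
* **Copy-number ladder**: per-genome depth multipliers, default
  plastid : mito : nuclear = 4 : 1 : 0.02 at 100× mitochondrial depth. The
  4:1 plastid ratio is a modelling choice consistent with the 3–4×
  coverage ratios the original mapping summaries imply; the true cellular
  ratios are not stated anywhere.
* **Cultivar profiles**: planted substitutions with per-variant allele
  fraction; fraction 1 is homoplasmy, below 1 heteroplasmy. Both mates of
  a fragment carry the same allele, drawn per fragment.
* **Reads**: 100 bp pairs, 300 ± 30 bp inserts, uniform fragment starts on
  linear genomes (circularity is not modelled), i.i.d. substitution errors
  at a default 0.1%, constant base-quality string encoding the error rate
  (`Phred = round(-10 log10 e)`, capped at 40). Every mate has exactly one
  truth record (origin, position, alleles carried).

What the generator does *not* emulate — indels, structural variation,
GC-bias, position-dependent error profiles, chimeric fragments, nuclear
insertions of organellar DNA beyond a uniform decoy — bounds what passing
tests show: they validate the pipeline's logic under its stated model, not
its robustness to every artifact of real libraries.

### The artifact experiment is a controlled experiment

The headline property (spurious heteroplasmic mitochondrial calls inside
transfer segments before filtering; none after; planted SNPs outside
segments retained) is demonstrated with sequencing error switched off.
This is deliberate. The binomial-tail quality score retains error
singletons and doubletons at marginal depths, and after filtering the only
low-depth sites left on the mitochondrial genome are the coverage ramps at
segment edges — so with any realistic error rate a handful of error-driven
"heteroplasmic" calls would appear inside segments through a mechanism
unrelated to cross-mapping (a production caller's QUAL model suppresses
these; this package's defined score intentionally does not imitate one).
Turning error off isolates the mechanism under study: every non-planted
call in the experiment is then attributable to cross-mapping, and the
filter's effect is measured exactly. The default error rate everywhere
else is 0.1%.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen so the full suite
completes in minutes on one CPU: full-default simulations (50 kb
mitochondrial genome, ~132,000 reads) for the artifact experiment;
2–8 kb genomes for focused properties; 945-topology exhaustive parsimony
oracles at 7 taxa; 100 bootstrap replicates in the analysis scripts
(1000 remains the package default); 500–1000 ILD permutations on the
fixture matrices, and 200 null pairs × 100 permutations for type-I error
control of the ILD test.

## Known limitations

* Ungapped mapping and substitution-only simulation; no indel calls.
* The MAPQ and variant-quality formulas are defined here, not inherited
  from BWA/bcftools; absolute quality values are not comparable to the
  published tables.
* Organellar circularity is ignored; reads never wrap the origin.
* Effect prediction ignores RNA editing (relevant to plant mitochondrial
  genes such as *matR*).
* With ≤ 57 informative sites, trees are expected to be poorly resolved —
  the low bootstrap supports the analysis scripts print mirror the source
  study's, and exact topologies/support values are not reproducible from
  the printed tables alone.
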