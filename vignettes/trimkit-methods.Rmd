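---
title: "Methods: TRIM annotation, dating, genotyping, and phylogeny in trimkit"
author: "trimkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TRIM annotation, dating, genotyping, and phylogeny in trimkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biology being modelled

Terminal-repeat retrotransposons in miniature (TRIMs) are small
non-autonomous LTR retrotransposons. The family this package models has
230-bp long terminal repeats around a 72-bp internal domain (532 bp in
total), integrates with a 5-bp target-site duplication (TSD), and carries
the two internal motifs required for reverse transcription: a primer-binding
site (PBS) just inside the 5' LTR and a polypurine tract (PPT) just ahead of
the 3' LTR. Three properties make TRIMs analytically convenient:

1. **The two LTRs are identical at integration.** Their subsequent neutral
   divergence K clocks the element's age as T = K/(2r), with r the neutral
   substitution rate (default 1.3e-8 substitutions/site/year).
2. **Integration duplicates the target site.** A genuine element is flanked
   by two identical 5-mers, which separates real copies from alignment
   artefacts and lets a split-read caller infer the precise insertion
   offset.
3. **Insertions are effectively homoplasy-free.** Presence/absence of an
   insertion across accessions is therefore a high-quality binary character
   for phylogeny.

The package implements the complete chain — simulation with ground truth,
structural annotation, LTR dating, split-read insertion detection,
flanking-sequence genotyping, and neighbor-joining phylogeny — with every
stage testable against the simulator's truth ledger.

## The synthetic-data generator

`makeTrimConsensus()` builds the consensus element; `makeReferenceGenome()`
plants intact, solo-LTR, truncated, and multi-LTR tandem copies of known age
into an i.i.d. background genome; `buildPopulation()` derives an accession
panel with group-structured insertion polymorphism; `simulateReads()`
produces paired-end reads with logged origins.

Design choices, and what they do and do not emulate:

* **Background genome**: i.i.d. bases at configurable GC (default 0.46,
  maize-like). There are no repeats besides the planted elements, so "unique
  flank mapping" is well defined at desk scale. Real plant genomes are
  repeat-rich; passing tests here demonstrate correctness of the logic, not
  robustness to repeat-induced mapping ambiguity.
* **Coordinates**: insertion points are 0-based inter-base offsets; the
  `tsdLength` bases left of the offset are duplicated around the element, so
  length bookkeeping is exact and the annotation round-trip can demand
  base-perfect intervals.
* **Aging** uses the exact Kimura two-parameter transition probabilities at
  per-copy time T and total rate r (transition/transversion rate ratio
  default 2), so multiple hits are modelled and the estimator-side identity
  E[K] = 2rT holds exactly. Simulating with the same model family as the
  estimator is deliberate: it makes parameter-recovery tests sharp. It does
  not test robustness to model misspecification (rate heterogeneity,
  indels), which the dating module does not claim.
* **Element categories**: truncated copies are one concrete truncation mode
  (5' LTR + internal domain, 3' LTR deleted). Multi-LTR tandems are built
  explicitly as LTR-internal-LTR-LTR... in one orientation, reflecting their
  interpretation as unequal-recombination products rather than simulating
  recombination itself. A nested foreign insertion is placed between the
  internal domain and the 3'-most LTR, so the element remains recognisable
  as intact with a recorded nested segment.
* **Panel structure**: three germplasm groups (default 4 accessions each)
  emulating the wild-ancestor / landrace / modern-line stratification;
  insertion sites come in fixed, group-private, and line-private sharing
  classes. Sites are placed at least 2.5 kb apart and away from reference
  elements so the annotation merge rule (below) can never fuse neighbours.
* **Reads**: 150-bp pairs (within the 132-250 bp regime of the short-read
  data the pipeline targets), normal fragment sizes (400 +/- 40 bp),
  per-chromosome Poisson fragment counts at the requested coverage, uniform
  substitution errors only (no indels). Default panel coverage is 5x, a
  typical resequencing-panel depth; recovery test suites use 20x error-free
  reads so that any miscall is a genuine defect.

Determinism: every generator function consumes an explicit seed (or derives
one from `TrimSimConfig@seed`) and restores the caller's RNG state, so a
config plus seed reproduces FASTA/FASTQ output byte-for-byte.

## Annotation

The published workflows this replaces used homology search plus manual
curation; `scanGenome()`/`assembleElements()` define a deterministic
surrogate:

1. **Seeding**: all 12-mers of each consensus component (LTR, internal) are
   matched exactly against both strands; seed hits are clustered by
   alignment diagonal.
2. **Extension**: each cluster window is locally aligned against the
   component (match +2, mismatch -1, gap open 5, gap extend 1). Hits pass at
   identity >= 0.80 and component coverage >= 0.80. The identity default
   admits the >= 90% within-family identity typical of young TRIM families
   with headroom for older copies; both thresholds are configurable.
3. **Assembly**: same-strand hits within 2 kb merge into one element;
   internal gaps > 50 bp that matched neither consensus are recorded as
   nested insertions. Categories: >= 2 LTRs plus internal = intact (with the
   LTR count kept, so tandem arrangements survive); a lone LTR = solo LTR;
   anything partial = truncated. Opposite-orientation adjacency starts a new
   element.
4. **TSD**: the element's flanking k-mers (default k = 5) are reported as a
   TSD only when identical.

A 12-mer seed is retained with high probability even at the oldest default
ages (a 3-Myr-old copy diverges ~4% from the consensus), and the
element-free-genome false-positive rate is negligible because a >= 80%
identity, >= 80% coverage local alignment of a 230-mer essentially never
arises in i.i.d. sequence.

Per-chromosome densities are reported as count/Mb **truncated** to two
decimals; that is the convention under which the worked examples 27/143 Mb
-> 0.18 and 12/161 Mb -> 0.07 both reproduce (half-up rounding would print
the former as 0.19).

Sequence logos over TSD + flank records (`tsdLogo()`) use raw frequencies
and information content 2 - H with no pseudocounts and no small-sample
correction (available as an option), i.e. the plain logo definition.

## Dating

For each intact element the 5'-most and 3'-most LTR copies are extracted
strand-aware, globally aligned, and compared over gap-free columns
(pairwise deletion, the common default of distance software; listwise
"complete deletion" is a flag). K2P gives
K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q) and T = K/(2r). Saturated pairs
(1 - 2P - Q <= 0 or 1 - 2Q <= 0) raise a classed condition and are excluded
and logged rather than clamped — mirroring the fact that published dated
subsets are typically smaller than published intact counts, without
inventing an additional filter. Alignment scoring constants are
configuration, not contract: "default parameters" of external aligners are
not portable, so fixed explicit constants are used.

Age histograms use left-closed 1-Myr bins with percentages rounded to the
nearest percent.

## Insertion detection

The three-step junction-read procedure:

1. **Select** reads containing an LTR terminus: a terminal LTR segment of
   >= 20 bp matching with <= 1 mismatch, with >= 20 bp of non-LTR flank
   remaining. Reads matching only the LTR interior are discarded (no
   positional information), as are reads whose "flank" itself contains an
   LTR terminal 20-mer (tandem LTR-LTR junctions).
2. **Map** each flank exhaustively against both strands of the reference;
   only unique loci are kept. Exhaustive search is the reference
   implementation at desk scale; any accelerated path must agree with it.
3. **Cluster** junction offsets within 10 bp; left- and right-junction
   clusters pair into one site when their offset difference (the TSD length)
   lies in [0, 10]; the TSD is read out of the reference between the two
   junctions. Calls overlapping an annotated reference element are labelled
   `reference`, the rest `non_reference`.

The call coordinate is the left-junction offset, identical to the
simulator's insertion point. A right-junction-only call reports the
right-junction offset, which sits TSD-length (<= 5) bp left of the true
point — within the +/- 5 bp window the recovery suite demands. The 10-bp
cluster window is a free choice suited to error-free desk-scale data and is
configurable; the published procedure's manual-inspection step has no
stated criteria, so this clustering + TSD-window rule is its explicit,
reproducible surrogate.

Sharing classes partition sites by carrier count — line-specific (1), two
lines (2), multiple lines (>= 3) — the only disjoint reading under which
published class counts sum to their published total.

## Genotyping

For each known site, 150-bp flanks are extracted from the reference and
three junction signatures built: flank-end + LTR-start, LTR-end + TSD +
flank-start (presence), and the unbroken reference across the site
(absence); for reference-carried sites the presence signatures use the
annotated element's actual termini and the absence signature is the
precise-excision sequence. A read supports an allele when it spans the
corresponding junction by >= 20 bp on each side (<= 1 mismatch per 20 bp;
exact matching available). A cell is 1 with presence support and no absence
support, 0 in the converse, and "?" with no informative reads — or with
conflicting support, which is flagged rather than resolved by vote, because
a majority rule was never defined for this assay. The support threshold
defaults to a single read, consistent with an assay whose published
per-site coverage averaged about three reads; it is configurable.
`buildPavMatrix()` batches all junction probes into one dictionary scan per
accession; the batched path is tested cell-for-cell against the per-site
reference path.

## Phylogeny

Distances are the mean pairwise character difference with pairwise deletion
of missing cells: d(i,j) = (differing jointly-scored sites)/(jointly-scored
sites); with no missing data this is the Hamming proportion. Listwise
deletion is available by flag; pairwise is the default because it is the
reading of "adjusts for missing data" that uses all available cells. A pair
with zero jointly-scored sites is an error naming the pair.

Neighbor joining is implemented directly (Saitou-Nei Q criterion) because
two behaviours need to be pinned that library implementations do not
expose: ties in Q break deterministically toward the smallest label-index
pair, and a negative branch length is clamped to zero with the deficit
transferred to its sibling so the joined pair keeps its summed length. The
"least-squares option" of legacy tree software is read as ordinary NJ
branch-length estimation — NJ is itself a greedy least-squares
agglomeration — with no iterative refinement. On additive matrices the
implementation recovers the generating topology exactly (verified against
an exhaustive least-squares topology search up to 6 taxa and generating
topologies up to 10); on tie-free matrices it agrees with an independent NJ
implementation. Newick output uses 6 significant digits and single-quotes
labels containing spaces or metacharacters.

Population-structure admixture modelling is explicitly out of scope;
cluster agreement is assessed as group monophyly on the NJ tree instead.

## Pipeline and problem sizes

`runAll()` chains the stages through a run directory; every report figure
is recomputed from on-disk stage TSVs, and a manifest with MD5 checksums
plus the echoed configuration make runs reproducible bit-for-bit.

The recovery suites run at deliberately modest sizes chosen to exercise
every code path while keeping the whole suite fast: a 2 x 50 kb reference
with 12 mixed elements for the annotation round-trip; 1000 replicates per
age point for dating recovery (Monte-Carlo SE of the mean ~3% of the 1-Myr
truth, so the 3-SE criterion is sharp); and a 12-accession, 15-site panel
on a 3 x 20 kb reference at 20x for detection/genotyping. The panel's
sharing structure (5 fixed, 6 group-private, 4 line-private sites) gives
each germplasm group private characters, so group monophyly is the expected
outcome under error-free genotyping.

## Known limitations

* The scanner assumes substitution-level divergence from the consensus;
  long internal deletions other than the modelled truncation mode and
  heavily nested copies are out of the simulated regime.
* Genotyping is haploid presence/absence; heterozygosity and genotype
  likelihoods are non-goals.
* Unique-mapping semantics follow the i.i.d. background; in repeat-rich
  genomes flank uniqueness — and thus sensitivity — degrades in ways the
  simulator does not emulate.
* The dating clock is a single global rate with no among-site
  heterogeneity.
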