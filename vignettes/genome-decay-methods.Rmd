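---
title: "Methods: comparing decaying endosymbiont genomes with ratchet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing decaying endosymbiont genomes with ratchet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratchet)
```

## The problem

Vertically transmitted intracellular symbionts evolve under tiny effective
population sizes. Purifying selection weakens, recombination and mismatch
repair are lost, and the genome decays: genes pseudogenize, drift toward
A+T, and are eventually deleted (Muller's ratchet). A particularly
informative stage of this process is a genome that is still large but
mostly non-coding — intergenic DNA that is really a graveyard of ancient
genes, too decayed to annotate but not yet deleted.

`ratchet` implements the comparative analyses used to characterise a pair
of such strains sharing a recent common ancestor:

1. **Synteny-aware one-to-one homolog pairing** with orphan calling.
2. **Pseudogene detection** from translated similarity between one
   strain's orphans and the other strain's unannotated intergenic DNA.
3. **Intergenic synteny** in nucleotide and translated modes — the
   contrast between the two is the fingerprint of once-coding DNA.
4. **Composition statistics** (GC, GC2, GC4, RSCU, CAI) with one-way
   ANOVA + Tukey HSD group comparisons, for GC stratification of genome
   compartments and composition-based contig-bin validation.
5. **Divergence metrics**: codon-aware per-gene protein/nucleotide
   identities, identity matrices, amplicon classification.

A seeded simulator (`simulate_strain_pair()`) generates
ancestor-to-descendants genome pairs with full ground truth, so the whole
pipeline can be exercised and validated with no external data.

## Coordinate conventions

All internal coordinates are 0-based half-open; GenBank (1-based
inclusive) and tabular hit files (1-based inclusive, subject start > end on
the minus strand) are converted at the I/O boundary. Both replicons are
treated as circular: an origin-spanning feature or intergenic region is
stored once with `end > length` and a wrap flag, and every "difference
between coordinates" in the synteny machinery is a circular distance.

## Homolog pairing and the synteny model

Pairing is the classic greedy procedure on an A-proteins-versus-B-proteins
hit table: keep each query's best (lowest e-value) hit, order all retained
hits by ascending e-value, and walk down the list discarding any pair whose
subject was already used. E-value ties break by higher bit score, then
lexicographic query and subject ids, so the result is deterministic. Genes
left unpaired are orphans — the raw material for pseudogene detection.

The expected location of a gene's partner is modelled globally as a scaled
circular offset,

\[ \hat b = (s\,a + o) \bmod L_B, \qquad s = L_B / L_A , \]

with the offset \(o\) chosen to minimise the median absolute circular
discrepancy over all pairs. The median makes the fit robust to a small
number of inversions or transpositions. The top 10% of pairs by
discrepancy are flagged for review rather than dropped, and inversions
surface as maximal runs of locally reversed partner order
(`reversed_segments()`).

## Pseudogene calls

An orphan's protein is searched (six-frame, tblastn-style) against the
partner's intergenic regions. Hits are grouped per region and chained
into locus clusters — consecutive hits join a cluster while the gap
between them is at most the orphan's length, so a decayed copy broken
into pieces still registers as one locus, while an isolated stray HSP
far away forms its own cluster and cannot veto a compact one. A call
requires some cluster to satisfy all three of:

* at least one hit;
* a span no larger than the orphan itself (`span_tolerance = 1.0`; real
  erosion includes deletions and insertions, so this is configurable);
* a position within a 20 kb circular window of the expected locus. In
  the pipeline the expected locus is anchored to the nearest *paired*
  gene's partner coordinate rather than the global offset model:
  neighbours move together with inversions, so a decayed copy inside an
  inverted segment is still sought — and found — at its true syntenic
  position, where the global model would mispredict by up to the
  inversion span. The global model remains the basis of the
  discrepancy/review flags.

Among qualifying clusters the best-supported one (highest summed bit
score) is reported. Frameshifts are counted as distinct subject reading
frames minus one; in-frame stops are counted in the best-supported
frame. Regions can also
be screened directly against a protein database: a region is called a
pseudogene when its best non-"hypothetical" hit has e-value below 1e-3.
Pseudogene-bearing regions are removed from the intergenic set before any
composition statistic is computed.

## Why translated intergenic search sees what BLASTN cannot

With the default nucleotide scoring (+2 match / −3 mismatch), the expected
per-column score of a gapless alignment turns negative below roughly 60%
nucleotide identity — heavily decayed intergenic DNA is invisible.
BLOSUM62, in contrast, retains a positive expected score down to ~25–30%
amino-acid identity. DNA that was once coding therefore keeps a detectable
translated signal long after its nucleotide-level similarity has
dissolved. The translated scan aggregates frame-wise HSPs per region pair
into a length-weighted mean identity, then reduces the pairs to a greedy
one-to-one matching by summed bit score: decayed relics pair one-to-one,
and the reduction suppresses the isolated weak frame matches that an
exhaustive Smith–Waterman scan (unlike a word-seeded heuristic search)
reports between unrelated AT-rich sequences.

## Alignment engine and statistics

Dynamic programming is delegated to `Biostrings::pairwiseAlignment`
(Smith–Waterman / Needleman–Wunsch, affine gaps, BLOSUM62 with gap
open/extend 11/1 for proteins, +2/−3 with 5/2 for DNA). The module adds:

* greedy multi-HSP enumeration — report the best HSP, mask the matched
  subject interval, repeat until the raw score drops below threshold;
* raw Karlin–Altschul statistics (protein: \(K = 0.134\),
  \(\lambda = 0.317\)) with no edge or composition corrections. E-values
  are used only for ordering and loose cutoffs (10, 1e-3); externally
  produced 12-column hit tables can be imported wherever bit-exact parity
  with an external search tool matters;
* six-frame translation with stops retained and scored at −20, so HSPs
  are confined to stop-free segments without explicit splitting, and DNA
  coordinate mapping with the usual start > end convention on the minus
  strand;
* exact k-mer seeding for batch searches (amino-acid 5-mers; nucleotide
  12-mers), followed by a vectorised score-only pass, with full alignment
  only for survivors. This is the same idea word-seeded search tools use,
  reduced to an exact prescreen, and is what makes the 300-gene reference
  scenario run in minutes on one CPU in pure R.

Ambiguity handling is conservative throughout: `N` never counts as an
identity in DNA comparisons and scores worse than a mismatch, and `X`/`*`
never count as identities in protein comparisons.

## Composition statistics

GC2 is the G+C fraction at second codon positions. GC4 is restricted to
third positions of the eight fourfold-degenerate families (CTN, GTN, TCN,
CCN, ACN, GCN, CGN, GGN) — the standard reading; an all-third-positions
GC3 alternative is exposed via `fourfold_only = FALSE`. RSCU is the codon
count over its synonymous-family mean, with a 0.5 pseudo-count for absent
codons (the reference set is typically one contig's genes, so rare codons
will be missing); relative adaptiveness \(w\) is RSCU over the family
maximum; CAI is the geometric mean of \(w\) over a gene's codons excluding
ATG, TGG and stops, which carry no information.

Group comparisons call `stats::aov` followed by `stats::TukeyHSD` — the
studentized-range adjustment, no Welch correction. Degenerate input
(fewer than two groups, singleton groups, zero pooled within-group
variance) is an error, never a silent p-value. The GC stratification
follows a two-stage procedure: per-category strain groups are merged when
not significantly different (pseudogenes are always merged across strains;
each strain alone has too few), then ANOVA + Tukey is rerun on the merged
groups. The contig screen flags the minimal set of contigs that covers all
significant pairwise differences on any of GC/GC2/GC4/CAI — the contigs
whose removal leaves a homogeneous bin.

## Divergence metrics

Per-gene identities are computed from a global protein alignment; the
nucleotide alignment is induced codon-wise from it (each aligned residue
pair contributes its three source bases, each protein gap a codon gap), so
the nucleotide alignment length is exactly three times the protein
alignment length. Identity denominators exclude columns with a gap in
either sequence by default; an include-gaps alternative is exposed.
Amplicon classification is local (reads are fragments), counting a read at
\(\ge\) 98% identity to the reference gene in either orientation.

## The simulator

`simulate_ancestor()` builds a circular genome of stop-free, ATG-started
ORFs at a coding GC target separated by spacers at an independent GC
target. `evolve_descendant()` then applies, per branch:

* **functional genes** — random point mutations accepted with probability
  1 if synonymous, `nonsyn_acceptance` (default 0.15) if nonsynonymous, 0
  if nonsense, until the branch protein-divergence target is met. This is
  a deliberately simple proxy for purifying selection that reproduces the
  synonymous-changes-favored signature the translated-vs-nucleotide
  contrast depends on, without a full codon-model engine;
* **pseudogenes** (fraction 0.05/branch) — diverge as functional genes
  first (loss is recent), then receive 1–3 disruptions (1-bp frameshifts,
  in-frame stops) and drift neutrally;
* **spacers** — neutral AT-biased drift (substitutions only);
* **inversions** — applied at block boundaries (genes are never split),
  on the second branch in `simulate_strain_pair()`, with breakpoints
  recorded; **deletions** (whole genes) are applied last.

Defaults define the package's reference scenario: 300 genes of ~300
codons, coding GC 41%, per-branch protein divergence 7.5% (two branches
compound to ~85–86% cross-strain protein identity, since
\(0.925^2 = 0.856\)), ancestral spacer GC 30% decaying under an AT bias
of 0.8, spacer drift 0.25 substitutions/site/branch (~40% pairwise
nucleotide divergence of intergenic DNA once double hits and AT
convergence are accounted for), pseudogene post-disruption drift 0.25
(enough erosion to land pseudogenes in the intermediate GC stratum while
keeping them detectable by translated search), 2% deletions, and two
~50 kb inversions. One seed drives everything; a fixed seed reproduces
the simulation bit for bit.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: indel length spectra beyond 1-bp
frameshifts, mobile elements and HGT, rearrangements other than
inversions, transcription-related strand asymmetries, RNA genes, and
annotation error other than clipped start codons. The generator's role is
to reproduce the statistical structure the analyses key on (one-to-one
synteny, compact decayed loci, GC strata, the translated-vs-nucleotide
contrast), with truth tables for every gene fate, disruption and
breakpoint.

## Numerical and design choices

* **Tie-breaking** in pairing is fully specified (bit score, then ids);
  reports are byte-stable given fixed inputs.
* **Offset fit**: candidate offsets are the observed circular residuals;
  the minimiser of the median absolute circular discrepancy over that set
  is exact for this loss at these sizes (O(n²) in the number of pairs).
* **Expected-coordinate input**: gene start coordinates of the
  plus-strand representation (midpoints would shift calls by half a gene
  length at most — well inside the 20 kb synteny window).
* **Coding density** is a union length (overlaps counted once), CDS-only
  by default with an all-genes alternative, since either definition is
  defensible; noncoding GC is likewise computed both with and without RNA
  genes by choosing the feature set.
* **Orphans** shorter than 300 bp with no similarity support can be
  dropped from inventories (`orphan_min_len`), mirroring standard
  practice; the pipeline never drops them silently.
* **Problem sizes**: the test suite validates parameter recovery on the
  full 300-gene reference scenario once, and uses 10–60 gene scenarios
  for unit-level properties; these sizes were chosen so the whole suite
  completes in a coffee break on a single CPU while keeping every rate
  estimate (recovery, sensitivity, specificity) based on dozens of truth
  events.

## Known limitations

* The aligner is exhaustive rather than word-seeded once a candidate pair
  passes the k-mer prescreen; it is *more* sensitive than 2013-era BLASTN
  at marginal nucleotide identity, so nucleotide intergenic hit counts
  here are upper bounds on what a seeded tool would report.
* Karlin–Altschul constants are fixed, not fitted; e-values are ordering
  devices, not calibrated significance statements.
* The pseudogene caller assumes the decayed copy still sits at its
  syntenic locus; a pseudogene that was also transposed would be missed
  (by design — the same is true of the manual procedure it mechanises).
* `aov`/`TukeyHSD` assume homoscedastic groups; the GC strata have
  visibly similar spreads in both simulated and real data, but no Welch
  correction is applied.
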