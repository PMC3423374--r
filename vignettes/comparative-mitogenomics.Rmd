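---
title: "Comparative mitochondrial genomics of dinotoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitochondrial genomics of dinotoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinomito)
```

## The problem

Dinotoms are dinoflagellates that carry a permanent diatom endosymbiont, and
they are the only known cells with two evolutionarily distinct mitochondria.
The two organellar genomes could hardly be more different, and each calls
for its own analysis style:

* The **endosymbiont (diatom-type) genome** is compact and circular-mapping
  (~35 kb of sequenced coding-plus-intergenic region, ~58--60 genes in three
  classes plus a couple of spurious ORFs, mean intergenic spacer of tens of
  bp, GC around 31%, strong A/T bias at third codon positions).  Questions
  about it are classical comparative genomics: feature statistics, gene
  order and inversion distance, synteny blocks, gene fission/fusion,
  in-frame insertions, introns.

* The **host (dinoflagellate-type) genome** encodes only three proteins
  (cox1, cob, cox3) plus fragmented LSU rRNA, with cox3 split in two pieces
  whose transcripts are trans-spliced, heavy substitutional mRNA editing
  (mostly A&rarr;G at codon positions 1--2), and a genome dominated by
  pseudogene fragments embedded in unrelated flanking sequence.

`dinomito` implements both analysis tracks as a tested pipeline, together
with seeded synthetic-data generators so that every stage can be verified
against planted ground truth without any external download.

## Genome representation and statistics

An `annotated_genome` holds the sequenced portion of a genome (IUPAC DNA),
its topology (`circular`, `linear`, or `linear_gapped` for circular-mapping
genomes with one unclosed gap), a genetic-code id (1 universal; 4 decodes
TGA as tryptophan, as in some centric diatoms), and a feature table whose
segments are 1-based inclusive plus-strand coordinates in reading order;
minus-strand features are the reverse complement of the concatenation, and a
segment of a circular genome may wrap the origin.  This matches GenBank
flat-file conventions directly, and `read_genbank()`/`write_genbank()`
round-trip the representation exactly.

Statistics follow the conventions that make compact-genome tables
reproducible:

* All denominators are the **sequenced length** (the coding-plus-intergenic
  region), never the unknown full genome --- required when the deposited
  record stops at an unclosed repeat-rich gap.
* **GC content** counts G+C among unambiguous bases only; ambiguity codes
  leave both numerator and denominator.
* **Coding fraction** is a position-set union over gene loci, so overlapping
  genes count once; intronic nucleotides count as part of their gene locus
  for coverage, but are excluded from spliced gene lengths.  These two
  conventions are deliberately different (coverage describes how densely the
  genome is packed with gene loci; gene length describes the genes), and the
  coverage convention is switchable in code by taking `spliced = TRUE`
  positions instead.
* **Spacers** come from a furthest-end sweep over gene loci ordered by
  start (cyclic on circular genomes): non-negative gaps are spacers,
  negative gaps are overlap pairs reported separately and excluded from the
  spacer mean.  The sweep gives the exact accounting identity
  `union coverage + sum(spacers) = sequenced length`, which the test suite
  asserts on every simulated genome.
* The **third-position A+T** statistic is taken over sense codons of
  complete protein-coding genes, excluding the terminal stop (a stop codon
  is not an amino-acid codon; the convention is stated here because the
  statistic moves by a few tenths of a percent either way).

## Signed reversal distance

Gene orders are compared as **signed permutations**: the reference order
defines the identity numbering and + orientation, the query is re-expressed
in that numbering, and genes with duplicated names are dropped with a
warning (minimum-distance rearrangement with duplicated markers is a
different, much harder problem).  The minimum number of reversals --- each
flipping both order and strand --- is computed exactly with the
Hannenhalli--Pevzner theory:

$$ d(\pi) = (n+1) - c(\pi) + h(\pi) + f(\pi) $$

where $c$ counts breakpoint-graph cycles, $h$ counts hurdles and $f$ marks a
fortress.  The implementation builds the unsigned doubling (each signed
marker becomes an ordered pair, the ends are capped), finds cycles by
union--find over gray-edge connections, merges cycles whose gray edges
interleave into components, calls a non-trivial unoriented component a
hurdle when its black-edge indices are cyclically consecutive within the
merged index list of all unoriented components (equivalently, when it does
not separate two other unoriented components), detects superhurdles by
deletion, and adds the fortress correction when an odd number of hurdles are
all superhurdles.  Everything is $O(n^2)$, ample at organellar scale
($n \approx 60$).

Circular gene orders are reduced to the linear problem by rotating (and, if
needed, reflecting) the circle so that marker 1 leads with + sign, dropping
it and renumbering: reversal distance on $n$ circular markers equals linear
distance on the remaining $n-1$.  Both modes are exposed, with circular the
default for circular genomes, since published inversion counts rarely state
the mode used.

Because hurdle/fortress code is notoriously easy to get subtly wrong, the
package carries an **independent oracle**: `bfs_reversal_distance()` does a
bidirectional breadth-first search over all reversal moves (C++, packed
64-bit states, guarded at $n \le 9$).  The test suite checks
`reversal_distance()` against the oracle on hundreds of seeded random
permutations; the two share no theory and no code.

**Synteny blocks** are maximal runs of genes, restricted to the genes shared
by all input genomes, whose adjacency and relative orientation are preserved
everywhere; a whole-block strand flip is allowed, per-gene flips are not.

## Structural events

All detectors share one alignment configuration (recorded in CLI output
headers): protein Smith--Waterman with BLOSUM62, gap open 11 / extend 1;
nucleotide match +2 / mismatch &minus;3, gap open 5 / extend 2; identity is
matches over aligned columns with terminal gaps excluded.  These are common
defaults, stated because identity percentages depend on them.

* **Fission** (`detect_fission`): an event is called when exactly two
  candidate proteins align locally to near-disjoint spans of the parent
  (each covering &ge; 25%, jointly &ge; 80%, overlap &le; 10 aa; all
  config-exposed).  The reported breakpoint is the (end of part 1, start of
  part 2) interval in parent coordinates.
* **Fusion** (`detect_fusions`): gene pairs adjacent in one genome are
  reported when a single protein of the other genome carries both parts in
  order in one stop-free reading frame, with the downstream part's
  initiator-position methionine retained --- the signature of an upstream
  gene losing its stop while the downstream keeps its start.
* **In-frame insertion** (`detect_inframe_insert`): a region present in
  every in-group homolog and gapped in every outgroup, of nucleotide length
  divisible by 3, found via global alignments of each in-group sequence
  against each outgroup; per-sequence amino-acid bounds are the median over
  outgroups, and identity is reported inside vs outside the insert.  At
  least one outgroup is required --- without it the polarity
  (insertion vs deletion) is undecidable.
* **Intron interruption** (`detect_intron_interruption`): the spliced cDNA
  is aligned globally against the locus with cheap gap extension so that
  introns open as long cDNA-side gaps; gaps &ge; 20 nt are reported in locus
  coordinates.  The decomposition is rejected unless &ge; 90% of cDNA
  residues align at &ge; 80% identity --- both guards are needed, because
  near-free gaps would otherwise "align" unrelated sequences at high
  per-column identity.
* **Trans-splice junction** (`locate_trans_splice_junction`): the transcript
  prefix is anchored ungapped in the 5&prime; piece and the suffix in the
  3&prime; piece, tolerating substitutions (host transcripts are heavily
  edited upstream of the junction) but no indels; residues between the two
  anchors are the junction insert (e.g. the penta-A carried over from the
  polyadenylated 5&prime; piece).  When the anchors overlap, the junction is
  reported as an interval, not a point.

## RNA editing

`call_editing_sites()` anchors a (possibly partial) transcript on its gene
CDS --- global in the transcript, local in the gene --- and reports every
mismatch with codon index, codon position and amino-acid consequence under
open-frame translation.  An indel inside the compared span is an error by
design: substitutional editing cannot shift frame, so an indel means the
pair is mis-assigned or mis-assembled.  RNA bases are mapped to the DNA
alphabet (U&rarr;T) so that edit types read uniformly as genomic &rarr;
transcript base.  The number of called sites equals the Hamming distance
over the compared span by construction, and the non-synonymous fraction is
*reported, never assumed* (codon-position-1 T&rarr;C edits, for instance,
can be synonymous).  Conservation of sites across species goes through a
codon-level homolog map built from a global alignment; sites match when the
map sends them to the same position with the same substitution type, which
makes the matching symmetric.

## Pseudogene mapping

`map_fragments()` aligns every contig against every reference gene on both
strands, accepts local matches above the reporting thresholds (&ge; 50 nt,
&ge; 40% identity --- below the most degenerate published case so the
observed range is not truncated), lets one contig carry several
non-overlapping matches (overlaps on the contig are resolved by score, then
longer gene interval, then gene name; accepted matches are masked and the
contig re-scanned), and reports per-match gene/fragment intervals,
amino-acid span, orientation, identity, flank lengths and a conservation
class (conserved &ge; 90%, degenerate < 60%, intermediate between;
config-exposed, monotone in identity).

Two numerical choices deserve explanation:

* **Boundary refinement.** The true boundary between a gene-derived core
  and an *unrelated* flank is a changepoint, and a Smith--Waterman end is a
  biased estimate of it: the local alignment never keeps a negative-scoring
  tail (so a planted mutation at the very end is trimmed), and under
  match +2 / mismatch &minus;3 it happily follows a lucky run of chance
  matches into the flank.  The mapper therefore re-derives both ends by
  ungapped extension from a slightly shrunk anchor, scoring each column by
  the log-likelihood ratio of "gene-derived at ~99% identity" vs "unrelated
  background at 25%" (match +1.4, mismatch &minus;4.3) and keeping the
  maximum.  This estimator is median-exact, but a random flank still
  continues the gene by four or more matching bases with probability of
  order 10^-3^--10^-2^ per end, so a small fraction of ends are off by more
  than a few nucleotides *no matter the scoring*.  The tests assert what the
  estimator can honestly deliver: median error 0 and &ge; 90--95% of ends
  within &plusmn;3 nt.  Refinement is only applied to matches whose core
  identity is &ge; 90%; degenerate matches keep their Smith--Waterman ends,
  since the 99%-core likelihood model does not describe them.
* **Placement-uniformity test.** The qualitative claim "pseudogene
  fragments derive from all regions of the gene, without hot spots" is
  formalized as a chi-square goodness-of-fit --- but on *placements*, not on
  position-wise depth.  Depth is correlated along a fragment (one placement
  covers hundreds of consecutive positions), so a multinomial chi-square on
  binned depth is grossly overdispersed and rejects even truly uniform
  placements almost always.  Instead each mapped fragment contributes one
  count at its midpoint bin, and its expected bin probabilities come from
  the uniform distribution over its own feasible placements (a long
  fragment's midpoint cannot fall near the gene ends).  Bins are merged
  until every expected count is &ge; 1 (Cochran's rule).  The depth profile
  itself is still computed and reported for plotting and for the
  conservation-of-mass identity `sum(depth) = sum(matched interval
  lengths)`.

## The synthetic-data generators

`simulate_genome()` emulates the compact diatom-type genome at its published
operating point, and these defaults *are* the study conditions: 58 genes
(33 protein-coding of which 2 spurious ORFs are split out as class `orf`,
2 rRNA, 23 tRNA), mean protein gene 793 nt (sd 220, a realistic spread for
organellar CDS), rRNA genes 1600/2700 nt (so the all-gene mean lands near
554 nt), tRNA ~72 nt, exponential spacers with mean 58 nt, GC 31%,
third-position A+T 79%, four small gene overlaps, circular topology,
universal code.  First/second codon position composition is *derived* from
the (GC, third-position A+T) pair so both targets are met simultaneously;
sense codons are drawn with stops rejected, so every simulated protein
translates cleanly --- an invariant the tests assert.  Overlaps are planted
only where the downstream gene is a tRNA, whose sequence has no codon
structure to corrupt.

The other generators plant: uniform random reversals (truth = the interval
list, so distance &le; k is checkable); exactly-n distinct substitution
edits with configurable type and codon-position weights (defaults: mostly
A&rarr;G, positions 1--2 only); fission/fusion/insert/trans-splice events
with full truth; and pseudogene fragment sets with uniform placements,
sampled identity levels (default 0.99--1.0, the published regime) and
random flanks.  A single master seed drives a named stream per generator
stage (an FNV-style hash of the stage label folded with the seed), so adding
a stage never perturbs another stage's draws and a fixed seed reproduces
byte-identical FASTA/GenBank output.

What the generators deliberately do **not** emulate: sequencing error and
read-level coverage (the pipeline consumes consensus sequences, as the
analyses it supports do), repeat families in flanking DNA (flanks are iid
random, which makes the "unrelated flank" assumption exactly true --- real
flanks with shared repeats would make fragment boundaries *harder*), codon
usage beyond positional composition, and selection on protein sequences.
Passing the planted-truth suite therefore demonstrates correctness of the
algorithms under the stated statistical structure, not robustness to
assembly artifacts.

## Problem sizes and determinism

The shipped test-suite and acceptance-script runs use: 500 random
permutations at $n \le 8$ against the BFS oracle, 100 seeded editing pairs,
3 seeded structural-event bundles, one 25-fragment pseudogene set mapped by
alignment plus 20 placement-uniformity replicates of 100 fragments each
(placement replicates bypass alignment and test the statistic directly),
and full-size (58-gene) genome simulations for the statistics.  These sizes
were chosen so the whole suite exercises every code path in a few minutes
while keeping each check statistically meaningful.  All randomness flows
from explicit seeds; `scripts/acceptance.R --seed N` is reproducible
end-to-end.

## Known limitations

* Reversal distance requires unique markers; duplicated gene names (e.g.
  two trnM copies) are dropped with a warning rather than modelled.
* Rearrangement scenarios, medians and DCJ distance are out of scope; only
  distances and blocks are computed.
* The GenBank reader covers the flat-file subset used by organellar
  deposits (LOCUS topology, CDS/rRNA/tRNA/intron keys,
  complement/join locations, the common qualifiers); it is not a general
  GenBank parser.
* Intron *classification* (group I vs group II) and secondary-structure
  folding are out of scope; only interruption intervals are reported.
* The accession-based reproduction of published table values requires the
  deposited records on disk (see `tests/testthat/test-acceptance.R`); the
  package does not download.
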