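---
title: "Mining and annotating cyclotide precursors: methods and design"
author: "cyclomine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and annotating cyclotide precursors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(cyclomine)
```

## The biological problem

Cyclotides are 26–37-residue plant defence peptides with a head-to-tail
cyclic backbone and a cyclic cystine knot: six conserved cysteines paired
I–IV, II–V, III–VI, with the III–VI disulfide threaded through the
macrocycle. In Fabaceae (the butterfly pea being the flagship producer)
cyclotide genes are embedded in albumin-1 genes, so the precursor reads:

    ER signal peptide ··· TEA | mature cyclotide | linker (~10 aa) |
    albumin-1a chain (~50 aa) | C-terminal propeptide

The signal peptide ends in a conserved Thr-Glu-Ala (TEA) motif, the
cleavage site of signal peptidase 1. The mature domain carries the
six-cysteine framework; a C-terminal Asn (rarely Asp) is the
transpeptidation site at which an asparaginyl endopeptidase (AEP) ligates
head to tail. `cyclomine` re-implements, as composable R functions, the
discovery-and-annotation workflow a transcriptome survey of such a plant
uses: ORF extraction, motif/homology mining, architecture parsing,
topology classification, mass-spectrometric confirmation, biosynthetic
enzyme annotation, expression clustering, and phylogenies.

## ORF extraction

`findOrfs()` enumerates maximal stop-to-stop segments in all six frames
and keeps segments of at least `minAa` residues (default 50, the
conventional long-ORF threshold for assembled transcripts). Two variants
are reported per segment: the full open segment and, where a Met exists,
the first-ATG form. Downstream mining uses the *open* segments: de novo
assemblies routinely truncate 5' ends, and insisting on ATG initiation
would discard exactly the partial precursors one wants to keep.
Coordinates are 0-based half-open on the forward strand (negative frames
store the forward-strand span of the reverse-complement ORF), and codons
containing `N` translate to `X` rather than failing.

## Mining: motifs, homology, curation

`scanPattern()` implements a PROSITE-style pattern language (literals,
classes `[..]`, negated classes `{..}`, wildcard `x`, counted repeats,
terminal anchors) with greedy regular-expression semantics; the bundled
`cyclotidePatterns()` describe the six-cysteine framework with
family-typical loop bounds. `localAlign()` is exact Smith–Waterman under
BLOSUM62 with affine gaps (open 11, extend 1 — a gap of length L costs
11 + L), replacing heuristic database search with the optimal algorithm
it approximates. A candidate is kept when a pattern matches or a
reference mature cyclotide aligns at ≥ 30% identity over ≥ 70% of the
reference — thresholds standard for this family's sequence conservation —
and additionally shows at least 5 cysteines within a 40-residue window.
That window rule is this package's reproducible stand-in for the manual
curation step of published surveys: it tolerates truncated and unusual
(5- or 7-cysteine) frameworks while excluding every decoy class the
generator produces. Identity is computed over aligned columns including
gaps and coverage over the query, the common reporting convention.

## Architecture parsing and topology

`parseArchitecture()` anchors regions in this order: the cysteine
cluster (≥ 5 cysteines with consecutive spacing ≤ 12) defines the mature
core; the last `TEA` before the cluster closes the signal peptide (its
absence marks a 5'-truncated transcript); the cyclization residue is the
first Asn/Asp within 12 residues after the last framework cysteine; the
linker and albumin-1a chain are located by local alignment to bundled
cysteine-free consensus sequences (synthetic stand-ins carrying the
architectural constraints — length, composition, conserved ends — which a
user can replace with curated references); whatever follows albumin-1a is
the C-terminal propeptide. When no TEA is present the mature N-terminus
defaults to 5 residues before Cys I, covering the atypical N-terminal
stretches and non-Gly starts seen in real precursors. When no
cyclization residue exists (acyclic products), the mature end falls back
to the linker anchor.

`extractLoops()` decomposes the mature domain: loop *i* (1–5) is the
segment strictly between Cys *i* and Cys *i+1*; loop 6 spans the
cyclization junction (post-Cys VI tail plus pre-Cys I flank). A cysteine
count other than six marks the domain `unusual` and skips decomposition.

`classifyTopology()` applies a fixed decision order: unusual → acyclic
(no cyclization residue) → Möbius (Pro anywhere in loop 5 — the
sequence-level proxy for the *cis*-Pro peptide bond, since isomer state
is unobservable from sequence) → otherwise a nearest-reference vote on
ungapped percent identity of loops 2 and 3 against labelled templates:
a Möbius-like winner means Hybrid (Möbius-like loops without the
loop-5 Pro), anything else Bracelet, with ties resolved toward Bracelet
as the majority subfamily. The Bracelet/Hybrid boundary is genuinely
underdetermined in the literature; the template vote is this package's
explicit, configurable operationalisation (`topologyReferences()`).
The conserved loop-1 Glu is reported as an annotation, never filtered on.

## Mass engine

`peptideMass()` sums monoisotopic (or average) residue masses plus one
water for a linear chain; head-to-tail cyclization removes the water
(−18.010565 Da) and each disulfide removes two hydrogens
(−2 × 1.0078250319 Da). Mature cyclotides are matched fully oxidized
(three disulfides) and cyclic; acyclic domains as linear oxidized.
`computeMh()` offers two conventions: the proton mass (+1.00728, default)
and the unit convention (+1.0) that printed "M + H" tables typically use;
both are exposed because reported m/z values are ambiguous between them.
`matchPeaks()` reports every peak/record pair within the tolerance
(default 0.5 Da, matching one-decimal MALDI peak lists; ppm mode
available), sorted per peak by absolute error — the match set is monotone
in the tolerance by construction.

## Enzyme annotation

Annotation transfers functionally important residues from an annotated
reference through a Needleman–Wunsch site map (`globalAlign()`), because
published residue numbering is alignment-based. The references bundled
under `inst/extdata` are *synthetic* sequences constructed to carry the
published residue rules at known coordinates; they are plain editable
FASTA + TSV so curated references can be dropped in.

* **AEP** (`annotateAep()`): ligase-like requires the complete
  Asn-His-Cys triad, an aromatic (F/Y/W) at LAD1 position 1, V/I/C/A
  (not Gly) at the gatekeeper (LAD1 position 2) and Gly/Ala at LAD2
  position 1; a Gly/Ser gatekeeper is protease-like; everything else is
  ambiguous. The MLA segment length is reported but deliberately excluded
  from the call — its causal role is disputed, so it stays informational.
* **PDI** (`annotatePdi()`): thioredoxin-fold segments are found by
  iterated local alignment to a fold consensus with masking; segments
  containing `C-x-x-C` are catalytic (`a`-type), others `b`-type, giving
  arrangement strings like `a-b-b'-a'`; the C-terminal tetrapeptide is
  tested against the ER-retention consensus `[KHN][DE]EL`, with
  non-canonical tails (e.g. `KDQI`) reported verbatim.
* **ERO1** (`annotateEro1()`): each annotated reference cysteine
  (outer/inner active pairs, regulatory set, long-range disulfide,
  PDI-interacting pair, non-catalytic) is mapped and reported as
  conserved, substituted (with the residue) or absent.
* **Cyclophilin** (`annotateCyp()`): the cyclophilin-like domain is
  located by local alignment to a reference CLD (≥ 30% identity, ≥ 70%
  reference coverage); a ≥ 20-residue flank matching an auxiliary motif
  (default a zinc-finger-like pattern) upgrades the call to multi-domain.

## Expression clustering and phylogenies

`correlationDistance()` computes 1 − Pearson *r* between per-gene
profiles after centring/unit-scaling rows (the heatmap convention;
zero-variance genes are dropped with a warning since their correlation is
undefined), and `clusterComplete()` performs complete-linkage
agglomeration via `stats::hclust`, whose merge heights are provably
non-decreasing. Replicate columns are averaged per tissue first
(`averageByTissue()`).

`cysAnchorAlign()` aligns six-cysteine domains without heuristic MSA by
exploiting the framework itself: per-loop blocks padded right to the
block maximum, giving gap-free, perfectly aligned cysteine columns.
Distances are p-distances with pairwise deletion (the default model of
common tree GUIs; the underlying model used by published trees is rarely
stated, so exact reproduction of published topologies is not claimed).
`njTree()` is Saitou–Nei neighbor joining (via `ape::nj`) with negative
branch lengths clamped to zero, and `bootstrapTree()` resamples alignment
columns with replacement, reporting for each internal edge the percentage
of replicates containing the same bipartition. The default is 1000
replicates — published surveys use 10,000, which is configurable but
unnecessary for the package's desk-scale analyses. Identical sequences
produce degenerate zero distances and a star-like tree; this is
documented behaviour, not an error.

## The synthetic-data generator

`generatePrecursorSet()` emits ground-truthed transcripts emulating the
study conditions of a Fabaceae cyclotide survey:

* topology proportions default to the published 51-domain tally
  (11 Möbius : 27 Bracelet : 8 Hybrid : 3 acyclic : 2 unusual),
  allocated by largest remainder so every class is represented;
* truncation probability defaults to 9/71 (the observed partial-transcript
  rate), removing the signal and/or the albumin-1a + tail independently;
* loop lengths default to loop1 = 3, loop2 = 4, loop3 ∈ [4,5] for
  Möbius/Hybrid vs [6,8] for Bracelet, loop4 = 1, loop5 ∈ [4,5] (with an
  obligatory Pro for Möbius), loop6 ∈ [5,8] ending in Asn (90%) or Asp —
  quantitative loop-length distributions are not published, so these are
  stated assumptions mirroring the qualitative contrast (shorter loop 3 in
  the Möbius cluster), exposed in `simConfig()`;
* nucleotide encoding draws uniform synonymous codons (mining operates at
  the protein level, so codon bias is irrelevant), brackets the CDS with
  in-frame stops, and — because random codon choice can create
  cysteine-rich ORFs in *other* frames — resamples the encoding until the
  designed protein is the transcript's only mineable product;
* decoys (albumin-1-like proteins without a cyclotide domain, random
  ORFs, shuffled precursors) are resampled until they lack the
  5-Cys/40-residue window that curation requires, which guarantees zero
  decoy false positives by construction — the generator defines the
  negative class, it does not merely hope for it.

`generatePeakList()` emits [M+H]+ of the oxidized cyclic (or linear)
monoisotopic masses for a sampled subset of domains with Gaussian noise
(default sd 0.1 Da, a realistic reflectron-MALDI error at 3 kDa) plus
uniform decoy peaks. `generateExpression()` plants `k` clusters (default
3, matching the major expression clusters across leaf/flower/pod/stem)
with log-normal dispersion (default sd 0.25 on the log scale).

What passing tests on these data do and do not show: the generator
produces clean codon usage, exact consensus-anchored linkers/albumin
chains, and noise-free architecture; real assemblies add misassembly,
sequencing error, allelic variants and diverged albumin-1a chains. The
synthetic results therefore validate the *logic* of every stage
(recovery is exact where the signal is exact) but do not certify recall
on a real transcriptome, where thresholds — all exposed as arguments —
may need loosening.

## Numerical and design choices

* All stochastic entry points take an explicit seed (`simConfig()` makes
  it mandatory); `withSeed()` scopes the RNG so no global state leaks.
  Every acceptance quantity is recomputed from scratch at run time.
* Masses use 5-decimal monoisotopic residue constants, water 18.010565,
  H 1.0078250319, proton 1.00728; the test suite cross-checks them
  against an elemental-composition oracle at 1e-4 Da.
* Alignment tie-breaking is delegated to the underlying dynamic program;
  scores (the quantities all rules consume) are tie-invariant.
* Agglomeration tie-breaking is `stats::hclust`'s; ties have measure zero
  for continuous expression data.
* Degenerate inputs: empty FASTA files are valid (empty set); proteins
  without a cysteine cluster raise a "not a precursor" error; a matrix
  with fewer than two columns cannot be correlated and errors; `k`
  larger than the item count errors; NJ requires ≥ 3 taxa.
* Problem sizes used by the bundled checks (40 + 60 transcripts, 1000
  random peptides, 100 additive matrices of 4–8 taxa, 500-replicate
  bootstraps, 45-gene expression matrices) were chosen as the smallest
  sets that exercise every code path and class; all complete in a couple
  of minutes on a single core.

## Known limitations

* The Bracelet/Hybrid vote depends on the supplied templates; distant
  families need their own references.
* Disulfide connectivity, 3-D structure, signal-peptide probability and
  PTMs are out of scope; masses assume unmodified peptides and single
  charge.
* The PROSITE dialect covers the constructs the framework patterns need;
  exotic features of the full grammar (e.g. `[G>]`) are not parsed.
* Enzyme calls are sequence rules, not activity predictions: a
  ligase-like AEP call is a hypothesis generator, nothing more.
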