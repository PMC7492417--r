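---
title: "Mining satellite-like tandem repeats and HINE elements: methods and design"
author: "hineminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining satellite-like tandem repeats and HINE elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short satellite-DNA-like tandem repeat arrays -- head-to-tail runs of
100-500 bp monomers with as few as two copies -- are scattered through
euchromatic genome assemblies. In the Pacific oyster, the most abundant of
these arrays are not free-standing satellite loci: each similarity cluster
of arrays sits inside a non-autonomous Helentron-associated interspersed
element (HINE), flanked by a conserved left module (LF: a 5' subterminal
inverted repeat, a short internal inverted repeat complementary to it, and
a microsatellite) and a conserved right module (RF: the 3' subTIR copy
followed by a palindrome). `hineminer` implements the complete discovery
chain -- tandem-repeat detection, array clustering, flank consensus
derivation, substructure annotation, element assembly and grouping, and
insertion-site characterization -- together with a synthetic-genome
generator that plants elements with machine-readable ground truth, so that
every stage is verifiable end to end.

## Tandem-repeat detection

Arrays are found with a seed-and-refine design in the spirit of Tandem
Repeats Finder. Exact 12-mer matches at distances within the period window
(100-500 bp, with a 10 bp margin) seed candidate loci; seed evidence is
grouped by position, and each candidate is refined one distance mode at a
time, so two adjacent arrays with periods differing by a single base (the
double-array organization) are peeled apart rather than refined as one
confused locus.

For one candidate, the monomer is polished by column-plurality over
period-phased chunks (chunks under 60% ungapped identity to the first chunk
are excluded, which keeps a junction with a neighbouring array from
corrupting the estimate). Array boundaries come from *local wraparound
dynamic programming*: the candidate window is aligned against unlimited
cyclic repetitions of the monomer under the tandem weights (+2 match, -7
mismatch, -7 per gap column), with the monomer phase free at both ends and
the region ends free. The accepted array's score is the *global* wraparound
score of its final span against its own cyclic consensus, and the score
floor (50), the period window, and the minimum copy number (2.0, reported
to one decimal) are applied exactly as configured. Arrays containing `N`
are discarded, and overlapping reports are resolved by the redundancy rule:
among arrays overlapping by strictly more than 50% of the shorter one, the
higher score wins, with ties broken by smaller period and then leftmost
position.

Three numerical details matter and are deliberate:

* **Period selection.** The seed distance mode can be off by one base.
  Candidate periods $p_0 - 1, p_0, p_0 + 1$ are each carried through
  polishing, boundary DP and refinement to their final span, and the period
  whose refined span is longest wins (ties resolve towards the modal
  distance). Neither the local nor the global alignment score can
  discriminate a one-base period error directly -- gaps absorb the drift
  and a single-chunk consensus fits itself exactly -- but an off-by-one
  period drifts out of register within one copy, so its ungapped refit
  collapses while the true period's refit holds the whole array.
* **Boundary refit.** The DP boundary both under-shoots (a mutated edge
  base is locally unprofitable at -7 per mismatch) and over-shoots (short
  chance matches against the rotated consensus drag the boundary into the
  flank). Each boundary is therefore re-placed at the maximum of a
  period-consistency partial sum (+0.4 for a base matching one period
  inside, -0.6 otherwise -- a 60% balance point), scanned from one period
  inside to one period outside the DP boundary. Where the refit *extends*
  the DP span it is trusted outright; where it *shrinks* the span, the two
  boundaries are arbitrated by global wraparound score (shortest span
  within 10 points wins, preferring a span that clears the copy floor),
  which keeps genuinely indel-shifted copies that the ungapped refit cannot
  see.
* **Boundary ambiguity is irreducible.** A flank base that happens to
  continue the cyclic consensus is indistinguishable from a true array
  base; detected boundaries therefore jitter by a base or two. Downstream
  stages absorb this explicitly (see flank derivation).

## Alignment conventions

All pairwise alignment in the package uses linear (per-column) gap costs
and defines identity as matches divided by alignment columns, gap columns
included; `N` never matches anything, including another `N`. Tie-breaking
is deterministic (diagonal, then gap in the second sequence, then gap in
the first), so every run is reproducible. Because identity is read off the
*score-optimal* alignment, a pair with $k$ mismatches over $n$ columns can
report an identity a fraction of a percent away from $1 - k/n$ when a
mismatch pair trades against a gap pair; closed-form expectations in the
tests carry a correspondingly small tolerance.

Monomers are compared cyclically: `cyclicIdentity()` maximizes
global-alignment identity over every rotation of one monomer and both
orientations, exhaustively. Inside genome-scale clustering an equivalent
but cheaper decision procedure is used (next section).

## Array clustering

Arrays whose consensus monomers reach 70% cyclic identity are connected by
an edge; clusters are the connected components with at least two members,
ranked by member count (`CL1` largest, ties by total bp then smallest
member id); everything else is the divergent singleton remainder.
Low-complexity consensuses (>80% one nucleotide) never form edges, a
DUST-style guard.

Evaluating the exact cyclic identity for every pair is cubic in monomer
length and quadratic in array count, so the edge decision uses two
shortcuts that do not change the outcome under realistic inputs:

1. *Sound accept shortcut.* Under weights $(m, -c, -c)$ every alignment
   path satisfies score $= (m + c)M - cC$ for $M$ matches over $C$ columns,
   so the identity of the score-optimal alignment is bounded below by
   $u \cdot L_{\min} / L_{\max}$, where $u$ is the best *ungapped* rotation
   identity. When that bound clears the threshold (possible whenever the
   threshold is at most $c/(m+c) = 7/9$), the edge is accepted with no DP
   at all. This decides nearly every within-cluster pair.
2. *Candidate rotations.* Otherwise the gapped identity is evaluated at the
   top ungapped rotation candidates only. Any pair near the threshold has
   long exact stretches, which the ungapped scan ranks first.

An 8-mer sharing prescreen (against the doubled forward and
reverse-complement consensus) skips pairs that cannot approach the
threshold, and pairs already connected through earlier edges are skipped by
union-find. Member orientation and monomer frame are then assigned against
a deterministic cluster representative, and the cluster monomer consensus
is a star alignment to the medoid (maximal summed identity over a
deterministic subsample) with column-plurality calling; gap-majority
columns are dropped, and IUPAC codes are emitted only under an explicit
flag when no base reaches half support. A neighbour-joining tree over
sampled, frame-normalized monomers (`ape::nj`) with a per-cluster
monophyly report replaces model-based phylogenetics as the cluster
separation check at desk scale.

## Flank consensus derivation

Up to 4,000 bp is extracted on each side of each clustered array, truncated
at scaffold bounds; members at a scaffold edge or with `N` in a flank are
excluded. Flank windows keep a 6 bp *backoff* into the array: because
detected array boundaries carry the irreducible ambiguity described above
(occasionally systematic, when the monomer head happens to resemble the RF
head), windows anchored exactly at the reported boundary can
systematically lose the first flank bases. The backoff bases are shared
within a cluster and are harmlessly carried as leading columns.

The left module sits *behind* a 10-500 bp variable linker, so LF cannot be
anchored positionally. Round 1 seeds column support by locally aligning
every member's array-proximal window onto a reference member -- chosen as
the window sharing the most 8-mers with the others, so a member with
mis-detected boundaries is never the anchor -- and trims to the maximal
contiguous block whose support exceeds 50%; round 2 re-aligns all members
to the round-1 consensus and re-derives it. The block is bounded to 40-120
bp keeping the 3'-most end. RF is 5'-anchored at the array end with the
same reference-seeded two-round procedure, bounded by the 60 bp RF window
plus the backoff. Two edge repairs follow: columns lost at the block edges
to member-level alignment trimming are restored by majority vote of
members whose alignments dangle beyond the consensus (leftwards for both
modules -- the LF 5' edge is the element terminus -- and rightwards for
the LF microsatellite tail, where periodic slippage smears support).

Cluster orientation from the clustering stage is anchored to an arbitrary
representative, but element orientation is defined by the flanks: RF abuts
the array directly while LF sits behind the linker. Each unit's consensus
is therefore derived in both orientations and the one with a supported,
properly anchored RF block wins; a supported "RF" whose members place it
deep inside their windows (median offset > 10 bp) is rejected as the
mirrored-LF artifact. A unit flip propagates to member orientations and to
the cluster order of double-array units.

A unit needs at least 5 eligible members, over 50% member support and over
70% mean member identity on both modules to carry a valid consensus
(thresholds as configured); decoy clusters with random flanks fail with an
explicit reason and are reported as bare tandem repeats.

## Double-array units

Some elements carry two consecutive arrays from different clusters. Pairing
is decided from member-locus adjacency immediately after clustering: two
arrays pair when they are consecutive on the same scaffold in consistent
orientation with a gap of at most 1,300 bp, and a cluster pair becomes one
element unit when at least half of both clusters' members pair this way
(minus-orientation members reverse the element-space order). Flank
consensus for a paired unit is then derived from the left flank of the
first array and the right flank of the second -- deriving an "RF" for the
first cluster alone would recover the second cluster's monomer prefix as a
spurious flank. Unpaired members are kept as incomplete.

## Substructure annotation

The LF and RF consensus of each unit are merged into a chimeric construct
(array removed, junction recorded) and the LF part is locally aligned
against the reverse complement of the RF part under the inverted-repeat
weights (+2, -5, -7). All non-overlapping pairs with score at least 14 and
identity at least 90% are reported through iterative best-hit masking, with
the positional filter that the left arm lies in LF and the right arm in RF.
The subTIR is the highest-scoring pair with an 11-12 bp arm; arms up to 2
bp longer are accepted and trimmed from the LF-leading side, because one or
two conserved insertion-context bases can extend a perfect arm. The
internal IR is the best 7-12 bp match to the reverse complement of the
subTIR downstream of it in LF (spacer 1-12 bp, at most one mismatch;
fewest mismatches first, then longest). The palindrome search downstream of
the RF subTIR enumerates all arm/loop decompositions (arm >= 5 bp, loop
3-12 bp, at most one arm mismatch) and reports the maximal arm --
arm reverse-complementarity standing in for thermodynamic stem-loop
folding. Microsatellites are detected by the same wraparound machinery at
3-8 nt units under (+2, -3, -5) with a floor of two clean copies, must lie
in the 3' half of LF, and only fundamental units are considered (a near-
repetitive 8-mer made of two similar 4-mers reports through its 4-mer).
Per member, the subTIR is re-annotated by motif search allowing one
mismatch. The canonical module order -- 5' subTIR, IR, microsatellite in
LF; subTIR then palindrome in RF -- is asserted on module starts, since
detected module *ends* can legitimately overlap by a few bases when a
tandem microsatellite phase-extends into the IR.

## Element assembly, grouping and reporting

A unit with a valid flank consensus, a subTIR pair and correct module order
is a valid element model, named `HINE_<clusters>`; units failing parts of
this are emitted with completeness flags, and units with no flank consensus
are bare tandem repeats. Member loci are extended from the array to the
located LF start and RF end; per-member linker lengths are recorded, and
orientation consistency (array orientation versus flank orientation) is
reported per element -- the expected value for real elements is exactly 1.

Elements are grouped by two relatedness criteria. Flank relatedness is the
global identity of concatenated LF+RF consensuses at a 70% threshold.
Monomer relatedness is deliberately *local*: the best local alignment of
one cluster consensus against the doubled partner consensus (either
strand) must reach 70% identity over at least 25 aligned columns with
score at least 40 under the tandem weights. Related monomers share
conserved motifs while being globally divergent, and a global 70% monomer
threshold cannot coexist with 70% single-linkage clustering: families
similar enough to clear it would be merged into a single cluster by the
clustering stage itself, noise on per-array identities sealing the merge.
The local criterion separates the two scales cleanly: the generator's
related families share a 60 bp motif at ~87% identity (local score ~48,
comfortably above the threshold of 40 and far above the ~20 ceiling of
random local alignments at these lengths) while their global cyclic
identity stays near 0.63, safely below the 0.70 clustering threshold.
Group 1 is a connected component (size >= 2) of the graph whose edges
satisfy both criteria; group 2, of the flank graph among the remaining
elements; group 3 is everything else.

The per-cluster report recomputes every column of the published-style
feature table: array counts, counts and percentages with >= 5 monomers,
total length, proportion of a configurable assembly size (559 Mb by
default), monomer counts, mean monomers per array, GC and consensus
length; the totals row sums the counts and averages the per-cluster means
(the convention of the published table), and the >= 5-monomer percentage is
reported under both numerator conventions since the literature uses both.

## Insertion-site analysis

The empty-site (pre-insertion) allele of a member locus is reconstructed by
joining 50 bp from each side of the element and searched over both strands
of all scaffolds with an 11-mer seeded local aligner; hits need 80%
identity over 85% of the query, never overlap the source locus, and
deliberately replace E-value statistics with the stated thresholds. The
insertion profile reads the junction dinucleotide and a +/-10 bp
composition window off the reconstructed empty allele, tests TT enrichment
against the genome-wide dinucleotide background with an exact binomial
test, and scans k = 2..10 for target-site duplications by exact comparison
of the k bases flanking the element, reporting the per-member longest
duplication and its modal length (0 = no TSD, the Helentron expectation).
Array dispersal on a reference is mapped by exact string matching only
(`Biostrings::vmatchPattern`), both strands.

## The synthetic-genome generator

The generator is first-class, tested code and defines the study
conditions. Background scaffolds are i.i.d. nucleotides at a target GC
(0.33 by default, with A/T-rich base frequencies mirroring a mollusc
assembly); no isochore or repeat-landscape structure is modelled, which is
sufficient for every stage contract but means recovery rates on real
genomes, with their own repeat families and segmental duplications, will
be lower than on synthetic ones.

The default roster mirrors the published inventory: 13 monomer clusters
with the published per-cluster consensus lengths (138-181 bp), mapped to
11 families; two double-array families (clusters 10+13 and 11+12); one
group-1 quadruple sharing a complete flank architecture derived from a
common ancestor at ~5% per-family divergence (one diagnostic subTIR
substitution each) plus a shared 60 bp monomer motif carrying four private
substitutions per carrier at a different position in each monomer; one
group-2 pair sharing a second flank ancestor with unrelated monomers; five
unrelated group-3 families. Planted subTIRs use the upper end of the
11-12 bp range: with an 11 bp subTIR, the conserved insertion-context
base plus a chance-complementary RF continuation is indistinguishable
from a 12th subTIR position, so a 12 bp design keeps exact recovery
well-defined. Several families carry GTCC/GTCT-class
microsatellite units. The motif design is deliberate on both margins: any
two carriers differ at 8 motif positions (~87% motif identity), giving a
local-alignment score near 48 for grouping, while global cyclic identity
between carrier monomers stays near 0.63 so single-linkage clustering at
0.70 never merges them; placing the motif at a different offset per
cluster additionally prevents in-phase extension across a double-array
junction. The roster is produced from a fixed internal seed and is
byte-stable.

Elements are realized per member: flank modules mutated at 2% per base,
monomer copies drawn from a copy-number law dominated by 2-3 copies
(P(2) = 0.35, P(3) = 0.21, P(4) = 0.14 with a geometric 2/3-ratio tail),
each copy substituted at 5% per base with single-base indels at 0.5% of
the substitution rate, and a random linker with lognormal length (median
~40 bp) clamped to 10-500 bp. About 5% of double-array members receive up
to 1.2 kb of anonymous sequence between their arrays. Insertion sites are
sampled TT dinucleotides (weighted towards T-rich context) with at least
2 kb separation and the element is placed between the two Ts on a random
strand with no target-site duplication; when a TSD is requested, the
duplicated target bases are kept as a forward direct repeat to the
element's left regardless of element strand. Decoy bare arrays (shared-
monomer families and one-off singletons), LF-only/RF-only truncations, and
copies of pre-insertion 100 bp loci (empty paralogs) are planted in a
second pass that shifts all existing truth coordinates exactly. Every
planted feature re-extracts byte-identically from the final genome.

Recovery is scored per stage: array precision/recall at 50% reciprocal
overlap with boundary mean absolute error, cluster Rand index against
planted labels, monomer/LF/RF consensus identity against the models
(measured as planted sequence recovered within the derived consensus, so
benign leading backoff columns do not count against it), exact subTIR
recovery per family, element counts, and the group confusion. The shipped
acceptance configuration runs 11 families x 40 elements on ~2.4 Mb across
four scaffolds -- chosen to exercise every design feature, including both
double-array families, at a few minutes of runtime on one core.

## Known limitations

* Substitution-dominated mutation: the generator's indel rate is low, and
  the detector's period-consistency refit is ungapped; heavily
  indel-eroded arrays would lose boundary accuracy (the DP-span
  arbitration recovers the common single-indel case).
* Monomer frames are propagated through a cluster representative; at
  divergences far beyond the study conditions the frame assignment, and
  with it consensus quality, degrades before the clustering itself does.
* The empty-site search is a seeded heuristic: a paralog with no shared
  11-mer in 100 bp (below ~70% identity) cannot seed, which is far below
  the 80% acceptance floor and therefore immaterial to the stated
  thresholds.
* Group assignment reproduces the published three-group structure by
  construction of its thresholds; on real data the grouping thresholds are
  configurable and should be read as one operating point, not as an
  inference.
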