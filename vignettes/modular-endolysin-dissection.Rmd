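---
title: "Dissecting modular endolysins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting modular endolysins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lysmod` dissects a set of modular peptidoglycan-hydrolase proteins into
shared domains, families, architectures and organization types, and
analyses the mosaic structure that domain shuffling leaves behind. This
vignette explains the models and the design choices; the README shows
the surface usage.

## The problem

Mycobacteriophage endolysins are mostly three-part proteins: an
N-terminal peptidase-like domain, a central catalytic domain and a
C-terminal cell-wall-binding motif, drawn from a limited menu of family
types and exchanged between phage lineages at a high rate. Two proteins
may share their full architecture, exactly one domain, or nothing; a
single protein's domains can have different evolutionary histories. The
analysis therefore has to (i) find homologous *segments*, not whole-protein
relatives, (ii) group segments into families across chains of diverged
members, and (iii) quantify the combinatorial and phylogenetic traces of
shuffling.

## Pairwise homology

All protein pairs are aligned with exact Smith–Waterman (affine gaps,
Gotoh recurrences) under BLOSUM62 with gap open 11 and extend 1 — exact
rather than heuristic search, because at a few hundred residues per
protein exactness is affordable and testable against a brute-force DP
oracle. Significance uses the Karlin–Altschul statistic
$E = K m n e^{-\lambda S}$ with the standard gapped parameters for this
matrix, $K = 0.041$, $\lambda = 0.267$, so E-values approximate those of
a default BLASTP search. Traceback is deterministic: the best cell with
the smallest `(end_a, end_b)`, moves preferring diagonal, then a gap in
the second sequence, then in the first. `X` is accepted and scores 0
against everything. After the best alignment of a pair, its intervals
are masked (with a strongly negative internal character, so masked
regions cannot be crossed for free) and the pair is searched once more;
this recovers co-linear repeats such as duplicated domains.

Two criteria decide whether a matched region pair counts as shared:

* **E-value route**: $E < 10^{-5}$, strict.
* **Identity route**: ClustalW-style *global* percent identity > 20%,
  strict (identical pairs over columns with at least one residue).

The default link rule is OR — the two criteria describe two independent
search methods — with AND available. An important practical point: the
identity criterion is computed from a *global* alignment of whole
sequences (pair level) or candidate domain intervals (family level),
never from the local alignment's own columns. Short spurious local hits
routinely exceed 20% column identity, whereas global identity of
unrelated domain-sized sequences sits near 14% and exceeds 20% only in
a small tail. Because even that tail is fatal under single linkage, two
guards back the identity route: the region pair must also align with at
least marginal significance (E < 1, `identity_evalue_cap`), and an
identity-only link merges two otherwise-unlinked groups only when a
second independent identity link connects the same two groups
(`identity_min_links = 2`). A genuinely diverged family member aligns
above threshold with many members of its family; a chance 20% pair
links once.

## From matches to domain families

Nodes of the clustering graph are per-protein intervals; edges are
matches mapped onto them; families are the connected components (single
linkage, chosen because family membership chains through intermediate
members — distant pairs may share little more than 20% identity).

The difficult step is interval definition. A match between two proteins
sharing their whole architecture spans several domains; naively merging
it with single-domain matches would collapse every domain of a protein
into one interval. `cluster_families` therefore decomposes segments at
**match-supported boundaries** before consolidating:

1. Segment endpoints from E-significant matches are clustered by greedy
   peak extraction (repeatedly take the ±10-residue window holding the
   most endpoints, report its median, remove its points). Peak
   extraction, unlike gap-based 1-D clustering, cannot chain two nearby
   true boundaries into one cluster via stray points between them.
2. A boundary is accepted when at least `boundary_min_support = 2`
   endpoints support it *and* endpoints make up at least 25% of the
   local evidence (endpoints plus segments spanning the position) —
   a few stray alignment overruns cannot cut a well-covered domain.
3. Every segment is cut at accepted interior boundaries; pieces shorter
   than `min_seg_len = 30` are dropped; pieces are merged when they
   overlap by at least half the shorter piece (`consolidate_segments`,
   exported with exactly that rule).
4. A second pass projects the first-pass interval boundaries of every
   match partner through the alignment onto the other protein. This
   consensus transfer matters when a protein's own partners all span a
   boundary (for instance after a swap that makes them share two
   flanking domains): the protein inherits the boundary evidence of the
   rest of the set.

Edges are then anchored by aligned-column counts: a match contributes an
edge between interval $I$ (on one protein) and the interval on the other
protein that captures the most aligned residue pairs of $I$ — counting
columns rather than taking the alignment span, which long gap blocks
would mislead. Each edge carries its own sub-alignment score/E-value and
the global identity of the two intervals, and must itself pass the dual
threshold. Finally, overlapping or abutting instances of one family on
one protein are fused (they are fragments of one domain; a genuine
tandem array of a single family is thereby reported as one instance),
and families with at most 3 instances whose median width is below twice
`min_seg_len` are dropped as alignment-edge fragments.

Positional classes follow a majority vote over members' normalized
midpoints (below 0.35 → N, above 0.65 → C, else CAT; ties and tiny
ambiguous families → UNASSIGNED); a user annotation mapping families to
classes overrides the vote.

## Architectures, organizations, combinatorics

A protein's architecture is its ordered (family, class) string; proteins
with identical signatures form an organization. Labels are assigned
deterministically — `Org-A` to the largest group, ties broken by the
smallest member id, continuing `Org-AA` past 26 — rather than following
any published figure's ordering; a mapping table to external names can
be applied downstream. Signatures are ordered tuples because content
alone cannot distinguish, say, a binding motif placed N-terminal to a
catalytic domain from the canonical arrangement. The combinatorial
space of a class menu is the plain product `n_N * n_CAT * n_C`; coverage
statistics report how many organizations are observed and what fraction
of proteins is canonically N+CAT+C. Internal-translation-start
arithmetic treats the internal start codon as included in the truncated
product (`full_length - start + 1`), the convention forced by the
published 384/144 → 241 case.

## Networks, trees, incongruence

Presence/absence of each family type per protein gives a binary matrix;
Hamming (default) or Jaccard distances feed a NeighborNet splits
network. The circular ordering and split weights come from the
agglomerative NeighborNet implementation in phangorn; weights below
1e-8 are dropped and the least-squares residual is recomputed from the
returned splits. For degenerate metrics on which the agglomeration
returns no splits (e.g. all distances equal), weights are refit by an
in-package Lawson–Hanson active-set NNLS over the full circular split
set. On an additive metric the network reproduces the tree's splits and
branch lengths with numerically zero residual; conflicting signals
appear as incompatible splits with positive weight.

Per-domain trees use neighbor joining (ape) on `1 − identity` distances
from a minimal progressive multiple alignment: guide tree = NJ on
pairwise global identities, midpoint-rooted (rooting at an arbitrary
leaf would force that leaf to align last against a mostly unrelated
profile), profiles aligned with mean-of-pairs column scores (existing
gaps score `-gap_extend` against residues, 0 against gaps; new gaps pay
the affine penalty). Negative NJ branch estimates are clamped to zero.
Bootstrap support resamples alignment columns with replacement from one
RNG stream in replicate-major order, so runs are exactly reproducible
given the seed; supports are the percentage of replicate trees
containing each reference split. Tree comparison uses the
Robinson–Foulds distance over canonical bipartition sets.

The incongruence scan compares the NJ trees of each pair of domain
classes over their shared proteins. A pair is flagged when two splits —
one per tree, each bootstrap-supported at ≥ 70% and each deep (smaller
side at least `min(4, n/4)` taxa) — are incompatible in a way
explainable by relocating at most two proteins: exactly one small cell
of the splits' incompatibility table, and that cell names the candidate
recombinants. The size and cell conditions are essential: independently
mutated instances of one family occasionally share enough coincidental
substitutions to support a 2–3-member clade, and distances between
*unrelated* families carry consistent noise that can support whole-family
groupings; both produce supported conflicts that have nothing to do with
recombination. A single swap, by contrast, moves one protein across
otherwise-agreeing family groups. With eight or fewer shared taxa every
cell is small and the distinction is unavailable; there the scan falls
back to plain supported incompatibility.

## The synthetic proteome generator

`generate_proteome` emulates the study corpus: each protein is
`linker · domain · linker · …` with

* a 6/5/4 family menu (N/CAT/C), ancestor domains of 60–180 residues
  drawn i.i.d. from a uniform residue background (no composition was
  available to fit),
* organization templates drawn with 0.90 probability for canonical
  `N+CAT+C` and 0.02 each for five deviants (missing central domain,
  duplicated central domain, duplicated C motif, missing N, missing C),
* instances mutated from their family ancestor i.i.d. per site at the
  configured divergence, substituting to a uniformly chosen different
  residue — no indels inside domains, which keeps the
  identity–divergence relation closed form:
  $\mathbb{E}[\mathrm{identity}] = (1-d)^2 + d^2/19$,
* linkers of 0–20 random residues,
* six lineages, each with a preferred family per slot, and a 0.05
  per-slot swap rate drawing the family from another lineage's
  preference (recorded as a truth swap event).

The default (`preference_scheme = "mosaic"`) preference matrix is
designed so that every lineage shares exactly its N family with one
other lineage and exactly its CAT family with another. This is what
makes domain boundaries *observable*: only partial pairwise matches
delimit domains, and a corpus whose lineages share nothing would present
every same-lineage pair as one full-length match. The flip side is that
the mosaic design itself encodes historical domain exchange, so its
class trees genuinely disagree even at swap rate 0. For controlled
incongruence experiments, `preference_scheme = "disjoint"` gives every
lineage its own family in every slot — a clean shared history in which
a single engineered swap (`apply_domain_swap`) must be the only signal.

What the generator does *not* emulate: insertions/deletions within
domains, realistic amino-acid composition and site-rate heterogeneity,
length variation between instances of one family, nucleotide-level
signals, and genome context. Passing recovery tests on this model shows
the pipeline's logic is sound under known ground truth; it does not
certify performance on real proteins, where boundary jitter and
composition biases are larger.

Recovery is scored by matching true to inferred instances at ≥ 50%
overlap of the shorter interval: the adjusted Rand index between true
and inferred family labels (unmatched instances count as singletons),
per-family precision/recall, and the fraction of proteins whose ordered
family string matches exactly under the maximum-weight family bijection
(Hungarian algorithm on co-assignment counts).

## Problem sizes and numerical choices

The shipped analysis and tests use 60-protein proteomes (about 1770
pairs, 300–600 residues per protein) for recovery, 24 proteins for the
controlled incongruence experiment, 100 bootstrap replicates, and
5–8-taxon metrics (100 replicates) for NJ correctness — sizes chosen so
the full suite runs in a few minutes while keeping every statistic
well away from its decision thresholds. Key constants: strict
thresholds 1e−5 / 20%; `min_seg_len` 30 aa; boundary tolerance 10 aa
with support ≥ 2 and ≥ 25% of local evidence; NNLS drop tolerance 1e−8;
bootstrap support threshold 70. All are `cluster_params()` /
function arguments, and all stages are deterministic given the
configuration and seed (radix ordering throughout, so results do not
depend on the locale).

## Known limitations

* Domain boundaries are estimated from alignment endpoints and carry
  ±linker-width uncertainty; coordinates may include a few flanking
  linker residues.
* A family occurring only once in the corpus is invisible: with no
  partner there is no match, hence no interval.
* Tandem arrays of one family are reported as a single instance.
* The identity-only route requires corroboration, so a two-member
  family whose only link is identity-based will stay split.
* The incongruence scan assumes domain swaps are rare relative to the
  corpus; a reciprocal exchange between exactly two proteins presents
  two small cells and is conservatively not flagged when more than
  eight taxa are shared.
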