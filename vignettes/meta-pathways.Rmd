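---
title: "Meta-pathways, global integrative networks and crosstalk analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-pathways, global integrative networks and crosstalk analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginet)
```

## The representation problem

Pathway databases draw signaling and metabolism differently. A signaling
edge runs from an upstream protein to the protein it modifies; a metabolic
edge runs from substrate to product, with the catalyzing enzyme annotated
*next to* the edge rather than connected to it. Merging the two pathway
classes under their native encodings produces a graph in which metabolic
enzymes are isolated vertices: the kinase at the end of a cascade has no
edge into the reaction it regulates, so the cascade and the metabolism stay
topologically disconnected even where biological crosstalk is well
established.

## The meta-pathway model

`ginet` re-encodes every reaction — metabolic or signaling — as a two-step
process through an introduced *intermediate* node representing the
transient complex of the substrate set with its enzyme:

* **type 1** subunit → protein complex (recorded when the enzyme is a
  multi-subunit complex),
* **type 2** enzyme unit → intermediate,
* **type 3** substrate → intermediate,
* **type 4** intermediate → product.

The intermediate's identifier is a pure function of its content,
`ITM[s1;s2|enzyme]`: the lexicographically sorted substrate ids, then the
enzyme unit id, empty for uncatalyzed reactions. Two consequences matter.
First, isoenzymes catalyzing the same conversion produce *distinct*
intermediates, so flux through one enzyme is never conflated with flux
through another. Second, the type-2 edge gives every enzyme a landing
point inside the reaction it catalyzes — this single design element is
what makes signaling cascades and metabolic reactions assemble into one
connected directed graph.

A signaling relation U → V is converted by the same rule, reading U as the
enzyme and V as both substrate and product (the reaction changes only a
small chemical group, so substrate and product coincide): U → `ITM[V|U]`
(type 2), V → `ITM[V|U]` (type 3), `ITM[V|U]` → V (type 4). The resulting
V → ITM → V self-return is intentional; it encodes exactly the
substrate-equals-product structure. The reverse "enzyme release" edge
(intermediate → enzyme) is deliberately never emitted: the enzyme is
unchanged by its reaction, and the edge would create biologically
meaningless shortcuts from every reaction back into its regulator.

Edge types are retained in all outputs but ignored by the graph
algorithms: all four represent transformation of the source into the
target, and the analyses (components, shortest paths) treat them
uniformly.

### Signs

Relations carry KGML subtypes. The mapping to edge signs is:
`activation`/`expression` → activation, `inhibition`/`repression` →
inhibition, everything else (binding/association, phosphorylation alone,
indirect effect, ...) → neutral. The sign is placed on the type-2
effector → intermediate edge, localizing the semantics of "U inhibits V"
on the edge that U actually contributes; type-3/4 edges stay neutral.
Signs never restrict traversal in path finding — an inhibitory edge is
still a mechanistic connection — they are annotation carried to the
results.

### Reversibility, isoenzymes, complexes

Reversible reactions are split into two opposed irreversible reactions,
each with its own intermediate(s). Each isoenzyme (a multi-name KGML
entry, or multiple entries referencing the same reaction) gets its own
intermediate per direction, so a reversible reaction with *k* enzyme units
produces 2*k* intermediates. The type-2/3/4 edges consequently double when
a reaction is made reversible; type-1 subunit edges are
direction-independent and appear once.

KGML `group` entries describe complexes whose slots may offer alternative
subunits. A group A + (B/C) + D is expanded over the Cartesian product of
its slots into units ABD and ACD; repeated members within a unit collapse
(a homodimer A + A is the single unit A), and duplicate units are removed.
Nested groups are flattened recursively. The complex unit id
`CPLX[m1+m2+...]` over sorted members is an invented canonical scheme: the
model only requires complexes to be distinct, deterministic nodes, and
KEGG identifiers contain none of `+[]`, so the scheme is collision-free
and invertible.

### Cofactor policy

Only molecules *present in a KGML file* take part in its meta-pathway.
KGML files omit ubiquitous cofactors (ATP/ADP and the like) outside their
biosynthesis pathways, and recovering them from the reaction equation
would connect functionally unrelated pathways through currency metabolites
and corrupt crosstalk distances. No reaction-equation lookup is performed.

Entries of type `map` (links to other pathway maps) and `ortholog` are
parsed and retained but excluded from graph construction by default: the
species-specific networks are built from gene, compound and group entries,
and a map reference is a pointer, not a molecule. `include_map_entries =
TRUE` reverses this for users who want inter-pathway link nodes. Relations
of type ECrel or maplink are classified "other" and never converted;
undirected binding/association relations yield a single triplet in the
file's stated direction (no mirroring by default).

## The GIN: merging and sub-networks

Meta-pathways of one species are merged by edge-set union. Two edges are
redundant when source, target, type and sign all coincide; the surviving
copy records every contributing pathway id. Union semantics make the merge
idempotent, commutative and associative, so pathway order is irrelevant.
Edges identical except for their sign are kept distinct — collapsing a
signed with a neutral copy would silently discard inhibition annotation.
GINs are written as SIF (source, relation label, target), sorted
lexicographically so repeated writes are byte-identical; a sidecar file
carries species and provenance for exact round trips.

Sub-networks are the *weakly* connected components of the directed graph.
Weak connectivity is the deliberate choice: the assembled network of a
species is a single visual piece regardless of edge directions, and strong
components would shatter linear cascades into singletons. Components with
more than 10 nodes are labeled 1..k by decreasing size — subnet 1 is the
assembled core; smaller fragments stay unlabeled as noise. Size ties are
broken by the lexicographically smallest member id for determinism.

Nodes are classified `compound_related` (compounds, and intermediates
containing a compound in either slot — a protein-compound relation places
the compound in the enzyme slot) or `protein_only`; the compound-related
fraction of a GIN indicates how metabolic versus signaling its content is.

## Cross-species sub-network comparison

Gene identifiers are species-specific, so sub-networks are compared after
mapping genes to KEGG Orthology (KO) ids; compounds already share a
namespace. The mapping is an input TSV, not a live database call, keeping
the analysis reproducible and offline; genes without a mapping are dropped
and counted. Each labeled sub-network reduces to a feature set of KO ids
plus compound ids — intermediates and complex nodes are derived constructs
and excluded — and pairs are scored with the Jaccard index |A∩B|/|A∪B|.
Conventions: two empty sets score 0 (avoiding 0/0 while making "nothing
shared" explicit); "matched" sub-networks are pairs scoring at or above a
threshold, default 0.5, exposed as a parameter because no canonical cutoff
exists. Subnet 1 can be excluded from the score matrix: the assembled
cores of two species match trivially, and the interesting question is
whether the detached fragments correspond.

## Crosstalk analysis

Given the member sets of two pathways (their gene and compound nodes,
extracted from the KGML; intermediates are GIN artifacts, and group
entries contribute their constituent genes), the GIN is treated as an
unweighted directed graph and breadth-first shortest paths are computed
for every ordered member pair in both directions. Members shared by both
pathways are excluded from the endpoint sets and reported — a shared node
is common infrastructure, not crosstalk — though paths may pass through
them. Distances count *nodes*: an adjacent pair has n = 2, unreachable
pairs are infinite. Each direction retains its single extreme shortest
path; among equal-length candidates the lexicographically smallest node
sequence wins, a pure tie-break for determinism with no biological
meaning. Connection weights W = (2/n)² map a direct link to 1 and
suppress long detours quadratically; the bipartite connection table lists
every reachable pair with distance, weight and direction.

KGML sporadically encodes misleading relations — an extracellular ligand
drawn onto the wrong receptor can fabricate a path between unrelated
pathways. The curation list (YAML records of source, target, reason)
removes such relations *as triplets*: both direct matching edges and every
edge incident to an intermediate whose enzyme slot matches the source and
whose substrates contain the target. Removal is logged per rule; a rule
matching nothing warns rather than fails, since curation lists are shared
across KEGG versions. Edge removal can only lengthen distances, never
shorten them, so curation is safe to apply before any distance analysis.

## The synthetic-KGML generator

Real KEGG files cannot ship with the package, and network access is not
assumed anywhere, so fixtures are generated. `fixture_spec()` defaults —
10 genes, 8 compounds, 5 reactions, 6 relations per file, 30 % reversible
reactions, 25 % complex-catalyzed reactions (one fixed subunit plus a
two-alternative slot), 25 % two-isoenzyme entries — are sized like a small
KEGG map and fixed once; the generator's purpose is structural coverage of
the conversion rules (every edge type, both directions, group expansion,
sign mapping), not statistical realism. It does not emulate KEGG's degree
distributions, multi-substrate stoichiometry beyond two substrates, or
graphics attributes, so passing tests demonstrate correctness of the
conversion and analysis machinery, not performance claims about real
KEGG-scale networks (a full species GIN is orders of magnitude larger).

Two planted motifs exercise the load-bearing structures: a three-gene
cascade whose terminal kinase catalyzes a compound conversion (the
crosstalk-connecting shape: the type-2 edge bridges the cascade into
metabolism), and a spurious ligand → receptor activation that the curation
machinery must remove. `generate_crosstalk_pair()` emits a metabolic-style
and a signaling-style pathway connected through shared linker molecules:
an uncatalyzed conversion into a linker compound that activates a receptor
(retained outgoing path, 5 nodes), a kinase inhibiting a linker enzyme
(retained incoming path, 5 nodes), a 7-node decoy route that must lose to
the 5-node bridge, and the curation artifact. With only two files in the
merged GIN, any crossing path necessarily passes through nodes present in
both files; the linkers are therefore deliberately shared members, which
the crosstalk machinery excludes from the endpoint sets — the *exclusive*
member sets of the two fixtures are disjoint. Everything is deterministic
in the seed (byte-identical files), and generation saves and restores the
caller's RNG state.

## Numerical and degenerate-input choices

* All orderings (entries, edges, SIF lines, members, substrate sets) are
  lexicographic, making every output byte-stable across runs.
* An empty pathway document yields an empty meta-pathway; an empty GIN has
  zero statistics and a subnet-1 fraction of 0.
* Uncatalyzed reactions form intermediates with an empty enzyme slot.
* Multi-substrate reactions form one intermediate containing the whole
  substrate set, not one per substrate.
* Self-relations in KGML are preserved and flagged by validation, not
  dropped.
* Duplicate edges are removed on (source, target, type, sign); provenance
  is unioned, so merging is loss-free for pathway attribution.

## Problem sizes in the test suite

The suite verifies the algorithms against independent brute-force oracles
on randomized inputs: 1,000 random groups (≤ 5 slots × ≤ 4 alternatives)
against a recursive Cartesian enumerator; 100 random graphs of up to 200
nodes against a union-find component finder; 50 random GINs of up to 200
nodes against a vectorized Floyd–Warshall all-pairs oracle; merge algebra
on random meta-pathway triples. These sizes give dense coverage of the
combinatorial space while keeping the whole suite fast; the algorithms
themselves (BFS, union of sorted edge sets) scale to far larger graphs.

## Known limitations

* No stoichiometry, mass balance or thermodynamics — the meta-pathway is a
  qualitative connectivity model.
* Homo-oligomer copy number is ignored by design (a homodimer is one
  unit).
* Cofactors absent from a KGML file are not recovered, so paths through
  omitted currency metabolites are invisible — the price of not
  fabricating crosstalk through ATP.
* Transcription-factor-mediated regulation (a signaling path ending in a
  TF that changes an enzyme's expression) is outside the model: only
  post-translational and metabolic conversions are edges.
* KO mappings must be supplied as tables; the package performs no live
  database queries.
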