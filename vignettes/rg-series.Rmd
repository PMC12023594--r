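---
title: "Detecting and summarising lead-optimisation series with reduced-graph cores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and summarising lead-optimisation series with reduced-graph cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lead-optimisation (LO) datasets contain hundreds of analogues built around a
small number of scaffolds, traditionally summarised as a Markush structure
with an R-group table. Substructure-based series detection is brittle: a
small change to the scaffold (an extra ring nitrogen, a chain homologation)
creates a "new" series even though a chemist would read it as the same one.
`rgcore` works at the **reduced graph** (RG) level instead. Each molecule is
collapsed into a small typed graph — rings, hydrogen-bonding groups, complex
atoms, inert linkers — and series are detected as **RG cores**: connected
subgraphs common to sets of molecules. Because the RG is a many-to-one
representation, molecules with different but functionally equivalent
substructures land in the same series.

## The reduced-graph model

Node typing runs in a fixed precedence:

1. **Rings.** One node per SSSR ring, labelled aromatic (all ring bonds
   aromatic) or aliphatic, and by hydrogen-bonding character derived from its
   atoms. An atom shared by fused rings is assigned to the first ring in a
   deterministic ring ordering (rings sorted by size, then atom indices); the
   fusion itself is recorded as a double edge between the two ring nodes.
2. **Acyclic H-bonding groups.** Atoms matching the acceptor (HBA) and/or
   donor (HBD) SMARTS are grouped with flagged neighbours into acyclic
   HBA / HBD / HBA-HBD nodes. The default patterns are the standard
   pharmacophoric definitions:
   HBA `[$([!#6;+0]);!$([F,Cl,Br,I]);!$([o,s,nX3]);!$([Nv5,Pv5,Sv4,Sv6])]`,
   HBD `[!#6;!H0]`. An atom matching both is HBA-HBD.
3. **Complex atoms.** Remaining acyclic heteroatoms (halogens included) and
   acyclic carbons with three or more heavy neighbours ("branched" carbons —
   the definition that makes CF3 and gem-dimethyl groups come out as single
   complex nodes) form complex (`Hg`) nodes, grouped when adjacent.
4. **Inert linkers.** Whatever acyclic atoms remain become acyclic inert
   nodes.

Two special rules follow: an acyclic carbonyl carbon joins its oxygen's
acceptor node (so amides collapse, after merging, into one HBA-HBD node),
while a ring carbonyl leaves the exocyclic oxygen as its own acceptor node;
and an acyclic halogen adjacent to an acyclic HBA node is absorbed into it
(acyl halides become one node). Merging then runs to a fixed point in the
order *same-type → HBA/HBD into HBA-HBD → inert into complex*; this order is
load-bearing (running the complex-absorption rule first could swallow a
linker that the HBA-HBD rule should claim) and is pinned by the unit tests.
Ring nodes never merge, so ring counts survive reduction.

Nodes are labelled with two-letter element codes (acyclic inert `Li`, acyclic
HBA `Ga`, HBD `Gd`, HBA-HBD `Ge`; aromatic `No`/`Na`/`Nd`/`Ne`; aliphatic
`Co`/`Ca`/`Cd`/`Ce`; complex `Hg`) so the RG serialises in SMILES grammar,
e.g. `[Ge][Li][No]([Hg])[Hg]`. A fused-ring double edge is written as the
adjacent bond plus one extra ring-closure pair (`[No]1[No]1`), since SMILES
cannot express parallel edges; the edge list remains authoritative and the
bundled parser restores multiplicity 2. Every node also carries the canonical
fragment SMILES of its atoms with `*` wildcards at attachment points
(`*c1ccccc1` for a mono-substituted phenyl), which is how substitution
patterns stay distinguishable after reduction.

Chemistry perception — SMILES parsing, sanitisation, aromaticity, SSSR,
SMARTS matching, salt stripping, neutralisation, canonical fragment SMILES —
is delegated to RDKit through a bundled Python helper
(`inst/python/chem_helper.py`), batched one subprocess call per dataset and
memoised per SMILES. Everything downstream of perception (node typing,
merging, serialisation, MCS, mapping, tables) is R.

## Series detection

Similarity between two RGs uses the graph variant of the Tanimoto
coefficient, `T = MCS / (A + B - MCS)`, with `A`, `B` the node counts and
`MCS` the node count of the maximum common connected subgraph under exact
label and edge-multiplicity matching. The MCS is exact, via maximal cliques
of the modular product graph (RGs have ~3–15 nodes, so exact search is
cheap); ties between equally sized common subgraphs are broken by a
canonical graph code so results are bit-reproducible. MCS values are cached
by unordered pair of canonical RG codes.

Extraction is iterative. Near-neighbour lists (all RGs with `T` at or above
the threshold, descending) are computed once; then, repeatedly: the
remaining molecule with the most remaining neighbours becomes the centroid
(ties: earliest input order); walking its neighbours from most distant to
nearest, the first MCS of at least `min_core_size` nodes becomes the
candidate core (if none qualifies, the largest MCS is kept and flagged
sub-minimal); every other remaining RG either contains the candidate (it is
associated and removed) or proposes `MCS(RG, candidate)`, accepted only when
that is a subgraph of the current candidate and still at least
`min_core_size` nodes — so a candidate only ever shrinks within one pass.
The surviving candidate becomes an RG core, and the loop repeats until every
molecule is associated. A centroid with no remaining neighbours becomes a
singleton core consisting of its entire RG; this closes the termination and
full-coverage argument for arbitrary datasets.

Two points the flow description leaves open were resolved as follows: when
the sub-minimal fallback fires, the centroid is removed together with the
consumed neighbour, mirroring the main branch; and the refinement scan
continues forward after accepting a new candidate rather than restarting.
Neighbour counts used for centroid selection are recomputed against the
remaining molecules each round, which keeps the centroid meaningful late in
the run when most molecules are consumed.

The defaults (`similarity_threshold = 0.5`, `min_core_size = 5`) are the
operating point used for LO-scale datasets; the bundled fixtures are smaller
and typically run at `min_core_size = 4`. `core_count_sweep()` reproduces
the usual sensitivity grid — core counts grow with the minimum size (small
cores are contained in many molecules) and react only weakly to the
threshold.

## Mapping molecules onto cores

A second pass maps every molecule onto every core its RG contains, which
both recovers molecules missed by processing order and makes multi-series
membership explicit. Embeddings are induced (edge multiplicities, including
edge absence, must match), and embeddings differing only by a core
automorphism over the same atoms are collapsed.

A molecule with several distinct embeddings is resolved with topological
distance maps. The **node distance map** records, for every core node pair,
the shortest through-bond distance between their mapped atom sets; the
**substituent distance map** records, per core node, the sorted distances to
every substitution site (the first atom outside the core image bonded to a
core atom). Reference maps are aggregated with frequency counts over the
molecules that map uniquely, then frozen — resolving one ambiguous molecule
never influences the next, so resolution is order-independent. The cascade:
unique node-map match; best-supported node-map match; the same two rules on
substituent maps; finally a deterministic fallback (smallest mapped atom
image), with the deciding stage recorded per molecule. The fallback replaces
whatever additional criteria a richer implementation might add below the
distance-map rules; in practice the node-map stage settles almost all cases.

## SAR tables

Per core node, members are grouped by the substructure their mapped RG node
carries; each group reports a count and the median, mean and sample standard
deviation (n−1; single-molecule groups report NA) of pIC50. Substructure
identity is canonical fragment-SMILES equality including stereo descriptors,
so epimeric ring substituents count separately. The combined-substructure
table keys rows by the tuple of per-node substructures and renders each row
as the connected fragment over the core-image atoms of a representative
molecule — equivalent to reassembling the per-node fragments along core
edges (the construction the figures suggest), but unambiguous about which
wildcard pairs join, which is why extraction from a representative was
chosen. Pie metadata (node size = distinct substructure count, segment
fraction = group frequency) serialises to JSON for any front end; no
rendering is done here.

## What the synthetic fixtures do and do not show

The generators write series the way LO programmes produce them: a fixed
scaffold with enumerated substituents and plausible activities
(normal around pIC50 7, sd 0.8 — mid-range for optimised series — drawn
under a caller-supplied seed). The demonstration series varies an amide
nitrogen so the six molecules share a four-node scaffold while pairwise
similarities straddle the 0.5/0.7 thresholds; the ambiguity fixture attaches
both an acetamide arm and a propanoic-acid arm to one ring so exactly one
molecule has two embeddings whose node distance maps differ (carbonyl two
vs three bonds from the ring), with the ground truth known by construction.
Fixture molecules have 4–25 heavy atoms and 1–7 RG nodes. What passing
these tests does **not** show: behaviour on ChEMBL-scale inputs (hundreds of
molecules, 9-node average RGs — the algorithms are the same but runtimes
grow with the pairwise similarity matrix), tautomer- or protomer-sensitive
perception, and SSSR pathologies in large fused cage systems. The test-suite
problem sizes (≈50 fixture molecules, all-pairs MCS checks against a
brute-force oracle on RGs of up to 7 nodes) were chosen so the whole suite
exercises every rule yet runs in about a minute.

## Numerical and degenerate-input choices

Distances are unweighted bond-graph BFS distances; map equality is exact
integer equality. Pie fractions are exact rationals up to double rounding
(tested to 1e-9). Cleaning keeps the largest fragment by heavy-atom count,
neutralises charges where a valence-consistent neutral form exists, drops
records without activity, and deduplicates by canonical SMILES keeping the
first occurrence; it is idempotent and order-preserving. Stereochemistry is
preserved in stored SMILES and substructure annotations, but RG node typing
itself is stereo-blind. Empty datasets yield empty summaries rather than
errors; an RG-isomorphic pair has Tanimoto exactly 1; two empty graphs have
no defined similarity and raise. SSSR ring nodes that end up with zero own
atoms (every atom claimed by earlier fused rings) are dropped — a
theoretical case for dense cages, not reachable from the fixture chemistry.

## Known limitations

- The canonical graph code uses Weisfeiler–Lehman refinement to prune the
  ordering search; for the labelled, tree-dominated graphs RG reduction
  produces this is exact, but adversarial regular graphs could in principle
  defeat the candidate-deduplication heuristic.
- Cores are connected by construction; a series whose common structure is
  genuinely disconnected (two motifs joined by variable linkers) appears as
  separate cores.
- The exact MCS is quadratic in dataset size with clique enumeration per
  pair; very large datasets would want the cache keyed at unique-RG level
  (already done) plus coarser pre-filters.
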