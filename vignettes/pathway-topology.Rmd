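---
title: "Preserving pathway topology when parsing KGML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preserving pathway topology when parsing KGML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgmlnet)
```

## The data model and why entry ids matter

A KGML document describes a drawn map: `<entry>` elements are boxes on the
canvas, `<relation>` elements are arrows between boxes.  Three properties
of this format drive the whole design of `kgmlnet`:

1. **An entry is not an entity.**  The same accession (a gene like
   `hsa:10000`, a compound like `cpd:C00165`) may be drawn several times,
   in neighborhoods that are biologically distinct — an active and an
   inactive arm of a cascade, two spatially separate complexes.  The only
   thing that distinguishes those occurrences is the numeric entry `id`.
2. **An entry may list several accessions.**  A box labelled with a gene
   family stands for every paralog in its `name` attribute.
3. **Edges may pass through non-gene boxes.**  Gene-to-gene signaling is
   frequently drawn as gene → compound → gene.

`kgmlnet` therefore keys every node by the pair (accession, entry id),
rendered as `accession-id` (`cpd:C00165-92`).  We call the `-id` suffix a
*terminal modifier*.  Entries with k accessions become k nodes sharing one
modifier; relations expand to the Cartesian product of their endpoint node
sets.  KGML encodes undirected binding/association with the glyph `---`;
such subtypes produce an edge in each direction, all other subtypes one
directed edge.  One edge is produced per relation subtype, so a relation
with two subtypes contributes two parallel edges that later aggregate to
comma-joined metadata (`PPrel, PPrel` / `-->,-->` /
`activation, activation`).

## Group expansion and compound propagation

KGML groups ("AND" complexes) are placeholder entries listing member
entries.  Expansion re-attaches every edge incident to a group to each of
its members and adds pairwise *clique* edges among the members (value
`Custom`, name `clique`), so a complex remains an internally connected
unit.  Nested groups resolve recursively; cyclic membership is an error
naming the entry ids; a group with no components is kept as a placeholder
and later transits like a compound.  Clique edges are ordinary edges: when
the members are genes they survive into gene-only output, labelled as
derived.  We assign clique rows the type `clique` — the relation-type
column has no KGML value for an edge that was never a relation, and reusing
`PPrel` would disguise a derived annotation as evidence.

Compound propagation removes non-kept nodes without disconnecting what
they joined: for every ordered pair (u, w) of kept nodes linked by a
directed path whose *interior* nodes are all non-kept, one edge u → w is
added with type `CPp`, value `Custom`, name `compound propagation`; then
all non-kept nodes are deleted.  Self-loops are discarded.  Which nodes are
"kept" depends on the output mode: gene mode keeps only nodes with the
organism prefix; mixed mode keeps genes, compounds and linked-pathway
(`path:`) nodes and transits only placeholders (groups without members,
`undefined` entries).  When a propagated pair already has an original edge,
the propagated duplicate is merged away and the original metadata wins —
propagation is an inference annotation, not evidence, so it never
overwrites evidence.  Multiple parallel compound routes between one gene
pair collapse to a single `CPp` row.

The implementation is a breadth-first search from each kept node through
non-kept nodes only.  Reachability, not path enumeration, is what the
definition requires, so cycles among non-kept nodes are harmless.  The test
suite checks this against an independent recursive depth-first enumeration
of non-kept-interior paths on hundreds of random graphs.

## The modifier policy, and why ordering is the whole point

Modifiers are stripped (or not) only **after** propagation:

* `unique = TRUE`: every node keeps its modifier.  Duplicated accessions
  in distant neighborhoods stay distinct nodes and the parse can be laid
  out exactly as KEGG drew it.
* gene mode, `unique = FALSE`: all modifiers stripped.  Duplicated *gene*
  accessions now merge — the conventional gene-network shape — but
  because compounds were propagated while still distinct, no artificial
  bridge was created through a shared compound.
* mixed mode, `unique = FALSE`: gene modifiers stripped, compound and
  pathway modifiers kept, preserving compound differentiation while gene
  labels stay clean.

`naive_gene_network()` deliberately performs the wrong order — stripping
before propagation — to emulate merge-by-accession parsers.  On the
bundled two-neighborhood fixture the correct order yields two connected
components, the naive order one; this contrast is asserted in the tests
and recomputed by `scripts/acceptance.R`.

Stripping can create parallel rows and self-loops (two entries of one gene
related to the same partner); parallel rows aggregate with first-seen
metadata order and self-loops are dropped, since an edge list cannot
express them.  Isolated nodes likewise cannot appear in the edge list;
they do appear in the graphics file, whose key set covers every kept node.

## Output conventions

Tables are written as UTF-8 TSV with header
`entry1	entry2	type	value	name`, sorted lexicographically by
(entry1, entry2) using C-locale byte order, so repeated runs are
byte-identical.  Graphics files (`node	x	y`) carry KEGG-native canvas
coordinates: origin top-left, y grows downward, values exactly as printed
in the XML.  We never flip y silently; negate it for standard
math-convention plotting.  When several accessions share one entry they
share its coordinates; when stripping merges several entries onto one key
the lowest entry id wins.

Identifier conversion maps gene accessions through the KEGG `conv`
endpoint (Entrez `ncbi-geneid:` by default, UniProt `up:` on request),
re-attaching modifiers afterwards; compounds and pathway nodes pass
through untouched, as do unmapped accessions (with a logged count), so row
counts and metadata are always preserved.  Namespace prefixes are kept on
output for reversibility.  Where KEGG offers several targets for one gene
the first listed wins, keeping edge-list cardinality stable.  Display
names come from the `list` endpoint, batched ten accessions per call:
genes take the description after the symbol list (the part following the
first semicolon), compounds and pathways the first semicolon-separated
synonym; `path:` accessions go through the same generic `list` call as
everything else.  The REST client sleeps 0.34 s between requests (staying
under three requests per second), retries three times with exponential
backoff, and caches every KGML file on disk, so a pathway is downloaded at
most once.  All network operations accept an injectable transport; the
entire test suite runs offline against canned responses, and live probes
are a separate script under `inst/network-tests/`.

## Evaluation metrics

Comparisons between parse variants use undirected, unweighted edge sets
(direction and multiplicity dropped, self-pairs excluded).  Pathway graphs
do contain cycles; nothing here assumes acyclicity.

*Per-pathway difference* is `ppd(A, B, n) = |A \ B| / n`: edges of the
query graph absent from a reference graph, normalized by the number of
pathways compared.  It is asymmetric by construction, zero iff A ⊆ B.

*Partition modularity* is evaluated exactly as
`Q = Σ_c [L_c/m − γ(k_c/2m)²]` with resolution γ = 1 by default.  The
implementation sums over communities; the tests verify it to 1e−9 against
an independent matrix-form evaluation on *every* partition of random
graphs up to 7 nodes (Bell-number enumeration) and against
`igraph::modularity`.  Degenerate inputs are rejected rather than
defaulted: an edgeless graph has no modularity, a non-covering or
overlapping partition is an error.  Community detection for the
unique-vs-plain comparison uses igraph's fast greedy agglomeration on the
simplified graph; any detector with the signature
`edge_set -> list of node sets` can be injected, so external algorithms
can be compared without being bundled.  Modifiers are kept on unique
graphs and absent on plain graphs during scoring — the comparison is of
parser outputs as produced, not of renamed copies.

## What the synthetic generator emulates

`random_pathway(n_genes, n_compounds, n_duplicated_hubs, seed)` emulates
the structural features the method responds to: several (2–4)
disconnected gene neighborhoods (random spanning trees plus a few extra
edges), compounds bridging gene pairs within a neighborhood, and
duplicated hub accessions planted once in each of two neighborhoods — the
exact mechanism by which merge-by-accession parsing fuses topologies.
Defaults are 12 genes, 3 compounds and 2 duplicated hubs, a desk-scale
stand-in for surveying hundreds of real human pathways; coordinates lie on
an 80 px grid so layout tests see distinct values.  The generator does
*not* emulate realistic relation-subtype frequencies, KEGG's biological
content, multi-accession family boxes (covered by dedicated fixtures), or
map-scale sizes, so passing tests demonstrate correctness of the graph
transformations, not biological fidelity of any particular network.
Generation is deterministic per seed and restores the caller's RNG state.

The acceptance checks run on these conditions: 200 random graphs of at
most 12 nodes for the propagation oracle, all partitions of graphs of at
most 7 nodes for modularity, and 20 random duplicated-hub pathways for the
modularity-gain comparison — sizes at which exhaustive oracles are exact
and the whole suite stays fast.

## Known limitations

* `<reaction>` elements are ignored; topology comes from relations only.
  Metabolic maps whose connectivity lives in reactions will parse sparse.
* Global/overview maps (the `011xx` style) are out of scope.
* The modularity comparison ships only the greedy detector; other
  algorithms must be injected by the caller.
* One-to-many identifier conversions keep the first target; alternatives
  are logged, not emitted.
* Edge lists cannot represent isolated nodes; use the graphics file to
  recover them.
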