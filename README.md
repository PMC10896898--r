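# kgmlnet

Topology-preserving KEGG pathway networks from KGML, in R.

## The problem

KEGG distributes every pathway map as a KGML (KEGG Markup Language) XML
file.  A KGML `<entry>` is a *box on the canvas*, not a biological entity:
the same gene or compound accession can appear as several entries in
different, often disconnected, neighborhoods of one map (a signaling lipid
drawn once in the "active" and once in the "inactive" arm, a kinase drawn
in two cascades).  Parsers that key nodes by bare accession merge those
entries into a single node, welding together neighborhoods that KEGG drew
apart — and after *compound propagation* (replacing gene → compound → gene
chains with direct gene–gene edges so that gene-only networks stay
connected) the spurious merges turn into gene–gene edges with no support in
the original map.

`kgmlnet` keeps duplicated accessions apart by attaching the numeric KGML
entry id to every accession as a **terminal modifier** (`cpd:C00165-92`),
running group expansion and compound propagation on the modifier-resolved
graph, and only then applying the requested identifier policy.  Four output
variants are produced, as tab-separated edge lists:

| mode  | `unique = TRUE`            | `unique = FALSE`                         |
|-------|----------------------------|------------------------------------------|
| gene  | all nodes keep modifiers   | all modifiers stripped (after propagation) |
| mixed | all nodes keep modifiers   | compounds keep modifiers, genes do not   |

Compound propagation connects each ordered pair of kept nodes joined by a
directed path whose interior nodes are all non-kept, annotating the new
edge `CPp / Custom / compound propagation`; KGML groups (complexes) are
expanded into their members with pairwise `clique` edges.

For evaluation the package implements the **per-pathway difference**
`ppd = |A \ B| / n` (edges of a query graph absent from a reference graph,
per pathway) and **partition modularity**

    Q = sum_c [ L_c / m  -  gamma * (k_c / (2m))^2 ]

with `m` total edges, `L_c` intra-community edges, `k_c` summed degree of
community `c`, resolution `gamma` (default 1), plus a greedy-modularity
detector and an injectable-detector comparison of unique vs plain parses.

## Worked example

The bundled generator builds the minimal failure case: one compound
accession (`cpd:C00165`, diacylglycerol) occurring in two disconnected
neighborhoods, bridging different gene pairs.

```r
library(kgmlnet)

p <- parse_kgml(make_shared_compound_scenario())
p
#> KGML pathway path:hsa99901 (shared compound scenario): 6 entries, 4 relations

build_network(p, mode = "gene", unique = TRUE)
#> network table: hsa99901, mode=gene, unique=TRUE, 2 edge row(s)
#>        entry1      entry2 type  value                 name          provenance
#> 1 hsa:1111-10 hsa:2222-11  CPp Custom compound propagation compound_propagated
#> 2 hsa:3333-20 hsa:4444-21  CPp Custom compound propagation compound_propagated
```

Both compounds were propagated away, each inside its own neighborhood: two
connected components, exactly as drawn.  A parser that merges by accession
fuses them instead:

```r
naive_gene_network(p)
#> network table: hsa99901, mode=gene, unique=FALSE, 4 edge row(s)
#>     entry1   entry2 type  value                 name          provenance
#> 1 hsa:1111 hsa:2222  CPp Custom compound propagation compound_propagated
#> 2 hsa:1111 hsa:4444  CPp Custom compound propagation compound_propagated
#> 3 hsa:3333 hsa:2222  CPp Custom compound propagation compound_propagated
#> 4 hsa:3333 hsa:4444  CPp Custom compound propagation compound_propagated

network_components(build_network(p, "gene", unique = TRUE))  # 2
network_components(naive_gene_network(p))                    # 1
```

Two of the four naive edges join genes that never interact in the map.
The mixed variant keeps compounds (with their modifiers) and the original
relation metadata, and the layout export recovers KEGG's canvas positions
(y grows downward; negate it for standard plotting):

```r
build_network(p, mode = "mixed", unique = FALSE)
#>          entry1        entry2  type value       name provenance
#> 1 cpd:C00165-12      hsa:2222 PCrel   --> activation   original
#> 2 cpd:C00165-22      hsa:4444 PCrel   --> activation   original
#> 3      hsa:1111 cpd:C00165-12 PCrel   --> activation   original
#> 4      hsa:3333 cpd:C00165-22 PCrel   --> activation   original

head(extract_coordinates(p, "mixed", unique = TRUE), 3)
#>            node   x   y
#> 1 cpd:C00165-12 160  80
#> 2 cpd:C00165-22 160 320
#> 3   hsa:1111-10  80  80
```

From a shell, the same workflow is available through the installed
launcher (`exec/kgmlnet` under the package library):

```sh
kgmlnet get-kgml hsa --out kgml/
kgmlnet genes kgml/ --unique --graphics
kgmlnet convert kgml/hsa04014_genes_unique.tsv --unique   # Entrez ids
```

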