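# vennkit

Comparing named lists — genes, proteins, gene families, or any other strings
— is one of the most common steps in omics analysis, and the Venn diagram is
its standard picture. `vennkit` is a scriptable R implementation of that
workflow for **one to six sets**: it computes every disjoint diagram region,
supports **shape-preserving set unions** driven by a binary union tree, a
union-list program, or union codes, and exports region element lists, count
tables and SVG diagrams. It is aimed at analysts who want the interactive
web-tool workflow as reproducible, pipeable code.

## The model

For an *n*-set family with labels *A, B, C, …* the universe
*U = S₁ ∪ … ∪ Sₙ* is partitioned into the 2ⁿ − 1 **disjoint regions** of the
Venn diagram. An element *x* belongs to the region with signature

> sig(x) = { L : x ∈ S_L },

the set of labels of exactly the sets containing it; a region's code is its
labels concatenated alphabetically (`"AC"`). A **union grouping** is a
partition *G* of the labels; it induces the quotient map

> S ↦ { g ∈ G : g ∩ S ≠ ∅ }

on signatures, and the quotient region table (2^m − 1 regions for *m*
groups) aggregates the original regions fibre-wise. Because the quotient is
computed on the region table, the drawn curves never move: uniting sets only
recolours curves and repositions counts. Groupings come from three sources:

* a **union code** (`"BC"`, `"AB,CD"`) naming groups directly;
* a **union list** (`";CD;CB;AB,CD"`) — a `;`-separated sequence of
  diagrams, each a `,`-separated collection of disjoint groups;
* a **union tree** — a strictly binary, topology-only Newick expression
  such as `(A,(B,(C,D)))` whose depth-*k* frontier (nodes at depth *k* plus
  shallower leaves) defines the grouping at level *k*, from all-singletons
  at the deepest leaf level to the single all-sets union at level 0.

All region tables are tibbles, so results compose with dplyr; fitted objects
have `tidy()`/`glance()` methods and `autoplot()` views.

## Worked example

Five feature-selection methods each propose a top-50 candidate list (here a
synthetic fixture whose 38-element all-methods core is known by
construction):

```r
library(vennkit)

lists <- generate_ranked_lists(5, n_top = 50, shared_core = 38, seed = 1,
  method_names = c("BetaBinomial", "NSC", "SVM-RFE", "tTest", "MWW"))
fam <- venn_family(lists)
glance(fam)
#> # A tibble: 1 × 3
#>   n_sets n_union n_total
#>    <int>   <int>   <int>
#> 1      5      78     250
```

78 distinct candidates across 250 list slots. The disjoint regions:

```r
rt <- venn_regions(fam)
region_counts(rt) |> dplyr::filter(count > 0)
#> # A tibble: 11 × 2
#>    code  count
#>    <chr> <int>
#>  1 A         4
#>  2 B         4
#>  ...
#> 11 ABCDE    38
```

All five methods agree on 38 candidates (`ABCDE`), and each has a
4-element exclusive tail. Uniting the two multivariate methods B (NSC) and
C (SVM-RFE) with the union code `"BC"` asks: how many candidates did *only*
they retrieve?

```r
q <- quotient_regions(rt, parse_union_code("BC", fam))
q$count[q$code == "BC"]
#> [1] 12
```

12 candidates are exclusive to B∪C: their 4 + 4 exclusive tails plus the 4
they share only with each other. Render it:

```r
write_svg(q, "union_BC.svg")          # canonical vector output
autoplot(q)                           # the same diagram as a ggplot
region_elements(q, "BC")              # the 12 element strings
```

The same analysis is available from a shell via the thin CLI wrapper:

```sh
VK=$(Rscript -e 'cat(system.file("cli", "vennkit.R", package = "vennkit"))')
Rscript "$VK" fixtures --type ranked --methods 5 --top 50 --core 38 \
        --seed 1 --out lists.sets
Rscript "$VK" union --sets lists.sets --code BC --out union_bc/
Rscript "$VK" tree --sets lists.sets --newick "(A,((B,C),(D,E)))" \
        --all-levels --out by_tree/
```

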