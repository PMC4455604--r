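---
title: "Venn diagram regions, shape-preserving unions, and how vennkit computes them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Venn diagram regions, shape-preserving unions, and how vennkit computes them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vennkit)
```

## The problem

Set comparison is ubiquitous in the life sciences: candidate-biomarker
lists from several feature-selection methods, gene-family clusters from
several genomes, hits from several screens. A Venn diagram displays every
one of the 2^n − 1 disjoint regions of an n-set comparison, whether or not
a region is empty — in contrast to Euler/area-proportional diagrams, which
draw only realized overlaps and cannot be made symmetric beyond four sets.
`vennkit` implements the computational side of this workflow: region
computation, set unions that preserve the diagram's shape, and exports.

## Regions and signatures

A family holds 1–6 named sets, labelled `A`.. in input order (the label
scheme that union codes such as `"ABCDE"` refer to). Element lists are
normalized on entry: one element per line, whitespace-trimmed, empty lines
dropped, within-set duplicates dropped keeping the first occurrence.
Comparison is case-sensitive and exact — no identifier mapping, no Unicode
normalization — because an element is defined only as a line of text, and
an exact contract is the least surprising one. Duplicates *across* sets
are, of course, the whole point and are kept. Empty sets are legal: a set
with no elements still occupies a label and a curve, so a diagram can be
built incrementally.

Every element of the union is assigned the signature of exactly the sets
containing it, and the region table lists all 2^n − 1 signatures, empty
regions included:

```{r}
fam <- venn_family(list(NSC = c("x", "y"), `SVM-RFE` = c("y", "z")))
venn_regions(fam)
```

The invariants this construction guarantees — regions pairwise disjoint,
union preserved, count conservation, key completeness — are asserted
against brute-force per-element membership evaluation over a thousand
seeded random families in the test suite.

## Union groupings and the quotient table

A *union grouping* is a partition of the labels; uniting sets means
quotienting the region table, not recomputing from merged inputs. Each
original signature S maps to the set of groups it touches, and a quotient
region aggregates the original regions in its fibre. The two computations
agree — quotienting equals recomputation on literally-united sets — and
that equivalence is a test, not an assumption. It is also why unions are
cheap enough to navigate interactively: the region table is computed once.

Three front-ends produce groupings:

* `parse_union_code("BC", fam)` — unite B and C; unmentioned labels stay
  singletons. `"AB,CD"` gives two coexisting groups.
* `parse_union_list(";CD;CB;AB,CD", fam)` — a `;`-separated sequence of
  diagram states (an empty step is the all-singletons identity). Groups
  within one step must be disjoint: overlapping groups are an **error**,
  not merged. A variant notation seen in the wild writes hierarchical
  sequences with a comma before the final cumulative code
  (`;CD;CDB,CDBA`); under this grammar that step would be contradictory
  (B appears in both `CDB` and `CDBA`), so it is rejected with a step
  index rather than silently reinterpreted — write `;CD;CDB;CDBA`.
* `parse_union_tree("(A,(B,(C,D)))", fam)` + `grouping_at_level(tree, k)`
  — tree-guided navigation, described next.

Group codes are canonical (member labels sorted: `"CD"`, never `"DC"`).
Quotient signatures print their group codes alphabetically, joined with
`_` whenever a multi-label group is involved (`"B_CD"`); all-singleton
signatures concatenate (`"AB"`), which keeps the identity quotient
byte-identical to the ungrouped table in every output format. Filenames
use the same codes (`B_CD.txt`), which stays unambiguous where plain
concatenation (`BCD`) would not.

## Union trees

The tree dialect is a strict Newick subset: labels or exact set names at
the leaves, strictly binary bifurcations, optional trailing semicolon and
whitespace — nothing else. Branch lengths, comments, quoted labels and
non-binary nodes are *rejected* with a position rather than tolerated,
because a silently ignored `:0.5` usually signals a user pasting the wrong
tree. (General-purpose parsers such as `ape::read.tree` rightly accept
those; the test suite uses ape as an independent cross-check on valid
topologies.) Set names take precedence over labels when a single-letter
name collides, so phylogeny-style trees written with species names work
unchanged.

Level semantics: the grouping at level k has one group per *frontier*
node — every node at depth k plus every leaf shallower than k. At
`max_level` (the deepest leaf) all groups are singletons; at level 0 all
sets are united. For unbalanced trees the frontier rule is the only
definition that makes every level a partition; it reproduces the expected
navigation for both the caterpillar tree `(A,(B,(C,D)))` (levels 3..0:
A|B|C|D, A|B|C∪D, A|B∪C∪D, all united) and six-leaf phylogenies where one
outgroup joins last:

```{r}
fam4 <- venn_family(list(s1 = "1", s2 = "2", s3 = "3", s4 = "4"))
tree <- parse_union_tree("(A,(B,(C,D)))", fam4)
tree_groupings(tree)
```

Successive levels refine each other (every level-k group lies inside a
level-(k−1) group), a property asserted over random topologies.

## Geometry

Diagram shape depends only on the number of sets, which is what makes
shape-preserving unions possible. The shipped geometry is **static data**
— plain-text vertex and anchor tables under `inst/extdata/geometry/`,
generated once by `data-raw/build_geometry.R` and validated rather than
computed at runtime, so output is reproducible to the byte:

* n ≤ 3: circles; n = 4, 5: the classic 4- and 5-ellipse arrangements;
* n = 6: an Edwards-style construction — two half-plane rectangles, a
  circle, and three cogwheel (star) polygons whose on/off teeth over 32
  angular sectors realize all 63 regions. The contract is the anchor
  invariant below, not any particular published curve aesthetic, whose
  exact equations are not standardized.

Each curve is a closed polygon with ≥ 64 vertices on a 700×700 canvas
(SVG user units, origin top-left, y down). Every region has one **anchor**
— the point where its count is drawn — chosen by the build script as the
deepest interior point of the region (maximum distance to any curve
boundary on a 2-unit grid, locally refined to 0.25 units, minimum
clearance 2.5 units; the shipped layouts achieve ≥ 11 units). The anchor
invariant — each anchor lies strictly inside exactly the curves of its
signature — is re-verified from the shipped files by the tests, using
even-odd ray casting; `mgcv::in.out` serves as an independent containment
oracle on random points.

For a quotient region the count is placed at the anchor of its *canonical
representative*: the original region whose signature contains all member
labels of every included group and none of the excluded ones. That region
always exists in the full layout, and the rule is deterministic — the
other constituent sub-regions are deliberately left unlabeled, since the
merged count refers to their union.

## Rendering

`render_svg()` emits SVG 1.1 built with xml2 (well-formedness by
construction): one filled polygon per set, set-name captions, and one
count text per region at its anchor. Curve path data is identical across
all groupings of one family; united sets share the fill colour of their
group's alphabetically first label. Defaults, all pinned for reproducible
bytes: 14 pt sans-serif, fill opacity 0.5, palette `#1f77b4` `#ff7f0e`
`#2ca02c` `#d62728` `#9467bd` `#8c564b`, 700×700 canvas. Opacity outside
[0, 1] and non-positive font sizes are rejected. `autoplot()` renders the
same geometry as a ggplot.

SVG is canonical. `rasterize_png()` is a small deterministic rasterizer
for the package's own SVG dialect (even-odd polygon fill, alpha
compositing over white, `png::writePNG`); it does not rasterize text
elements, which is a documented limitation of the PNG convenience path,
not of the diagram model.

## File formats and the CLI

The save format is an original FASTA-like block format: a version line
(`#vennkit-sets 1`), then per set a `>name` line followed by element
lines. It exists because saved-set files from interactive web tools have
no documented syntax; importing such files is explicitly unsupported. A
line-initial `>` or `\` in an element is escaped with a backslash so the
write→read→write round trip is byte-identical for arbitrary single-line
element strings; `>` anywhere else is stored verbatim. Reads tolerate
CRLF; errors carry line numbers.

Exports: per-region element files (one element per line, sorted
lexicographically, empty regions skipped, plus a manifest) and a counts
TSV with a trailing `TOTAL` row. All writes are atomic — staged next to
the destination and renamed — so a failure never leaves partial files.
The CLI (`venn_cli()`, wrapped by `inst/cli/vennkit.R`) parses all inputs
before writing anything, prints exactly one diagnostic line to stderr on
failure, and reserves a distinct exit code (2) for usage errors.
Union-list and tree runs serialize the navigation as `step0/`, `step1/`,
… and `level3/`, `level2/`, … directories.

## Synthetic fixtures

The real study datasets behind typical published comparisons (ranked
biomarker lists, gene-family clusters) are not reproducible from their
papers, so the package ships seeded generators instead:

* `generate_family(n, counts, seed)` builds a family whose region table
  matches the requested per-region counts *exactly*, returning the
  ground-truth table alongside — a by-construction oracle for the engine.
* `generate_ranked_lists(n_methods, n_top, shared_core, seed)` emulates
  the structure of a multi-method top-n comparison: an all-methods core of
  exactly `shared_core` elements, and (with ≥ 3 methods) a tail split
  one-third pairwise-shared with the cyclically next method, the rest
  method-exclusive — so all-shared, pairwise-shared and exclusive regions
  are all populated, the pattern such comparisons exhibit. With 2 methods
  tails are fully exclusive, keeping the all-methods region exactly at
  `shared_core`.

Element strings are deterministic alphanumeric tokens (`EL00042`), not
real gene symbols, to avoid implying biological content. What passing
tests on these fixtures shows is that the *engine* is correct on families
with known structure; they say nothing about identifier hygiene in real
lists (synonyms, case variants, versioned accessions), which the package
deliberately does not attempt to resolve.

## Numerical and scale choices

Everything is exact integer/string computation except geometry, where the
only numerics are ray casting and point-segment distances on polygons with
double coordinates rounded to 3 decimals in the shipped tables — anchor
clearances of ≥ 11 units make the strict/non-strict boundary distinction
immaterial. Property sweeps use fixed seeds and modest sizes (families of
≤ 200 elements, 1000 families for the oracle sweep, 50 random groupings
for quotient equivalence), sizes at which the combinatorics are already
fully exercised — every n in 1..6, every signature, empty regions and
empty sets included.

## Known limitations

* Six sets is a hard ceiling, matching the layout family shipped (and the
  practical readability ceiling of Venn diagrams).
* No Euler/area-proportional layouts; region area carries no meaning.
* PNG export does not draw text; use the SVG.
* No identifier mapping or fuzzy matching; elements are opaque strings.
* The union-list grammar rejects overlapping groups within a step by
  design; hierarchical sequences must be written with `;` between steps.
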