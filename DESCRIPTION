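Package: vennkit
Title: Venn Diagram Region Analysis with Shape-Preserving Set Unions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes all disjoint regions of Venn diagrams for one to six
    named sets and supports shape-preserving set unions guided by a binary
    union tree (a topology-only Newick dialect), a union-list program, or
    union codes. Region element lists, count tables and SVG diagrams can be
    exported; a seeded fixture generator synthesises set families and ranked
    top-n lists for reproducible testing of gene- and protein-list
    comparisons. Region tables are tibbles, so results compose with dplyr
    and friends; fitted objects have tidy() and glance() methods and
    ggplot2 autoplot() views.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    png,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    ape,
    jsonlite,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
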