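fam4 <- venn_family(list(w = "1", x = "2", y = "3", z = "4"))
fam6 <- venn_family(setNames(as.list(as.character(1:6)), paste0("sp", 1:6)))

test_that("the caterpillar tree parses with the expected leaf depths", {
  tree <- parse_union_tree("(A,(B,(C,D)))", fam4)
  d <- tree_leaf_depths(tree$root)
  expect_identical(d[c("A", "B", "C", "D")], c(A = 1L, B = 2L, C = 3L, D = 3L))
  expect_identical(max_level(tree), 3L)
})

test_that("balanced trees and trailing semicolons are accepted", {
  tree <- parse_union_tree("((A,B),(C,D));", fam4)
  expect_true(all(tree_leaf_depths(tree$root) == 2L))
  expect_identical(max_level(tree), 2L)
})

test_that("a six-leaf unbalanced tree has the max leaf depth as max level", {
  tree <- parse_union_tree("(A,((B,(C,D)),(E,F)))", fam6)
  d <- tree_leaf_depths(tree$root)
  expect_identical(unname(d[c("A", "B", "C", "D", "E", "F")]),
                   c(1L, 3L, 4L, 4L, 3L, 3L))
  expect_identical(max_level(tree), 4L)
})

test_that("leaves may be set names, with names taking precedence", {
  fam <- venn_family(list(NSC = "1", `SVM-RFE` = "2", ttest = "3"))
  tree <- parse_union_tree("(NSC,(SVM-RFE,ttest))", fam)
  expect_identical(sort(tree_leaf_labels(tree$root)), c("A", "B", "C"))
  # a single-letter *name* colliding with another set's label wins
  fam2 <- venn_family(list(B = "1", other = "2"))  # set named "B" gets label A
  tree2 <- parse_union_tree("(B,other)", fam2)
  expect_identical(tree_leaf_labels(tree2$root), c("A", "B"))
})

test_that("the strict Newick dialect rejects malformed input with positions", {
  expect_error(parse_union_tree("(A,(B,C))", fam4), "D",
               class = "vennkit_parse_error")               # missing leaf
  expect_error(parse_union_tree("(A,B,(C,D))", fam4), "non-binary",
               class = "vennkit_parse_error")
  expect_error(parse_union_tree("(A,(B,(C,D))", fam4), "parenthes",
               class = "vennkit_parse_error")
  expect_error(parse_union_tree("(A:1,(B,(C,D)))", fam4), "branch length",
               class = "vennkit_parse_error")
  expect_error(parse_union_tree("(A,(B,(C,D)))[c]", fam4),
               class = "vennkit_parse_error")
  expect_error(parse_union_tree("('A',(B,(C,D)))", fam4), "quoted",
               class = "vennkit_parse_error")
  expect_error(parse_union_tree("(A,(B,(C,E)))", fam4), "E",
               class = "vennkit_parse_error")               # unknown leaf
  expect_error(parse_union_tree("(A,(A,(C,D)))", fam4),
               class = "vennkit_parse_error")               # duplicate leaf
  err <- tryCatch(parse_union_tree("(A,(B,(C,D:0.5)))", fam4),
                  condition = identity)
  expect_s3_class(err, "vennkit_parse_error")
  expect_true(!is.null(err$position))
})

test_that("leaf depths agree with ape on random binary topologies", {
  skip_if_not_installed("ape")
  for (seed in 1:10) {
    n <- (seed %% 5) + 2L
    fam <- venn_family(setNames(as.list(as.character(1:n)), paste0("s", 1:n)))
    nwk <- random_newick(fam$label, seed)
    tree <- parse_union_tree(nwk, fam)
    ours <- tree_leaf_depths(tree$root)

    phy <- ape::read.tree(text = paste0(nwk, ";"))
    depths <- ape::node.depth.edgelength(ape::compute.brlen(phy, 1))
    theirs <- setNames(round(depths[seq_along(phy$tip.label)]), phy$tip.label)
    expect_identical(ours[sort(names(ours))],
                     as.integer(theirs)[order(names(theirs))] |>
                       setNames(sort(names(theirs))))
  }
})

test_that("tree levels reproduce the worked four-set navigation", {
  tree <- parse_union_tree("(A,(B,(C,D)))", fam4)
  expect_identical(grouping_as_sets(grouping_at_level(tree, 3)),
                   c("A", "B", "C", "D"))
  expect_identical(grouping_as_sets(grouping_at_level(tree, 2)),
                   c("A", "B", "C D"))
  expect_identical(grouping_as_sets(grouping_at_level(tree, 1)),
                   c("A", "B C D"))
  expect_identical(grouping_as_sets(grouping_at_level(tree, 0)),
                   "A B C D")
  expect_error(grouping_at_level(tree, 4), class = "vennkit_range_error")
  expect_error(grouping_at_level(tree, -1), class = "vennkit_range_error")
})

test_that("six-genome-style navigation groups clades level by level", {
  # ((((C,E),B),(A,D)),F): e.g. five monocots vs one eudicot outgroup
  tree <- parse_union_tree("((((C,E),B),(A,D)),F)", fam6)
  expect_identical(max_level(tree), 4L)
  expect_identical(grouping_as_sets(grouping_at_level(tree, 4)),
                   c("A", "B", "C", "D", "E", "F"))
  expect_identical(grouping_as_sets(grouping_at_level(tree, 3)),
                   c("A", "B", "C E", "D", "F"))
  expect_identical(grouping_as_sets(grouping_at_level(tree, 2)),
                   c("A D", "B C E", "F"))
  expect_identical(grouping_as_sets(grouping_at_level(tree, 1)),
                   c("A B C D E", "F"))
  expect_identical(grouping_as_sets(grouping_at_level(tree, 0)),
                   "A B C D E F")
})

test_that("each level refines the one above it, down to the root", {
  for (seed in 11:20) {
    n <- (seed %% 5) + 2L
    fam <- venn_family(setNames(as.list(as.character(1:n)), paste0("s", 1:n)))
    tree <- parse_union_tree(random_newick(fam$label, seed), fam)
    m <- max_level(tree)
    expect_true(grouping_is_identity(grouping_at_level(tree, m)))
    expect_identical(length(grouping_codes(grouping_at_level(tree, 0))), 1L)
    for (k in seq_len(m)) {
      fine <- grouping_groups(grouping_at_level(tree, k))
      coarse <- grouping_groups(grouping_at_level(tree, k - 1L))
      for (g in fine) {
        expect_true(any(vapply(coarse, function(cg) all(g %in% cg),
                               logical(1))))
      }
    }
  }
})

test_that("tree_groupings runs from the leaves level to the root", {
  tree <- parse_union_tree("(A,(B,(C,D)))", fam4)
  gs <- tree_groupings(tree)
  expect_identical(names(gs), c("level3", "level2", "level1", "level0"))
  expect_true(grouping_is_identity(gs[[1]]))
  expect_identical(grouping_as_sets(gs[[4]]), "A B C D")
})
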