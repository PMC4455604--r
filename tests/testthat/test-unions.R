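fam4 <- venn_family(list(w = "1", x = "2", y = "3", z = "4"))
fam5 <- venn_family(setNames(as.list(as.character(1:5)), paste0("m", 1:5)))

test_that("union codes unite the named sets, singletons elsewhere", {
  g <- parse_union_code("BC", fam5)
  expect_identical(grouping_as_sets(g), c("A", "B C", "D", "E"))
  g_all <- parse_union_code("ABCDE", fam5)
  expect_identical(grouping_as_sets(g_all), "A B C D E")
  # order-insensitive, case-insensitive input; canonical group codes
  expect_identical(parse_union_code("cb", fam5)$group,
                   parse_union_code("BC", fam5)$group)
  expect_identical(sort(unique(parse_union_code("DC", fam4)$group)),
                   c("A", "B", "CD"))
})

test_that("overlapping or unknown union groups are rejected", {
  expect_error(parse_union_code("AB,BC", fam4),
               "B", class = "vennkit_validation_error")
  expect_error(parse_union_code("AG", fam4),
               "G", class = "vennkit_validation_error")
  expect_error(parse_union_code("", fam4), class = "vennkit_validation_error")
})

test_that("the union-list mini-language yields one grouping per step", {
  prog <- parse_union_list(";CD;CB;AB,CD", fam4)
  expect_length(prog, 4L)
  expect_identical(grouping_as_sets(prog[[1]]), c("A", "B", "C", "D"))
  expect_identical(grouping_as_sets(prog[[2]]), c("A", "B", "C D"))
  expect_identical(grouping_as_sets(prog[[3]]), c("A", "B C", "D"))
  expect_identical(grouping_as_sets(prog[[4]]), c("A B", "C D"))
})

test_that("empty steps denote the identity grouping", {
  prog <- parse_union_list("", fam4)
  expect_length(prog, 1L)
  expect_true(grouping_is_identity(prog[[1]]))
  # trailing separator adds a trailing identity step
  prog2 <- parse_union_list(";CD;", fam4)
  expect_length(prog2, 3L)
  expect_true(grouping_is_identity(prog2[[3]]))
})

test_that("union-list errors identify the failing step", {
  expect_error(parse_union_list(";CD;AB,BC", fam4),
               "step 3", class = "vennkit_parse_error")
})

test_that("a hierarchical union list matches tree-level navigation", {
  prog <- parse_union_list(";CD;CDB;CDBA", fam4)
  tree <- parse_union_tree("(A,(B,(C,D)))", fam4)
  for (i in 1:4) {
    expect_identical(grouping_as_sets(prog[[i]]),
                     grouping_as_sets(grouping_at_level(tree, 4L - i)))
  }
})

test_that("quotient under the identity grouping is the original table", {
  for (seed in 41:45) {
    rt <- venn_regions(random_family(seed, max_elements = 60))
    q <- quotient_regions(rt, identity_grouping(regions_family(rt)))
    expect_identical(q$code, rt$code)
    expect_identical(q$elements, rt$elements)
    expect_identical(q$count, rt$count)
  }
})

test_that("quotient regions merge exactly as forced by the mapping rule", {
  fam <- venn_family(list(w = "x", x = "y", y = "z", z = "z"))
  q <- quotient_regions(venn_regions(fam), parse_union_code("CD", fam))
  counts <- setNames(q$count, q$code)
  expect_identical(counts[["A"]], 1L)
  expect_identical(counts[["B"]], 1L)
  expect_identical(counts[["CD"]], 1L)
  expect_identical(sum(q$count), 3L)
  expect_identical(sort(region_elements(q, "CD")), "z")
  expect_identical(nrow(q), 7L)  # 2^3 - 1 for 3 groups
})

# independent oracle: recompute a region table on the literally-united sets
literal_union_regions <- function(sets, grouping) {
  groups <- grouping_groups(grouping)
  labels <- LETTERS[seq_along(sets)]
  united <- lapply(groups, function(members) {
    unique(unlist(sets[match(members, labels)], use.names = FALSE))
  })
  venn_regions(venn_family(setNames(united, paste0("g_", names(groups)))))
}

test_that("quotient equals recomputation on literally-united sets", {
  sets <- random_sets(seed = 77, n = 5, max_elements = 150)
  rt <- venn_regions(venn_family(sets))
  grouping <- parse_union_code("BC", venn_family(sets))
  q <- quotient_regions(rt, grouping)
  direct <- literal_union_regions(sets, grouping)
  # group codes sort like the fresh family's labels here: A, BC, D, E
  expect_identical(q$count, direct$count)
  for (i in seq_len(nrow(q))) {
    expect_setequal(q$elements[[i]], direct$elements[[i]])
  }
})

test_that("quotient counts are conserved for random groupings", {
  for (seed in 46:55) {
    fam <- random_family(seed, max_elements = 100)
    rt <- venn_regions(fam)
    g <- random_grouping(fam$label, seed * 13)
    q <- quotient_regions(rt, g)
    expect_identical(sum(q$count), sum(rt$count))
    expect_identical(nrow(q), as.integer(2^length(grouping_codes(g)) - 1))
  }
})

test_that("quotients compose: grouping the groups equals one coarser quotient", {
  fam <- random_family(99, n = 5, max_elements = 120)
  rt <- venn_regions(fam)
  g1 <- parse_union_code("AB,CD", fam)           # groups AB, CD, E
  q1 <- quotient_regions(rt, g1)
  # unite group AB with group E on top of g1
  g2 <- new_venn_grouping(list(c("AB", "E")), grouping_codes(g1))
  q21 <- quotient_regions(q1, g2)
  coarse <- new_venn_grouping(list(c("A", "B", "E"), c("C", "D")),
                              fam$label)
  q_direct <- quotient_regions(rt, coarse)
  expect_identical(q21$code, q_direct$code)
  expect_identical(q21$count, q_direct$count)
  for (i in seq_len(nrow(q21))) {
    expect_setequal(q21$elements[[i]], q_direct$elements[[i]])
  }
})

test_that("grouping/table mismatches are rejected", {
  rt <- venn_regions(fam4)
  g5 <- parse_union_code("BC", fam5)
  expect_error(quotient_regions(rt, g5), class = "vennkit_validation_error")
  expect_error(quotient_regions(rt, "BC"), class = "vennkit_validation_error")
})
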