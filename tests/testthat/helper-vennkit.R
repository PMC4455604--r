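# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: membership is evaluated per element against
# each input set directly.

# brute-force membership signature of one element against the input sets
oracle_signature <- function(element, sets) {
  paste(LETTERS[seq_along(sets)][vapply(sets, function(s) element %in% s,
                                        logical(1))], collapse = "")
}

# brute-force signature table for a family's raw input sets
oracle_signatures <- function(sets) {
  universe <- unique(unlist(sets, use.names = FALSE))
  vapply(universe, oracle_signature, character(1), sets = sets)
}

# random family with controlled overlap: n sets drawn from a shared token
# pool so every overlap degree occurs
random_sets <- function(seed, n = NULL, max_elements = 200) {
  set.seed(seed)
  n <- n %||% sample(1:6, 1)
  pool_size <- max(2L, rpois(1, max_elements / 2) + 2L)
  pool <- sprintf("tok%04d", seq_len(pool_size))
  sets <- lapply(seq_len(n), function(i) {
    k <- sample(0:min(pool_size, max_elements), 1)
    sample(pool, k)
  })
  names(sets) <- paste0("set", seq_len(n))
  sets
}

random_family <- function(seed, n = NULL, max_elements = 200) {
  venn_family(random_sets(seed, n = n, max_elements = max_elements))
}

# random partition of a label vector into union groups
random_grouping <- function(labels, seed) {
  set.seed(seed)
  ids <- sample(seq_along(labels), length(labels), replace = TRUE)
  new_venn_grouping(unname(split(labels, ids)), labels)
}

# random strictly binary Newick string over the labels
random_newick <- function(labels, seed) {
  set.seed(seed)
  build <- function(labs) {
    if (length(labs) == 1) return(labs)
    k <- sample(seq_len(length(labs) - 1), 1)
    sprintf("(%s,%s)", build(labs[1:k]), build(labs[-(1:k)]))
  }
  build(sample(labels))
}

# groupings as canonical sets-of-sets for order-free comparison
grouping_as_sets <- function(grouping) {
  unname(sort(vapply(grouping_groups(grouping), paste, character(1),
                     collapse = " ")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
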