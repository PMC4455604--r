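# Union trees: a strictly binary, topology-only Newick dialect whose depth
# levels define progressively coarser union groupings — leaves (deepest
# level) down to the single all-sets union at level 0.

#' Parse a union tree in topology-only Newick notation
#'
#' Parses expressions such as `"(A,(B,(C,D)))"`, where parentheses group
#' subtrees and commas indicate bifurcation. Leaves may be set labels
#' (`A`..`F`) or exact set names; a name takes precedence over a label if it
#' is a single colliding letter. A trailing semicolon and whitespace are
#' tolerated. The dialect is deliberately strict: branch lengths (`:`),
#' comments (`[...]`), quoted labels and non-binary nodes are rejected with
#' the offending position, and the leaves must be exactly the family's sets,
#' each once.
#'
#' @param text The Newick-subset string.
#' @param family The `venn_family` whose sets the leaves name.
#' @return A `venn_union_tree` object.
#' @examples
#' fam <- venn_family(list(a = "1", b = "2", c = "3", d = "4"))
#' parse_union_tree("(A,(B,(C,D)))", fam)
#' @export
parse_union_tree <- function(text, family) {
  assert_family(family)
  if (length(text) != 1L || !is.character(text)) {
    stop_validation("`text` must be a single string")
  }
  chars <- strsplit(text, "")[[1]]
  pos <- 1L
  n_char <- length(chars)

  peek <- function() if (pos <= n_char) chars[[pos]] else ""
  skip_ws <- function() {
    while (pos <= n_char && grepl("[[:space:]]", chars[[pos]])) pos <<- pos + 1L
  }
  reject <- function(msg) stop_parse(msg, position = pos)

  parse_node <- function() {
    skip_ws()
    ch <- peek()
    if (ch == "") reject("unexpected end of tree expression")
    if (ch == ":") reject("branch lengths are not supported")
    if (ch == "[") reject("Newick comments are not supported")
    if (ch %in% c("'", "\"")) reject("quoted labels are not supported")
    if (ch == "(") {
      open_pos <- pos
      pos <<- pos + 1L
      left <- parse_node()
      skip_ws()
      if (peek() != ",") {
        if (peek() == ")") reject("internal node with a single child")
        reject("expected ',' in bifurcation")
      }
      pos <<- pos + 1L
      right <- parse_node()
      skip_ws()
      if (peek() == ",") reject("non-binary node: more than two children")
      if (peek() != ")") {
        pos <<- open_pos
        reject("unbalanced parentheses: '(' never closed")
      }
      pos <<- pos + 1L
      skip_ws()
      if (peek() == ":") reject("branch lengths are not supported")
      return(list(leaf = FALSE, children = list(left, right)))
    }
    # leaf token: any run of characters outside the structural set
    start <- pos
    while (pos <= n_char && !chars[[pos]] %in% c("(", ")", ",", ";", ":",
                                                 "[", "]", "'", "\"")) {
      pos <<- pos + 1L
    }
    if (peek() == ":") reject("branch lengths are not supported")
    if (peek() == "[") reject("Newick comments are not supported")
    token <- trimws(paste(chars[start:(pos - 1L)], collapse = ""))
    if (pos == start || !nzchar(token)) {
      pos <<- start
      reject("expected a leaf label")
    }
    list(leaf = TRUE, token = token, token_pos = start)
  }

  root <- parse_node()
  skip_ws()
  if (peek() == ";") {
    pos <- pos + 1L
    skip_ws()
  }
  if (pos <= n_char) {
    if (peek() == ")") reject("unbalanced parentheses: unmatched ')'")
    reject("unexpected trailing characters after tree")
  }

  labels <- family_labels(family)
  resolve <- function(node) {
    if (!node$leaf) {
      node$children <- lapply(node$children, resolve)
      return(node)
    }
    token <- node$token
    hit <- match(token, family$name)           # exact set name wins
    if (is.na(hit) && toupper(token) %in% labels) {
      hit <- match(toupper(token), labels)
    }
    if (is.na(hit)) {
      stop_parse(sprintf("unknown leaf '%s'", token), position = node$token_pos)
    }
    list(leaf = TRUE, label = labels[[hit]])
  }
  root <- resolve(root)

  leaves <- tree_leaf_labels(root)
  if (anyDuplicated(leaves)) {
    stop_parse(sprintf("leaf '%s' appears more than once",
                       leaves[duplicated(leaves)][[1]]))
  }
  missing <- setdiff(labels, leaves)
  if (length(missing)) {
    stop_parse(sprintf("leaf%s missing from tree: %s",
                       if (length(missing) > 1) "s" else "",
                       paste(missing, collapse = ", ")))
  }
  structure(
    list(root = root, labels = labels, text = text),
    class = "venn_union_tree"
  )
}

tree_leaf_labels <- function(node) {
  if (node$leaf) return(node$label)
  unlist(lapply(node$children, tree_leaf_labels), use.names = FALSE)
}

tree_leaf_depths <- function(node, depth = 0L) {
  if (node$leaf) {
    out <- depth
    names(out) <- node$label
    return(out)
  }
  c(tree_leaf_depths(node$children[[1]], depth + 1L),
    tree_leaf_depths(node$children[[2]], depth + 1L))
}

#' @export
print.venn_union_tree <- function(x, ...) {
  d <- tree_leaf_depths(x$root)
  cat(sprintf("# venn_union_tree over %s (max level %d)\n",
              paste(x$labels, collapse = ","), max_level(x)))
  cat(sprintf("  %s\n", x$text))
  invisible(x)
}

#' Number of levels of a union tree
#'
#' Level 0 is the root (all sets united); the maximum level is the deepest
#' leaf, where all sets are distinct.
#'
#' @param tree A `venn_union_tree`.
#' @return The maximum leaf depth (a non-negative integer).
#' @examples
#' fam <- venn_family(list(a = "1", b = "2", c = "3", d = "4"))
#' max_level(parse_union_tree("(A,(B,(C,D)))", fam))
#' @export
max_level <- function(tree) {
  if (!inherits(tree, "venn_union_tree")) {
    stop_validation("`tree` must be a `venn_union_tree`")
  }
  max(tree_leaf_depths(tree$root))
}

#' Union grouping induced by a tree level
#'
#' Cutting a union tree at depth `k` yields one union group per frontier
#' node: every node at depth `k`, plus every leaf shallower than `k`. At the
#' maximum level all groups are singletons (no sets united); at level 0
#' there is a single group uniting all sets. Navigating `k` downward unites
#' sets along the tree, e.g. for `(A,(B,(C,D)))`: level 2 gives A, B, C∪D;
#' level 1 gives A, B∪C∪D; level 0 gives A∪B∪C∪D.
#'
#' @param tree A `venn_union_tree`.
#' @param k Level, between 0 and [max_level()].
#' @return A `venn_grouping`.
#' @examples
#' fam <- venn_family(list(a = "1", b = "2", c = "3", d = "4"))
#' tr <- parse_union_tree("(A,(B,(C,D)))", fam)
#' grouping_at_level(tr, 2)
#' @export
grouping_at_level <- function(tree, k) {
  if (!inherits(tree, "venn_union_tree")) {
    stop_validation("`tree` must be a `venn_union_tree`")
  }
  if (length(k) != 1L || is.na(k) || k != as.integer(k)) {
    stop_range("`k` must be a single integer level")
  }
  k <- as.integer(k)
  if (k < 0L || k > max_level(tree)) {
    stop_range(sprintf("level %d out of range 0..%d", k, max_level(tree)))
  }
  frontier <- function(node, depth) {
    if (depth == k || node$leaf) return(list(tree_leaf_labels(node)))
    c(frontier(node$children[[1]], depth + 1L),
      frontier(node$children[[2]], depth + 1L))
  }
  new_venn_grouping(frontier(tree$root, 0L), tree$labels)
}

#' All groupings of a union tree, from leaves to root
#'
#' @param tree A `venn_union_tree`.
#' @return A named list of `venn_grouping` objects, ordered from the leaves
#'   level (`max_level`, all singletons) down to level 0 (all sets united) —
#'   the order in which the diagrams are navigated.
#' @examples
#' fam <- venn_family(list(a = "1", b = "2", c = "3", d = "4"))
#' tree_groupings(parse_union_tree("(A,(B,(C,D)))", fam))
#' @export
tree_groupings <- function(tree) {
  levels <- seq(max_level(tree), 0L)
  out <- lapply(levels, grouping_at_level, tree = tree)
  names(out) <- paste0("level", levels)
  out
}
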