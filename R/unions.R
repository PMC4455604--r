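# Union groupings, union codes, union-list programs, union trees and the
# quotient of a region table under a grouping.

#' @rdname parse_union_code
#' @export
new_venn_grouping <- function(groups, units) {
  groups <- lapply(groups, function(g) sort(unique(as.character(g))))
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat)) {
    stop_validation(sprintf(
      "union groups must be disjoint; repeated: %s",
      paste(unique(flat[duplicated(flat)]), collapse = ", ")
    ))
  }
  bad <- setdiff(flat, units)
  if (length(bad)) {
    stop_validation(sprintf(
      "unknown label%s in union group: %s (valid: %s)",
      if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "),
      paste(units, collapse = ", ")
    ))
  }
  # unmentioned units become singleton groups
  groups <- c(groups, as.list(setdiff(units, flat)))
  out <- tibble(
    label = unlist(groups, use.names = FALSE),
    group = rep(vapply(groups, group_code, character(1)),
                lengths(groups))
  )
  out <- out[match(units, out$label), ]
  class(out) <- c("venn_grouping", class(out))
  out
}

# canonical code of one union group: the sorted letters of the union of its
# members' labels ("C" + "D" -> "CD"; "B" + "CD" -> "BCD")
group_code <- function(members) {
  paste(sort(unique(unlist(strsplit(members, "")))), collapse = "")
}

is_venn_grouping <- function(x) inherits(x, "venn_grouping")

grouping_codes <- function(grouping) sort(unique(grouping$group))

grouping_is_identity <- function(grouping) {
  all(grouping$label == grouping$group)
}

# list of member-unit vectors, named by group code
grouping_groups <- function(grouping) {
  split(grouping$label, grouping$group)
}

#' @export
print.venn_grouping <- function(x, ...) {
  groups <- grouping_groups(x)
  cat(sprintf(
    "# venn_grouping: %s\n",
    paste(vapply(groups, paste, character(1), collapse = "+"),
          collapse = " | ")
  ))
  NextMethod()
}

#' Parse a union code into a grouping
#'
#' A union code names the sets to unite by concatenating their labels:
#' `"BC"` unites sets B and C; `"AB,CD"` unites A with B and, separately,
#' C with D. Labels not mentioned remain singleton groups, so every code
#' yields a full partition of the family's labels.
#'
#' `new_venn_grouping()` is the low-level constructor from a list of
#' member-label vectors (over set labels, or over group codes of an existing
#' grouping when composing unions).
#'
#' @param code A union code string, e.g. `"BC"` or `"AB,CD"`.
#' @param family The `venn_family` the code refers to.
#' @param groups For `new_venn_grouping()`: a list of character vectors of
#'   unit codes; units not mentioned become singletons.
#' @param units For `new_venn_grouping()`: the complete vector of unit codes
#'   being partitioned.
#' @return A `venn_grouping`: a tibble with one row per label and columns
#'   `label`, `group` (the canonical group code).
#' @examples
#' fam <- venn_family(list(a = "1", b = "2", c = "3", d = "4", e = "5"))
#' parse_union_code("BC", fam)
#' @export
parse_union_code <- function(code, family) {
  assert_family(family)
  if (length(code) != 1L || !is.character(code)) {
    stop_validation("`code` must be a single string")
  }
  parts <- strsplit(code, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop_validation("union code is empty")
  groups <- lapply(parts, function(p) {
    strsplit(toupper(gsub("[[:space:]]", "", p)), "")[[1]]
  })
  new_venn_grouping(groups, family_labels(family))
}

# the all-singletons grouping of a family
identity_grouping <- function(family) {
  new_venn_grouping(list(), family_labels(family))
}

#' Parse a union-list program
#'
#' A union list describes a sequence of diagrams: steps are separated by
#' `";"` and, within a step, coexisting disjoint union groups by `","`. An
#' empty step denotes the all-singletons identity grouping, so
#' `";CD;CB;AB,CD"` yields four diagrams: no sets united, then C∪D, then
#' B∪C, and finally A∪B together with C∪D. Groups that overlap within one
#' step are an error, not merged.
#'
#' @param text The union-list string.
#' @param family The `venn_family` the program refers to.
#' @return A `venn_union_program`: a list of `venn_grouping` steps in
#'   textual order.
#' @examples
#' fam <- venn_family(list(a = "1", b = "2", c = "3", d = "4"))
#' parse_union_list(";CD;CB;AB,CD", fam)
#' @export
parse_union_list <- function(text, family) {
  assert_family(family)
  if (length(text) != 1L || !is.character(text)) {
    stop_validation("`text` must be a single string")
  }
  n_sep <- lengths(regmatches(text, gregexpr(";", text, fixed = TRUE)))
  if (!nzchar(text)) n_sep <- 0L
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  # strsplit drops trailing empty fields; restore them so ";CD;" has 3 steps
  parts <- c(parts, rep("", n_sep + 1L - length(parts)))
  steps <- lapply(seq_along(parts), function(i) {
    p <- trimws(parts[[i]])
    if (!nzchar(p)) return(identity_grouping(family))
    tryCatch(parse_union_code(p, family), vennkit_error = function(e) {
      stop_parse(sprintf("union list step %d: %s", i, conditionMessage(e)))
    })
  })
  structure(steps, class = "venn_union_program")
}

#' @export
print.venn_union_program <- function(x, ...) {
  cat(sprintf("# venn_union_program with %d step(s)\n", length(x)))
  for (i in seq_along(x)) {
    groups <- grouping_groups(x[[i]])
    cat(sprintf("  step %d: %s\n", i,
                paste(names(groups), collapse = " | ")))
  }
  invisible(x)
}

#' Quotient a region table under a union grouping
#'
#' Merges the disjoint regions of a Venn diagram according to a partition of
#' its sets into union groups, preserving the underlying diagram. Each
#' original signature S maps to the quotient signature made of the groups it
#' touches; the quotient region's elements are the union of the original
#' regions mapping to it. The result has exactly \eqn{2^m - 1} rows for
#' \eqn{m} groups and is itself a `venn_regions` table.
#'
#' @param table A `venn_regions` table. A quotient table may be quotiented
#'   again by a grouping over its group codes (composition of unions).
#' @param grouping A `venn_grouping` partitioning the table's labels (or
#'   group codes).
#' @return A quotient `venn_regions` tibble.
#' @examples
#' fam <- venn_family(list(a = "x", b = "y", c = "z", d = "z"))
#' quotient_regions(venn_regions(fam), parse_union_code("CD", fam))
#' @export
quotient_regions <- function(table, grouping) {
  assert_regions(table)
  if (!is_venn_grouping(grouping)) {
    stop_validation("`grouping` must be a `venn_grouping`")
  }
  units <- regions_units(table)
  if (!setequal(grouping$label, units) ||
      length(grouping$label) != length(units)) {
    stop_validation(sprintf(
      "grouping is over [%s] but the table is keyed by [%s]",
      paste(grouping$label, collapse = ","), paste(units, collapse = ",")
    ))
  }
  groups <- grouping_groups(grouping)
  gcodes <- names(groups)
  # quotient signature of each original signature: the groups it intersects
  qsig_of <- vapply(table$members, function(members) {
    touched <- gcodes[vapply(groups, function(g) any(g %in% members),
                             logical(1))]
    signature_code(touched)
  }, character(1))
  qsigs <- all_signatures(gcodes)
  qcodes <- vapply(qsigs, signature_code, character(1))
  elements <- lapply(qcodes, function(qc) {
    unique(unlist(table$elements[qsig_of == qc], use.names = FALSE))
  })
  fam <- regions_family(table)
  new_venn_regions(qsigs, elements, family = fam, grouping = grouping)
}
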