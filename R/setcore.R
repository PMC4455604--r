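#' Normalize raw element text into a clean element vector
#'
#' One element per line: lines are split on newlines (LF or CRLF), stripped of
#' leading/trailing whitespace, empty lines dropped, and duplicates removed
#' keeping the first occurrence. Comparison is case-sensitive and exact; no
#' identifier mapping is attempted.
#'
#' @param text A character scalar of raw multi-line text, or a character
#'   vector of lines.
#' @return A character vector of unique, trimmed, non-empty elements in
#'   first-occurrence order (possibly empty).
#' @examples
#' venn_normalize(" KLK3 \nACPP\n\nKLK3\n")
#' @export
venn_normalize <- function(text) {
  if (length(text) == 0) return(character())
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\r\n|\r|\n"), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  unique(lines)
}

SET_LABELS <- LETTERS[1:6]

#' Build a named set family
#'
#' Assembles up to six named sets into a `venn_family`, a tibble with one row
#' per set and columns `label`, `name` and `elements` (a list column).
#' Labels `A`, `B`, ... are assigned in input order; each set's elements pass
#' through [venn_normalize()]. Empty sets are permitted: a set with no
#' elements still occupies a label and a curve in the diagram.
#'
#' @param sets A named list. Each component is either a character vector of
#'   elements or a single multi-line string (one element per line). Names are
#'   the set display names and must be non-empty and distinct.
#' @return A `venn_family` tibble with columns `label`, `name`, `elements`.
#' @examples
#' venn_family(list(NSC = "x\ny", `SVM-RFE` = c("y", "z")))
#' @export
venn_family <- function(sets) {
  if (!is.list(sets)) stop_validation("`sets` must be a named list")
  n <- length(sets)
  if (n < 1) stop_validation("a set family needs at least one set")
  if (n > 6) {
    stop_capacity(sprintf("a family may contain at most 6 sets, got %d", n))
  }
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(trimws(nms)))) {
    stop_validation("every set must have a non-empty name")
  }
  if (anyDuplicated(nms)) {
    stop_validation(sprintf(
      "set names must be distinct; duplicated: %s",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ))
  }
  elements <- lapply(sets, function(x) {
    if (!is.character(x)) stop_validation("set elements must be character")
    venn_normalize(x)
  })
  out <- tibble(
    label = SET_LABELS[seq_len(n)],
    name = as.character(nms),
    elements = unname(elements)
  )
  class(out) <- c("venn_family", class(out))
  out
}

is_venn_family <- function(x) inherits(x, "venn_family")

assert_family <- function(family) {
  if (!is_venn_family(family)) {
    stop_validation("expected a `venn_family` (see `venn_family()`)")
  }
  invisible(family)
}

family_labels <- function(family) family$label

#' @export
print.venn_family <- function(x, ...) {
  cat(sprintf("# A venn_family of %d set(s)\n", nrow(x)))
  NextMethod()
}

# Canonical region code: member labels, uppercased, deduplicated, sorted.
canonical_code <- function(code) {
  chars <- strsplit(toupper(code), "")[[1]]
  chars <- chars[chars != " "]
  paste(sort(unique(chars)), collapse = "")
}

# All 2^n - 1 non-empty membership signatures over `codes` (labels or group
# codes), ordered by signature size then alphabetically. Returns a list of
# member-code character vectors.
all_signatures <- function(codes) {
  n <- length(codes)
  sigs <- unlist(lapply(seq_len(n), function(k) {
    combn(codes, k, simplify = FALSE)
  }), recursive = FALSE)
  sigs
}

# Canonical string form of a signature (a set of member codes). Single-letter
# member codes concatenate ("AB"); signatures touching any multi-letter group
# code join with "_" ("B_CD") to stay unambiguous.
signature_code <- function(members) {
  members <- sort(members)
  sep <- if (any(nchar(members) > 1L)) "_" else ""
  paste(members, collapse = sep)
}

new_venn_regions <- function(members, elements, family, grouping = NULL) {
  out <- tibble(
    members = members,
    code = vapply(members, signature_code, character(1)),
    elements = elements,
    count = vapply(elements, length, integer(1))
  )
  class(out) <- c("venn_regions", class(out))
  attr(out, "family") <- family
  attr(out, "grouping") <- grouping
  out
}

#' Compute the disjoint-region partition of a set family
#'
#' Partitions the union of all sets into the \eqn{2^n - 1} disjoint Venn
#' regions of an \eqn{n}-set family. An element belongs to the region whose
#' signature is exactly the set of labels of the sets containing it. All
#' signatures are present as rows, including empty regions.
#'
#' @param family A `venn_family`.
#' @return A `venn_regions` tibble with columns `members` (list of member
#'   labels), `code` (canonical signature string, e.g. `"AC"`), `elements`
#'   (list of element vectors) and `count`.
#' @examples
#' fam <- venn_family(list(P = c("x", "y"), Q = c("y", "z")))
#' venn_regions(fam)
#' @export
venn_regions <- function(family) {
  assert_family(family)
  labels <- family_labels(family)
  universe <- unique(unlist(family$elements, use.names = FALSE))
  # membership matrix: elements x sets
  if (length(universe)) {
    member <- vapply(family$elements, function(e) universe %in% e,
                     logical(length(universe)))
    member <- matrix(member, nrow = length(universe))
    sig_of <- apply(member, 1L, function(row) {
      paste(labels[row], collapse = "")
    })
  } else {
    sig_of <- character()
  }
  sigs <- all_signatures(labels)
  codes <- vapply(sigs, paste, character(1), collapse = "")
  elements <- lapply(codes, function(code) universe[sig_of == code])
  new_venn_regions(sigs, elements, family = family)
}

is_venn_regions <- function(x) inherits(x, "venn_regions")

assert_regions <- function(table) {
  if (!is_venn_regions(table)) {
    stop_validation("expected a `venn_regions` table (see `venn_regions()`)")
  }
  invisible(table)
}

regions_family <- function(table) attr(table, "family")
regions_grouping <- function(table) attr(table, "grouping")

# group codes the table is keyed by: set labels for a plain table, grouping
# group codes for a quotient table
regions_units <- function(table) {
  g <- regions_grouping(table)
  if (is.null(g)) family_labels(regions_family(table)) else
    sort(unique(g$group))
}

#' @export
print.venn_regions <- function(x, ...) {
  g <- regions_grouping(x)
  what <- if (is.null(g)) "venn_regions" else "quotient venn_regions"
  cat(sprintf("# %s: %d region(s), %d element(s) in union\n",
              what, nrow(x), sum(x$count)))
  NextMethod()
}

#' Elements of one diagram region
#'
#' Returns the elements of the exclusive region denoted by `code` — the
#' elements in every set of the signature and in no other set (not the full
#' intersection). The code is canonicalized first: uppercased, deduplicated
#' and sorted, so `"ba"` and `"AB"` denote the same region.
#'
#' @param table A `venn_regions` table.
#' @param code Region code, e.g. `"AB"`. For quotient tables, group codes
#'   joined by `"_"` (or a character vector of group codes).
#' @return A character vector of elements (possibly empty).
#' @examples
#' fam <- venn_family(list(P = c("x", "y"), Q = c("y", "z")))
#' region_elements(venn_regions(fam), "ab")
#' @export
region_elements <- function(table, code) {
  assert_regions(table)
  units <- regions_units(table)
  if (is.null(regions_grouping(table))) {
    if (length(code) != 1L || !is.character(code) || !nzchar(trimws(code))) {
      stop_validation("`code` must be a single non-empty region code")
    }
    members <- strsplit(canonical_code(code), "")[[1]]
  } else {
    members <- if (length(code) > 1L) code else strsplit(code, "_")[[1]]
    members <- sort(unique(toupper(members)))
    if (!length(members)) stop_validation("`code` must be non-empty")
  }
  bad <- setdiff(members, units)
  if (length(bad)) {
    stop_validation(sprintf(
      "unknown label%s in region code: %s (valid: %s)",
      if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "),
      paste(units, collapse = ", ")
    ))
  }
  want <- signature_code(members)
  table$elements[[match(want, table$code)]]
}

#' Region counts and union total
#'
#' @param table A `venn_regions` table (plain or quotient).
#' @return A tibble with columns `code` and `count`, one row per region, with
#'   attribute `total` equal to the size of the union of all sets (which also
#'   equals `sum(count)`).
#' @examples
#' fam <- venn_family(list(P = "x", Q = "y"))
#' region_counts(venn_regions(fam))
#' @export
region_counts <- function(table) {
  assert_regions(table)
  out <- tibble(code = table$code, count = table$count)
  attr(out, "total") <- sum(out$count)
  out
}
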