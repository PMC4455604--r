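# broom-style verbs

#' Tidy a set family
#'
#' @param x A `venn_family`.
#' @param ... Unused.
#' @return A tibble with one row per set: `label`, `name`, `n_elements`.
#' @exportS3Method generics::tidy
tidy.venn_family <- function(x, ...) {
  tibble(label = x$label, name = x$name,
         n_elements = vapply(x$elements, length, integer(1)))
}

#' Summarise a set family
#'
#' @param x A `venn_family`.
#' @param ... Unused.
#' @return A one-row tibble: `n_sets`, `n_union` (distinct elements across
#'   all sets), `n_total` (sum of set sizes).
#' @exportS3Method generics::glance
glance.venn_family <- function(x, ...) {
  sizes <- vapply(x$elements, length, integer(1))
  tibble(
    n_sets = nrow(x),
    n_union = length(unique(unlist(x$elements, use.names = FALSE))),
    n_total = sum(sizes)
  )
}

#' Tidy a region table
#'
#' @param x A `venn_regions` table (plain or quotient).
#' @param ... Unused.
#' @return A tibble with one row per region: `code`, `degree` (number of
#'   sets/groups in the signature) and `count`.
#' @exportS3Method generics::tidy
tidy.venn_regions <- function(x, ...) {
  tibble(code = x$code,
         degree = vapply(x$members, length, integer(1)),
         count = x$count)
}

#' Summarise a region table
#'
#' @param x A `venn_regions` table.
#' @param ... Unused.
#' @return A one-row tibble: `n_groups` (sets, or union groups for a
#'   quotient), `n_regions`, `n_nonempty`, `n_union` (total elements, equal
#'   to the sum of region counts).
#' @exportS3Method generics::glance
glance.venn_regions <- function(x, ...) {
  tibble(
    n_groups = length(regions_units(x)),
    n_regions = nrow(x),
    n_nonempty = sum(x$count > 0L),
    n_union = sum(x$count)
  )
}
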