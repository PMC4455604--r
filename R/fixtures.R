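# Seeded synthetic fixtures. Element strings are deterministic alphanumeric
# tokens, not real gene symbols: the generators emulate the *structure* of
# multi-method biomarker-list and multi-genome comparisons (a shared core,
# method-exclusive tails, pairwise overlaps), with no biological content.

# run `expr` under a local, seeded RNG without disturbing the caller's state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

token_pool <- function(n) sprintf("EL%05d", seq_len(n))

#' Generate a set family with exact per-region counts
#'
#' Synthesizes a family of `n` sets whose disjoint-region partition matches
#' `counts` exactly: `counts["AB"]` elements fall in region AB, and so on.
#' Regions not mentioned are empty. Also returns the construction-time
#' ground-truth region table, so engine output can be cross-checked. Output
#' is deterministic for a given seed.
#'
#' @param n Number of sets, 1 to 6.
#' @param counts Named non-negative integer vector; names are region codes
#'   valid for `n` sets (canonicalized, so `"ba"` works).
#' @param seed Integer seed.
#' @param set_names Optional display names (default `"Set A"`..).
#' @return A list with components `family` (a `venn_family`) and `truth`
#'   (the ground-truth `venn_regions` table).
#' @examples
#' fx <- generate_family(2, c(A = 1, B = 1, AB = 1), seed = 7)
#' identical(venn_regions(fx$family)$count, fx$truth$count)
#' @export
generate_family <- function(n, counts, seed = 1L, set_names = NULL) {
  if (length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1 || n > 6) {
    stop_range("`n` must be an integer between 1 and 6")
  }
  n <- as.integer(n)
  labels <- SET_LABELS[1:n]
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop_validation("`counts` must be named by region codes")
    }
    if (any(is.na(counts)) || any(counts < 0) ||
        any(counts != as.integer(counts))) {
      stop_validation("`counts` must be non-negative integers")
    }
  }
  codes <- vapply(names(counts), canonical_code, character(1))
  bad <- codes[!vapply(strsplit(codes, ""), function(m) {
    length(m) > 0 && all(m %in% labels)
  }, logical(1))]
  if (length(bad)) {
    stop_validation(sprintf("invalid region code%s for %d sets: %s",
                            if (length(bad) > 1) "s" else "", n,
                            paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(codes)) {
    stop_validation("`counts` names canonicalize to duplicate region codes")
  }
  set_names <- set_names %||% paste("Set", labels)
  if (length(set_names) != n) {
    stop_validation("`set_names` must have one name per set")
  }

  sigs <- all_signatures(labels)
  sig_codes <- vapply(sigs, paste, character(1), collapse = "")
  target <- stats::setNames(integer(length(sig_codes)), sig_codes)
  target[codes] <- as.integer(counts)

  total <- sum(target)
  with_local_seed(seed, {
    pool <- sample(token_pool(max(total, 1L)))
    idx <- 0L
    region_elements <- lapply(sig_codes, function(code) {
      k <- target[[code]]
      if (k == 0L) return(character())
      out <- pool[(idx + 1L):(idx + k)]
      idx <<- idx + k
      out
    })
    sets <- lapply(labels, function(lab) {
      in_region <- vapply(sigs, function(m) lab %in% m, logical(1))
      unlist(region_elements[in_region], use.names = FALSE)
    })
    names(sets) <- set_names
    family <- venn_family(sets)
    truth <- new_venn_regions(sigs, region_elements, family = family)
    list(family = family, truth = truth)
  })
}

#' Generate ranked top-n lists with a controlled shared core
#'
#' Emulates the structure of comparing the top-n ranked candidate lists of
#' several feature-selection methods: every method's list contains the same
#' `shared_core` elements, plus (when room allows) elements shared with the
#' neighbouring method and method-exclusive elements. The region shared by
#' *all* methods therefore has exactly `shared_core` elements. Deterministic
#' for a given seed.
#'
#' @param n_methods Number of methods (sets), 2 to 6.
#' @param n_top List length per method.
#' @param shared_core Number of elements common to all methods
#'   (`<= n_top`).
#' @param seed Integer seed.
#' @param method_names Optional method names (default `"method1"`..).
#' @return A named list of `n_methods` character vectors, each of length
#'   `n_top`; pass to [venn_family()].
#' @examples
#' lists <- generate_ranked_lists(5, n_top = 50, shared_core = 38, seed = 1)
#' fam <- venn_family(lists)
#' region_elements(venn_regions(fam), "ABCDE")  # exactly the 38-element core
#' @export
generate_ranked_lists <- function(n_methods, n_top, shared_core, seed = 1L,
                                  method_names = NULL) {
  if (length(n_methods) != 1L || is.na(n_methods) ||
      n_methods != as.integer(n_methods) || n_methods < 2 || n_methods > 6) {
    stop_validation("`n_methods` must be an integer between 2 and 6")
  }
  if (!is.numeric(n_top) || n_top < 1 || n_top != as.integer(n_top)) {
    stop_validation("`n_top` must be a positive integer")
  }
  if (!is.numeric(shared_core) || shared_core < 0 || shared_core > n_top ||
      shared_core != as.integer(shared_core)) {
    stop_validation("`shared_core` must be an integer within 0..n_top")
  }
  n_methods <- as.integer(n_methods)
  n_top <- as.integer(n_top)
  shared_core <- as.integer(shared_core)
  method_names <- method_names %||% paste0("method", seq_len(n_methods))
  if (length(method_names) != n_methods || anyDuplicated(method_names)) {
    stop_validation("`method_names` must be distinct, one per method")
  }

  tail_len <- n_top - shared_core
  # with >= 3 methods a third of each tail is shared with the next method
  # (cyclically), so pairwise-shared regions are populated without ever
  # touching the all-methods core
  pair_len <- if (n_methods >= 3L) tail_len %/% 3L else 0L
  excl_len <- tail_len - 2L * pair_len

  n_tokens <- shared_core + n_methods * (pair_len + excl_len)
  with_local_seed(seed, {
    pool <- sample(token_pool(max(n_tokens, 1L)))
    take <- local({
      idx <- 0L
      function(k) {
        if (k == 0L) return(character())
        out <- pool[(idx + 1L):(idx + k)]
        idx <<- idx + k
        out
      }
    })
    core <- take(shared_core)
    pair <- lapply(seq_len(n_methods), function(i) take(pair_len))
    excl <- lapply(seq_len(n_methods), function(i) take(excl_len))
    lists <- lapply(seq_len(n_methods), function(i) {
      prev <- if (i == 1L) n_methods else i - 1L
      c(core, pair[[i]], pair[[prev]], excl[[i]])
    })
    names(lists) <- method_names
    lists
  })
}
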