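# File formats: the SetsFile save format, per-region element exports and the
# counts TSV. All writes are atomic — content is staged in a temporary file
# in the destination directory and renamed into place, so an error never
# leaves a partial file.

SETSFILE_VERSION <- "#vennkit-sets 1"

atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("directory does not exist: %s", dir))
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- tryCatch(file(tmp, open = "wb"), error = function(e) {
    stop_io(sprintf("cannot write %s: %s", path, conditionMessage(e)))
  })
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  if (!file.rename(tmp, path)) stop_io(sprintf("cannot write %s", path))
  invisible(path)
}

atomic_write_bin <- function(bytes, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("directory does not exist: %s", dir))
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeBin(bytes, tmp)
  if (!file.rename(tmp, path)) stop_io(sprintf("cannot write %s", path))
  invisible(path)
}

# Element lines are stored verbatim except that a line-initial '>' or '\'
# is escaped with a backslash, so '>' remains structural only at the start
# of a header line and round-trips are exact for any element string.
escape_body_line <- function(x) {
  ifelse(grepl("^[>\\\\]", x), paste0("\\", x), x)
}
unescape_body_line <- function(x) sub("^\\\\", "", x)

#' Save a set family as a SetsFile
#'
#' The SetsFile format is a FASTA-like plain-text format: a version line
#' (`#vennkit-sets 1`) followed by one block per set — a `>`-prefixed name
#' line and the set's elements, one per line. Output is UTF-8 with LF line
#' endings and is byte-deterministic for a given family; write→read→write
#' is byte-identical.
#'
#' @param family A `venn_family`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @seealso [read_sets_file()]
#' @export
write_sets_file <- function(family, path) {
  assert_family(family)
  lines <- SETSFILE_VERSION
  for (i in seq_len(nrow(family))) {
    lines <- c(lines, paste0(">", family$name[[i]]),
               escape_body_line(family$elements[[i]]))
  }
  atomic_write_lines(lines, path)
  invisible(path)
}

#' Load a set family from a SetsFile
#'
#' Reads the format written by [write_sets_file()]. LF and CRLF line endings
#' are tolerated; element lines pass through [venn_normalize()] per block.
#' Labels are reassigned `A`.. in block order.
#'
#' @param path Path to a SetsFile.
#' @return A `venn_family`.
#' @export
read_sets_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (!length(lines) || trimws(lines[[1]]) != SETSFILE_VERSION) {
    stop_format(sprintf("missing version line '%s'", SETSFILE_VERSION),
                line = 1L)
  }
  headers <- which(grepl("^>", lines))
  if (!length(headers)) stop_format("no set blocks found ('>' name lines)")
  if (headers[[1]] > 1L) {
    stray <- setdiff(seq_len(headers[[1]] - 1L), 1L)
    stray <- stray[nzchar(trimws(lines[stray]))]
    if (length(stray)) {
      stop_format("content before the first set block", line = stray[[1]])
    }
  }
  if (length(headers) > 6L) {
    stop_capacity(sprintf("a SetsFile may contain at most 6 sets, got %d",
                          length(headers)), line = headers[[7]])
  }
  nms <- sub("^>", "", lines[headers])
  dup <- duplicated(nms)
  if (any(dup)) {
    stop_format(sprintf("duplicate set name '%s'", nms[dup][[1]]),
                line = headers[dup][[1]])
  }
  if (any(!nzchar(trimws(nms)))) {
    stop_format("empty set name", line = headers[!nzchar(trimws(nms))][[1]])
  }
  ends <- c(headers[-1] - 1L, length(lines))
  sets <- lapply(seq_along(headers), function(i) {
    body <- if (headers[[i]] + 1L > ends[[i]]) character() else
      lines[(headers[[i]] + 1L):ends[[i]]]
    unescape_body_line(body)
  })
  names(sets) <- nms
  venn_family(sets)
}

#' Export per-region element lists
#'
#' Writes one plain-text file per non-empty region, named by its canonical
#' code (`AB.txt`; quotient codes joined by `_`, e.g. `B_CD.txt`), with one
#' element per line sorted lexicographically, plus a `manifest.tsv` listing
#' the files and their counts. Empty regions produce no file.
#'
#' @param table A `venn_regions` table (plain or quotient).
#' @param dir Destination directory (created if missing).
#' @return The manifest as a tibble with columns `file`, `code`, `count`,
#'   invisibly.
#' @export
export_region_elements <- function(table, dir) {
  assert_regions(table)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop_io(sprintf("cannot create directory %s", dir))
  }
  keep <- table$count > 0L
  manifest <- tibble(
    file = paste0(table$code[keep], ".txt"),
    code = table$code[keep],
    count = table$count[keep]
  )
  for (i in which(keep)) {
    atomic_write_lines(sort(table$elements[[i]]),
                       file.path(dir, paste0(table$code[[i]], ".txt")))
  }
  atomic_write_lines(
    c("file\tcode\tcount",
      sprintf("%s\t%s\t%d", manifest$file, manifest$code, manifest$count)),
    file.path(dir, "manifest.tsv")
  )
  invisible(manifest)
}

#' Export region counts as TSV
#'
#' Writes a two-column TSV (`region_code`, `count`), one row per region in
#' table order, followed by a `TOTAL` row equal to the union size.
#'
#' @param table A `venn_regions` table.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
export_counts <- function(table, path) {
  assert_regions(table)
  counts <- region_counts(table)
  atomic_write_lines(
    c("region_code\tcount",
      sprintf("%s\t%d", counts$code, counts$count),
      sprintf("TOTAL\t%d", attr(counts, "total"))),
    path
  )
  invisible(path)
}
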