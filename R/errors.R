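# Condition helpers. Every user-facing failure is a classed condition under
# "vennkit_error" so the CLI can map it to a single diagnostic line and a
# stable exit code.

stop_venn <- function(msg, class, ...) {
  abort(msg, class = c(class, "vennkit_error"), ...)
}

stop_validation <- function(msg, ...) stop_venn(msg, "vennkit_validation_error", ...)
stop_capacity   <- function(msg, ...) stop_venn(msg, "vennkit_capacity_error", ...)
stop_parse      <- function(msg, position = NULL, ...) {
  if (!is.null(position)) msg <- sprintf("%s (at position %d)", msg, position)
  stop_venn(msg, "vennkit_parse_error", position = position, ...)
}
stop_range  <- function(msg, ...) stop_venn(msg, "vennkit_range_error", ...)
stop_format <- function(msg, line = NULL, ...) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  stop_venn(msg, "vennkit_format_error", line = line, ...)
}
stop_io <- function(msg, ...) stop_venn(msg, "vennkit_io_error", ...)
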