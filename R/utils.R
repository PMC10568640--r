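# Internal helpers: classed conditions and channel-name normalization.

md_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "myodiff_error"),
                      call = call))
}

#' @noRd
# Channel identifiers are matched case-insensitively with '.' and '-'
# treated as the same separator ("GRN.B.HLin" == "GRN-B-HLin").
normalize_channel_name <- function(x) {
  tolower(gsub("[.\\-]", ".", x))
}

# Resolve a channel name to a column index of a sample's event matrix.
resolve_channel <- function(sample, name) {
  avail <- sample$channels$name
  hit <- which(normalize_channel_name(avail) == normalize_channel_name(name))
  if (length(hit) != 1L) {
    md_stop(sprintf("channel '%s' not found; available: %s", name,
                    paste(avail, collapse = ", ")),
            "myodiff_channel_error")
  }
  hit
}

has_channel <- function(sample, name) {
  any(normalize_channel_name(sample$channels$name) ==
        normalize_channel_name(name))
}

channel_values <- function(sample, name) {
  sample$events[, resolve_channel(sample, name)]
}
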