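# Internal interval helpers. All coordinates in this package are 0-based
# half-open [start, end); conversion to 1-based happens only at the GFF3
# boundary and when slicing R strings.

iv <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end)
  list(start = as.integer(start), end = as.integer(end))
}

iv_len <- function(x) x$end - x$start

iv_overlap <- function(a, b) {
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

iv_contains <- function(outer, inner) {
  inner$start >= outer$start && inner$end <= outer$end
}

# substring of a 0-based half-open interval
seq_slice <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# union length of a set of [start, end) intervals given as a 2-column matrix
union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(r))
}
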