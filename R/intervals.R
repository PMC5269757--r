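# Internal interval helpers. All package coordinates are 0-based half-open
# [start, end); IRanges is 1-based closed, so conversion happens only here.

.iv_to_iranges <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

.iranges_to_iv <- function(ir) {
  tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

# merged (disjoint, sorted) union of a start/end tibble
.iv_reduce <- function(iv) {
  if (nrow(iv) == 0) return(tibble(start = integer(), end = integer()))
  .iranges_to_iv(IRanges::reduce(.iv_to_iranges(iv)))
}

.iv_total <- function(iv) sum(iv$end - iv$start)

# intersection of two merged interval sets
.iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  .iranges_to_iv(IRanges::intersect(.iv_to_iranges(a), .iv_to_iranges(b)))
}

# per-base stabbing counts over [0, len) from a list of interval tibbles;
# returns an Rle of support counts
.iv_coverage <- function(iv_list, len) {
  irl <- lapply(iv_list, function(iv) {
    IRanges::reduce(.iv_to_iranges(iv))
  })
  ir <- do.call(c, unname(irl))
  IRanges::coverage(ir, width = len)
}
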