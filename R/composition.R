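#' Cut contigs into composition fragments
#'
#' Tetranucleotide signatures are computed on fragments of roughly uniform
#' size so that long contigs do not dominate: contigs shorter than `min_len`
#' are discarded, contigs within `[min_len, max_len]` are kept whole, and
#' longer contigs are cut into consecutive `max_len` windows whose terminal
#' remainder is kept only if it still reaches `min_len`.
#'
#' @param contigs A `sag_assembly`, a list of them, or a contig tibble with
#'   `contig_id` and `sequence` (optionally `sag_id`, `foreign`).
#' @param min_len,max_len Fragment size window in bp (defaults 2500 / 5000).
#' @return A tibble: `fragment_id`, `contig_id`, `sag_id`, `foreign`,
#'   `sequence`, `length`.
#' @export
fragment_contigs <- function(contigs, min_len = 2500, max_len = 5000) {
  if (min_len >= max_len) abort("min_len must be smaller than max_len")
  tbl <- .fragment_input_tbl(contigs)
  pieces <- purrr::pmap(tbl, function(contig_id, sag_id, foreign, sequence) {
    len <- nchar(sequence)
    if (len < min_len) return(NULL)
    if (len <= max_len) {
      starts <- 0L
      ends <- len
    } else {
      starts <- seq(0L, len - 1L, by = max_len)
      ends <- pmin(starts + max_len, len)
      keep <- (ends - starts) >= min_len
      starts <- starts[keep]
      ends <- ends[keep]
    }
    if (length(starts) == 0) return(NULL)
    tibble(
      fragment_id = sprintf("%s_f%02d", contig_id, seq_along(starts)),
      contig_id = contig_id, sag_id = sag_id, foreign = foreign,
      sequence = substring(sequence, starts + 1, ends),
      length = ends - starts
    )
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble(fragment_id = character(), contig_id = character(),
                  sag_id = character(), foreign = logical(),
                  sequence = character(), length = integer())
  }
  out
}

.fragment_input_tbl <- function(contigs) {
  if (inherits(contigs, "sag_assembly")) contigs <- list(contigs)
  if (is.list(contigs) && !is.data.frame(contigs) &&
      all(vapply(contigs, inherits, TRUE, "sag_assembly"))) {
    contigs <- bind_rows(lapply(contigs, function(a) {
      mutate(a$contigs, sag_id = a$sag_id)
    }))
  }
  tbl <- .contig_tbl(contigs)
  if (!"sag_id" %in% names(tbl)) tbl$sag_id <- NA_character_
  if (!"foreign" %in% names(tbl)) tbl$foreign <- FALSE
  select(tbl, "contig_id", "sag_id", "foreign", "sequence")
}

#' Tetranucleotide frequency vector of a sequence
#'
#' Counts every 4-mer window with a 1 bp slide on the sequence and on its
#' reverse complement, then normalizes by the total number of counted
#' windows. Windows containing non-ACGT symbols are skipped. Both-strand
#' counting makes the vector identical for a sequence and its reverse
#' complement.
#'
#' @param sequence A DNA string of length >= 4.
#' @return A named numeric vector of 256 frequencies summing to 1, in fixed
#'   lexicographic order AAAA..TTTT.
#' @export
tetra_freq <- function(sequence) {
  if (nchar(sequence) < 4) abort("sequence must be at least 4 bp")
  m <- .tetra_counts(sequence)
  tot <- sum(m)
  if (tot == 0) abort("sequence has no ACGT-only 4-mer window")
  m / tot
}

.tetra_counts <- function(sequences) {
  x <- Biostrings::DNAStringSet(toupper(sequences))
  fwd <- Biostrings::oligonucleotideFrequency(x, width = 4)
  rev <- Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(x), width = 4)
  counts <- fwd + rev
  if (length(sequences) == 1) counts[1, ] else counts
}

#' Tetranucleotide profile matrix of a fragment set
#'
#' @param fragments A fragment tibble from [fragment_contigs()].
#' @return A numeric matrix (fragments x 256) of class `tetra_matrix`, rows
#'   named by `fragment_id`, columns AAAA..TTTT; rows sum to 1. Attribute
#'   `normalized` is `FALSE`.
#' @export
tetra_profile <- function(fragments) {
  if (nrow(fragments) == 0) abort("no fragments to profile")
  counts <- .tetra_counts(fragments$sequence)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  freq <- counts / rowSums(counts)
  rownames(freq) <- fragments$fragment_id
  structure(freq, class = c("tetra_matrix", "matrix", "array"),
            normalized = FALSE, norm_center = NULL, norm_scale = NULL)
}

#' Robust per-column standardization of a tetranucleotide matrix
#'
#' Centers each of the 256 columns at its median and scales by
#' `1.4826 * MAD`, the standard consistent robust estimate of sigma.
#' Columns with zero robust scale map to all zeros. Center and scale are
#' stored as attributes so new fragments can be projected with the same
#' transform.
#'
#' @param mat A `tetra_matrix` (or plain matrix) with >= 2 rows.
#' @param center,scale Optional precomputed center/scale vectors to reuse.
#' @return The standardized matrix with attributes `normalized = TRUE`,
#'   `norm_center`, `norm_scale`.
#' @export
robust_zt_normalize <- function(mat, center = NULL, scale = NULL) {
  if (nrow(mat) < 2 && is.null(center)) {
    abort("need at least 2 rows to estimate robust center and scale")
  }
  if (is.null(center)) center <- apply(mat, 2, median)
  if (is.null(scale)) scale <- apply(mat, 2, mad)  # mad() already x 1.4826
  out <- sweep(mat, 2, center, "-")
  nz <- scale > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, scale[nz], "/")
  out[, !nz] <- 0
  structure(out, class = c("tetra_matrix", "matrix", "array"),
            normalized = TRUE, norm_center = center, norm_scale = scale)
}

#' GC content per contig and length-weighted aggregate
#'
#' @param contigs A `sag_assembly` or contig tibble.
#' @return A list with `per_contig` (tibble `contig_id`, `gc`, `length`;
#'   `gc` is `NA` for all-ambiguous contigs) and `aggregate`
#'   (length-weighted GC fraction over unambiguous bases).
#' @export
gc_content <- function(contigs) {
  tbl <- .contig_tbl(contigs)
  if (nrow(tbl) == 0) abort("no contigs")
  x <- Biostrings::DNAStringSet(toupper(tbl$sequence))
  acgt <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  gc <- rowSums(acgt[, c("C", "G"), drop = FALSE])
  tot <- rowSums(acgt)
  per <- tibble(
    contig_id = tbl$contig_id,
    gc = ifelse(tot > 0, gc / tot, NA_real_),
    length = nchar(tbl$sequence)
  )
  list(per_contig = per, aggregate = sum(gc) / sum(tot))
}
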