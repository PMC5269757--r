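#' Average nucleotide identity and shared fractions from a hit table
#'
#' ANI is the alignment-length-weighted mean percent identity over accepted
#' hits. Because each amplified cell recovers a different genome region, the
#' comparable fraction differs per assembly, so both per-assembly shared
#' fractions are reported: the percent of each assembly's length covered by
#' at least one accepted hit (overlaps merged).
#'
#' @param hits A hit tibble from [pairwise_local_hits()] (query = `a`,
#'   subject = `b`).
#' @param a_len,b_len Total assembly lengths of query and subject in bp.
#' @param sag_a,sag_b Identifiers recorded in the result.
#' @return A one-row tibble of class `ani_result`: `sag_a`, `sag_b`,
#'   `ani_mean`, `ani_sd` (alignment-length-weighted), `shared_fraction_a`,
#'   `shared_fraction_b` (percent), `n_hits`, `aligned_bp`. With zero hits
#'   `ani_mean`/`ani_sd` are `NA` and shared fractions 0.
#' @export
compute_ani <- function(hits, a_len, b_len, sag_a = "A", sag_b = "B") {
  if (a_len <= 0 || b_len <= 0) abort("assembly lengths must be positive")
  if (nrow(hits) == 0) {
    out <- tibble(sag_a = sag_a, sag_b = sag_b,
                  ani_mean = NA_real_, ani_sd = NA_real_,
                  shared_fraction_a = 0, shared_fraction_b = 0,
                  n_hits = 0L, aligned_bp = 0L)
    class(out) <- c("ani_result", class(out))
    return(out)
  }
  w <- hits$aligned_len
  mu <- sum(w * hits$identity) / sum(w)
  sdv <- if (nrow(hits) > 1) {
    sqrt(sum(w * (hits$identity - mu)^2) / sum(w))
  } else 0
  cov_a <- sum(sum(IRanges::width(IRanges::reduce(S4Vectors::split(
    IRanges::IRanges(hits$q_start + 1L, hits$q_end),
    hits$query_contig
  )))))
  cov_b <- sum(sum(IRanges::width(IRanges::reduce(S4Vectors::split(
    IRanges::IRanges(hits$s_start + 1L, hits$s_end),
    hits$subject_contig
  )))))
  out <- tibble(
    sag_a = sag_a, sag_b = sag_b,
    ani_mean = mu, ani_sd = sdv,
    shared_fraction_a = 100 * cov_a / a_len,
    shared_fraction_b = 100 * cov_b / b_len,
    n_hits = nrow(hits), aligned_bp = sum(w)
  )
  class(out) <- c("ani_result", class(out))
  out
}

#' Pairwise ANI between two assemblies
#'
#' Convenience wrapper: runs [pairwise_local_hits()] then [compute_ani()].
#'
#' @param a,b `sag_assembly` objects or contig tibbles.
#' @param ... Passed to [pairwise_local_hits()].
#' @return A one-row `ani_result` tibble.
#' @export
sag_ani <- function(a, b, ...) {
  ta <- .contig_tbl(a)
  tb <- .contig_tbl(b)
  hits <- pairwise_local_hits(a, b, ...)
  compute_ani(hits,
              a_len = sum(nchar(ta$sequence)),
              b_len = sum(nchar(tb$sequence)),
              sag_a = if (inherits(a, "sag_assembly")) a$sag_id else "A",
              sag_b = if (inherits(b, "sag_assembly")) b$sag_id else "B")
}

#' All-vs-all ANI over a set of assemblies
#'
#' @param sags A list of `sag_assembly` objects.
#' @param ... Passed to [pairwise_local_hits()].
#' @return A tibble with one row per unordered pair.
#' @export
ani_matrix <- function(sags, ...) {
  n <- length(sags)
  pairs <- utils::combn(n, 2)
  bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    sag_ani(sags[[pairs[1, j]]], sags[[pairs[2, j]]], ...)
  }))
}

#' Marker-gene identity screen between two cells
#'
#' Globally aligns the two recovered marker sequences (e.g. 18S rDNA) and
#' declares them identical only with zero mismatches and zero indels. Indel
#' positions count towards `n_mismatches` (conservative).
#'
#' @param a_marker,b_marker Non-empty DNA strings.
#' @return A list: `identical` (flag), `n_mismatches` (substitutions plus
#'   gapped positions).
#' @export
marker_identity <- function(a_marker, b_marker) {
  if (nchar(a_marker) == 0 || nchar(b_marker) == 0) {
    abort("marker sequences must be non-empty")
  }
  if (identical(toupper(a_marker), toupper(b_marker))) {
    return(list(identical = TRUE, n_mismatches = 0L))
  }
  aln <- Biostrings::pairwiseAlignment(
    toupper(a_marker), toupper(b_marker), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  n_mm <- sum(gap) + sum(!gap & p != s)
  list(identical = n_mm == 0L, n_mismatches = as.integer(n_mm))
}

#' Decide whether two cells may be co-assembled
#'
#' The three-criterion rule: identical marker gene (18S rDNA stand-in), ANI
#' above the threshold (default > 95%), and membership in the same
#' composition cluster. All three must hold.
#'
#' @param marker_identical Flag from [marker_identity()].
#' @param ani_mean Mean ANI in percent; must be defined.
#' @param same_cluster Flag from the composition screen.
#' @param ani_threshold ANI threshold in percent (default 95; the test is
#'   strictly greater).
#' @param pair Optional identifier recorded in the decision.
#' @return A one-row tibble: `pair`, `marker_identical`, `ani_pass`,
#'   `same_composition_cluster`, `verdict`, `rationale`.
#' @export
decide_compatibility <- function(marker_identical, ani_mean, same_cluster,
                                 ani_threshold = 95, pair = "A|B") {
  if (is.na(ani_mean)) abort("ani_mean is undefined; compute ANI first")
  ani_pass <- ani_mean > ani_threshold
  verdict <- isTRUE(marker_identical) && ani_pass && isTRUE(same_cluster)
  fails <- c(
    if (!isTRUE(marker_identical)) "marker genes differ",
    if (!ani_pass) sprintf("ANI %.1f%% not above %.0f%%", ani_mean,
                           ani_threshold),
    if (!isTRUE(same_cluster)) "different composition clusters"
  )
  tibble(
    pair = pair,
    marker_identical = isTRUE(marker_identical),
    ani_pass = ani_pass,
    same_composition_cluster = isTRUE(same_cluster),
    verdict = verdict,
    rationale = if (verdict) "all criteria met" else {
      paste(fails, collapse = "; ")
    }
  )
}
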