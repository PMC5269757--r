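#' Per-base SAG support counts over a co-assembly
#'
#' Determines, for every base of the co-assembly, how many cells contribute
#' evidence for it. Default mode aligns each cell's contigs to the
#' co-assembly (hits at `min_identity` or better) and marks the covered
#' subject ranges; read mode places error-free reads by exact match and
#' marks read-covered bases. A base's count is the number of distinct cells
#' marking it.
#'
#' @param coassembly A contig tibble (or `sag_assembly`/named character) of
#'   the co-assembled genome.
#' @param sags A list of `sag_assembly` objects (contig mode) or a named
#'   list of `read_pairs` tibbles (read mode).
#' @param mode `"contigs"` (default) or `"reads"`.
#' @param min_identity Minimum hit identity for contig evidence
#'   (default 95).
#' @param ... Passed to [pairwise_local_hits()] in contig mode.
#' @return An object of class `coverage_mask`: list with `counts` (a list
#'   of integer [S4Vectors::Rle] per co-assembly contig), `contig_len`,
#'   `sag_ids`, `per_sag` (list of per-SAG covered interval tibbles, keyed
#'   by contig).
#' @export
build_coverage_mask <- function(coassembly, sags, mode = c("contigs", "reads"),
                                min_identity = 95, ...) {
  mode <- match.arg(mode)
  co <- .contig_tbl(coassembly)
  lens <- setNames(nchar(co$sequence), co$contig_id)
  sag_ids <- if (!is.null(names(sags)) && all(nzchar(names(sags)))) {
    names(sags)
  } else {
    vapply(seq_along(sags), function(i) {
      s <- sags[[i]]
      if (inherits(s, "sag_assembly")) s$sag_id else sprintf("SAG%02d", i)
    }, "")
  }
  per_sag <- vector("list", length(sags))
  names(per_sag) <- sag_ids
  for (i in seq_along(sags)) {
    iv <- if (mode == "contigs") {
      hits <- pairwise_local_hits(sags[[i]], co,
                                  min_identity = min_identity, ...)
      if (nrow(hits) && !all(hits$subject_contig %in% co$contig_id)) {
        abort("hit references an unknown co-assembly contig")
      }
      hits |>
        select(contig = "subject_contig", start = "s_start",
               end = "s_end")
    } else {
      .place_reads(sags[[i]], co)
    }
    per_sag[[i]] <- iv |>
      group_by(.data$contig) |>
      dplyr::group_modify(~ .iv_reduce(.x)) |>
      ungroup()
  }
  counts <- lapply(co$contig_id, function(cid) {
    ivs <- lapply(per_sag, function(tbl) {
      filter(tbl, .data$contig == cid) |> select("start", "end")
    })
    ivs <- ivs[vapply(ivs, nrow, 0L) > 0]
    if (length(ivs) == 0) {
      return(S4Vectors::Rle(0L, lens[[cid]]))
    }
    .iv_coverage(ivs, lens[[cid]])
  })
  names(counts) <- co$contig_id
  structure(list(counts = counts, contig_len = lens, sag_ids = sag_ids,
                 per_sag = per_sag, mode = mode),
            class = "coverage_mask")
}

# exact placement of error-free fixed-width reads via PDict matching;
# each read (or its reverse complement) is placed at its first exact match
.place_reads <- function(reads, co) {
  rl <- attr(reads, "read_len") %||% nchar(reads$seq1[1])
  allseq <- c(reads$seq1, reads$seq2)
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(allseq))
  subj <- Biostrings::DNAStringSet(setNames(toupper(co$sequence),
                                            co$contig_id))
  out <- list()
  for (ci in seq_along(subj)) {
    for (strand in c("+", "-")) {
      target <- if (strand == "+") subj[[ci]] else {
        Biostrings::reverseComplement(subj[[ci]])
      }
      m <- Biostrings::matchPDict(pdict, target)
      st <- BiocGenerics::start(m)
      hit <- which(lengths(st) > 0)
      if (length(hit) == 0) next
      pos <- vapply(st[hit], `[`, 0L, 1L) - 1L
      if (strand == "-") pos <- length(target) - pos - rl
      out[[length(out) + 1L]] <- tibble(
        contig = co$contig_id[ci], start = pos, end = pos + rl
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  bind_rows(out)
}

#' @export
print.coverage_mask <- function(x, ...) {
  tot <- sum(vapply(x$counts, length, 0))
  cov <- sum(vapply(x$counts, function(r) sum(S4Vectors::runValue(r) > 0) *
                      0 + sum(S4Vectors::runLength(r)[S4Vectors::runValue(r) > 0]),
                    0))
  cat(sprintf("<coverage_mask> %d contigs, %d cells, %.1f%% of %s bp covered\n",
              length(x$counts), length(x$sag_ids), 100 * cov / tot,
              format(tot, big.mark = ",")))
  invisible(x)
}

#' Sharing spectrum: co-assembly bases by exact number of supporting cells
#'
#' Tallies how many covered bases of the co-assembly are supported by
#' exactly k cells, for k = 1..n. Fractions are over covered bases
#' (k >= 1): every co-assembly base derives from at least one cell by
#' construction, so uncovered bases reflect evidence loss, not sharing.
#'
#' @param mask A `coverage_mask`.
#' @return A tibble of class `sharing_spectrum`: `k`, `bp`, `fraction`
#'   (fractions sum to 1 over k >= 1), plus attributes `covered_total` and
#'   `uncovered_bp`.
#' @export
sharing_spectrum <- function(mask) {
  stopifnot(inherits(mask, "coverage_mask"))
  if (length(mask$counts) == 0) abort("empty coverage mask")
  n <- length(mask$sag_ids)
  bp <- integer(n)
  uncov <- 0
  for (r in mask$counts) {
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    uncov <- uncov + sum(l[v == 0])
    for (k in seq_len(n)) bp[k] <- bp[k] + sum(l[v == k])
  }
  covered <- sum(bp)
  if (covered == 0) abort("no covered bases in the mask")
  out <- tibble(k = seq_len(n), bp = bp, fraction = bp / covered)
  attr(out, "covered_total") <- covered
  attr(out, "uncovered_bp") <- uncov
  class(out) <- c("sharing_spectrum", class(out))
  out
}

#' Compare marker genes recovered from cells and from the co-assembly
#'
#' For every marker found in at least one cell and in the co-assembly, the
#' mean pairwise identity among the cell copies classifies it as
#' `identical` (exactly 100), `ge95` (in [95, 100)), or `lt95` (< 95);
#' markers recovered in exactly one cell get `NA_single_sag` since no
#' within-cell comparison exists. Markers seen only in cells are
#' `solely_in_sags`; only in the co-assembly, `solely_in_coassembly`.
#'
#' @param sag_markers Tibble of recovered cell copies: `marker_id`,
#'   `sag_id`, `sequence`.
#' @param coassembly_markers Tibble of co-assembly copies: `marker_id`,
#'   `sequence`.
#' @return A tibble of class `marker_comparison`: `marker_id`, `category`,
#'   `n_sags`, `mean_identity`.
#' @export
compare_markers <- function(sag_markers, coassembly_markers) {
  in_sags <- unique(sag_markers$marker_id)
  in_co <- unique(coassembly_markers$marker_id)
  both <- intersect(in_sags, in_co)
  rows <- purrr::map_dfr(both, function(m) {
    copies <- sag_markers$sequence[sag_markers$marker_id == m]
    nsag <- length(copies)
    if (nsag == 1) {
      return(tibble(marker_id = m, category = "NA_single_sag",
                    n_sags = 1L, mean_identity = NA_real_))
    }
    prs <- utils::combn(nsag, 2)
    ids <- vapply(seq_len(ncol(prs)), function(j) {
      .global_pid(copies[prs[1, j]], copies[prs[2, j]])
    }, 0)
    mu <- mean(ids)
    cat <- if (mu == 100) "identical" else if (mu >= 95) "ge95" else "lt95"
    tibble(marker_id = m, category = cat, n_sags = nsag,
           mean_identity = mu)
  })
  extra <- bind_rows(
    tibble(marker_id = setdiff(in_sags, in_co),
           category = "solely_in_sags"),
    tibble(marker_id = setdiff(in_co, in_sags),
           category = "solely_in_coassembly")
  )
  if (nrow(extra)) {
    extra$n_sags <- NA_integer_
    extra$mean_identity <- NA_real_
  }
  out <- bind_rows(rows, extra) |> arrange(.data$marker_id)
  class(out) <- c("marker_comparison", class(out))
  out
}

# percent identity over global alignment columns (gaps included)
.global_pid <- function(a, b) {
  if (identical(a, b)) return(100)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Category totals of a marker comparison
#'
#' @param comparison A `marker_comparison` tibble (any tibble with a
#'   `category` column).
#' @return A one-row tibble with counts per category, `detected_in_both`
#'   (identical + ge95 + lt95 + NA_single_sag), `solely_in_sags`,
#'   `solely_in_coassembly`.
#' @export
marker_category_totals <- function(comparison) {
  cnt <- function(cat) sum(comparison$category == cat)
  tibble(
    identical = cnt("identical"),
    ge95 = cnt("ge95"),
    lt95 = cnt("lt95"),
    na_single_sag = cnt("NA_single_sag"),
    detected_in_both = cnt("identical") + cnt("ge95") + cnt("lt95") +
      cnt("NA_single_sag"),
    solely_in_sags = cnt("solely_in_sags"),
    solely_in_coassembly = cnt("solely_in_coassembly")
  )
}

#' Concordance of one cell's assembly against the co-assembly
#'
#' Aligns the cell's contigs to the co-assembly and reports the percent of
#' the cell's assembly length inside accepted (>= `min_identity`) hits,
#' plus mismatch and indel-event rates per 100 kbp of aligned bases
#' (indels counted per gap opening, not per gap base).
#'
#' @param sag A `sag_assembly` or contig tibble.
#' @param coassembly A contig tibble of the co-assembly.
#' @param min_identity Hit acceptance threshold (default 95).
#' @param ... Passed to [pairwise_local_hits()].
#' @return A one-row tibble: `sag_id`, `aligned_fraction`,
#'   `unaligned_fraction` (percent, summing to 100),
#'   `mismatches_per_100kbp`, `indels_per_100kbp`, `aligned_bp`.
#' @export
concordance_stats <- function(sag, coassembly, min_identity = 95, ...) {
  tbl <- .contig_tbl(sag)
  if (nrow(tbl) == 0) abort("empty assembly")
  total <- sum(nchar(tbl$sequence))
  hits <- pairwise_local_hits(sag, coassembly, min_identity = min_identity,
                              ...)
  sag_id <- if (inherits(sag, "sag_assembly")) sag$sag_id else "SAG"
  if (nrow(hits) == 0) {
    return(tibble(sag_id = sag_id, aligned_fraction = 0,
                  unaligned_fraction = 100,
                  mismatches_per_100kbp = NA_real_,
                  indels_per_100kbp = NA_real_, aligned_bp = 0L))
  }
  cov <- sum(sum(IRanges::width(IRanges::reduce(S4Vectors::split(
    IRanges::IRanges(hits$q_start + 1L, hits$q_end), hits$query_contig
  )))))
  aligned_bp <- sum(hits$aligned_len)
  tibble(
    sag_id = sag_id,
    aligned_fraction = 100 * cov / total,
    unaligned_fraction = 100 * (total - cov) / total,
    mismatches_per_100kbp = 1e5 * sum(hits$mismatches) / aligned_bp,
    indels_per_100kbp = 1e5 * sum(hits$indel_events) / aligned_bp,
    aligned_bp = as.integer(aligned_bp)
  )
}
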