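#' Pairwise local alignment hits between two contig sets
#'
#' A light-weight local aligner for assembly-vs-assembly comparison: exact
#' k-mer seeds against both strands of the subject are merged into maximal
#' exact anchors, anchors are chained per (query contig, subject contig,
#' strand, diagonal band), and inter-anchor gaps are resolved by global
#' alignment (direct comparison when the two gap lengths are equal). Hits
#' below `min_identity` or `min_hit_len` are discarded, and overlapping hits
#' on the same query region are resolved best-score-first. This replaces a
#' BLAST e-value screen with a minimum-hit-length filter at desk scale.
#'
#' @param a Query: `sag_assembly`, contig tibble, or named character vector.
#' @param b Subject: same forms as `a`.
#' @param k Seed length (>= 11; default 15).
#' @param min_identity Minimum percent identity of a reported hit
#'   (default 70).
#' @param min_hit_len Minimum alignment length of a reported hit in bp
#'   (default 100).
#' @param band_width Diagonal band width for seed grouping (default 32).
#' @param chain_gap Maximum gap between chained anchors in bp (default 500).
#' @param max_kmer_occ Seeds from subject k-mers occurring more often than
#'   this are ignored as repeats (default 20).
#' @return A tibble of hits: `query_contig`, `subject_contig`, `strand`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open, subject
#'   coordinates on the forward strand), `identity`, `aligned_len`,
#'   `matches`, `mismatches`, `indel_events`, `gap_bases`, `score`.
#' @export
pairwise_local_hits <- function(a, b, k = 15, min_identity = 70,
                                min_hit_len = 100, band_width = 32,
                                chain_gap = 500, max_kmer_occ = 20) {
  if (k < 11) abort("seed length k must be >= 11")
  qa <- .contig_tbl(a)
  sb <- .contig_tbl(b)
  empty <- tibble(
    query_contig = character(), subject_contig = character(),
    strand = character(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), identity = numeric(),
    aligned_len = integer(), matches = integer(), mismatches = integer(),
    indel_events = integer(), gap_bases = integer(), score = numeric()
  )
  if (nrow(qa) == 0 || nrow(sb) == 0) return(empty)

  qseqs <- setNames(toupper(qa$sequence), qa$contig_id)
  sfwd <- setNames(toupper(sb$sequence), sb$contig_id)
  srev <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sfwd))), sb$contig_id)
  slen <- nchar(sfwd)
  names(slen) <- sb$contig_id

  sidx <- data.table::rbindlist(list(
    .kmer_dt(sfwd, k, strand = "+"),
    .kmer_dt(srev, k, strand = "-")
  ))
  if (nrow(sidx) == 0) return(empty)
  data.table::setnames(sidx, c("contig", "pos"), c("scontig", "spos"))
  sidx <- sidx[, if (.N <= max_kmer_occ) .SD, by = "kmer"]
  qidx <- .kmer_dt(qseqs, k, strand = NULL)
  data.table::setnames(qidx, c("contig", "pos"), c("qcontig", "qpos"))

  seeds <- merge(qidx, sidx, by = "kmer", allow.cartesian = TRUE)
  if (nrow(seeds) == 0) return(empty)
  seeds[, `:=`(diag = qpos - spos)]
  seeds[, band := diag %/% band_width]
  data.table::setorder(seeds, qcontig, scontig, strand, band, diag, qpos)

  # merge seeds on one diagonal into maximal exact anchors (gap <= k keeps
  # the merged span exact)
  grp <- paste(seeds$qcontig, seeds$scontig, seeds$strand, seeds$band,
               seeds$diag, sep = "\r")
  newrun <- c(TRUE, grp[-1] != grp[-length(grp)] |
                diff(seeds$qpos) > k)
  seeds[, run := cumsum(newrun)]
  anchors <- seeds[, list(
    qcontig = qcontig[1], scontig = scontig[1], strand = strand[1],
    band = band[1], diag = diag[1],
    qstart = qpos[1], qend = qpos[.N] + k
  ), by = "run"]
  data.table::setorder(anchors, qcontig, scontig, strand, band, qstart)

  hits <- .chain_and_score(anchors, qseqs, sfwd, srev, k, chain_gap)
  if (nrow(hits) == 0) return(empty)

  # map minus-strand subject coordinates back to the forward strand
  minus <- hits$strand == "-"
  if (any(minus)) {
    sl <- slen[hits$subject_contig[minus]]
    s0 <- hits$s_start[minus]
    s1 <- hits$s_end[minus]
    hits$s_start[minus] <- sl - s1
    hits$s_end[minus] <- sl - s0
  }
  hits <- filter(hits, .data$identity >= min_identity,
                 .data$aligned_len >= min_hit_len)
  .resolve_overlaps(hits)
}

# k-mer table of a named character vector; pos is 0-based
.kmer_dt <- function(seqs, k, strand) {
  out <- lapply(names(seqs), function(id) {
    n <- nchar(seqs[[id]])
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.table::data.table(
      kmer = substring(seqs[[id]], starts, starts + k - 1L),
      contig = id, pos = starts - 1L
    )
  })
  dt <- data.table::rbindlist(out)
  if (nrow(dt) && !is.null(strand)) dt[, strand := strand]
  dt
}

# chain anchors per (qcontig, scontig, strand, band) and score each chain
.chain_and_score <- function(anchors, qseqs, sfwd, srev, k, chain_gap) {
  key <- paste(anchors$qcontig, anchors$scontig, anchors$strand,
               anchors$band, sep = "\r")
  res <- list()
  for (g in split(seq_len(nrow(anchors)), key)) {
    an <- anchors[g]
    chains <- .greedy_chain(an, chain_gap)
    for (ch in chains) {
      sseq <- if (ch$strand == "-") srev[[ch$scontig]] else sfwd[[ch$scontig]]
      st <- .score_chain(ch, qseqs[[ch$qcontig]], sseq)
      res[[length(res) + 1L]] <- st
    }
  }
  bind_rows(res)
}

# greedy collinear chaining of anchors sorted by qstart; overlapping anchor
# fronts are trimmed (exact runs, so trimming keeps coordinates consistent)
.greedy_chain <- function(an, chain_gap) {
  chains <- list()
  cur <- NULL
  for (i in seq_len(nrow(an))) {
    qs <- an$qstart[i]; qe <- an$qend[i]; dg <- an$diag[i]
    ss <- qs - dg; se <- qe - dg
    if (is.null(cur)) {
      cur <- list(qcontig = an$qcontig[i], scontig = an$scontig[i],
                  strand = an$strand[i],
                  qstart = qs, qend = qe, sstart = ss, send = se,
                  aq = qs, ae = qe, ad = dg)
      next
    }
    trim <- max(cur$qend - qs, cur$send - ss, 0L)
    qs2 <- qs + trim; ss2 <- ss + trim
    if (qs2 < qe &&
        qs2 - cur$qend <= chain_gap && ss2 - cur$send <= chain_gap) {
      cur$aq <- c(cur$aq, qs2); cur$ae <- c(cur$ae, qe)
      cur$ad <- c(cur$ad, dg)
      cur$qend <- qe; cur$send <- se
    } else {
      chains[[length(chains) + 1L]] <- cur
      cur <- list(qcontig = an$qcontig[i], scontig = an$scontig[i],
                  strand = an$strand[i],
                  qstart = qs, qend = qe, sstart = ss, send = se,
                  aq = qs, ae = qe, ad = dg)
    }
  }
  if (!is.null(cur)) chains[[length(chains) + 1L]] <- cur
  chains
}

# alignment statistics of one chain from its exact anchors + gap alignments
.score_chain <- function(ch, qseq, sseq) {
  m <- 0L; x <- 0L; gb <- 0L; ev <- 0L
  n_anchor <- length(ch$aq)
  for (i in seq_len(n_anchor)) {
    m <- m + (ch$ae[i] - ch$aq[i])
    if (i < n_anchor) {
      qg0 <- ch$ae[i]; qg1 <- ch$aq[i + 1L]
      sg0 <- qg0 - ch$ad[i]; sg1 <- ch$aq[i + 1L] - ch$ad[i + 1L]
      qgap <- qg1 - qg0; sgap <- sg1 - sg0
      if (qgap == 0L && sgap == 0L) next
      if (qgap == 0L || sgap == 0L) {
        gb <- gb + abs(qgap - sgap)
        ev <- ev + 1L
      } else {
        qs <- substring(qseq, qg0 + 1L, qg1)
        ss <- substring(sseq, sg0 + 1L, sg1)
        st <- .align_gap(qs, ss)
        m <- m + st[1]; x <- x + st[2]; gb <- gb + st[3]; ev <- ev + st[4]
      }
    }
  }
  aligned <- m + x + gb
  tibble(
    query_contig = ch$qcontig, subject_contig = ch$scontig,
    strand = ch$strand,
    q_start = ch$qstart, q_end = ch$qend,
    s_start = ch$sstart, s_end = ch$send,
    identity = 100 * m / aligned, aligned_len = as.integer(aligned),
    matches = as.integer(m), mismatches = as.integer(x),
    indel_events = as.integer(ev), gap_bases = as.integer(gb),
    score = 2 * m - 3 * x - 5 * ev - 2 * gb
  )
}

# match/mismatch/gap statistics of one inter-anchor gap
.align_gap <- function(qs, ss) {
  if (nchar(qs) == nchar(ss)) {
    qc <- strsplit(qs, "")[[1]]
    sc <- strsplit(ss, "")[[1]]
    eq <- sum(qc == sc)
    return(c(eq, length(qc) - eq, 0L, 0L))
  }
  aln <- Biostrings::pairwiseAlignment(
    qs, ss, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  mt <- sum(!gap & p == s)
  mm <- sum(!gap & p != s)
  gbases <- sum(gap)
  ev <- sum(diff(c(FALSE, p == "-")) == 1) + sum(diff(c(FALSE, s == "-")) == 1)
  c(mt, mm, gbases, ev)
}

# best-score-first: drop hits overlapping an accepted hit on the same query
# region by more than half their length
.resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  hits <- arrange(hits, dplyr::desc(.data$score))
  keep <- logical(nrow(hits))
  acc <- list()
  for (i in seq_len(nrow(hits))) {
    qc <- hits$query_contig[i]
    ir <- IRanges::IRanges(hits$q_start[i] + 1L, hits$q_end[i])
    prev <- acc[[qc]]
    ov <- if (is.null(prev)) 0 else {
      sum(IRanges::width(IRanges::intersect(ir, prev)))
    }
    if (ov <= 0.5 * IRanges::width(ir)) {
      keep[i] <- TRUE
      acc[[qc]] <- IRanges::reduce(c(prev %||% IRanges::IRanges(), ir))
    }
  }
  arrange(hits[keep, ], .data$query_contig, .data$q_start)
}
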