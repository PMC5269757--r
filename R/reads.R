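#' Simulate paired-end reads from an assembly or genome
#'
#' Fragments of fixed length `insert_mean` are sampled uniformly over the
#' source contigs (weighted by the number of valid fragment placements); mate
#' 1 is the first `read_len` bases of the fragment, mate 2 the reverse
#' complement of the last `read_len` bases. Base qualities are constant `"I"`.
#' The number of pairs is `floor(depth * source_len / (2 * read_len))`.
#'
#' When the source contigs carry truth coordinates (`truth_start`), each read
#' pair records the genome-coordinate interval of its fragment, which
#' downstream saturation analyses use as mapping truth.
#'
#' @param source A `sag_assembly`, `genome_truth`, or contig tibble.
#' @param read_len Read length in bp (default 101).
#' @param insert_mean Insert (fragment) length in bp; must be >= `read_len`.
#' @param depth Fold sequencing depth over the source (> 0).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A tibble of class `read_pairs`: `read_id`, `contig_id`, `start`
#'   (0-based offset of the fragment in its contig), `gstart`, `gend`
#'   (genome coordinates of the fragment, NA without truth), `seq1`, `qual1`,
#'   `seq2`, `qual2`, and attribute `read_len`.
#' @export
simulate_reads <- function(source, read_len = 101, insert_mean = 300,
                           depth = 20, error_rate = 0, seed = 1) {
  if (read_len > insert_mean) abort("read_len must not exceed insert_mean")
  if (depth <= 0) abort("depth must be positive")
  contigs <- .contig_tbl(source)
  lens <- nchar(contigs$sequence)
  usable <- lens >= insert_mean
  if (!any(usable)) abort("no contig long enough for the insert size")
  contigs <- contigs[usable, ]
  lens <- lens[usable]
  total <- sum(lens)
  n_pairs <- as.integer(floor(depth * total / (2 * read_len)))
  withr::with_seed(seed, {
    nplace <- lens - insert_mean + 1
    ci <- sample.int(nrow(contigs), n_pairs, replace = TRUE,
                     prob = nplace / sum(nplace))
    st <- as.integer(floor(runif(n_pairs, 0, nplace[ci])))
    frag <- substring(contigs$sequence[ci], st + 1, st + insert_mean)
    s1 <- substring(frag, 1, read_len)
    s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substring(frag, insert_mean - read_len + 1, insert_mean))))
    if (error_rate > 0) {
      s1 <- vapply(s1, .mutate_seq, "", rate = error_rate, USE.NAMES = FALSE)
      s2 <- vapply(s2, .mutate_seq, "", rate = error_rate, USE.NAMES = FALSE)
    }
    gs <- if ("truth_start" %in% names(contigs)) {
      contigs$truth_start[ci] + st
    } else rep(NA_real_, n_pairs)
    qual <- strrep("I", read_len)
    out <- tibble(
      read_id = sprintf("rp%07d", seq_len(n_pairs)),
      contig_id = contigs$contig_id[ci],
      start = st,
      gstart = gs, gend = gs + insert_mean,
      seq1 = s1, qual1 = qual, seq2 = s2, qual2 = qual
    )
  })
  attr(out, "read_len") <- as.integer(read_len)
  class(out) <- c("read_pairs", class(out))
  out
}

#' Subsample a paired read set without replacement
#'
#' Read pairs stay together; the output has `round(fraction * n)` pairs per
#' replicate, each drawn with its own seed so replicates are independent but
#' reproducible.
#'
#' @param reads A `read_pairs` tibble (or any tibble of paired reads).
#' @param fractions Fractions of pairs to keep, each in (0, 1].
#' @param replicates Number of independent replicates per fraction.
#' @param seeds Integer seeds, one per replicate.
#' @return A tibble with one row per (fraction, replicate) holding the
#'   subsampled pairs in a list-column `reads`, plus `n_pairs`.
#' @export
subsample_reads <- function(reads, fractions = c(0.17, 0.33, 0.50, 0.67, 0.83),
                            replicates = 5, seeds = seq_len(replicates)) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("fractions must be in (0, 1]")
  }
  if (length(seeds) != replicates) {
    abort("need exactly one seed per replicate")
  }
  n <- nrow(reads)
  grid <- tidyr::expand_grid(fraction = fractions,
                             replicate = seq_len(replicates))
  grid$reads <- purrr::map2(grid$fraction, grid$replicate, function(f, r) {
    k <- as.integer(round(f * n))
    withr::with_seed(seeds[r], reads[sample.int(n, k), ])
  })
  grid$n_pairs <- vapply(grid$reads, nrow, 0L)
  grid
}

#' Idealized assembly of error-free reads via their truth coordinates
#'
#' Emulates what an assembler recovers from a read set: the genome intervals
#' covered by the two mates of each pair are merged, maximal covered runs
#' become contigs, and runs shorter than `min_contig` are dropped. This is an
#' idealization (perfect read placement, no assembly errors) used to study
#' recovery-vs-effort saturation; it requires reads simulated with truth
#' coordinates and zero error rate.
#'
#' @param genome The `genome_truth` the reads derive from.
#' @param reads A `read_pairs` tibble with `gstart`/`gend` truth columns.
#' @param min_contig Minimum contig length kept (default 1000 bp).
#' @param sag_id Identifier for the resulting assembly.
#' @return A `sag_assembly` whose contigs are the covered genome runs.
#' @export
assemble_from_reads <- function(genome, reads, min_contig = 1000,
                                sag_id = "reassembly") {
  stopifnot(inherits(genome, "genome_truth"))
  if (nrow(reads) == 0 || all(is.na(reads$gstart))) {
    abort("reads carry no truth coordinates")
  }
  rl <- attr(reads, "read_len") %||% nchar(reads$seq1[1])
  iv <- bind_rows(
    tibble(start = as.integer(reads$gstart),
           end = as.integer(reads$gstart) + rl),
    tibble(start = as.integer(reads$gend) - rl,
           end = as.integer(reads$gend))
  )
  iv <- .iv_reduce(iv)
  iv <- filter(iv, .data$end - .data$start >= min_contig)
  contigs <- tibble(
    contig_id = sprintf("%s_c%04d", sag_id, seq_len(nrow(iv))),
    sequence = substring(genome$sequence, iv$start + 1, iv$end),
    length = iv$end - iv$start,
    truth_start = iv$start, truth_end = iv$end,
    foreign = FALSE
  )
  profile <- structure(
    list(sag_id = sag_id, intervals = iv,
         p = .iv_total(iv) / genome$length,
         mean_block = if (nrow(iv)) mean(iv$end - iv$start) else 0,
         genome_len = genome$length),
    class = "amplification_profile"
  )
  structure(list(sag_id = sag_id, contigs = contigs, reads = reads,
                 truth = profile),
            class = "sag_assembly")
}
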