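#' Simulate a reference genome with embedded single-copy marker genes
#'
#' Generates an i.i.d. nucleotide sequence at a target GC content, then
#' overwrites `n_markers` non-overlapping single-copy marker loci. Markers are
#' drawn at the same GC as the host (so the realized genome GC stays on
#' target) but with a fixed purine/strand skew, giving them a recognizable
#' composition while leaving the GC invariant intact. The simulated genome
#' stands in for an unknown 10-100 Mbp-class protist genome at desk scale.
#'
#' @param length Genome length in bp (>= 50000).
#' @param gc_target Target GC fraction in (0, 1).
#' @param n_markers Number of single-copy marker genes to embed.
#' @param marker_len Length of each marker in bp. `n_markers * marker_len`
#'   must not exceed `length / 2`.
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @return An object of class `genome_truth`: a list with `sequence`,
#'   `length`, `gc_target`, `seed` and a `markers` tibble
#'   (`marker_id`, `start`, `end`, `sequence`; 0-based half-open).
#' @examples
#' g <- simulate_genome(60000, 0.44, n_markers = 5, marker_len = 900, seed = 1)
#' gc_content(tibble::tibble(contig_id = "g", sequence = g$sequence))
#' @export
simulate_genome <- function(length, gc_target, n_markers = 0, marker_len = 0,
                            seed = 1) {
  if (length <= 0) abort("genome length must be positive")
  if (length < 50000) abort("genome length must be >= 50000 bp")
  if (gc_target <= 0 || gc_target >= 1) abort("gc_target must be in (0, 1)")
  if (n_markers > 0 && n_markers * marker_len > length / 2) {
    abort("markers may occupy at most half the genome")
  }
  withr::with_seed(seed, {
    base_probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
                    G = gc_target / 2, T = (1 - gc_target) / 2)
    seq_chars <- sample(names(base_probs), length, replace = TRUE,
                        prob = base_probs)
    markers <- tibble(marker_id = character(), start = integer(),
                      end = integer(), sequence = character())
    if (n_markers > 0) {
      starts <- .place_nonoverlapping(length, n_markers, marker_len)
      # skewed-but-GC-preserving composition: P(A|AT) = P(G|GC) = 0.65
      mprobs <- c(A = 0.65 * (1 - gc_target), C = 0.35 * gc_target,
                  G = 0.65 * gc_target, T = 0.35 * (1 - gc_target))
      mseqs <- vapply(seq_len(n_markers), function(i) {
        paste0(sample(names(mprobs), marker_len, replace = TRUE,
                      prob = mprobs), collapse = "")
      }, "")
      for (i in seq_len(n_markers)) {
        idx <- (starts[i] + 1L):(starts[i] + marker_len)
        seq_chars[idx] <- strsplit(mseqs[i], "")[[1]]
      }
      markers <- tibble(
        marker_id = sprintf("CEG%04d", seq_len(n_markers)),
        start = starts, end = starts + as.integer(marker_len),
        sequence = mseqs
      )
      markers <- arrange(markers, .data$start)
    }
    structure(
      list(sequence = paste0(seq_chars, collapse = ""),
           length = as.integer(length), gc_target = gc_target,
           markers = markers, seed = as.integer(seed)),
      class = "genome_truth"
    )
  })
}

# rejection-sample n non-overlapping placements of width w in [0, len)
.place_nonoverlapping <- function(len, n, w) {
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    cand <- as.integer(floor(runif(1, 0, len - w)))
    if (!any(cand < starts + w & starts < cand + w)) {
      starts <- c(starts, cand)
    }
    tries <- tries + 1L
    if (tries > 10000L * n) abort("could not place markers without overlap")
  }
  starts
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("<genome_truth> %s bp, GC target %.3f, %d markers, seed %d\n",
              format(x$length, big.mark = ","), x$gc_target,
              nrow(x$markers), x$seed))
  invisible(x)
}

#' Simulate MDA amplification bias as a random block-coverage profile
#'
#' Multiple displacement amplification recovers a different random subset of
#' the genome in every cell. The model: blocks with exponentially distributed
#' lengths (mean `mean_block`) and uniform start positions are laid down
#' independently until the union covers `p` of the genome; the final block is
#' trimmed so the covered fraction lands on the target.
#'
#' @param genome_len Genome length in bp.
#' @param p Target covered fraction in (0, 1].
#' @param mean_block Mean amplified block length in bp.
#' @param seed Integer seed.
#' @param sag_id Identifier recorded in the profile.
#' @return An object of class `amplification_profile`: list with `sag_id`,
#'   `intervals` (sorted disjoint tibble of `start`,`end`, 0-based half-open),
#'   `p`, `mean_block`, `genome_len`.
#' @export
simulate_mda_coverage <- function(genome_len, p, mean_block, seed = 1,
                                  sag_id = "SAG") {
  if (p <= 0) abort("covered fraction p must be positive")
  if (p > 1) abort("covered fraction p cannot exceed 1")
  if (mean_block <= 0 || mean_block > genome_len) {
    abort("mean_block must be in (0, genome_len]")
  }
  if (p == 1) {
    iv <- tibble(start = 0L, end = as.integer(genome_len))
    return(structure(list(sag_id = sag_id, intervals = iv, p = p,
                          mean_block = mean_block,
                          genome_len = as.integer(genome_len)),
                     class = "amplification_profile"))
  }
  target <- round(p * genome_len)
  withr::with_seed(seed, {
    iv <- tibble(start = integer(), end = integer())
    covered <- 0
    while (covered < target) {
      len <- max(1L, as.integer(round(rexp(1, 1 / mean_block))))
      st <- as.integer(floor(runif(1, 0, genome_len)))
      en <- min(st + len, as.integer(genome_len))
      cand <- .iv_reduce(bind_rows(iv, tibble(start = st, end = en)))
      overshoot <- .iv_total(cand) - target
      if (overshoot > 0) {
        # trim the tail of the newly covered territory back to the target
        cand <- .iv_trim_tail(cand, overshoot, iv)
      }
      iv <- cand
      covered <- .iv_total(iv)
    }
  })
  structure(list(sag_id = sag_id, intervals = iv, p = p,
                 mean_block = mean_block,
                 genome_len = as.integer(genome_len)),
            class = "amplification_profile")
}

# remove `excess` bp of newly added coverage (cand \ prev), trimming from the
# right end of the newly covered runs
.iv_trim_tail <- function(cand, excess, prev) {
  new_iv <- if (nrow(prev) == 0) cand else {
    .iranges_to_iv(IRanges::setdiff(.iv_to_iranges(cand), .iv_to_iranges(prev)))
  }
  keep <- new_iv
  for (i in rev(seq_len(nrow(new_iv)))) {
    w <- keep$end[i] - keep$start[i]
    cut <- min(w, excess)
    keep$end[i] <- keep$end[i] - cut
    excess <- excess - cut
    if (excess <= 0) break
  }
  keep <- filter(keep, .data$end > .data$start)
  .iv_reduce(bind_rows(prev, keep))
}

#' @export
print.amplification_profile <- function(x, ...) {
  cat(sprintf("<amplification_profile> %s: %d blocks, %s/%s bp (%.1f%%)\n",
              x$sag_id, nrow(x$intervals),
              format(.iv_total(x$intervals), big.mark = ","),
              format(x$genome_len, big.mark = ","),
              100 * .iv_total(x$intervals) / x$genome_len))
  invisible(x)
}

#' Emulate the assembly of one amplified cell
#'
#' Stands in for a short-read assembler at desk scale: every amplified block
#' is emitted as one or more contigs (Poisson breakpoints at `frag_rate`
#' breaks/bp), point substitutions are applied at `error_rate`, and contigs
#' shorter than `min_contig` are discarded, mirroring the >= 1 kbp contig
#' filter used in SAG assembly practice.
#'
#' @param genome A `genome_truth`.
#' @param profile An `amplification_profile` within the genome bounds.
#' @param frag_rate Expected breakpoints per bp (0 = no fragmentation).
#' @param error_rate Per-base substitution probability.
#' @param min_contig Minimum contig length kept (default 1000 bp).
#' @param seed Integer seed.
#' @return An object of class `sag_assembly`: list with `sag_id`, a `contigs`
#'   tibble (`contig_id`, `sequence`, `length`, `truth_start`, `truth_end`,
#'   `foreign`), and `truth` (the profile).
#' @export
emulate_assembly <- function(genome, profile, frag_rate = 0, error_rate = 0,
                             min_contig = 1000, seed = 1) {
  stopifnot(inherits(genome, "genome_truth"),
            inherits(profile, "amplification_profile"))
  if (nrow(profile$intervals) &&
      max(profile$intervals$end) > genome$length) {
    abort("amplification profile exceeds genome bounds")
  }
  withr::with_seed(seed, {
    pieces <- list()
    for (i in seq_len(nrow(profile$intervals))) {
      st <- profile$intervals$start[i]
      en <- profile$intervals$end[i]
      w <- en - st
      nbreak <- if (frag_rate > 0) rpois(1, frag_rate * w) else 0L
      cuts <- sort(unique(as.integer(floor(runif(nbreak, 1, w)))))
      bounds <- c(0L, cuts, w)
      for (j in seq_len(length(bounds) - 1L)) {
        pieces[[length(pieces) + 1L]] <-
          c(st + bounds[j], st + bounds[j + 1L])
      }
    }
    contigs <- tibble(
      truth_start = vapply(pieces, `[`, 0, 1L),
      truth_end   = vapply(pieces, `[`, 0, 2L)
    )
    contigs <- filter(contigs,
                      .data$truth_end - .data$truth_start >= min_contig)
    seqs <- if (nrow(contigs)) {
      substring(genome$sequence, contigs$truth_start + 1, contigs$truth_end)
    } else character()
    if (error_rate > 0) seqs <- vapply(seqs, .mutate_seq, "",
                                       rate = error_rate,
                                       USE.NAMES = FALSE)
    contigs <- mutate(contigs,
      contig_id = sprintf("%s_c%04d", profile$sag_id, row_number()),
      sequence = seqs,
      length = nchar(seqs),
      foreign = FALSE
    ) |>
      select("contig_id", "sequence", "length",
             "truth_start", "truth_end", "foreign")
  })
  structure(list(sag_id = profile$sag_id, contigs = contigs,
                 reads = NULL, truth = profile),
            class = "sag_assembly")
}

# point substitutions: each base flipped to one of the other three w.p. rate
.mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  pick <- sample.int(3, length(hit), replace = TRUE)
  chars[hit] <- vapply(seq_along(hit), function(i) {
    substr(alt[[chars[hit[i]]]], pick[i], pick[i])
  }, "", USE.NAMES = FALSE)
  paste0(chars, collapse = "")
}

#' @export
print.sag_assembly <- function(x, ...) {
  cat(sprintf("<sag_assembly> %s: %d contigs, %s bp%s\n", x$sag_id,
              nrow(x$contigs), format(sum(x$contigs$length), big.mark = ","),
              if (any(x$contigs$foreign)) {
                sprintf(" (%d foreign)", sum(x$contigs$foreign))
              } else ""))
  invisible(x)
}

#' Total assembly length in bp
#' @param assembly A `sag_assembly` or a contig tibble.
#' @return Total bp.
#' @export
assembly_size <- function(assembly) {
  sum(nchar(.contig_tbl(assembly)$sequence))
}

# normalize sag_assembly / tibble / named character to a contig tibble
.contig_tbl <- function(x) {
  if (inherits(x, "sag_assembly")) return(x$contigs)
  if (inherits(x, "genome_truth")) {
    return(tibble(contig_id = "genome", sequence = x$sequence))
  }
  if (is.data.frame(x)) return(x)
  if (is.character(x)) {
    ids <- names(x) %||% sprintf("seq%d", seq_along(x))
    return(tibble(contig_id = ids, sequence = unname(x)))
  }
  abort("expected a sag_assembly, genome_truth, contig tibble or character")
}

#' Append simulated foreign-DNA contigs to an assembly
#'
#' Emulates low-level contamination (e.g. DNA of a picoalgal prey inside the
#' sorted cell) by drawing fragments from an independently simulated genome
#' at a different GC content and appending them as contigs flagged
#' `foreign = TRUE` in the truth table.
#'
#' @param assembly A `sag_assembly`.
#' @param source_label Label recorded in the foreign contig ids.
#' @param gc_target GC fraction of the contaminant source genome.
#' @param n_fragments Number of foreign contigs to add (0 = no-op).
#' @param fragment_len Length range `c(min, max)` of foreign contigs in bp.
#' @param seed Integer seed.
#' @return The assembly with foreign contigs appended.
#' @export
inject_contaminant <- function(assembly, source_label = "contam",
                               gc_target = 0.55, n_fragments = 0,
                               fragment_len = c(2500, 5000), seed = 1) {
  stopifnot(inherits(assembly, "sag_assembly"))
  if (n_fragments < 0) abort("n_fragments must be >= 0")
  if (n_fragments == 0) return(assembly)
  src_len <- max(50000, n_fragments * max(fragment_len) * 2)
  src <- simulate_genome(src_len, gc_target, seed = seed + 1L)
  withr::with_seed(seed, {
    lens <- as.integer(round(runif(n_fragments, fragment_len[1],
                                   fragment_len[2])))
    starts <- vapply(lens, function(l) {
      as.integer(floor(runif(1, 0, src$length - l)))
    }, 0L)
    foreign <- tibble(
      contig_id = sprintf("%s_%s_f%03d", assembly$sag_id, source_label,
                          seq_len(n_fragments)),
      sequence = substring(src$sequence, starts + 1, starts + lens),
      length = lens,
      truth_start = NA_real_, truth_end = NA_real_,
      foreign = TRUE
    )
  })
  assembly$contigs <- bind_rows(assembly$contigs, foreign)
  assembly
}
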