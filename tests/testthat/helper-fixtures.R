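# Shared fixture builders. Everything is generated in code at test time.

# a small genome + n error-free SAG assemblies from it
fixture_scenario <- function(n_sags = 5, genome_len = 2e5, p = 0.3,
                             gc = 0.34, n_markers = 0, marker_len = 0,
                             mean_block = 8000, error_rate = 0,
                             seed = 42) {
  g <- simulate_genome(genome_len, gc, n_markers = n_markers,
                       marker_len = marker_len, seed = seed)
  sags <- lapply(seq_len(n_sags), function(i) {
    prof <- simulate_mda_coverage(genome_len, p, mean_block,
                                  seed = seed + 100 + i,
                                  sag_id = sprintf("S%02d", i))
    emulate_assembly(g, prof, error_rate = error_rate,
                     seed = seed + 200 + i)
  })
  list(genome = g, sags = sags)
}

# a random DNA string (independent of the package's simulator)
rand_dna <- function(n, seed = 1, gc = 0.5) {
  withr::with_seed(seed, {
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
           collapse = "")
  })
}

# apply k substitutions at distinct positions (oracle-side mutation, kept
# independent of the package's .mutate_seq)
mutate_at_rate <- function(seq, d, seed = 1) {
  withr::with_seed(seed, {
    n <- nchar(seq)
    k <- round(d * n)
    pos <- sample.int(n, k)
    chars <- strsplit(seq, "")[[1]]
    for (i in pos) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
    paste0(chars, collapse = "")
  })
}

# reverse complement without Biostrings (oracle side)
rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# per-base support counts of truth intervals over [0, len) (brute force)
stab_counts <- function(iv_list, len) {
  cnt <- integer(len)
  for (iv in iv_list) {
    for (i in seq_len(nrow(iv))) {
      idx <- (iv$start[i] + 1L):iv$end[i]
      cnt[idx] <- cnt[idx] + 1L
    }
  }
  cnt
}
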