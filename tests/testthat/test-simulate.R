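test_that("simulated genomes hit the GC target and are seed-deterministic", {
  g <- simulate_genome(100000, 0.339, n_markers = 20, marker_len = 1200,
                       seed = 7)
  gc <- gc_content(tibble::tibble(contig_id = "g",
                                  sequence = g$sequence))$aggregate
  expect_gte(gc, 0.329)
  expect_lte(gc, 0.349)

  a <- simulate_genome(100000, 0.5, seed = 1)
  b <- simulate_genome(100000, 0.5, seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence,
                         simulate_genome(100000, 0.5, seed = 2)$sequence))

  expect_error(simulate_genome(-5, 0.5), "positive")
  expect_error(simulate_genome(100000, 1.2), "gc_target")
})

test_that("embedded markers are single-copy, non-overlapping and in-bounds", {
  g <- simulate_genome(100000, 0.5, n_markers = 20, marker_len = 1200,
                       seed = 3)
  mk <- g$markers
  expect_equal(nrow(mk), 20)
  expect_false(anyDuplicated(mk$marker_id) > 0)
  expect_true(all(mk$end - mk$start == 1200))
  expect_true(all(mk$start >= 0 & mk$end <= g$length))
  ord <- mk[order(mk$start), ]
  expect_true(all(head(ord$end, -1) <= tail(ord$start, -1)))
  # marker sequences are actually written into the genome
  for (i in seq_len(nrow(mk))) {
    expect_identical(substring(g$sequence, mk$start[i] + 1, mk$end[i]),
                     mk$sequence[i])
  }
})

test_that("MDA coverage profiles respect the target fraction", {
  full <- simulate_mda_coverage(1000000, 1.0, 10000, seed = 9)
  expect_equal(full$intervals, tibble::tibble(start = 0L, end = 1000000L))

  p <- simulate_mda_coverage(1000000, 0.2, 10000, seed = 5)
  covered <- sum(p$intervals$end - p$intervals$start)
  expect_gte(covered, 180000)
  expect_lte(covered, 220000)
  # disjoint sorted intervals within bounds
  expect_true(all(p$intervals$start < p$intervals$end))
  expect_true(all(head(p$intervals$end, -1) <= tail(p$intervals$start, -1)))
  expect_true(all(p$intervals$start >= 0 & p$intervals$end <= 1000000))

  expect_error(simulate_mda_coverage(1e6, 0, 1e4), "positive")
  expect_error(simulate_mda_coverage(1e6, 1.5, 1e4), "exceed")
})

test_that("union coverage of independent profiles follows 1 - (1-p)^n", {
  len <- 2e5; p <- 0.2; n <- 5; reps <- 20
  fracs <- vapply(seq_len(reps), function(r) {
    ivs <- lapply(seq_len(n), function(i) {
      simulate_mda_coverage(len, p, 5000, seed = 1000 * r + i)$intervals
    })
    u <- Reduce(function(acc, iv) sagco:::.iv_reduce(rbind(acc, iv)), ivs)
    sum(u$end - u$start) / len
  }, 0)
  expected <- 1 - (1 - p)^n
  se <- sd(fracs) / sqrt(reps)
  expect_lt(abs(mean(fracs) - expected), 3 * se + 1e-9)
})

test_that("per-base support of independent profiles is Binomial(n, p)", {
  len <- 1e5; p <- 0.25; n <- 6; reps <- 20
  frac_k <- matrix(0, reps, n + 1)
  for (r in seq_len(reps)) {
    ivs <- lapply(seq_len(n), function(i) {
      simulate_mda_coverage(len, p, 4000, seed = 5000 * r + i)$intervals
    })
    cnt <- stab_counts(ivs, len)
    frac_k[r, ] <- tabulate(cnt + 1L, n + 1) / len
  }
  expected <- dbinom(0:n, n, p)
  for (k in 0:n) {
    se <- sd(frac_k[, k + 1]) / sqrt(reps)
    expect_lt(abs(mean(frac_k[, k + 1]) - expected[k + 1]),
              3 * se + 0.01)
  }
})

test_that("emulated assemblies honor identity, contig filter and error rate", {
  g <- simulate_genome(60000, 0.4, seed = 11)
  prof <- structure(list(sag_id = "S1",
                         intervals = tibble::tibble(start = 0L, end = 5000L),
                         p = 5000 / 60000, mean_block = 5000,
                         genome_len = 60000L),
                    class = "amplification_profile")
  a <- emulate_assembly(g, prof, frag_rate = 0, error_rate = 0)
  expect_equal(nrow(a$contigs), 1)
  expect_identical(a$contigs$sequence[1], substring(g$sequence, 1, 5000))

  short <- prof
  short$intervals <- tibble::tibble(start = 0L, end = 800L)
  expect_equal(nrow(emulate_assembly(g, short, min_contig = 1000)$contigs), 0)

  long <- prof
  long$intervals <- tibble::tibble(start = 0L, end = 10000L)
  b <- emulate_assembly(g, long, error_rate = 0.02, seed = 5)
  truth <- substring(g$sequence, 1, 10000)
  nmm <- sum(strsplit(b$contigs$sequence[1], "")[[1]] !=
               strsplit(truth, "")[[1]])
  sigma <- sqrt(10000 * 0.02 * 0.98)
  expect_lt(abs(nmm - 200), 3 * sigma)
})

test_that("markers inside amplified intervals survive error-free assembly", {
  g <- simulate_genome(100000, 0.45, n_markers = 10, marker_len = 1000,
                       seed = 21)
  prof <- simulate_mda_coverage(100000, 0.5, 10000, seed = 22,
                                sag_id = "S1")
  a <- emulate_assembly(g, prof, frag_rate = 0, error_rate = 0)
  inside <- vapply(seq_len(nrow(g$markers)), function(i) {
    any(g$markers$start[i] >= prof$intervals$start &
          g$markers$end[i] <= prof$intervals$end)
  }, TRUE)
  for (i in which(inside)) {
    expect_true(any(grepl(g$markers$sequence[i], a$contigs$sequence,
                          fixed = TRUE)))
  }
  expect_gt(sum(inside), 0)  # scenario actually exercises the property
})

test_that("contaminant injection appends labelled foreign contigs", {
  sc <- fixture_scenario(n_sags = 1, genome_len = 60000, p = 0.3,
                         seed = 31)
  a <- sc$sags[[1]]
  expect_identical(inject_contaminant(a, n_fragments = 0), a)
  b <- inject_contaminant(a, gc_target = 0.55, n_fragments = 36, seed = 2)
  expect_equal(sum(b$contigs$foreign), 36)
  expect_equal(nrow(b$contigs), nrow(a$contigs) + 36)
  fgc <- gc_content(b$contigs[b$contigs$foreign, ])$aggregate
  expect_gt(fgc, 0.50)  # clearly away from the 0.34 host
})

test_that("simulation operations are deterministic under a fixed seed", {
  p1 <- simulate_mda_coverage(1e5, 0.3, 5000, seed = 8)
  p2 <- simulate_mda_coverage(1e5, 0.3, 5000, seed = 8)
  expect_identical(p1$intervals, p2$intervals)
  g <- simulate_genome(1e5, 0.4, seed = 1)
  a1 <- emulate_assembly(g, p1, frag_rate = 1e-4, error_rate = 0.01,
                         seed = 3)
  a2 <- emulate_assembly(g, p1, frag_rate = 1e-4, error_rate = 0.01,
                         seed = 3)
  expect_identical(a1$contigs, a2$contigs)
})
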