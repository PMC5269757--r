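test_that("coverage masks count distinct supporting cells per base", {
  s <- rand_dna(20000, 1)
  co <- tibble::tibble(contig_id = "co1", sequence = s)
  one <- structure(list(sag_id = "S1",
                        contigs = tibble::tibble(contig_id = "S1_c1",
                                                 sequence = s),
                        reads = NULL, truth = NULL),
                   class = "sag_assembly")
  mask <- build_coverage_mask(co, list(one))
  expect_true(all(as.integer(mask$counts[["co1"]]) == 1L))

  # two cells with disjoint halves never exceed count 1
  a <- structure(list(sag_id = "A", contigs = tibble::tibble(
    contig_id = "A_c1", sequence = substring(s, 1, 10000)),
    reads = NULL, truth = NULL), class = "sag_assembly")
  b <- structure(list(sag_id = "B", contigs = tibble::tibble(
    contig_id = "B_c1", sequence = substring(s, 10001, 20000)),
    reads = NULL, truth = NULL), class = "sag_assembly")
  m2 <- build_coverage_mask(co, list(a, b))
  expect_lte(max(as.integer(m2$counts[["co1"]])), 1L)
  expect_equal(sum(as.integer(m2$counts[["co1"]]) == 1L), 20000)
})

test_that("error-free masks equal the truth-interval stabbing counts", {
  sc <- fixture_scenario(n_sags = 5, genome_len = 2e5, p = 0.3, seed = 13)
  co <- tibble::tibble(contig_id = "genome", sequence = sc$genome$sequence)
  mask <- build_coverage_mask(co, sc$sags)
  got <- as.integer(mask$counts[["genome"]])
  # oracle: the contigs' own genome coordinates (blocks < 1 kbp never made
  # it into the assemblies, so the profile intervals are not the evidence)
  truth <- stab_counts(lapply(sc$sags, function(s) {
    tibble::tibble(start = s$contigs$truth_start, end = s$contigs$truth_end)
  }), 2e5)
  expect_identical(got, truth)

  spec <- sharing_spectrum(mask)
  expect_equal(sum(spec$fraction), 1, tolerance = 1e-9)
  truth_hist <- tabulate(truth[truth > 0], nbins = 5)
  expect_identical(spec$bp, truth_hist)
  expect_equal(attr(spec, "covered_total") + attr(spec, "uncovered_bp"),
               2e5)
})

test_that("read-mode masks place error-free reads exactly", {
  s <- rand_dna(8000, 3)
  co <- tibble::tibble(contig_id = "co1", sequence = s)
  rp <- simulate_reads(co, read_len = 80, insert_mean = 200, depth = 6,
                       seed = 5)
  mask <- build_coverage_mask(co, list(S1 = rp), mode = "reads")
  got <- as.integer(mask$counts[["co1"]])
  # oracle: union of the two 80 bp mate intervals of each pair
  iv <- rbind(
    data.frame(start = rp$start, end = rp$start + 80),
    data.frame(start = rp$start + 200 - 80, end = rp$start + 200)
  )
  truth <- stab_counts(list(iv), 8000)
  expect_identical(got > 0L, truth > 0L)
})

test_that("spectrum of a single-cell mask is concentrated at k = 1", {
  s <- rand_dna(12000, 7)
  co <- tibble::tibble(contig_id = "co1", sequence = s)
  one <- structure(list(sag_id = "S1",
                        contigs = tibble::tibble(contig_id = "c", sequence = s),
                        reads = NULL, truth = NULL),
                   class = "sag_assembly")
  spec <- sharing_spectrum(build_coverage_mask(co, list(one)))
  expect_equal(spec$fraction, 1)
  expect_equal(spec$k, 1)
})

test_that("marker comparison classifies identity tiers and exclusives", {
  m1 <- rand_dna(900, 1); m2 <- rand_dna(900, 2); m3 <- rand_dna(900, 3)
  m3b <- mutate_at_rate(m3, 0.30, seed = 4)     # very distant variant
  m2b <- mutate_at_rate(m2, 0.01, seed = 5)     # ~99% identical copy
  sagm <- tibble::tibble(
    marker_id = c("M1", "M1", "M1", "M2", "M2", "M3", "M3", "M4", "M5"),
    sag_id = c("S1", "S2", "S3", "S1", "S2", "S1", "S2", "S1", "S1"),
    sequence = c(m1, m1, m1, m2, m2b, m3, m3b, rand_dna(900, 6),
                 rand_dna(900, 7))
  )
  com <- tibble::tibble(
    marker_id = c("M1", "M2", "M3", "M4", "M6"),
    sequence = c(m1, m2, m3, rand_dna(900, 6), rand_dna(900, 8))
  )
  mc <- compare_markers(sagm, com)
  cat_of <- setNames(mc$category, mc$marker_id)
  expect_equal(unname(cat_of["M1"]), "identical")
  expect_equal(unname(cat_of["M2"]), "ge95")
  expect_equal(unname(cat_of["M3"]), "lt95")
  expect_equal(unname(cat_of["M4"]), "NA_single_sag")
  expect_equal(unname(cat_of["M5"]), "solely_in_sags")
  expect_equal(unname(cat_of["M6"]), "solely_in_coassembly")
  tot <- marker_category_totals(mc)
  expect_equal(tot$detected_in_both, 4)
  expect_equal(tot$identical + tot$ge95 + tot$lt95 + tot$na_single_sag,
               tot$detected_in_both)
  # no marker lands in two categories
  expect_equal(anyDuplicated(mc$marker_id), 0)
})

test_that("concordance statistics count events per aligned 100 kbp", {
  co_seq <- rand_dna(30000, 9)
  co <- tibble::tibble(contig_id = "co1", sequence = co_seq)

  verbatim <- tibble::tibble(contig_id = "s1",
                             sequence = substring(co_seq, 2001, 12000))
  cs <- concordance_stats(verbatim, co)
  expect_equal(cs$aligned_fraction, 100)
  expect_equal(cs$mismatches_per_100kbp, 0)
  expect_equal(cs$indels_per_100kbp, 0)

  # 5 interior substitutions in a 10 kbp contig -> 50 mismatches / 100 kbp
  sagseq <- substring(co_seq, 2001, 12000)
  chars <- strsplit(sagseq, "")[[1]]
  for (p in c(1000, 3000, 5000, 7000, 9000)) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  mut <- tibble::tibble(contig_id = "s1",
                        sequence = paste0(chars, collapse = ""))
  cs2 <- concordance_stats(mut, co)
  expect_equal(cs2$aligned_fraction, 100)
  expect_equal(cs2$mismatches_per_100kbp, 50)

  # appending a 1 kbp foreign contig to a 9 kbp match -> 10% unaligned
  mixed <- tibble::tibble(
    contig_id = c("s1", "s2"),
    sequence = c(substring(co_seq, 1, 9000), rand_dna(1000, 10)))
  cs3 <- concordance_stats(mixed, co)
  expect_equal(cs3$unaligned_fraction, 10)
  expect_equal(cs3$aligned_fraction + cs3$unaligned_fraction, 100)
})
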