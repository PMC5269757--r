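test_that("self-comparison yields full-length identity-100 hits", {
  tbl <- tibble::tibble(contig_id = c("c1", "c2"),
                        sequence = c(rand_dna(6000, 1), rand_dna(4000, 2)))
  hits <- pairwise_local_hits(tbl, tbl)
  self <- hits[hits$query_contig == hits$subject_contig, ]
  expect_equal(nrow(self), 2)
  expect_true(all(self$identity == 100))
  expect_equal(self$q_end[self$query_contig == "c1"] -
                 self$q_start[self$query_contig == "c1"], 6000)
  expect_equal(sort(self$aligned_len), c(4000, 6000))
})

test_that("reverse-complement subjects produce full minus-strand hits", {
  s <- rand_dna(5000, 3)
  hits <- pairwise_local_hits(c(q = s), c(s = rc(s)))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$identity, 100)
  expect_equal(hits$aligned_len, 5000)
  expect_equal(hits$s_start, 0)
  expect_equal(hits$s_end, 5000)
  expect_true(nrow(pairwise_local_hits(
    tibble::tibble(contig_id = character(), sequence = character()),
    c(s = s))) == 0)
})

test_that("identity estimates track substitution divergence (ANI monotone)", {
  base <- rand_dna(30000, 7)
  anis <- vapply(c(0, 0.01, 0.02, 0.05), function(d) {
    mut <- if (d == 0) base else mutate_at_rate(base, d, seed = round(100 * d))
    ani <- compute_ani(pairwise_local_hits(c(a = base), c(b = mut)),
                       30000, 30000)
    ani$ani_mean
  }, 0)
  for (i in seq_along(anis)) {
    expect_lt(abs(anis[i] - 100 * (1 - c(0, 0.01, 0.02, 0.05)[i])), 0.5)
  }
  expect_true(all(diff(anis) < 0))
})

test_that("shared fractions match the truth-interval oracle on simulations", {
  sc <- fixture_scenario(n_sags = 2, genome_len = 2e5, p = 0.3, seed = 55)
  a <- sc$sags[[1]]; b <- sc$sags[[2]]
  ani <- sag_ani(a, b)
  expect_gt(ani$ani_mean, 99.9)
  ov <- sagco:::.iv_intersect(sagco:::.iv_reduce(a$truth$intervals),
                              sagco:::.iv_reduce(b$truth$intervals))
  oracle_a <- 100 * sum(ov$end - ov$start) / sum(a$contigs$length)
  oracle_b <- 100 * sum(ov$end - ov$start) / sum(b$contigs$length)
  expect_lt(abs(ani$shared_fraction_a - oracle_a), 2)
  expect_lt(abs(ani$shared_fraction_b - oracle_b), 2)

  # swapping arguments swaps the shared fractions and preserves ANI
  rev <- sag_ani(b, a)
  expect_lt(abs(rev$ani_mean - ani$ani_mean), 0.1)
  expect_lt(abs(rev$shared_fraction_a - ani$shared_fraction_b), 2)
  expect_lt(abs(rev$shared_fraction_b - ani$shared_fraction_a), 2)
})

test_that("compute_ani handles identical and disjoint assemblies", {
  s <- rand_dna(5000, 9)
  ani <- sag_ani(c(c1 = s), c(c1 = s))
  expect_equal(ani$ani_mean, 100)
  expect_equal(ani$shared_fraction_a, 100)
  expect_equal(ani$shared_fraction_b, 100)

  ani0 <- sag_ani(c(a = rand_dna(3000, 10)), c(b = rand_dna(3000, 11)))
  expect_equal(ani0$shared_fraction_a, 0)
  expect_equal(ani0$shared_fraction_b, 0)
  expect_true(is.na(ani0$ani_mean))
})

test_that("marker identity counts substitutions and indels conservatively", {
  s <- rand_dna(1500, 12)
  expect_equal(marker_identity(s, s), list(identical = TRUE,
                                           n_mismatches = 0L))
  sub1 <- paste0(substring(s, 1, 699),
                 setdiff(c("A", "C", "G", "T"),
                         substring(s, 700, 700))[1],
                 substring(s, 701, 1500))
  r <- marker_identity(s, sub1)
  expect_false(r$identical)
  expect_equal(r$n_mismatches, 1L)
  indel <- paste0(substring(s, 1, 700), substring(s, 702, 1500))
  r2 <- marker_identity(s, indel)
  expect_false(r2$identical)
  expect_gte(r2$n_mismatches, 1L)
})

test_that("the co-assembly verdict is the AND of the three criteria", {
  expect_true(decide_compatibility(TRUE, 99.1, TRUE)$verdict)
  d1 <- decide_compatibility(TRUE, 94.0, TRUE)
  expect_false(d1$verdict)
  expect_match(d1$rationale, "ANI")
  d2 <- decide_compatibility(FALSE, 100.0, TRUE)
  expect_false(d2$verdict)
  expect_match(d2$rationale, "marker")
  expect_false(decide_compatibility(TRUE, 99.0, FALSE)$verdict)
  # boundary: threshold is strict
  expect_false(decide_compatibility(TRUE, 95.0, TRUE)$verdict)
  expect_error(decide_compatibility(TRUE, NA, TRUE), "undefined")
})

test_that("cells from two species are blocked while conspecific pairs pass", {
  gA <- simulate_genome(120000, 0.34, seed = 61)
  seqB <- mutate_at_rate(gA$sequence, 0.10, seed = 62)  # ~90% ANI species
  mk_sag <- function(seqsrc, id, seed) {
    prof <- simulate_mda_coverage(120000, 0.4, 8000, seed = seed,
                                  sag_id = id)
    gt <- structure(list(sequence = seqsrc, length = 120000L,
                         gc_target = 0.34,
                         markers = tibble::tibble(), seed = 1L),
                    class = "genome_truth")
    emulate_assembly(gt, prof, seed = seed + 1)
  }
  a1 <- mk_sag(gA$sequence, "A1", 71)
  a2 <- mk_sag(gA$sequence, "A2", 72)
  b1 <- mk_sag(seqB, "B1", 73)
  within <- sag_ani(a1, a2)
  cross <- sag_ani(a1, b1)
  expect_gt(within$ani_mean, 99)
  expect_lt(cross$ani_mean, 95)
  expect_true(decide_compatibility(TRUE, within$ani_mean, TRUE)$verdict)
  expect_false(decide_compatibility(TRUE, cross$ani_mean, TRUE)$verdict)
})
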