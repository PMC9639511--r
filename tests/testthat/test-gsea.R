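test_that("enrichment score reproduces the hand-traced fixtures exactly", {
  rl <- ranked_list(c("g1", "g2", "g3", "g4"), c(2, 1, -1, -2))
  ## single hit at the top: P_hit jumps to 1 at rank 1 while P_miss is 0
  expect_equal(enrichment_score(rl, "g1")$ES, 1.0)
  ## single hit at the bottom: P_miss reaches 1 before the only hit
  expect_equal(enrichment_score(rl, "g4")$ES, -1.0)
  ## flat scores (gene-id tie-break keeps g1..g4 order), hit at rank 2:
  ## deviations -1/3, +2/3, +1/3, 0
  rl2 <- ranked_list(c("g1", "g2", "g3", "g4"), c(1, 1, 1, 1))
  expect_equal(enrichment_score(rl2, "g2")$ES, 2 / 3)
  ## degenerate inputs
  expect_error(enrichment_score(rl, c("g1", "g2", "g3", "g4")), "set equals universe")
  expect_error(enrichment_score(rl, "nope"), "empty intersection")
})

test_that("all-zero member scores fall back to uniform weights", {
  rl <- ranked_list(c("g1", "g2", "g3", "g4"), c(1, 0, 0, -1))
  ## members g2, g3 all score 0: N_R = 0 -> |s|^0 weights
  es <- enrichment_score(rl, c("g2", "g3"))
  ## uniform deviations: -1/2, 0, 1/2, 0 -> extremes tie at 1/2, smallest index
  expect_equal(es$ES, -1 / 2)
})

test_that("leading edge is the members up to / beyond the extremum", {
  rl <- ranked_list(sprintf("g%02d", 1:10), 10:1)
  es <- enrichment_score(rl, c("g01", "g03", "g09"))
  expect_gt(es$ES, 0)
  expect_identical(es$leading_edge, c("g01", "g03"))
  es2 <- enrichment_score(rl, c("g08", "g10"))
  expect_lt(es2$ES, 0)
  expect_identical(es2$leading_edge, c("g08", "g10"))
})

test_that("fast positional ES agrees with the running-sum implementation", {
  set.seed(21)
  for (i in 1:300) {
    N <- sample(5:60, 1)
    k <- sample(seq_len(min(N - 1, 12)), 1)
    rl <- ranked_list(sprintf("g%03d", 1:N), rnorm(N))
    idx <- sort(sample.int(N, k))
    main <- enrichment_score(rl, rl$gene[idx])$ES
    fast <- scHomology:::es_from_positions(abs(rl$score), N, idx)
    expect_equal(fast, main, tolerance = 1e-12)
  }
})

test_that("ES is antisymmetric under list reversal with negated scores", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(10:40, 1)
    k <- sample(2:6, 1)
    sc <- rnorm(N)
    rl <- ranked_list(sprintf("g%03d", 1:N), sc)
    set <- sample(rl$gene, k)
    rl_rev <- ranked_list(rl$gene, -rl$score)
    expect_equal(enrichment_score(rl_rev, set)$ES, -enrichment_score(rl, set)$ES,
      tolerance = 1e-12
    )
  }
})

test_that("permutation null is deterministic, bounded, and matches exhaustive enumeration", {
  rl <- ranked_list(c("g1", "g2", "g3", "g4"), c(1.4, 0.5, -0.6, -1.6))
  a <- permutation_null(rl, 2, 500, seed = 77)
  b <- permutation_null(rl, 2, 500, seed = 77)
  expect_identical(a, b)
  expect_true(all(a >= -1 & a <= 1))

  ## exhaustive oracle: ES of each of the C(4,2) = 6 subsets
  subsets <- utils::combn(4, 2)
  exact <- apply(subsets, 2, function(ii) enrichment_score(rl, rl$gene[ii])$ES)
  big <- permutation_null(rl, 2, 6000, seed = 5)
  expect_true(all(big %in% exact |
    vapply(big, function(e) any(abs(e - exact) < 1e-12), TRUE)))
  ## each subset is drawn uniformly: frequencies within 5 sigma of 1000
  counts <- vapply(exact, function(e) sum(abs(big - e) < 1e-12), numeric(1))
  expect_true(all(abs(counts - 1000) < 5 * sqrt(6000 * (1 / 6) * (5 / 6))))
})

test_that("NES and the add-one p-value follow their estimators", {
  ## boundary: 499 same-sign nulls all below the observation
  null <- c(seq(0.01, 0.79, length.out = 499), -0.5)
  r <- nes_and_pvalue(0.8, null)
  expect_equal(r$p, 1 / 500)
  ## forced arithmetic: mean same-sign |null| = 0.4
  r2 <- nes_and_pvalue(0.8, c(0.4, 0.4, 0.4, -0.9))
  expect_equal(r2$NES, 2.0)
  ## sign convention
  r3 <- nes_and_pvalue(0, c(0.5, -0.5))
  expect_equal(r3$NES, 0)
  expect_equal(r3$p, 1)
  ## empty same-sign subset
  r4 <- nes_and_pvalue(0.5, c(-0.1, -0.2, -0.3))
  expect_true(is.na(r4$NES))
  expect_equal(r4$p, 1 / 4)
  ## p never exactly 0
  expect_gt(nes_and_pvalue(0.99, seq(-0.9, 0.9, length.out = 1000))$p, 0)
})

test_that("BH step-up matches hand computation and the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(1.2), "\\(0, 1\\]")
})

test_that("size filter intersects with the universe before thresholding", {
  universe <- sprintf("u%03d", 1:600)
  expect_false(filter_gene_set(universe[1:14], universe)$kept)
  expect_true(filter_gene_set(universe[1:15], universe)$kept)
  expect_true(filter_gene_set(universe[1:500], universe)$kept)
  expect_false(filter_gene_set(universe[1:501], universe)$kept)
  ## nominal 20 but only 14 present in the universe -> rejected
  set20 <- c(universe[1:14], sprintf("x%d", 1:6))
  f <- filter_gene_set(set20, universe)
  expect_false(f$kept)
  expect_equal(f$size, 14)
})

test_that("enrich_collection rejects by size, BH-adjusts within the list, and seeds per pair", {
  set.seed(13)
  rl <- ranked_list(sprintf("g%03d", 1:100), rnorm(100))
  coll <- gene_set_collection(list(
    s1 = sprintf("g%03d", 1:20),
    s2 = sprintf("g%03d", 41:70),
    tiny = sprintf("g%03d", 1:5)
  ))
  er <- enrich_collection(rl, coll, "t1", min_size = 15, n_perm = 200, seed = 9)
  expect_equal(er$rejections$source_cluster, "tiny")
  expect_equal(er$rejections$reason, "size_filtered")
  expect_equal(sort(er$results$source_cluster), c("s1", "s2"))
  expect_equal(er$results$padj, bh_adjust(er$results$pval))
  ## deterministic given the master seed, independent of set evaluation order
  er2 <- enrich_collection(rl, coll, "t1", min_size = 15, n_perm = 200, seed = 9)
  expect_identical(er$results, er2$results)
})
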