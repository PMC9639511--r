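test_that("rank-sum test handles the forced cases", {
  ## complete separation: minimal U
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_lt(r$z, 0)
  ## symmetry: identical groups
  r <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  ## zero-variance degenerate case: all pooled values identical
  r <- rank_sum_test(c(5, 5, 5), c(5, 5))
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  expect_error(rank_sum_test(1, c(1, 2)), ">= 2")
})

test_that("rank-sum z/p agree with the reference tie-corrected implementation", {
  ## stats::wilcox.test(correct = FALSE) implements the same tie-corrected
  ## normal approximation; use it as an independent cross-check on data with
  ## heavy ties (the single-cell regime: many zeros)
  set.seed(11)
  for (i in 1:20) {
    a <- rpois(15, 1)
    b <- rpois(25, 1.5)
    mine <- rank_sum_test(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exchanging groups negates U deviation and z, leaves p unchanged", {
  set.seed(3)
  a <- rnorm(8)
  b <- rnorm(13, 0.5)
  f <- rank_sum_test(a, b)
  g <- rank_sum_test(b, a)
  expect_equal(f$U + g$U, length(a) * length(b))
  expect_equal(f$z, -g$z)
  expect_equal(f$p, g$p)
})

test_that("average log fold change matches its closed form", {
  ## equal group means -> 0
  expect_equal(average_log_fc(c(log(2), log(4)), c(log(4), log(2))), 0)
  ## mean(expm1) in = 9, out = 4, eps = 1 -> ln 2
  expect_equal(average_log_fc(log(10), log(5)), log(2))
  ## out group all zeros, in mean 9 -> ln 10
  expect_equal(average_log_fc(log(10), c(0, 0, 0)), log(10))
  expect_error(average_log_fc(numeric(0), 1), "non-empty")
})

test_that("find_markers flags a planted marker gene ahead of all noise genes", {
  ## fixed-seed fixture: gene gM has 4x mean counts in cluster A; the oracle
  ## is a direct rank-sum on the fixture's normalized values
  set.seed(99)
  n_a <- 30
  n_b <- 40
  counts <- rbind(
    gM = c(rpois(n_a, 8), rpois(n_b, 2)),
    matrix(rpois(20 * (n_a + n_b), 2), 20,
      dimnames = list(sprintf("gN%02d", 1:20), NULL)
    )
  )
  colnames(counts) <- sprintf("c%03d", seq_len(n_a + n_b))
  counts[2, ] <- counts[2, ] + 1 # guard against zero-total cells
  cm <- count_matrix(counts)
  nm <- normalize_log(cm)
  lb <- cluster_labels(colnames(counts), rep(c("A", "B"), c(n_a, n_b)))

  tab <- find_markers(nm, lb, "A", mode = "full")
  row_m <- tab[tab$gene == "gM", ]
  expect_gt(row_m$avg_logFC, 0)
  expect_true(all(row_m$p < tab$p[tab$gene != "gM"]))
  expect_equal(tab$gene[1], "gM")

  ## oracle: the same gene through the standalone test on extracted values
  v <- as.matrix(nm$values)["gM", ]
  oracle <- rank_sum_test(v[1:n_a], v[-(1:n_a)])
  expect_equal(row_m$U, oracle$U)
  expect_equal(row_m$p, oracle$p)
  lfc_oracle <- average_log_fc(v[1:n_a], v[-(1:n_a)])
  expect_equal(row_m$avg_logFC, lfc_oracle)
})

test_that("constant genes are null and filtered mode drops them", {
  vals <- rbind(
    gconst = rep(1.5, 8),
    gup = c(2, 2.2, 2.1, 2.3, 0.1, 0, 0.2, 0)
  )
  nm <- toy_norm(vals, c("gconst", "gup"), sprintf("c%d", 1:8))
  lb <- cluster_labels(sprintf("c%d", 1:8), rep(c("A", "B"), each = 4))
  full <- find_markers(nm, lb, "A", mode = "full")
  expect_equal(full$z[full$gene == "gconst"], 0)
  expect_equal(full$p[full$gene == "gconst"], 1)
  filt <- find_markers(nm, lb, "A", mode = "filtered")
  expect_false("gconst" %in% filt$gene) # |logFC| = 0 < 0.25
  expect_true("gup" %in% filt$gene)
})

test_that("marker tables obey the deterministic sort and BH invariants", {
  sim <- generate_paired_datasets(small_sim_params())
  nm <- normalize_log(sim$source$counts)
  tab <- find_markers(nm, sim$source$labels, "ms1", mode = "full")
  ## tri-level sort: p asc, |logFC| desc, gene asc
  key_ok <- order(tab$p, -abs(tab$avg_logFC), tab$gene, method = "radix")
  expect_equal(key_ok, seq_len(nrow(tab)))
  ## BH: padj >= p, monotone non-decreasing along the p ranking
  expect_true(all(tab$padj >= tab$p))
  expect_true(all(diff(tab$padj[order(tab$p)]) >= -1e-15))
  ## full mode covers every gene with a nonzero count anywhere
  expressed <- rownames(nm$values)[Matrix::rowSums(nm$values != 0) > 0]
  expect_setequal(tab$gene, expressed)
  ## detection fractions are true fractions
  expect_true(all(tab$pct_in >= 0 & tab$pct_in <= 1))
  expect_true(all(tab$pct_out >= 0 & tab$pct_out <= 1))
})

test_that("under a global null the rank-sum p-values are calibrated", {
  ## 2,000 genes, both groups drawn from one distribution; fraction of
  ## p < 0.05 must lie in the 99% binomial interval around 0.05
  set.seed(1234)
  n1 <- 40
  n2 <- 60
  pvals <- vapply(seq_len(2000), function(i) {
    v <- rpois(n1 + n2, 1.2)
    rank_sum_test(v[seq_len(n1)], v[-seq_len(n1)])$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  hw <- binom99_halfwidth(0.05, 2000)
  expect_gt(frac, 0.05 - hw)
  expect_lt(frac, 0.05 + hw)
})
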