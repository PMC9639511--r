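test_that("generator is deterministic: same params + seed give byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_paired_datasets(small_sim_params(seed = 42)), d1)
  write_dataset(generate_paired_datasets(small_sim_params(seed = 42)), d2)
  for (f in list.files(d1)) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
  ## different seed changes the counts
  d3 <- withr::local_tempdir()
  write_dataset(generate_paired_datasets(small_sim_params(seed = 43)), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "source_counts.mtx"))),
    unname(tools::md5sum(file.path(d3, "source_counts.mtx")))
  ))
})

test_that("parameter invariants are enforced", {
  expect_error(sim_params(theta = 0.5), "theta")
  expect_error(sim_params(dispersion = 0), "dispersion")
  ## program demand exhausting the shared pool
  expect_error(
    sim_params(
      n_source_clusters = 5, n_target_clusters = 5,
      n_shared_orthologs = 100, markers_per_program = 30
    ),
    "exhaust"
  )
  ## a target cluster may follow at most one source program
  expect_error(
    sim_params(correspondence = data.frame(
      source = c("ms1", "ms2"), target = c("ht1", "ht1")
    )),
    "at most one"
  )
})

test_that("planted markers realize the requested fold change (law of large numbers)", {
  p <- sim_params(
    n_source_clusters = 3, n_target_clusters = 3,
    n_shared_orthologs = 400, n_private_genes = 0,
    markers_per_program = 60, cells_per_cluster = 200,
    theta = exp(1.0), seed = 5
  )
  sim <- generate_paired_datasets(p)
  truth <- sim$truth
  counts <- as.matrix(sim$source$counts$counts)
  cl <- sim$source$labels$assignment[colnames(counts)]
  for (sc in c("ms1", "ms2", "ms3")) {
    mk <- truth$markers_source[[sc]]
    inside <- mean(counts[mk, cl == sc])
    outside <- mean(counts[mk, cl != sc])
    ratio <- inside / outside
    ## empirical in/out mean ratio within 15% of theta
    expect_gt(ratio, exp(1.0) * 0.85)
    expect_lt(ratio, exp(1.0) * 1.15)
  }
})

test_that("corresponding clusters share programs through the ortholog pairing", {
  sim <- generate_paired_datasets(small_sim_params())
  truth <- sim$truth
  orth <- sim$orthologs
  for (i in seq_len(nrow(truth$correspondence))) {
    sc <- truth$correspondence$source[i]
    tc <- truth$correspondence$target[i]
    mapped <- orth$target[match(truth$markers_source[[sc]], orth$source)]
    expect_identical(mapped, truth$markers_target[[tc]])
  }
  ## unmatched target clusters have disjoint programs
  un <- setdiff(names(truth$markers_target), truth$correspondence$target)
  matched_genes <- unlist(truth$markers_target[truth$correspondence$target])
  expect_length(intersect(unlist(truth$markers_target[un]), matched_genes), 0)
})

test_that("sparsity and overdispersion respond monotonically to the knobs", {
  base <- function(mu0, phi, seed = 9) {
    p <- sim_params(
      n_source_clusters = 2, n_target_clusters = 2,
      n_shared_orthologs = 200, n_private_genes = 0,
      markers_per_program = 20, cells_per_cluster = 80,
      baseline_meanlog = mu0, dispersion = phi, seed = seed
    )
    as.matrix(generate_paired_datasets(p)$source$counts$counts)
  }
  lo <- base(-2, 0.5)
  hi <- base(0, 0.5)
  expect_gt(mean(lo == 0), mean(hi == 0)) # higher baseline mean -> fewer zeros
  tight <- base(-1, 0.2)
  wide <- base(-1, 3)
  vmr <- function(m) mean(apply(m, 1, stats::var) / pmax(rowMeans(m), 1e-9))
  expect_gt(vmr(wide), vmr(tight)) # larger phi -> more overdispersion
})

test_that("with no planted structure the downstream pair p-values are calibrated", {
  ## C = empty, theta = 1: the full marker -> gene set -> enrichment chain is
  ## run at a scaled-down size over 20 seeds; the fraction of pair p < 0.05
  ## must lie in the 99% binomial interval around 0.05
  pvals <- c()
  for (seed in 1:20) {
    p <- sim_params(
      n_source_clusters = 4, n_target_clusters = 5,
      correspondence = data.frame(source = character(0), target = character(0)),
      n_shared_orthologs = 400, n_private_genes = 60,
      markers_per_program = 40, theta = 1,
      cells_per_cluster = 50, seed = seed
    )
    sim <- generate_paired_datasets(p)
    nm_s <- normalize_log(sim$source$counts)
    nm_t <- normalize_log(sim$target$counts)
    sm <- find_all_markers(nm_s, sim$source$labels, mode = "filtered")
    tm <- find_all_markers(nm_t, sim$target$labels, mode = "full")
    sets <- suppressWarnings(build_gene_sets(sm, sim$orthologs))
    rls <- lapply(sim$target$labels$clusters, function(tc) {
      build_ranked_list(tm[tm$cluster == tc, ])
    })
    names(rls) <- sim$target$labels$clusters
    hm <- score_homology(sets, rls, n_perm = 200, seed = seed + 1000)
    ok <- hm$cells$status == "ok"
    pvals <- c(pvals, hm$cells$pval[ok])
  }
  expect_gt(length(pvals), 150) # enough pairs survived the size filter
  frac <- mean(pvals < 0.05)
  hw <- binom99_halfwidth(0.05, length(pvals))
  expect_gt(frac, 0.05 - hw)
  expect_lt(frac, 0.05 + hw)
})
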