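## Independent oracles and fixture builders. These deliberately do NOT share
## code paths with the package implementations they check.

## Naive O(N*k) running-sum enrichment score: for every rank position,
## re-scan the set membership from scratch. Returns the signed maximal
## deviation with the smallest-index tie-break.
naive_es <- function(genes, scores, set, w = 1) {
  N <- length(genes)
  members <- intersect(genes, set)
  k <- length(members)
  aw <- abs(scores)^w
  nr <- sum(aw[genes %in% members])
  uniform <- nr == 0
  best <- 0
  best_abs <- -1
  for (i in seq_len(N)) {
    phit <- 0
    nmiss <- 0
    for (j in seq_len(i)) {
      if (genes[j] %in% members) {
        phit <- phit + (if (uniform) 1 / k else aw[j] / nr)
      } else {
        nmiss <- nmiss + 1
      }
    }
    dev <- phit - nmiss / (N - k)
    if (abs(dev) > best_abs + 1e-15) {
      best_abs <- abs(dev)
      best <- dev
    }
  }
  best
}

## Exact Wilcoxon oracle by enumeration. U is computed by pair counting
## (not via ranks); the exact two-sided p enumerates all C(n, n1)
## assignments of the pooled values.
pair_count_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

exact_wilcoxon <- function(a, b) {
  n1 <- length(a)
  v <- c(a, b)
  n <- length(v)
  idx <- utils::combn(n, n1)
  Us <- apply(idx, 2, function(ii) pair_count_U(v[ii], v[-ii]))
  mu <- n1 * (n - n1) / 2
  u_obs <- pair_count_U(a, b)
  list(
    U = u_obs,
    p = mean(abs(Us - mu) >= abs(u_obs - mu) - 1e-9),
    null_U = Us
  )
}

## Dense toy normalized matrix with labels, for marker tests.
toy_norm <- function(values, genes, cells, species = "toy") {
  m <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  m <- methods::as(m, "generalMatrix")
  dimnames(m) <- list(genes, cells)
  structure(list(values = m, scale_factor = 1e4, species = species), class = "norm_matrix")
}

## Small simulation used by several suites (fast: ~1 s).
small_sim_params <- function(seed = 7) {
  sim_params(
    n_source_clusters = 3, n_target_clusters = 4,
    correspondence = data.frame(
      source = c("ms1", "ms2"), target = c("ht1", "ht2"),
      stringsAsFactors = FALSE
    ),
    n_shared_orthologs = 300, n_private_genes = 50,
    markers_per_program = 40, cells_per_cluster = 60, seed = seed
  )
}

run_small_pipeline <- function(dir_in, dir_out, seed = 11, n_perm = 200) {
  cfg <- run_config(
    source_mtx = file.path(dir_in, "source_counts.mtx"),
    source_genes = file.path(dir_in, "source_genes.tsv"),
    source_cells = file.path(dir_in, "source_cells.tsv"),
    source_labels = file.path(dir_in, "source_labels.tsv"),
    target_mtx = file.path(dir_in, "target_counts.mtx"),
    target_genes = file.path(dir_in, "target_genes.tsv"),
    target_cells = file.path(dir_in, "target_cells.tsv"),
    target_labels = file.path(dir_in, "target_labels.tsv"),
    orthologs = file.path(dir_in, "orthologs.tsv"),
    out_dir = dir_out, n_perm = n_perm, seed = seed
  )
  suppressMessages(run_pipeline(cfg))
}

## 99% binomial CI half-width around rate r at n trials
binom99_halfwidth <- function(r, n) stats::qnorm(0.995) * sqrt(r * (1 - r) / n)
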