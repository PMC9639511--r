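## From-scratch preranked gene-set enrichment: weighted Kolmogorov-Smirnov
## running sum, gene-permutation null, NES, add-one permutation p-values,
## size filters, Benjamini-Hochberg. The multilevel adaptive p-value scheme
## of fast GSEA implementations is deliberately replaced by plain gene
## permutation (see the methods vignette); the substitution is recorded in
## run metadata.

#' Size-filter a gene set against a ranked universe
#'
#' The effective set is the intersection with the universe; it is kept iff
#' `min_size <= |effective| <= max_size`. Rejection is a recorded outcome,
#' not an error.
#'
#' @param set character vector of gene ids.
#' @param universe genes of the ranked list.
#' @param min_size,max_size inclusive size bounds (defaults 15 and 500).
#' @return list with `kept` (logical), `effective` (the intersected set, in
#'   universe order of first appearance in `set`), and `size`.
#' @export
filter_gene_set <- function(set, universe, min_size = 15, max_size = 500) {
  if (min_size > max_size) abort_input("filter_gene_set: min_size > max_size")
  effective <- set[set %in% universe]
  effective <- effective[!duplicated(effective)]
  k <- length(effective)
  list(kept = (k >= min_size && k <= max_size), effective = effective, size = k)
}

#' Weighted running-sum enrichment score
#'
#' With genes in rank order and scores `s_i`, hits are the members of `set`:
#' `P_hit(i) = sum_{j <= i, hit} |s_j|^w / N_R` with
#' `N_R = sum_{hit} |s|^w`, `P_miss(i) = #misses up to i / (N - k)`. ES is
#' the deviation `P_hit - P_miss` of maximal absolute value (ties broken at
#' the smallest rank index). If every member score is zero (`N_R = 0`) the
#' weights fall back to uniform (`|s|^0`). The leading edge is the members at
#' ranks up to the extremum for positive ES, at or beyond it for negative ES.
#'
#' @param ranked a [ranked_list()].
#' @param set gene ids; the intersection with the ranked universe must be
#'   non-empty and strictly smaller than the universe.
#' @param w weight exponent (default 1).
#' @return list with `ES`, `leading_edge`, `size` (the intersection size).
#' @export
enrichment_score <- function(ranked, set, w = 1) {
  genes <- ranked$gene
  scores <- ranked$score
  N <- length(genes)
  hit <- genes %in% set
  k <- sum(hit)
  if (k == 0) abort_input("enrichment_score: empty intersection of set and ranked universe")
  if (k == N) abort_input("enrichment_score: set equals universe (miss denominator zero)")
  aw <- abs(scores)^w
  nr <- sum(aw[hit])
  if (nr == 0) {
    aw <- rep(1, N)
    nr <- k
  }
  inc <- numeric(N)
  inc[hit] <- aw[hit] / nr
  dev <- cumsum(inc) - cumsum(!hit) / (N - k)
  ## smallest index among deviations tied (to float tolerance) for maximal
  ## magnitude -- exact ties (e.g. -1/3 vs +1/3) must not be broken by
  ## round-off noise in the cumulative sums
  m <- max(abs(dev))
  i <- which(abs(dev) >= m - 1e-12 * max(m, 1))[1]
  es <- dev[i]
  le <- if (es > 0) {
    genes[hit & seq_len(N) <= i]
  } else if (es < 0) {
    genes[hit & seq_len(N) >= i]
  } else {
    character(0)
  }
  list(ES = es, leading_edge = le, size = k)
}

## O(k log k) enrichment score from sorted hit positions; agrees with
## enrichment_score including the smallest-index tie-break. Used by the
## permutation null where only the extremum value is needed.
es_from_positions <- function(aw, N, idx) {
  k <- length(idx)
  wi <- aw[idx]
  nr <- sum(wi)
  if (nr == 0) {
    wi <- rep(1, k)
    nr <- k
  }
  H <- cumsum(wi) / nr
  missfrac <- (idx - seq_len(k)) / (N - k)
  dev_top <- H - missfrac          # deviation at each hit position
  dev_bot <- c(0, H[-k]) - missfrac # deviation just before each hit
  cand_val <- c(dev_top, dev_bot)
  cand_pos <- c(idx, idx - 1L)     # full-sequence position of each candidate
  m <- max(abs(cand_val))
  sel <- which(abs(cand_val) >= m - 1e-12 * max(m, 1))
  cand_val[sel][which.min(cand_pos[sel])]
}

#' Gene-permutation null distribution of the enrichment score
#'
#' Draws `n_perm` uniformly random k-subsets of the ranked universe (without
#' replacement) and returns their enrichment scores. The stream is fully
#' determined by `seed`.
#'
#' @param ranked a [ranked_list()].
#' @param k subset size, `1 <= k < N`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for this stream.
#' @param w weight exponent.
#' @return numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, k, n_perm, seed, w = 1) {
  N <- nrow(ranked)
  if (k < 1 || k >= N) abort_input("permutation_null: need 1 <= k < N (k = %d, N = %d)", k, N)
  if (n_perm < 100) abort_input("permutation_null: n_perm must be >= 100")
  aw <- abs(ranked$score)^w
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(aw, N, sort.int(sample.int(N, k), method = "quick"))
    }, numeric(1))
  })
}

#' Normalized enrichment score and permutation p-value
#'
#' With the same-sign null subset `Q`: `NES = ES / mean(|Q|)` and
#' `p = (1 + #{e in Q : |e| >= |ES|}) / (1 + |Q|)` (add-one estimator, never
#' exactly 0). `ES = 0` gives `NES = 0, p = 1`. An empty `Q` leaves NES
#' undefined (`NA`) with `p = 1 / (length(null) + 1)`.
#'
#' @param es_obs observed enrichment score.
#' @param null numeric vector of null enrichment scores.
#' @return list with `NES` and `p`.
#' @export
nes_and_pvalue <- function(es_obs, null) {
  if (!length(null)) abort_input("nes_and_pvalue: empty null")
  if (es_obs == 0) {
    return(list(NES = 0, p = 1))
  }
  q <- null[sign(null) == sign(es_obs)]
  if (!length(q)) {
    return(list(NES = NA_real_, p = 1 / (length(null) + 1)))
  }
  list(
    NES = es_obs / mean(abs(q)),
    p = (1 + sum(abs(q) >= abs(es_obs))) / (1 + length(q))
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= i} p_(j) * n / j`, clipped at 1, returned in input order.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values, elementwise >= the input and <= 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) abort_input("bh_adjust: p-values must lie in (0, 1]")
  bh_step_up(pvals)
}

#' Enrich every gene set of a collection in one ranked list
#'
#' Applies [filter_gene_set()], computes observed ES, the per-set
#' gene-permutation null (stream seeded by
#' `derive_seed(seed, target_id, set name)` so results are order-independent),
#' NES and p, then BH-adjusts across the kept sets of this ranked list.
#'
#' @param ranked a [ranked_list()] for one target cluster.
#' @param collection a [gene_set_collection()].
#' @param target_id label of the ranked list's cluster (used in output and in
#'   per-pair seed derivation).
#' @param min_size,max_size size filter bounds.
#' @param w weight exponent.
#' @param n_perm permutations per set.
#' @param seed master seed.
#' @return list of data.frames `results` (source_cluster, target_cluster,
#'   set_size, ES, NES, pval, padj, n_perm_used, leading_edge) and
#'   `rejections` (source_cluster, target_cluster, reason, set_size).
#' @export
enrich_collection <- function(ranked, collection, target_id,
                              min_size = 15, max_size = 500, w = 1,
                              n_perm = 10000, seed = 1) {
  universe <- ranked$gene
  res <- list()
  rej <- list()
  for (nm in names(collection$sets)) {
    flt <- filter_gene_set(collection$sets[[nm]], universe, min_size, max_size)
    if (!flt$kept) {
      rej[[nm]] <- data.frame(
        source_cluster = nm, target_cluster = target_id,
        reason = "size_filtered", set_size = flt$size, stringsAsFactors = FALSE
      )
      next
    }
    es <- enrichment_score(ranked, flt$effective, w = w)
    null <- permutation_null(ranked, es$size, n_perm, derive_seed(seed, target_id, nm), w = w)
    np <- nes_and_pvalue(es$ES, null)
    res[[nm]] <- data.frame(
      source_cluster = nm, target_cluster = target_id, set_size = es$size,
      ES = es$ES, NES = np$NES, pval = np$p, padj = NA_real_,
      n_perm_used = n_perm,
      leading_edge = paste(es$leading_edge, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, unname(res)) %||% data.frame(
    source_cluster = character(0), target_cluster = character(0),
    set_size = integer(0), ES = numeric(0), NES = numeric(0),
    pval = numeric(0), padj = numeric(0), n_perm_used = integer(0),
    leading_edge = character(0), stringsAsFactors = FALSE
  )
  if (nrow(results)) results$padj <- bh_adjust(results$pval)
  rejections <- do.call(rbind, unname(rej)) %||%
    data.frame(
      source_cluster = character(0), target_cluster = character(0),
      reason = character(0), set_size = integer(0), stringsAsFactors = FALSE
    )
  list(results = results, rejections = rejections)
}
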