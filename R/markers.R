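## One-vs-rest marker detection: tie-corrected Wilcoxon rank-sum (normal
## approximation, no continuity correction -- matching the fast rank-sum
## implementations used inside single-cell toolkits) plus the classic
## natural-log avg_logFC with pseudocount 1 on de-logged normalized means.

#' Wilcoxon / Mann-Whitney rank-sum test (tie-corrected normal approximation)
#'
#' Returns the Mann-Whitney statistic `U` for group `a`, the normal deviate
#' `z` with mean `n1*n2/2` and tie-corrected variance
#' `(n1*n2/12) * ((n+1) - sum(t^3 - t) / (n*(n-1)))` over tie groups of size
#' `t`, and the two-sided tail probability `p`. No continuity correction.
#' A degenerate pooled sample (all values identical, hence zero variance)
#' returns `z = 0, p = 1`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with elements `U`, `z`, `p`.
#' @export
rank_sum_test <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort_input("rank_sum_test: both groups need >= 2 observations")
  v <- c(a, b)
  n <- n1 + n2
  r <- rank(v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie <- sum(rle(sort.int(v, method = "quick"))$lengths^3) - n
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(U = U, z = 0, p = 1))
  }
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, z = z, p = min(1, 2 * pnorm(-abs(z))))
}

#' Average log fold change on log-normalized values
#'
#' `ln(mean(expm1(x_in)) + eps) - ln(mean(expm1(x_out)) + eps)`: group means
#' are taken on the de-logged normalized scale, then re-logged with a
#' pseudocount (default 1, the classic natural-log avg_logFC convention).
#'
#' @param in_values,out_values normalized expression values of one gene in
#'   the cluster cells and the remaining cells.
#' @param eps positive pseudocount.
#' @return the fold change (natural log).
#' @export
average_log_fc <- function(in_values, out_values, eps = 1) {
  if (!length(in_values) || !length(out_values)) {
    abort_input("average_log_fc: both groups must be non-empty")
  }
  log(mean(expm1(in_values)) + eps) - log(mean(expm1(out_values)) + eps)
}

## Per-row ranks (average-tie) and tie terms sum(t^3) - n over a dense block.
row_rank_stats <- function(M) {
  G <- nrow(M)
  n <- ncol(M)
  ranks <- matrix(0, G, n)
  tie <- numeric(G)
  for (i in seq_len(G)) {
    v <- M[i, ]
    ranks[i, ] <- rank(v)
    tie[i] <- sum(rle(sort.int(v, method = "quick"))$lengths^3) - n
  }
  list(ranks = ranks, tie = tie)
}

## BH step-up without the (0,1] domain check (marker p-values may underflow
## to 0 at extreme z; the exported bh_adjust keeps its strict contract).
bh_step_up <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * n / rev(seq_len(n))))[ro]
}

#' One-vs-rest differential expression for one cluster
#'
#' For every tested gene: detection fractions (`pct_in`, `pct_out` = fraction
#' of cells with normalized value > 0), [average_log_fc()], and the
#' tie-corrected [rank_sum_test()] of cluster cells versus all remaining
#' cells, with Benjamini-Hochberg adjustment across the tested genes of this
#' cluster.
#'
#' In `filtered` mode only genes with
#' `max(pct_in, pct_out) >= min_pct` and `|avg_logFC| >= logfc_threshold`
#' are tested. In `full` mode both thresholds are forced to 0 and every gene
#' with at least one nonzero count anywhere is tested -- the complete ranked
#' universe needed downstream.
#'
#' Output is sorted by p ascending, ties by |avg_logFC| descending, then gene
#' id, so "top N" is reproducible.
#'
#' @param norm a `norm_matrix` from [normalize_log()].
#' @param labels a [cluster_labels()] covering all cells of `norm`.
#' @param cluster cluster id to contrast against the rest.
#' @param min_pct,logfc_threshold detection-fraction and fold-change filters
#'   (`filtered` mode only; defaults 0.1 and 0.25).
#' @param mode `"filtered"` or `"full"`.
#' @param eps pseudocount for [average_log_fc()].
#' @param .precomp internal: shared rank precomputation from
#'   [find_all_markers()].
#' @return data.frame with columns cluster, gene, avg_logFC, U, z, p, padj,
#'   pct_in, pct_out.
#' @export
find_markers <- function(norm, labels, cluster, min_pct = 0.1, logfc_threshold = 0.25,
                         mode = c("filtered", "full"), eps = 1, .precomp = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(norm, "norm_matrix"))
  X <- norm$values
  cells <- colnames(X)
  if (!all(cells %in% names(labels$assignment))) {
    abort_input("find_markers: unlabelled cells present")
  }
  cl <- labels$assignment[cells]
  if (!cluster %in% cl) abort_input("find_markers: cluster '%s' not present", cluster)
  in_idx <- which(cl == cluster)
  n1 <- length(in_idx)
  n2 <- ncol(X) - n1
  if (n1 < 2) abort_input("find_markers: cluster '%s' has %d cells (< 2)", cluster, n1)
  if (n2 < 2) abort_input("find_markers: rest group for cluster '%s' has %d cells (< 2)", cluster, n2)

  nz_total <- Matrix::rowSums(X != 0)
  expressed <- nz_total > 0
  nz_in <- Matrix::rowSums(X[, in_idx, drop = FALSE] != 0)
  pct_in <- nz_in / n1
  pct_out <- (nz_total - nz_in) / n2

  E <- X
  E@x <- expm1(E@x)
  sum_total <- Matrix::rowSums(E)
  sum_in <- Matrix::rowSums(E[, in_idx, drop = FALSE])
  lfc <- log(sum_in / n1 + eps) - log((sum_total - sum_in) / n2 + eps)

  keep <- if (mode == "filtered") {
    expressed & (pmax(pct_in, pct_out) >= min_pct) & (abs(lfc) >= logfc_threshold)
  } else {
    expressed
  }
  keep_idx <- which(keep)
  if (!length(keep_idx)) {
    return(data.frame(
      cluster = character(0), gene = character(0), avg_logFC = numeric(0),
      U = numeric(0), z = numeric(0), p = numeric(0), padj = numeric(0),
      pct_in = numeric(0), pct_out = numeric(0), stringsAsFactors = FALSE
    ))
  }

  if (!is.null(.precomp) && all(keep_idx %in% .precomp$idx)) {
    sel <- match(keep_idx, .precomp$idx)
    ranks <- .precomp$ranks[sel, , drop = FALSE]
    tie <- .precomp$tie[sel]
  } else {
    rs <- row_rank_stats(as.matrix(X[keep_idx, , drop = FALSE]))
    ranks <- rs$ranks
    tie <- rs$tie
  }

  n <- n1 + n2
  U <- rowSums(ranks[, in_idx, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- pmax(0, (n1 * n2 / 12) * ((n + 1) - tie / (n * (n - 1))))
  z <- ifelse(sigma2 > 0, (U - mu) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, pmin(1, 2 * pnorm(-abs(z))), 1)

  out <- data.frame(
    cluster = cluster,
    gene = rownames(X)[keep_idx],
    avg_logFC = lfc[keep_idx],
    U = U, z = z, p = p,
    padj = bh_step_up(p),
    pct_in = pct_in[keep_idx], pct_out = pct_out[keep_idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, -abs(out$avg_logFC), out$gene, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' One-vs-rest markers for every cluster
#'
#' Loops [find_markers()] over clusters; in `full` mode the per-gene ranks
#' (which do not depend on the cluster) are computed once and shared.
#'
#' @inheritParams find_markers
#' @param clusters cluster ids to test (default: all, in label order).
#' @return row-bound marker table across clusters.
#' @export
find_all_markers <- function(norm, labels, clusters = labels$clusters,
                             min_pct = 0.1, logfc_threshold = 0.25,
                             mode = c("filtered", "full"), eps = 1) {
  mode <- match.arg(mode)
  precomp <- NULL
  if (mode == "full") {
    idx <- which(Matrix::rowSums(norm$values != 0) > 0)
    rs <- row_rank_stats(as.matrix(norm$values[idx, , drop = FALSE]))
    precomp <- list(idx = idx, ranks = rs$ranks, tie = rs$tie)
  }
  tabs <- lapply(clusters, function(cl) {
    find_markers(norm, labels, cl,
      min_pct = min_pct, logfc_threshold = logfc_threshold,
      mode = mode, eps = eps, .precomp = precomp
    )
  })
  do.call(rbind, tabs)
}
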