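## Cross-species bridging: ortholog-mapped gene sets from source-cluster
## markers, and signed-p ranked lists from target-cluster marker tables.

#' Build ortholog-mapped gene sets from source-cluster markers
#'
#' Per source cluster: keep only up-regulated markers (`avg_logFC > 0`), walk
#' the table in its deterministic sort order, keep genes having at least one
#' ortholog, and stop after `top_n` such source genes (the mapping filter is
#' applied *during* selection, so the result is the top `top_n` *mappable*
#' markers). The emitted set is the union of their target orthologs in
#' first-seen order, deduplicated. One-to-many orthologs expand to all
#' targets; many-to-one collapse by dedup.
#'
#' A cluster whose markers cannot produce any mapped gene is dropped with a
#' warning and recorded in the collection's `omitted` field.
#'
#' @param source_markers marker table covering the source clusters (as from
#'   [find_all_markers()]; any cluster subset is accepted).
#' @param orthologs an [ortholog_table()].
#' @param top_n number of mapped source genes per set (default 100).
#' @return a [gene_set_collection()] in the target namespace.
#' @export
build_gene_sets <- function(source_markers, orthologs, top_n = 100) {
  if (top_n < 1) abort_input("build_gene_sets: top_n must be >= 1")
  stopifnot(inherits(orthologs, "ortholog_table"))
  map <- split(orthologs$target, orthologs$source)
  clusters <- unique(source_markers$cluster)
  sets <- list()
  omitted <- character(0)
  for (cl in clusters) {
    tab <- source_markers[source_markers$cluster == cl & source_markers$avg_logFC > 0, ]
    tab <- tab[order(tab$p, -abs(tab$avg_logFC), tab$gene, method = "radix"), ]
    members <- character(0)
    used <- 0L
    for (g in tab$gene) {
      targets <- map[[g]]
      if (is.null(targets)) next
      members <- c(members, targets)
      used <- used + 1L
      if (used >= top_n) break
    }
    members <- members[!duplicated(members)]
    if (!length(members)) {
      warning(sprintf("build_gene_sets: cluster '%s' has no mappable positive marker; omitted", cl))
      omitted <- c(omitted, cl)
    } else {
      sets[[cl]] <- members
    }
  }
  if (!length(sets)) abort_input("build_gene_sets: no cluster produced a non-empty gene set")
  gene_set_collection(sets, omitted = omitted)
}

#' Build a ranked gene list for one target cluster
#'
#' `signedP` scores each gene `sign(avg_logFC) * (-log10(max(p, p_floor)))`
#' (a gene with `avg_logFC` exactly 0 scores 0); `avg_logFC` uses the fold
#' change directly. The marker table must come from `full`-mode
#' [find_markers()] so every expressed gene is present.
#'
#' @param target_markers marker table rows of a single cluster.
#' @param metric `"signedP"` (default) or `"avg_logFC"`.
#' @param p_floor lower bound applied to p before taking `-log10`
#'   (default 1e-300, so p = 0 scores `sign(avg_logFC) * 300`).
#' @return a [ranked_list()].
#' @export
build_ranked_list <- function(target_markers, metric = c("signedP", "avg_logFC"),
                              p_floor = 1e-300) {
  metric <- match.arg(metric)
  if (length(unique(target_markers$cluster)) > 1) {
    abort_input("build_ranked_list: marker table spans more than one cluster")
  }
  if (anyDuplicated(target_markers$gene)) {
    abort_input(
      "build_ranked_list: duplicate gene '%s'",
      target_markers$gene[duplicated(target_markers$gene)][1]
    )
  }
  score <- if (metric == "signedP") {
    sign(target_markers$avg_logFC) * (-log10(pmax(target_markers$p, p_floor)))
  } else {
    target_markers$avg_logFC
  }
  ranked_list(target_markers$gene, score, metric = metric)
}
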