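## The source x target homology matrix (the cross-species heatmap), the
## best-match calling rule, and its rendering.

#' Assemble enrichment results into a complete homology matrix
#'
#' Every (source, target) pair must be covered exactly once, either by an
#' enrichment result or by an explicit rejection (size filter, omitted
#' cluster); anything else is an error. Row/column order follows the supplied
#' cluster orders exactly.
#'
#' @param results data.frame with columns source_cluster, target_cluster,
#'   set_size, ES, NES, pval, padj, n_perm_used, leading_edge.
#' @param rejections data.frame with columns source_cluster, target_cluster,
#'   reason (and optionally set_size).
#' @param source_clusters,target_clusters ordered cluster ids.
#' @return a `homology_matrix`: list with the cluster orders and a `cells`
#'   data.frame (one row per pair, `status` is `"ok"` or the rejection
#'   reason).
#' @export
assemble_matrix <- function(results, rejections, source_clusters, target_clusters) {
  source_clusters <- as.character(source_clusters)
  target_clusters <- as.character(target_clusters)
  empty_res <- data.frame(
    source_cluster = character(0), target_cluster = character(0),
    set_size = integer(0), ES = numeric(0), NES = numeric(0),
    pval = numeric(0), padj = numeric(0), n_perm_used = integer(0),
    leading_edge = character(0), stringsAsFactors = FALSE
  )
  if (is.null(results) || !nrow(results)) results <- empty_res
  if (is.null(rejections) || !nrow(rejections)) {
    rejections <- data.frame(
      source_cluster = character(0), target_cluster = character(0),
      reason = character(0), stringsAsFactors = FALSE
    )
  }
  if (!"set_size" %in% names(rejections)) {
    rejections$set_size <- rep(NA_integer_, nrow(rejections))
  }

  key <- function(s, t) paste(s, t, sep = "\x1f")
  all_keys <- c(
    key(results$source_cluster, results$target_cluster),
    key(rejections$source_cluster, rejections$target_cluster)
  )
  if (anyDuplicated(all_keys)) {
    d <- all_keys[duplicated(all_keys)][1]
    pair <- strsplit(d, "\x1f", fixed = TRUE)[[1]]
    abort_input("assemble_matrix: duplicate cell for pair (%s, %s)", pair[1], pair[2])
  }
  grid <- expand.grid(
    source_cluster = source_clusters, target_cluster = target_clusters,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  gk <- key(grid$source_cluster, grid$target_cluster)
  uncovered <- setdiff(gk, all_keys)
  if (length(uncovered)) {
    pair <- strsplit(uncovered[1], "\x1f", fixed = TRUE)[[1]]
    abort_input(
      "assemble_matrix: %d pairs uncovered, first (%s, %s)",
      length(uncovered), pair[1], pair[2]
    )
  }
  stray <- setdiff(all_keys, gk)
  if (length(stray)) {
    pair <- strsplit(stray[1], "\x1f", fixed = TRUE)[[1]]
    abort_input("assemble_matrix: cell (%s, %s) outside the declared cluster grid", pair[1], pair[2])
  }

  cells <- grid
  cells$status <- "ok"
  cells$set_size <- NA_integer_
  cells$ES <- NA_real_
  cells$NES <- NA_real_
  cells$pval <- NA_real_
  cells$padj <- NA_real_
  cells$n_perm_used <- NA_integer_
  cells$leading_edge <- NA_character_
  ri <- match(gk, key(results$source_cluster, results$target_cluster))
  hit <- !is.na(ri)
  for (col in c("set_size", "ES", "NES", "pval", "padj", "n_perm_used", "leading_edge")) {
    cells[[col]][hit] <- results[[col]][ri[hit]]
  }
  xi <- match(gk, key(rejections$source_cluster, rejections$target_cluster))
  rej_hit <- !is.na(xi)
  cells$status[rej_hit] <- rejections$reason[xi[rej_hit]]
  cells$set_size[rej_hit] <- rejections$set_size[xi[rej_hit]]

  structure(
    list(source_clusters = source_clusters, target_clusters = target_clusters, cells = cells),
    class = "homology_matrix"
  )
}

#' Extract the NES grid of a homology matrix
#'
#' @param hm a `homology_matrix`.
#' @return numeric matrix source x target; rejected cells are `NA`.
#' @export
nes_matrix <- function(hm) {
  stopifnot(inherits(hm, "homology_matrix"))
  m <- matrix(NA_real_,
    nrow = length(hm$source_clusters), ncol = length(hm$target_clusters),
    dimnames = list(hm$source_clusters, hm$target_clusters)
  )
  ok <- hm$cells$status == "ok"
  m[cbind(
    match(hm$cells$source_cluster[ok], hm$source_clusters),
    match(hm$cells$target_cluster[ok], hm$target_clusters)
  )] <- hm$cells$NES[ok]
  m
}

#' @export
print.homology_matrix <- function(x, ...) {
  cat(sprintf(
    "homology_matrix: %d source x %d target clusters (%d cells ok, %d rejected)\n",
    length(x$source_clusters), length(x$target_clusters),
    sum(x$cells$status == "ok"), sum(x$cells$status != "ok")
  ))
  invisible(x)
}

#' Call the best-matching source cluster per target cluster
#'
#' Candidates are cells with `padj <= alpha` and `NES > 0`; the best match is
#' the maximal NES (ties go to the smaller source index in the matrix's
#' order); the margin is best NES minus runner-up NES (0 when there is no
#' runner-up). A target with no candidate is `"unassigned"`.
#'
#' @param hm a `homology_matrix`.
#' @param alpha FDR threshold in (0, 1), default 0.05.
#' @return data.frame: target_cluster, best_source, NES, padj, runner_up,
#'   margin.
#' @export
best_matches <- function(hm, alpha = 0.05) {
  stopifnot(inherits(hm, "homology_matrix"))
  if (!(alpha > 0 && alpha < 1)) abort_input("best_matches: alpha must lie in (0, 1)")
  out <- lapply(hm$target_clusters, function(tc) {
    cand <- hm$cells[
      hm$cells$target_cluster == tc &
        hm$cells$status == "ok" &
        !is.na(hm$cells$NES) &
        hm$cells$padj <= alpha &
        hm$cells$NES > 0, ,
      drop = FALSE
    ]
    if (!nrow(cand)) {
      return(data.frame(
        target_cluster = tc, best_source = "unassigned",
        NES = NA_real_, padj = NA_real_, runner_up = NA_character_,
        margin = NA_real_, stringsAsFactors = FALSE
      ))
    }
    cand <- cand[order(-cand$NES, match(cand$source_cluster, hm$source_clusters)), ]
    best <- cand[1, ]
    runner <- if (nrow(cand) > 1) cand[2, ] else NULL
    data.frame(
      target_cluster = tc,
      best_source = best$source_cluster,
      NES = best$NES,
      padj = best$padj,
      runner_up = if (is.null(runner)) NA_character_ else runner$source_cluster,
      margin = if (is.null(runner)) 0 else best$NES - runner$NES,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Render the homology heatmap and its TSV twin
#'
#' Diverging color scale centered at 0 (positive NES red, negative blue);
#' rejected cells render in a distinct grey, not as 0. The plotted NES grid
#' is also written as TSV so the image has a diffable text twin.
#'
#' @param hm a `homology_matrix`.
#' @param path output image path (`.png`).
#' @param tsv_path output path for the plotted values (default: `path` with
#'   extension replaced by `.tsv`).
#' @return invisibly, the plotted NES matrix.
#' @export
render_heatmap <- function(hm, path, tsv_path = sub("\\.[A-Za-z]+$", ".tsv", path)) {
  m <- nes_matrix(hm)
  write_nes_grid(m, tsv_path)
  lim <- max(abs(m), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1 # all-zero / all-rejected: flat mid-scale
  breaks <- seq(-lim, lim, length.out = 101)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
  pheatmap::pheatmap(m,
    cluster_rows = FALSE, cluster_cols = FALSE,
    color = pal, breaks = breaks, na_col = "grey75",
    border_color = "grey60",
    main = "Source-cluster gene-set enrichment per target cluster (NES)",
    filename = path, silent = TRUE
  )
  invisible(m)
}

write_nes_grid <- function(m, path) {
  lines <- c(
    paste(c("source_cluster", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(NULL)
}

#' Score a gene-set collection against every target ranked list
#'
#' Runs [enrich_collection()] per target cluster (per-pair permutation
#' streams derived from the master seed, so evaluation order is irrelevant),
#' marks source clusters omitted at gene-set building as rejections, and
#' assembles the complete homology matrix. BH adjustment is per target
#' cluster across its source sets.
#'
#' @param collection a [gene_set_collection()] (its `omitted` field
#'   contributes `empty_set` rejection cells).
#' @param ranked_lists named list of [ranked_list()]s, one per target
#'   cluster.
#' @param source_clusters ordered source cluster ids (default: collection
#'   sets then omitted clusters).
#' @inheritParams enrich_collection
#' @return a `homology_matrix`.
#' @export
score_homology <- function(collection, ranked_lists, source_clusters = NULL,
                           min_size = 15, max_size = 500, w = 1,
                           n_perm = 10000, seed = 1) {
  if (is.null(names(ranked_lists))) abort_input("score_homology: ranked_lists must be named by target cluster")
  source_clusters <- source_clusters %||% c(names(collection$sets), collection$omitted)
  target_clusters <- names(ranked_lists)
  res <- list()
  rej <- list()
  for (tc in target_clusters) {
    er <- enrich_collection(ranked_lists[[tc]], collection, tc,
      min_size = min_size, max_size = max_size, w = w, n_perm = n_perm, seed = seed
    )
    res[[tc]] <- er$results
    rej[[tc]] <- er$rejections
    if (length(collection$omitted)) {
      rej[[paste0(tc, ".omit")]] <- data.frame(
        source_cluster = collection$omitted, target_cluster = tc,
        reason = "empty_set", set_size = NA_integer_, stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, unname(res))
  rejections <- do.call(rbind, unname(rej))
  assemble_matrix(results, rejections, source_clusters, target_clusters)
}

#' Serialize / read the long-format enrichment results table
#'
#' @param hm a `homology_matrix`.
#' @param path TSV path.
#' @export
write_homology_results <- function(hm, path) {
  cells <- hm$cells
  out <- data.frame(
    source_cluster = cells$source_cluster,
    target_cluster = cells$target_cluster,
    status = cells$status,
    set_size = ifelse(is.na(cells$set_size), "NA", as.character(cells$set_size)),
    ES = fmt_num(cells$ES),
    NES = fmt_num(cells$NES),
    pval = fmt_num(cells$pval),
    padj = fmt_num(cells$padj),
    n_perm_used = ifelse(is.na(cells$n_perm_used), "NA", as.character(cells$n_perm_used)),
    leading_edge = ifelse(is.na(cells$leading_edge), "", cells$leading_edge),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_homology_results
#' @param path TSV path written by `write_homology_results`.
#' @export
read_homology_results <- function(path) {
  if (!file.exists(path)) abort_input("read_homology_results: file not found: %s", path)
  tab <- read.delim(path,
    stringsAsFactors = FALSE,
    colClasses = c(source_cluster = "character", target_cluster = "character", status = "character")
  )
  ok <- tab$status == "ok"
  results <- tab[ok, c(
    "source_cluster", "target_cluster", "set_size", "ES", "NES",
    "pval", "padj", "n_perm_used", "leading_edge"
  )]
  rejections <- tab[!ok, c("source_cluster", "target_cluster", "status", "set_size")]
  names(rejections)[names(rejections) == "status"] <- "reason"
  assemble_matrix(
    results, rejections,
    unique(tab$source_cluster), unique(tab$target_cluster)
  )
}
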