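## On-disk formats. MatrixMarket parsing/serialization is delegated to the
## Matrix package (the field standard); everything around it -- sidecar
## validation, error wording, round-trip guarantees -- lives here. TSV dialect
## throughout: tab-separated, UTF-8, no quoting; header row for label and
## ortholog tables, none for the one-column gene/cell sidecars.

#' Read a sparse count matrix from MatrixMarket + TSV sidecars
#'
#' @param mtx_path MatrixMarket coordinate file (1-based on disk).
#' @param genes_path,cells_path one identifier per line, no header.
#' @param species species tag stored on the result.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(mtx_path, genes_path, cells_path, species = "unknown") {
  for (p in c(mtx_path, genes_path, cells_path)) {
    if (!file.exists(p)) abort_input("read_count_matrix: file not found: %s", p)
  }
  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    abort_input("read_count_matrix: invalid MatrixMarket file %s: %s", mtx_path, conditionMessage(e))
  })
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (nrow(m) != length(genes)) {
    abort_input(
      "read_count_matrix: %d genes in %s but MTX header declares %d rows",
      length(genes), genes_path, nrow(m)
    )
  }
  if (ncol(m) != length(cells)) {
    abort_input(
      "read_count_matrix: %d cells in %s but MTX header declares %d columns",
      length(cells), cells_path, ncol(m)
    )
  }
  count_matrix(m, genes = genes, cells = cells, species = species)
}

#' Write a count matrix as MatrixMarket + TSV sidecars
#'
#' @param cm a [count_matrix()].
#' @param mtx_path,genes_path,cells_path output paths.
#' @export
write_count_matrix <- function(cm, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(cm, "count_matrix"))
  Matrix::writeMM(cm$counts, mtx_path)
  writeLines(rownames(cm$counts), genes_path)
  writeLines(colnames(cm$counts), cells_path)
  invisible(NULL)
}

read_two_col_tsv <- function(path, what) {
  if (!file.exists(path)) abort_input("%s: file not found: %s", what, path)
  lines <- readLines(path)
  if (!length(lines)) abort_input("%s: %s is empty (header line required)", what, path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort_input("%s: line %d of %s has %d fields, expected 2", what, bad[1] + 1L, path, lengths(parts)[bad[1]])
  }
  list(
    a = vapply(parts, `[[`, "", 1),
    b = vapply(parts, `[[`, "", 2)
  )
}

#' Read an ortholog table (two-column TSV, header required)
#'
#' Exact duplicate pairs are collapsed to one; order is otherwise preserved.
#' @param path TSV path with columns source gene, target gene.
#' @return an [ortholog_table()].
#' @export
read_ortholog_table <- function(path) {
  cols <- read_two_col_tsv(path, "read_ortholog_table")
  ortholog_table(cols$a, cols$b)
}

#' @rdname read_ortholog_table
#' @param orthologs an [ortholog_table()] to serialize.
#' @export
write_ortholog_table <- function(orthologs, path) {
  writeLines(c("source_gene\ttarget_gene", paste(orthologs$source, orthologs$target, sep = "\t")), path)
  invisible(NULL)
}

#' Read / write per-cell cluster labels (TSV: cell, cluster; header required)
#' @param path TSV path.
#' @return a [cluster_labels()].
#' @export
read_cluster_labels <- function(path) {
  cols <- read_two_col_tsv(path, "read_cluster_labels")
  cluster_labels(cols$a, cols$b)
}

#' @rdname read_cluster_labels
#' @param labels a [cluster_labels()] to serialize.
#' @export
write_cluster_labels <- function(labels, path) {
  writeLines(
    c("cell\tcluster", paste(names(labels$assignment), labels$assignment, sep = "\t")),
    path
  )
  invisible(NULL)
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description (empty), tab-separated members.
#' GMT cannot represent tabs inside identifiers; those are an error.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gene_sets_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- character(length(collection$sets))
  for (i in seq_along(collection$sets)) {
    nm <- names(collection$sets)[i]
    members <- collection$sets[[i]]
    if (!length(members)) abort_input("write_gene_sets_gmt: set '%s' is empty", nm)
    if (any(grepl("\t", c(nm, members), fixed = TRUE))) {
      abort_input("write_gene_sets_gmt: set '%s' contains a tab character (not representable in GMT)", nm)
    }
    lines[i] <- paste(c(nm, "", members), collapse = "\t")
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' @rdname write_gene_sets_gmt
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) abort_input("read_gene_sets_gmt: file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort_input("read_gene_sets_gmt: line %d has fewer than 3 fields (name, description, members)", bad[1])
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  gene_set_collection(sets)
}

#' Write a ranked list in RNK format (gene TAB score, descending)
#'
#' Scores are serialized with 12+ significant digits so round-trips are exact
#' to float round-off.
#'
#' @param ranked a [ranked_list()].
#' @param path output path.
#' @export
write_ranked_list_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  writeLines(paste(ranked$gene, fmt_num(ranked$score), sep = "\t"), path)
  invisible(NULL)
}

#' @rdname write_ranked_list_rnk
#' @param metric metric tag to attach on read (RNK does not store it).
#' @export
read_ranked_list_rnk <- function(path, metric = "signedP") {
  if (!file.exists(path)) abort_input("read_ranked_list_rnk: file not found: %s", path)
  cols <- strsplit(readLines(path), "\t", fixed = TRUE)
  cols <- cols[lengths(cols) > 0]
  bad <- which(lengths(cols) != 2)
  if (length(bad)) abort_input("read_ranked_list_rnk: line %d has %d fields, expected 2", bad[1], lengths(cols)[bad[1]])
  genes <- vapply(cols, `[[`, "", 1)
  scores <- as.numeric(vapply(cols, `[[`, "", 2))
  if (any(is.na(scores))) abort_input("read_ranked_list_rnk: non-numeric score at line %d", which(is.na(scores))[1])
  ranked_list(genes, scores, metric = metric)
}

#' Write / read a marker table as TSV
#'
#' Fixed column order: cluster, gene, avg_logFC, U, z, p, padj, pct_in,
#' pct_out.
#'
#' @param markers a marker table data.frame (see [find_markers()]).
#' @param path output path.
#' @export
write_marker_table <- function(markers, path) {
  cols <- c("cluster", "gene", "avg_logFC", "U", "z", "p", "padj", "pct_in", "pct_out")
  stopifnot(all(cols %in% names(markers)))
  out <- markers[, cols]
  for (nm in c("avg_logFC", "U", "z", "p", "padj", "pct_in", "pct_out")) {
    out[[nm]] <- fmt_num(out[[nm]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) abort_input("read_marker_table: file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(cluster = "character", gene = "character"))
}
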