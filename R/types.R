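## Domain containers. All are light S3 wrappers over base/Matrix structures:
## a sparse dgCMatrix for counts and normalized values, plain data.frames for
## tables. Constructors validate the invariants once; downstream code trusts
## them.

#' Construct a sparse single-cell count matrix
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer UMI counts.
#' @param genes,cells identifier vectors; default to the dimnames of `counts`.
#' @param species free-text species tag (e.g. `"mouse"`, `"human"`).
#' @return a `count_matrix` object wrapping a `dgCMatrix` with dimnames.
#' @export
count_matrix <- function(counts, genes = rownames(counts), cells = colnames(counts),
                         species = "unknown") {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(genes) || is.null(cells)) {
    abort_input("count_matrix: gene and cell identifiers are required")
  }
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    abort_input(
      "count_matrix: dimension mismatch: matrix is %d x %d but %d genes / %d cells supplied",
      nrow(counts), ncol(counts), length(genes), length(cells)
    )
  }
  if (anyDuplicated(genes)) {
    abort_input("count_matrix: duplicate gene identifier '%s'", genes[duplicated(genes)][1])
  }
  if (anyDuplicated(cells)) {
    abort_input("count_matrix: duplicate cell identifier '%s'", cells[duplicated(cells)][1])
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v)))) {
    abort_input("count_matrix: counts must be non-negative integers")
  }
  dimnames(counts) <- list(genes, cells)
  structure(list(counts = counts, species = species), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d cells (%s), %.1f%% nonzero\n",
    nrow(x$counts), ncol(x$counts), x$species,
    100 * length(x$counts@x) / prod(dim(x$counts))
  ))
  invisible(x)
}

#' Per-cell cluster labels
#'
#' @param cells cell identifiers.
#' @param clusters cluster identifier per cell (same length as `cells`).
#' @return a `cluster_labels` object: named character vector `assignment`
#'   (names are cells) plus `clusters`, the distinct cluster ids in first-seen
#'   order.
#' @export
cluster_labels <- function(cells, clusters) {
  cells <- as.character(cells)
  clusters <- as.character(clusters)
  if (length(cells) != length(clusters)) {
    abort_input("cluster_labels: %d cells but %d labels", length(cells), length(clusters))
  }
  if (anyDuplicated(cells)) {
    abort_input("cluster_labels: duplicate cell identifier '%s'", cells[duplicated(cells)][1])
  }
  assignment <- stats::setNames(clusters, cells)
  structure(list(assignment = assignment, clusters = unique(clusters)),
    class = "cluster_labels"
  )
}

## Check labels against a companion matrix: every cell labelled exactly once,
## every cluster with >= 2 cells (a one-vs-rest test needs two groups).
check_labels <- function(labels, cm) {
  cells <- colnames(cm$counts)
  missing <- setdiff(cells, names(labels$assignment))
  if (length(missing)) {
    abort_input(
      "cluster labels: %d cells of the count matrix are unlabelled (first: '%s')",
      length(missing), missing[1]
    )
  }
  extra <- setdiff(names(labels$assignment), cells)
  if (length(extra)) {
    abort_input(
      "cluster labels: %d labelled cells absent from the count matrix (first: '%s')",
      length(extra), extra[1]
    )
  }
  sizes <- table(labels$assignment)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    abort_input("cluster labels: cluster '%s' has < 2 cells", small[1])
  }
  invisible(TRUE)
}

#' Two-column ortholog table
#'
#' Exact duplicate pairs are collapsed to one (first occurrence kept);
#' one-to-many and many-to-one pairs are permitted.
#'
#' @param source,target gene identifier vectors of equal length.
#' @return an `ortholog_table`: data.frame with columns `source`, `target`.
#' @export
ortholog_table <- function(source, target) {
  source <- as.character(source)
  target <- as.character(target)
  if (length(source) != length(target)) {
    abort_input("ortholog_table: column lengths differ (%d vs %d)", length(source), length(target))
  }
  if (any(!nzchar(source)) || any(!nzchar(target))) {
    abort_input("ortholog_table: empty gene identifier at row %d", which(!nzchar(source) | !nzchar(target))[1])
  }
  keep <- !duplicated(paste(source, target, sep = "\x1f"))
  structure(
    data.frame(source = source[keep], target = target[keep], stringsAsFactors = FALSE),
    class = c("ortholog_table", "data.frame")
  )
}

#' Named gene-set collection (target-species namespace)
#'
#' @param sets named list of non-empty, duplicate-free character vectors;
#'   names are source cluster ids.
#' @param omitted character vector of source clusters dropped because no
#'   marker could be mapped (bookkeeping for run metadata).
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, omitted = character(0)) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_input("gene_set_collection: every set needs a name")
  }
  for (nm in names(sets)) {
    members <- as.character(sets[[nm]])
    if (!length(members)) abort_input("gene_set_collection: set '%s' is empty", nm)
    if (anyDuplicated(members)) abort_input("gene_set_collection: set '%s' has duplicate members", nm)
    sets[[nm]] <- members
  }
  structure(list(sets = sets, omitted = as.character(omitted)), class = "gene_set_collection")
}

#' Ranked gene list
#'
#' Entries are stored in strictly deterministic order: score descending, then
#' gene id ascending on ties.
#'
#' @param genes gene identifiers (unique).
#' @param scores numeric ranking scores.
#' @param metric ranking metric tag, `"signedP"` or `"avg_logFC"`.
#' @return a `ranked_list`: data.frame with columns `gene`, `score` and a
#'   `metric` attribute.
#' @export
ranked_list <- function(genes, scores, metric = c("signedP", "avg_logFC")) {
  metric <- match.arg(metric)
  genes <- as.character(genes)
  if (length(genes) != length(scores)) {
    abort_input("ranked_list: %d genes but %d scores", length(genes), length(scores))
  }
  if (anyDuplicated(genes)) {
    abort_input("ranked_list: duplicate gene '%s'", genes[duplicated(genes)][1])
  }
  if (any(!is.finite(scores))) abort_input("ranked_list: non-finite score")
  o <- order(-scores, genes, method = "radix")
  out <- data.frame(gene = genes[o], score = as.numeric(scores[o]), stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"), metric = metric)
}
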