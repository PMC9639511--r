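## End-to-end orchestration: normalize -> markers (source filtered, target
## full) -> ortholog gene sets -> signed-p ranked lists -> per-pair
## enrichment -> homology matrix -> best-match report.

config_defaults <- function() {
  list(
    source_mtx = NULL, source_genes = NULL, source_cells = NULL, source_labels = NULL,
    target_mtx = NULL, target_genes = NULL, target_cells = NULL, target_labels = NULL,
    orthologs = NULL, out_dir = NULL,
    scale_factor = 1e4, min_pct = 0.1, logfc_threshold = 0.25,
    top_n = 100, metric = "signedP", p_floor = 1e-300,
    min_size = 15, max_size = 500, weight = 1, n_perm = 10000,
    alpha = 0.05, seed = 1
  )
}

#' Build or load a pipeline run configuration
#'
#' Defaults follow the analysis' stated settings: top 100 mapped markers per
#' set, signedP ranking, size bounds 15/500, plus the package's documented
#' reconstructions (scale factor 10,000, marker filters 0.1/0.25, weight 1,
#' 10,000 permutations). Unknown keys are rejected.
#'
#' @param ... key = value overrides of the defaults (see
#'   `scHomology:::config_defaults()`).
#' @param file optional JSON config file; `...` overrides its values.
#' @return a validated `run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- config_defaults()
  supplied <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) abort_input("run_config: config file not found: %s", file)
    supplied <- jsonlite::read_json(file, simplifyVector = TRUE)
  }
  supplied <- utils::modifyList(supplied, list(...))
  unknown <- setdiff(names(supplied), names(cfg))
  if (length(unknown)) {
    abort_input("run_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, supplied)
  if (!cfg$metric %in% c("signedP", "avg_logFC")) {
    abort_input("run_config: metric must be 'signedP' or 'avg_logFC'")
  }
  required <- c(
    "source_mtx", "source_genes", "source_cells", "source_labels",
    "target_mtx", "target_genes", "target_cells", "target_labels",
    "orthologs", "out_dir"
  )
  miss <- required[vapply(cfg[required], is.null, TRUE)]
  if (length(miss)) abort_input("run_config: missing required key(s): %s", paste(miss, collapse = ", "))
  structure(cfg, class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "schomology_stage_error")) stop(e)
    cls <- if (inherits(e, "schomology_input_error")) {
      c("schomology_stage_error", "schomology_input_error", "schomology_error")
    } else {
      c("schomology_stage_error", "schomology_error")
    }
    stop(errorCondition(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      class = cls, stage = stage
    ))
  })
}

#' Run the full cross-species homology pipeline
#'
#' Executes every stage on the configured inputs and writes the report files
#' into `out_dir`: `gene_sets.gmt`, per-target RNK files under `rnk/`,
#' `enrichment_results.tsv` (long format with rejection markers),
#' `homology_matrix.tsv` (the NES grid, TSV twin of the heatmap),
#' `match_calls.tsv`, `heatmap.png`, and `run_metadata.json`. Stage
#' boundaries are logged with record counts; files written by a failing run
#' are removed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the homology matrix, match calls, marker
#'   tables and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  written <- character(0)
  out <- config$out_dir
  on_fail_clean <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    dir.create(out, recursive = TRUE, showWarnings = FALSE)

    src <- run_stage("io", {
      cm <- read_count_matrix(config$source_mtx, config$source_genes, config$source_cells, "source")
      lb <- read_cluster_labels(config$source_labels)
      check_labels(lb, cm)
      log_stage("io", "source: %d genes x %d cells, %d clusters", nrow(cm$counts), ncol(cm$counts), length(lb$clusters))
      list(cm = cm, lb = lb)
    })
    tgt <- run_stage("io", {
      cm <- read_count_matrix(config$target_mtx, config$target_genes, config$target_cells, "target")
      lb <- read_cluster_labels(config$target_labels)
      check_labels(lb, cm)
      log_stage("io", "target: %d genes x %d cells, %d clusters", nrow(cm$counts), ncol(cm$counts), length(lb$clusters))
      list(cm = cm, lb = lb)
    })

    norm <- run_stage("preprocess", {
      list(
        src = normalize_log(src$cm, config$scale_factor),
        tgt = normalize_log(tgt$cm, config$scale_factor)
      )
    })

    src_markers <- run_stage("markers", {
      m <- find_all_markers(norm$src, src$lb,
        min_pct = config$min_pct,
        logfc_threshold = config$logfc_threshold, mode = "filtered"
      )
      log_stage("markers", "source filtered mode: %d records", nrow(m))
      m
    })
    tgt_markers <- run_stage("markers", {
      m <- find_all_markers(norm$tgt, tgt$lb, mode = "full")
      log_stage("markers", "target full mode: %d records", nrow(m))
      m
    })

    cross <- run_stage("crossmap", {
      orth <- read_ortholog_table(config$orthologs)
      sets <- build_gene_sets(src_markers, orth, top_n = config$top_n)
      ranked <- lapply(tgt$lb$clusters, function(tc) {
        build_ranked_list(tgt_markers[tgt_markers$cluster == tc, ],
          metric = config$metric, p_floor = config$p_floor
        )
      })
      names(ranked) <- tgt$lb$clusters
      log_stage(
        "crossmap", "%d gene sets (%d clusters omitted), %d ranked lists",
        length(sets$sets), length(sets$omitted), length(ranked)
      )
      list(orth = orth, sets = sets, ranked = ranked)
    })

    gmt_path <- file.path(out, "gene_sets.gmt")
    write_gene_sets_gmt(cross$sets, gmt_path)
    written <- c(written, gmt_path)
    rnk_dir <- file.path(out, "rnk")
    dir.create(rnk_dir, showWarnings = FALSE)
    for (tc in names(cross$ranked)) {
      p <- file.path(rnk_dir, paste0(tc, ".rnk"))
      write_ranked_list_rnk(cross$ranked[[tc]], p)
      written <- c(written, p)
    }

    hm <- run_stage("gsea", {
      hm <- score_homology(cross$sets, cross$ranked,
        source_clusters = src$lb$clusters,
        min_size = config$min_size, max_size = config$max_size,
        w = config$weight, n_perm = config$n_perm, seed = config$seed
      )
      log_stage(
        "gsea", "%d cells scored, %d rejected",
        sum(hm$cells$status == "ok"), sum(hm$cells$status != "ok")
      )
      hm
    })

    report <- run_stage("report", {
      calls <- best_matches(hm, alpha = config$alpha)
      paths <- c(
        results = file.path(out, "enrichment_results.tsv"),
        matrix = file.path(out, "homology_matrix.tsv"),
        calls = file.path(out, "match_calls.tsv"),
        heatmap = file.path(out, "heatmap.png"),
        metadata = file.path(out, "run_metadata.json")
      )
      write_homology_results(hm, paths["results"])
      render_heatmap(hm, paths["heatmap"], tsv_path = paths["matrix"])
      calls_out <- calls
      for (nm in c("NES", "padj", "margin")) calls_out[[nm]] <- fmt_num(calls_out[[nm]])
      calls_out$runner_up[is.na(calls$runner_up)] <- "NA"
      write.table(calls_out, paths["calls"], sep = "\t", quote = FALSE, row.names = FALSE)
      meta <- list(
        package = "scHomology",
        version = as.character(packageVersion("scHomology")),
        config = unclass(config),
        source_clusters = src$lb$clusters,
        target_clusters = tgt$lb$clusters,
        omitted_source_clusters = cross$sets$omitted,
        n_source_marker_records = nrow(src_markers),
        n_target_marker_records = nrow(tgt_markers),
        substitutions = paste(
          "permutation p-values use plain gene permutation with the add-one",
          "estimator in place of an adaptive multilevel estimator"
        )
      )
      jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
      log_stage("report", "%d match calls written to %s", nrow(calls), out)
      list(calls = calls, paths = paths)
    })
    written <- c(written, report$paths)

    invisible(list(
      homology = hm, calls = report$calls,
      source_markers = src_markers, target_markers = tgt_markers,
      gene_sets = cross$sets, paths = report$paths
    ))
  }, error = on_fail_clean)
}
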