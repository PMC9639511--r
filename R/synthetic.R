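## Paired-dataset simulator: negative-binomial UMI counts over a shared
## ortholog-linked gene space, with one planted marker program per source
## cluster, reused (through the ortholog pairing) by the corresponding target
## clusters. Unmatched target clusters get their own programs from the shared
## pool. Emits ground truth sufficient to regenerate everything bit-identically.

#' Simulation parameters for paired source/target datasets
#'
#' Defaults mirror the analyzed datasets' shapes (10 source clusters, 18
#' target clusters); distributional choices are the package's own (see the
#' methods vignette): log-normal baseline gene means shared between ortholog
#' partners, per-cell log-normal library factors, NB dispersion `phi`
#' (variance `mu + phi * mu^2`), and a multiplicative marker effect `theta`
#' on each cluster's program genes.
#'
#' @param n_source_clusters,n_target_clusters cluster counts (defaults 10, 18).
#' @param n_shared_orthologs size of the ortholog-linked gene space.
#' @param n_private_genes species-specific genes per species (no ortholog).
#' @param markers_per_program planted marker genes per cluster program.
#' @param theta multiplicative marker effect (>= 1; `theta = 1` is the null).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean parameters.
#' @param dispersion NB dispersion `phi` (> 0); `size = 1/phi`.
#' @param cells_per_cluster scalar, or length-2 `c(source, target)`.
#' @param total_cells optional length-2 total cell counts; overrides
#'   `cells_per_cluster` by distributing totals as evenly as possible.
#' @param lib_sdlog sdlog of the per-cell library-size factor.
#' @param correspondence data.frame with columns `source`, `target` (cluster
#'   ids) giving the planted map; `NULL` (default) pairs cluster i with
#'   cluster i up to `min(K_s, K_t)`; a 0-row data.frame plants nothing.
#' @param decoy_frac fraction of shared source genes given an extra decoy
#'   one-to-many ortholog pair into the target's private genes.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_source_clusters = 10, n_target_clusters = 18,
                       n_shared_orthologs = 2000, n_private_genes = 500,
                       markers_per_program = 100, theta = exp(1.5),
                       baseline_meanlog = -1.5, baseline_sdlog = 1,
                       dispersion = 0.5, cells_per_cluster = 300,
                       total_cells = NULL, lib_sdlog = 0.3,
                       correspondence = NULL, decoy_frac = 0.05, seed = 1) {
  ks <- as.integer(n_source_clusters)
  kt <- as.integer(n_target_clusters)
  if (ks < 1 || kt < 1) abort_input("sim_params: need at least one cluster per species")
  if (theta < 1) abort_input("sim_params: theta must be >= 1")
  if (dispersion <= 0) abort_input("sim_params: dispersion must be > 0")
  src_ids <- paste0("ms", seq_len(ks))
  tgt_ids <- paste0("ht", seq_len(kt))
  if (is.null(correspondence)) {
    k <- min(ks, kt)
    correspondence <- data.frame(
      source = src_ids[seq_len(k)], target = tgt_ids[seq_len(k)],
      stringsAsFactors = FALSE
    )
  }
  correspondence$source <- as.character(correspondence$source)
  correspondence$target <- as.character(correspondence$target)
  if (nrow(correspondence)) {
    if (!all(correspondence$source %in% src_ids) || !all(correspondence$target %in% tgt_ids)) {
      abort_input("sim_params: correspondence names unknown clusters")
    }
    if (anyDuplicated(correspondence$target)) {
      abort_input("sim_params: a target cluster may correspond to at most one source program")
    }
  }
  n_prog <- ks + sum(!tgt_ids %in% correspondence$target)
  if (markers_per_program * n_prog > n_shared_orthologs) {
    abort_input(
      "sim_params: %d programs x %d markers exhaust the %d shared ortholog genes",
      n_prog, markers_per_program, n_shared_orthologs
    )
  }
  if (length(cells_per_cluster) == 1) cells_per_cluster <- rep(cells_per_cluster, 2)
  structure(list(
    n_source_clusters = ks, n_target_clusters = kt,
    source_ids = src_ids, target_ids = tgt_ids,
    n_shared_orthologs = as.integer(n_shared_orthologs),
    n_private_genes = as.integer(n_private_genes),
    markers_per_program = as.integer(markers_per_program),
    theta = theta, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, dispersion = dispersion,
    cells_per_cluster = as.integer(cells_per_cluster),
    total_cells = if (is.null(total_cells)) NULL else as.integer(total_cells),
    lib_sdlog = lib_sdlog, correspondence = correspondence,
    decoy_frac = decoy_frac, seed = as.integer(seed)
  ), class = "sim_params")
}

#' Preset: the compact regime used by the acceptance suite
#'
#' 6 source / 8 target clusters, 5 planted correspondences, 2,000 shared
#' orthologs, 150 markers per program with effect `exp(1.5)`, 300 cells per
#' cluster, dispersion 0.5 -- small enough for desk-scale minutes.
#'
#' @param seed integer seed.
#' @return a `sim_params` object.
#' @export
acceptance_sim_params <- function(seed = 1) {
  sim_params(
    n_source_clusters = 6, n_target_clusters = 8,
    correspondence = data.frame(
      source = paste0("ms", 1:5), target = paste0("ht", 1:5),
      stringsAsFactors = FALSE
    ),
    n_shared_orthologs = 2000, markers_per_program = 150,
    theta = exp(1.5), cells_per_cluster = 300, dispersion = 0.5,
    seed = seed
  )
}

#' Preset: the analyzed datasets' shape (10 x 18 clusters, 6,146 / 12,073 cells)
#'
#' Intended for manual runs; substantially heavier than the acceptance
#' regime.
#'
#' @param seed integer seed.
#' @return a `sim_params` object.
#' @export
paper_shape_params <- function(seed = 1) {
  sim_params(
    n_source_clusters = 10, n_target_clusters = 18,
    total_cells = c(6146, 12073), seed = seed
  )
}

split_total <- function(total, k) {
  base <- total %/% k
  n <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
  n
}

gen_species_counts <- function(lambda, marker_rows, cluster_ids, n_per_cluster,
                               theta, phi, lib_sdlog, gene_names, prefix) {
  G <- length(lambda)
  blocks <- vector("list", length(cluster_ids))
  cell_names <- character(0)
  labels <- character(0)
  for (j in seq_along(cluster_ids)) {
    nc <- n_per_cluster[j]
    mu_g <- lambda
    mr <- marker_rows[[cluster_ids[j]]]
    if (length(mr)) mu_g[mr] <- mu_g[mr] * theta
    ell <- rlnorm(nc, 0, lib_sdlog)
    M <- matrix(
      rnbinom(G * nc, mu = rep(mu_g, nc) * rep(ell, each = G), size = 1 / phi),
      nrow = G, ncol = nc
    )
    blocks[[j]] <- as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix")
    cell_names <- c(cell_names, sprintf("%s_%s_c%04d", prefix, cluster_ids[j], seq_len(nc)))
    labels <- c(labels, rep(cluster_ids[j], nc))
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- gene_names
  colnames(counts) <- cell_names
  list(counts = counts, cells = cell_names, labels = labels)
}

#' Generate paired source/target datasets with planted correspondences
#'
#' Each gene's baseline mean is log-normal and shared between ortholog
#' partners; a cell of cluster `c` draws
#' `x ~ NB(mean = lib * lambda_g * theta^[g in program(c)], dispersion phi)`.
#' Source cluster `j` owns marker program `j` (a block of shared ortholog
#' genes); target clusters named in the correspondence express their source
#' partner's program through the ortholog pairing, the remaining target
#' clusters express fresh programs from the shared pool. The ortholog table
#' covers exactly the shared genes plus a configurable fraction of decoy
#' one-to-many pairs into the target's private genes.
#'
#' @param params a [sim_params()] object.
#' @return list with `source` and `target` (each `counts` = [count_matrix()],
#'   `labels` = [cluster_labels()]), `orthologs` ([ortholog_table()]), and
#'   `truth` (correspondence, per-program marker lists in both namespaces,
#'   realized parameters, seed).
#' @export
generate_paired_datasets <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    go <- p$n_shared_orthologs
    gp <- p$n_private_genes
    mg <- sprintf("mOG%05d", seq_len(go))
    hg <- sprintf("hOG%05d", seq_len(go))
    mpriv <- if (gp) sprintf("mPV%04d", seq_len(gp)) else character(0)
    hpriv <- if (gp) sprintf("hPV%04d", seq_len(gp)) else character(0)

    lambda_shared <- rlnorm(go, p$baseline_meanlog, p$baseline_sdlog)
    lambda_ps <- if (gp) rlnorm(gp, p$baseline_meanlog, p$baseline_sdlog) else numeric(0)
    lambda_pt <- if (gp) rlnorm(gp, p$baseline_meanlog, p$baseline_sdlog) else numeric(0)

    ## program blocks over the shared pool: one per source cluster, then one
    ## per unmatched target cluster
    m <- p$markers_per_program
    unmatched_t <- setdiff(p$target_ids, p$correspondence$target)
    prog_owner <- c(p$source_ids, unmatched_t)
    prog_rows <- lapply(seq_along(prog_owner), function(i) ((i - 1) * m + 1):(i * m))
    names(prog_rows) <- prog_owner

    src_marker_rows <- prog_rows[p$source_ids]
    tgt_marker_rows <- stats::setNames(vector("list", p$n_target_clusters), p$target_ids)
    for (tc in p$target_ids) {
      sc <- p$correspondence$source[p$correspondence$target == tc]
      tgt_marker_rows[[tc]] <- if (length(sc)) prog_rows[[sc]] else prog_rows[[tc]]
    }

    nsrc <- if (!is.null(p$total_cells)) {
      split_total(p$total_cells[1], p$n_source_clusters)
    } else {
      rep(p$cells_per_cluster[1], p$n_source_clusters)
    }
    ntgt <- if (!is.null(p$total_cells)) {
      split_total(p$total_cells[2], p$n_target_clusters)
    } else {
      rep(p$cells_per_cluster[2], p$n_target_clusters)
    }

    src <- gen_species_counts(
      c(lambda_shared, lambda_ps), src_marker_rows, p$source_ids, nsrc,
      p$theta, p$dispersion, p$lib_sdlog, c(mg, mpriv), "src"
    )
    tgt <- gen_species_counts(
      c(lambda_shared, lambda_pt), tgt_marker_rows, p$target_ids, ntgt,
      p$theta, p$dispersion, p$lib_sdlog, c(hg, hpriv), "tgt"
    )

    osrc <- mg
    otgt <- hg
    nd <- floor(p$decoy_frac * go)
    if (nd > 0 && gp > 0) {
      osrc <- c(osrc, sample(mg, nd))
      otgt <- c(otgt, sample(hpriv, nd, replace = TRUE))
    }

    truth <- list(
      correspondence = p$correspondence,
      markers_source = lapply(src_marker_rows, function(r) mg[r]),
      markers_target = lapply(tgt_marker_rows, function(r) hg[r]),
      params = unclass(p)[setdiff(names(unclass(p)), c("correspondence"))],
      seed = p$seed
    )

    list(
      source = list(
        counts = count_matrix(src$counts, species = "source"),
        labels = cluster_labels(src$cells, src$labels)
      ),
      target = list(
        counts = count_matrix(tgt$counts, species = "target"),
        labels = cluster_labels(tgt$cells, tgt$labels)
      ),
      orthologs = ortholog_table(osrc, otgt),
      truth = truth
    )
  })
}

#' Write a simulated paired dataset to a directory
#'
#' Emits exactly the file set the pipeline consumes (MTX + sidecars + label
#' TSVs per species, ortholog TSV) plus `truth.json`.
#'
#' @param sim result of [generate_paired_datasets()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    source_mtx = file.path(dir, "source_counts.mtx"),
    source_genes = file.path(dir, "source_genes.tsv"),
    source_cells = file.path(dir, "source_cells.tsv"),
    source_labels = file.path(dir, "source_labels.tsv"),
    target_mtx = file.path(dir, "target_counts.mtx"),
    target_genes = file.path(dir, "target_genes.tsv"),
    target_cells = file.path(dir, "target_cells.tsv"),
    target_labels = file.path(dir, "target_labels.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_count_matrix(sim$source$counts, paths["source_mtx"], paths["source_genes"], paths["source_cells"])
  write_cluster_labels(sim$source$labels, paths["source_labels"])
  write_count_matrix(sim$target$counts, paths["target_mtx"], paths["target_genes"], paths["target_cells"])
  write_cluster_labels(sim$target$labels, paths["target_labels"])
  write_ortholog_table(sim$orthologs, paths["orthologs"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
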