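#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one serializable object. The
#' defaults reproduce the study settings: chips scaled to mean 150, two-fold
#' kinetic filter, agreement level delta = 0.7, trivial-cluster p-value
#' 0.05, EASE enrichment threshold 1e-3 and wave pivot at day 3. The
#' remaining entries (K* scan range, permutation count, base-method
#' settings) are implementation parameters with documented defaults.
#'
#' @param target_mean chip scaling target
#' @param fold_threshold kinetic filter fold threshold
#' @param k_range candidate cluster numbers for the K* scan
#' @param delta minimum pairwise agreement within a consensus cluster
#' @param p_value trivial-cluster significance threshold
#' @param n_permutations permutation draws for the trivial-cluster screen
#' @param alpha EASE enrichment threshold
#' @param rules wave classification rules, see [wave_rules()]
#' @param seed master seed; every stochastic stage derives its stream from
#'   it
#' @param fanny_memb_exp fuzzifier of the fuzzy medoid method (fanny);
#'   values near 2 collapse to uniform memberships on raw intensity scales,
#'   hence the 1.5 default
#' @param cmeans_m fuzzifier of fuzzy c-means
#' @param kmeans_nstart random restarts for k-means
#' @param som_epochs training epochs of the 1-by-k self-organizing map
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(target_mean = 150,
                            fold_threshold = 2,
                            k_range = 2:12,
                            delta = 0.7,
                            p_value = 0.05,
                            n_permutations = 1000,
                            alpha = 1e-3,
                            rules = wave_rules(),
                            seed = 1,
                            fanny_memb_exp = 1.5,
                            cmeans_m = 2,
                            kmeans_nstart = 10,
                            som_epochs = 20) {
  if (delta <= 0 || delta > 1) stop("'delta' must lie in (0, 1]")
  if (p_value <= 0 || p_value >= 1) stop("'p_value' must lie in (0, 1)")
  structure(list(target_mean = target_mean, fold_threshold = fold_threshold,
                 k_range = k_range, delta = delta, p_value = p_value,
                 n_permutations = n_permutations, alpha = alpha,
                 rules = rules, seed = seed,
                 fanny_memb_exp = fanny_memb_exp, cmeans_m = cmeans_m,
                 kmeans_nstart = kmeans_nstart, som_epochs = som_epochs),
            class = "pipeline_config")
}

#' Run the full kinetic consensus-clustering pipeline
#'
#' Executes the whole analysis on a raw replicate-level matrix: chip scaling
#' to a common mean, replicate averaging, the two-fold kinetic filter, the
#' K* scan, the twelve-method base ensemble at K*, the agreement matrix,
#' delta-constrained consensus agglomeration, the trivial-cluster screen,
#' and kinetic-wave annotation of the surviving clusters. Cluster ids in the
#' result are renumbered so that waves appear in their temporal order
#' (early down, transient, early up, late up) and, within a wave, clusters
#' follow their smallest probe index — mirroring the 1..12 numbering
#' convention of kinetic cluster tables. Optional stages run when their
#' inputs are given: EASE enrichment against `gene_sets`, and differential
#' calling plus the overlap contingency test for a paired `treatment`
#' experiment.
#'
#' @param raw replicate-level [tc_matrix()]
#' @param config a [pipeline_config()]
#' @param gene_sets optional [gene_set_collection()]
#' @param treatment optional list with `control` and `treated`
#'   [tc_matrix()] objects (e.g. from [generate_treatment_experiment()])
#' @param overlap_universe gene universe size for the overlap test
#'   (defaults to the number of distinct genes on the input matrix)
#' @param out_dir optional directory; when given, every stage output and a
#'   run manifest (settings, seed, stage counts) are written as TSV
#' @return object of class `kinwave_result`; see Details
#' @details The result bundles: `config`; `counts` (probes in, kept,
#'   clustered, unassigned); `k_star` and `k_scores`; `ensemble_provenance`
#'   and `dropped`; `agreement` (the agreement matrix); `labels` (final
#'   cluster id per filtered probe, `NA` = unassigned); `trivial_removed`;
#'   `waves`, `profiles` and `report` from [annotate_waves()]; `table` (the
#'   probe/gene/cluster/wave assignment table with raw averaged values);
#'   optionally `enrichment`, `differential`, `responsive`, `overlap` and
#'   `cluster_response`.
#' @export
run_pipeline <- function(raw, config = pipeline_config(), gene_sets = NULL,
                         treatment = NULL, overlap_universe = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(raw, "tc_matrix"))
  scaled <- scale_chips(raw, config$target_mean)
  averaged <- if (is.null(tc_replicates(scaled))) scaled
              else average_replicates(scaled)
  filt <- kinetic_filter(averaged, config$fold_threshold)
  x <- filt$matrix
  message(sprintf("kinetic filter: %d of %d probes kept", nrow(x),
                  nrow(averaged)))
  k_range <- config$k_range[config$k_range <= nrow(x) - 1 &
                              config$k_range >= 2]
  if (length(k_range) == 0) stop("no admissible k in 'k_range'")
  ks <- select_k_star(x, k_range, seed = config$seed, config = config)
  message(sprintf("K* scan: k* = %d", ks$k_star))
  ens <- run_base_clusterers(x, ks$k_star, seed = config$seed,
                             config = config)
  am <- build_agreement_matrix(ens)
  raw_labels <- consensus_agglomerate(am, config$delta)
  triv <- remove_trivial_clusters(raw_labels, am, config$p_value,
                                  config$n_permutations,
                                  seed = child_seed(config$seed, 99L))
  labels <- triv$labels
  message(sprintf("consensus: %d clusters before screen, %d after",
                  length(unique(raw_labels)),
                  length(unique(labels[!is.na(labels)]))))

  if (all(is.na(labels))) {
    warning("no significant cluster survived the trivial-cluster screen",
            call. = FALSE)
    ann <- NULL
  } else {
    ann <- annotate_waves(x, labels, rules = config$rules)
    # renumber clusters: wave temporal order first, smallest member within
    wave_rank <- match(ann$waves, c(wave_levels(), "none"))
    first_idx <- vapply(as.integer(rownames(ann$profiles)),
                        function(cl) min(which(labels == cl)), 0L)
    new_of_old <- order(order(wave_rank, first_idx))
    old_ids <- as.integer(rownames(ann$profiles))
    relab <- rep(NA_integer_, length(labels))
    for (i in seq_along(old_ids))
      relab[!is.na(labels) & labels == old_ids[i]] <- new_of_old[i]
    names(relab) <- names(labels)
    labels <- relab
    ann <- annotate_waves(x, labels, rules = config$rules)
  }

  tab <- data.frame(probe_id = rownames(x), gene_symbol = tc_genes(x),
                    cluster = unname(labels),
                    wave = ifelse(is.na(labels), NA_character_,
                                  unname(ann$waves[as.character(labels)])),
                    tc_values(x), check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)

  counts <- list(probes_in = nrow(raw), probes_kept = nrow(x),
                 probes_clustered = sum(!is.na(labels)),
                 probes_unassigned = sum(is.na(labels)),
                 clusters_before_screen = length(unique(raw_labels)),
                 clusters_significant =
                   length(unique(labels[!is.na(labels)])))

  res <- list(config = config, counts = counts, k_star = ks$k_star,
              k_scores = ks$scores, ensemble_provenance = ens$provenance,
              dropped = ens$dropped, agreement = am, labels = labels,
              trivial_removed = triv$trivial_removed,
              waves = if (is.null(ann)) NULL else ann$waves,
              profiles = if (is.null(ann)) NULL else ann$profiles,
              report = if (is.null(ann)) NULL else ann$report,
              table = tab, averaged = x)

  if (!is.null(gene_sets) && !is.null(ann)) {
    res$enrichment <- enrich_clusters(labels, tc_genes(x), gene_sets,
                                      config$alpha)
  }
  if (!is.null(treatment)) {
    calls <- call_responsive(treatment$control, treatment$treated,
                             config$fold_threshold)
    res$differential <- calls
    res$responsive <- responsive_summary(calls)
    if (!is.null(ann)) {
      res$cluster_response <- per_cluster_response_counts(
        labels, tc_genes(x), calls)
      resp_genes <- calls$gene_calls$gene_symbol[
        calls$gene_calls$direction != "unchanged"]
      clustered_genes <- unique(tc_genes(x)[!is.na(labels)])
      clustered_genes <- clustered_genes[clustered_genes != ""]
      if (is.null(overlap_universe)) {
        g <- tc_genes(treatment$control)
        overlap_universe <- length(unique(g[!is.na(g) & g != ""]))
      }
      res$overlap <- overlap_analysis(resp_genes, clustered_genes,
                                      universe = overlap_universe)
    }
  }
  res <- structure(res, class = "kinwave_result")
  if (!is.null(out_dir)) write_result_bundle(res, out_dir)
  res
}

#' @export
print.kinwave_result <- function(x, ...) {
  cat("kinetic consensus clustering result\n")
  cat(sprintf("  probes: %d in, %d kept, %d clustered, %d unassigned\n",
              x$counts$probes_in, x$counts$probes_kept,
              x$counts$probes_clustered, x$counts$probes_unassigned))
  cat(sprintf("  k* = %d; %d significant clusters (delta = %.2f, p = %.2f)\n",
              x$k_star, x$counts$clusters_significant, x$config$delta,
              x$config$p_value))
  if (!is.null(x$report)) {
    print(x$report[, c("cluster", "wave", "n_probes", "n_genes")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a cluster assignment table
#'
#' Writes the result's probe/gene/cluster/wave table (with the raw averaged
#' values appended) as TSV, the layout conventionally used for
#' supplementary cluster listings.
#'
#' @param result a `kinwave_result`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_consensus_table <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Serialize every stage of a result bundle plus a plain-text manifest.
write_result_bundle <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_consensus_table(res, file.path(dir, "clusters.tsv"))
  utils::write.table(res$k_scores, file.path(dir, "k_scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(res$agreement, check.names = FALSE),
                     file.path(dir, "agreement_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = TRUE)
  if (!is.null(res$report))
    utils::write.table(res$report, file.path(dir, "cluster_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$trivial_removed) && nrow(res$trivial_removed))
    utils::write.table(res$trivial_removed,
                       file.path(dir, "trivial_removed.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment))
    utils::write.table(res$enrichment, file.path(dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$differential))
    utils::write.table(res$differential$gene_calls,
                       file.path(dir, "differential_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cfg <- res$config
  manifest <- c(
    sprintf("target_mean=%g", cfg$target_mean),
    sprintf("fold_threshold=%g", cfg$fold_threshold),
    sprintf("k_range=%s", paste(range(cfg$k_range), collapse = ":")),
    sprintf("delta=%g", cfg$delta),
    sprintf("p_value=%g", cfg$p_value),
    sprintf("n_permutations=%d", cfg$n_permutations),
    sprintf("alpha=%g", cfg$alpha),
    sprintf("pivot_day=%g", cfg$rules$pivot_day),
    sprintf("seed=%d", cfg$seed),
    sprintf("k_star=%d", res$k_star),
    vapply(names(res$counts),
           function(n) sprintf("%s=%d", n, res$counts[[n]]), "")
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Audit an assignment table against printed counts
#'
#' Tallies a cluster assignment table of the supplementary-listing layout
#' (columns `probe_id`, `gene_symbol`, `cluster`, `wave`; extra value
#' columns ignored): probe-set and unique-gene totals overall, per cluster,
#' per wave, and for the cluster groupings conventionally reported for a
#' 12-cluster kinetic analysis (down-regulated clusters 1-6, early-down 1-3,
#' up-regulated 7-12, late-up 10-12, and the early transcriptome 1-9).
#' Blank or missing gene symbols are excluded from gene counts; probes
#' without a cluster are excluded entirely.
#'
#' @param table data frame or TSV path
#' @return list with `n_probes`, `n_genes`, `per_cluster`, `per_wave` and
#'   `groups` data frames
#' @export
audit_cluster_table <- function(table) {
  if (is.character(table)) {
    table <- utils::read.delim(table, check.names = FALSE,
                               stringsAsFactors = FALSE)
  }
  need <- c("probe_id", "gene_symbol", "cluster", "wave")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("malformed table, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- table[!is.na(table$cluster), need]
  tab$cluster <- as.integer(tab$cluster)
  gene_count <- function(g) {
    g <- g[!is.na(g) & g != ""]
    length(unique(g))
  }
  per_cluster <- do.call(rbind, lapply(sort(unique(tab$cluster)),
    function(cl) {
      sub <- tab[tab$cluster == cl, ]
      data.frame(cluster = cl, n_probes = nrow(sub),
                 n_genes = gene_count(sub$gene_symbol))
    }))
  per_wave <- do.call(rbind, lapply(unique(tab$wave), function(w) {
    sub <- tab[tab$wave == w, ]
    data.frame(wave = w, n_probes = nrow(sub),
               n_genes = gene_count(sub$gene_symbol))
  }))
  groups_def <- list(clusters_1_6 = 1:6, clusters_1_3 = 1:3,
                     clusters_7_12 = 7:12, clusters_10_12 = 10:12,
                     clusters_1_9 = 1:9)
  groups <- do.call(rbind, lapply(names(groups_def), function(g) {
    sub <- tab[tab$cluster %in% groups_def[[g]], ]
    data.frame(group = g, n_probes = nrow(sub),
               n_genes = gene_count(sub$gene_symbol))
  }))
  list(n_probes = nrow(tab), n_genes = gene_count(tab$gene_symbol),
       per_cluster = per_cluster, per_wave = per_wave, groups = groups)
}
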