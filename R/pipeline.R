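#' Run the stratification pipeline for one or more correction modes
#'
#' Orchestrates the full analysis for each requested mode: normalization
#' (identity for \code{uncorrected}, per-site or grand-mean log-ratio
#' otherwise), soft-power selection, topological-overlap module
#' detection, module expression profiles, cosine/Ward clustering of
#' tumours on module-member gene expression with silhouette-chosen k,
#' Kruskal-Wallis + Dunn tests of module expression across clusters,
#' Kruskal-Wallis + Tukey tests across primary sites, optional
#' over-representation analysis, and the per-site cluster-enrichment
#' stratification call.
#'
#' Each mode runs its own module detection (different normalizations
#' yield different co-expression structure). Clustering features are the
#' individual expression values of all module-member genes; module means
#' are used for the statistics tables.
#'
#' @param tumour,normal [expression_matrix()] objects on the
#'   \code{tpm_plus1} scale, sharing gene ids.
#' @param sheet a [sample_sheet()] covering both matrices.
#' @param modes subset of \code{c("uncorrected", "tissue", "grand")}.
#' @param net_cfg a [network_config()].
#' @param k_max upper bound of the silhouette search (default
#'   \code{min(20, n - 1)}).
#' @param pathways optional \code{pathway_collection} for ORA.
#' @param annotation optional gene annotation; when given, the
#'   protein-coding filter is applied first.
#' @param min_samples matched-cohort per-site threshold.
#' @param exclude_sites primary sites dropped regardless of counts.
#' @param alpha_ora,alpha_strat,alpha_posthoc significance thresholds.
#' @param outdir optional directory; when given, every stage's table is
#'   written under \code{outdir/<mode>/} and a run manifest is written.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a list with one element per mode, each containing
#'   \code{corrected}, \code{power}, \code{assignment}, \code{profile},
#'   \code{clusters}, \code{k}, \code{silhouette}, \code{cluster_tests},
#'   \code{site_tests}, \code{ora} (or NULL), \code{stratification};
#'   plus \code{cohort} (the matched [restrict_matched_cohort()] pair)
#'   and \code{manifest}.
#' @export
run_pipeline <- function(tumour, normal, sheet,
                         modes = c("uncorrected", "tissue", "grand"),
                         net_cfg = network_config(), k_max = NULL,
                         pathways = NULL, annotation = NULL,
                         min_samples = 20, exclude_sites = character(),
                         alpha_ora = 0.05, alpha_strat = 0.05,
                         alpha_posthoc = 0.05, outdir = NULL, seed = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  stage <- "protein_coding_filter"
  res <- withCallingHandlers({
    if (!is.null(annotation)) {
      tumour <- filter_protein_coding(tumour, annotation)$matrix
      normal <- filter_protein_coding(normal, annotation)$matrix
    }
    stage <- "matched_cohort"
    cohort <- restrict_matched_cohort(tumour, normal, sheet,
                                      min_samples = min_samples,
                                      exclude_sites = exclude_sites)
    sm <- site_mean_normal(cohort$normal, cohort$sheet)
    gm <- grand_mean_normal(cohort$normal, cohort$sheet)
    out <- list(cohort = cohort)
    for (mode in modes) {
      stage <- paste0(mode, ":normalization")
      corrected <- switch(mode,
        uncorrected = cohort$tumour,
        tissue = tissue_correct(cohort$tumour, cohort$sheet, sm),
        grand = grand_correct(cohort$tumour, gm))
      expr <- unclass(corrected)
      if (!is.null(net_cfg$top_n_variable) &&
          net_cfg$top_n_variable < nrow(expr)) {
        v <- apply(expr, 1L, stats::var)
        expr <- expr[order(-v)[seq_len(net_cfg$top_n_variable)], ,
                     drop = FALSE]
      }
      stage <- paste0(mode, ":soft_power")
      sds <- apply(expr, 1L, stats::sd)
      expr <- expr[sds > 0, , drop = FALSE]
      pw <- pick_soft_power(expr, net_cfg)
      stage <- paste0(mode, ":modules")
      tom <- compute_tom(expr, pw$power, net_cfg$sign_mode)
      assignment <- detect_modules(tom, net_cfg)
      profile <- summarize_modules(expr, assignment)
      stage <- paste0(mode, ":clustering")
      member_genes <- names(assignment)[assignment != "unassigned"]
      feat <- t(expr[member_genes, , drop = FALSE])
      d <- cosine_distance(feat)
      tree <- ward_tree(d)
      km <- if (is.null(k_max)) min(20L, nrow(d) - 1L) else k_max
      fk <- find_k(d, tree, km)
      clusters <- cut_clusters(tree, fk$k)
      stage <- paste0(mode, ":statistics")
      cl_groups <- stats::setNames(paste0("cluster", clusters),
                                   names(clusters))
      cluster_tests <- module_group_tests(profile, cl_groups,
                                          posthoc = "dunn",
                                          alpha = alpha_posthoc)
      site_of <- stats::setNames(cohort$sheet$primary_site,
                                 cohort$sheet$sample)
      site_tests <- module_group_tests(profile, site_of[colnames(profile)],
                                       posthoc = "tukey",
                                       alpha = alpha_posthoc)
      ora <- NULL
      if (!is.null(pathways)) {
        stage <- paste0(mode, ":ora")
        ora <- run_ora(assignment, pathways,
                       universe = rownames(unclass(corrected)),
                       alpha = alpha_ora)
      }
      stage <- paste0(mode, ":stratification")
      strat <- site_cluster_enrichment(clusters, cohort$sheet,
                                       alpha = alpha_strat)
      out[[mode]] <- list(corrected = corrected, power = pw,
                          assignment = assignment, profile = profile,
                          tree = tree, clusters = clusters, k = fk$k,
                          silhouette = fk$widths,
                          cluster_tests = cluster_tests,
                          site_tests = site_tests, ora = ora,
                          stratification = strat)
    }
    out
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  res$manifest <- pipeline_manifest(res, modes, net_cfg, seed)
  if (!is.null(outdir)) write_pipeline_outputs(res, modes, outdir)
  res
}

pipeline_manifest <- function(res, modes, net_cfg, seed) {
  cfg_repr <- paste(utils::capture.output(utils::str(net_cfg)),
                    collapse = "\n")
  tf <- tempfile()
  writeLines(cfg_repr, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  counts <- lapply(modes, function(m) {
    r <- res[[m]]
    c(genes = nrow(unclass(r$corrected)),
      samples = ncol(unclass(r$corrected)),
      modules = length(setdiff(unique(r$assignment), "unassigned")),
      module_genes = sum(r$assignment != "unassigned"),
      k = r$k,
      stratified_sites = sum(r$stratification$sites$stratified))
  })
  names(counts) <- modes
  list(package_version = as.character(utils::packageVersion("pancanstrat")),
       r_version = R.version.string,
       config_hash = hash, seed = seed, modes = modes, counts = counts)
}

write_pipeline_outputs <- function(res, modes, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, path) data.table::fwrite(df, path, sep = "\t")
  for (m in modes) {
    r <- res[[m]]
    d <- file.path(outdir, m)
    dir.create(d, showWarnings = FALSE)
    write_expression(r$corrected, file.path(d, "corrected_matrix.tsv"))
    wr(data.frame(gene = names(r$assignment), module = r$assignment),
       file.path(d, "module_assignment.tsv"))
    wr(data.frame(module = rownames(r$profile), r$profile,
                  check.names = FALSE),
       file.path(d, "module_profile.tsv"))
    wr(data.frame(sample = names(r$clusters),
                  cluster = as.integer(r$clusters)),
       file.path(d, "cluster_assignment.tsv"))
    writeLines(tree_newick(r$tree), file.path(d, "dendrogram.nwk"))
    wr(r$cluster_tests$omnibus, file.path(d, "kruskal_wallis_clusters.tsv"))
    wr(r$cluster_tests$pairwise, file.path(d, "dunn_clusters.tsv"))
    wr(r$site_tests$omnibus, file.path(d, "kruskal_wallis_sites.tsv"))
    wr(r$site_tests$pairwise, file.path(d, "tukey_sites.tsv"))
    if (!is.null(r$ora)) wr(r$ora, file.path(d, "ora.tsv"))
    wr(r$stratification$tests, file.path(d, "site_cluster_tests.tsv"))
    wr(r$stratification$sites, file.path(d, "stratification.tsv"))
  }
  manifest <- res$manifest
  json <- c(
    "{",
    sprintf('  "package_version": "%s",', manifest$package_version),
    sprintf('  "config_hash": "%s",', manifest$config_hash),
    sprintf('  "modes": "%s"', paste(manifest$modes, collapse = ",")),
    "}")
  writeLines(json, file.path(outdir, "manifest.json"))
  invisible(outdir)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, near 0 for independent ones. Used to score
#' recovery of planted modules and latent clusters.
#'
#' @param a,b label vectors of equal length (names ignored; order
#'   aligned).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
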