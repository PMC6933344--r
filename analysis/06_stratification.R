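#!/usr/bin/env Rscript
# The statistics battery: module expression differences across clusters
# (Kruskal-Wallis + Dunn) and across primary sites (Kruskal-Wallis +
# Tukey), then the per-site hypergeometric cluster-enrichment test and
# the stratification call (a site is stratified when over-represented in
# two or more clusters). Ends with the sites-by-mode count matrix and a
# comparison against the planted truth.

suppressPackageStartupMessages(library(pancanstrat))

out <- "results/stratification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- read_truth("results/data")
sheet <- read_sample_sheet("results/normalized/cohort_sheet.tsv")
site_of <- setNames(sheet$primary_site, sheet$sample)

reports <- list()
for (mode in c("uncorrected", "tissue", "grand")) {
  prof_df <- data.table::fread(
    file.path("results/modules", paste0(mode, "_profile.tsv")))
  prof <- as.matrix(prof_df[, -1])
  rownames(prof) <- prof_df$module
  cl_df <- data.table::fread(
    file.path("results/clusters", paste0(mode, "_clusters.tsv")))
  cl <- structure(cl_df$cluster, k = max(cl_df$cluster),
                  names = cl_df$sample, class = "cluster_assignment")

  cl_groups <- setNames(paste0("cluster", cl), names(cl))
  by_cluster <- module_group_tests(prof, cl_groups, posthoc = "dunn")
  by_site <- module_group_tests(prof, site_of[colnames(prof)],
                                posthoc = "tukey")
  strat <- site_cluster_enrichment(cl, sheet, alpha = 0.05)
  reports[[mode]] <- strat

  n_sig <- sum(by_cluster$omnibus$p <= 1e-6)
  message(sprintf(
    "%-11s %d/%d modules differ across clusters (KW p <= 1e-6); %d/%d Dunn pairs significant",
    mode, n_sig, nrow(by_cluster$omnibus),
    sum(by_cluster$pairwise$significant), nrow(by_cluster$pairwise)))

  data.table::fwrite(by_cluster$omnibus,
                     file.path(out, paste0(mode, "_kw_clusters.tsv")),
                     sep = "\t")
  data.table::fwrite(by_cluster$pairwise,
                     file.path(out, paste0(mode, "_dunn_clusters.tsv")),
                     sep = "\t")
  data.table::fwrite(by_site$omnibus,
                     file.path(out, paste0(mode, "_kw_sites.tsv")),
                     sep = "\t")
  data.table::fwrite(by_site$pairwise,
                     file.path(out, paste0(mode, "_tukey_sites.tsv")),
                     sep = "\t")
  data.table::fwrite(strat$tests,
                     file.path(out, paste0(mode, "_site_cluster_tests.tsv")),
                     sep = "\t")
  data.table::fwrite(strat$sites,
                     file.path(out, paste0(mode, "_stratification.tsv")),
                     sep = "\t")
}

mat <- stratification_matrix(reports)
message("enriched-cluster counts (sites x modes):")
for (s in rownames(mat))
  message(sprintf("  %-8s %s", s, paste(mat[s, ], collapse = "  ")))
data.table::fwrite(data.frame(site = rownames(mat), mat),
                   file.path(out, "stratification_matrix.tsv"), sep = "\t")

called <- reports$tissue$sites
agree <- identical(
  called$stratified[match(truth$sites$site, called$site)],
  truth$sites$stratified)
message("tissue-corrected stratification calls match planted truth: ",
        agree)
message("stratification tables written under ", out)
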