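#!/usr/bin/env Rscript
# Cluster tumours on the expression of module-member genes: cosine
# distance, Ward agglomeration, k chosen by maximal average silhouette
# width. Scores recovered clusters against the planted latent clusters.

suppressPackageStartupMessages(library(pancanstrat))

nrm <- "results/normalized"
mod <- "results/modules"
out <- "results/clusters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- read_truth("results/data")
srcs <- c(uncorrected = "uncorrected.tsv", tissue = "tissue_corrected.tsv",
          grand = "grand_corrected.tsv")
scales <- c(uncorrected = "tpm_plus1", tissue = "log_ratio",
            grand = "log_ratio")

for (mode in names(srcs)) {
  expr <- as.matrix(read_expression(file.path(nrm, srcs[[mode]]),
                                    declared_scale = scales[[mode]]))
  asg <- data.table::fread(file.path(mod, paste0(mode, "_assignment.tsv")))
  members <- asg$gene[asg$module != "unassigned"]
  feat <- t(expr[members, , drop = FALSE])
  d <- cosine_distance(feat)
  tree <- ward_tree(d)
  fk <- find_k(d, tree)
  cl <- cut_clusters(tree, fk$k)
  ari <- adjusted_rand_index(as.integer(cl),
                             truth$clusters[names(cl)])
  message(sprintf(
    "%-11s k = %d (mean silhouette %.3f) | ARI vs latent clusters %.3f",
    mode, fk$k, max(fk$widths), ari))
  data.table::fwrite(data.frame(sample = names(cl),
                                cluster = as.integer(cl)),
                     file.path(out, paste0(mode, "_clusters.tsv")),
                     sep = "\t")
  data.table::fwrite(data.frame(k = as.integer(names(fk$widths)),
                                mean_silhouette = unname(fk$widths)),
                     file.path(out, paste0(mode, "_silhouette.tsv")),
                     sep = "\t")
  writeLines(tree_newick(tree),
             file.path(out, paste0(mode, "_dendrogram.nwk")))
}
message("cluster tables written under ", out)
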