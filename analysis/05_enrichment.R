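#!/usr/bin/env Rscript
# Functional annotation of detected modules by over-representation
# analysis against the pathway collection (hypergeometric upper tail,
# Benjamini-Hochberg per module), with all analysed protein-coding genes
# as the reference universe.

suppressPackageStartupMessages(library(pancanstrat))

mod <- "results/modules"
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pathways <- read_gmt("results/data/pathways.gmt")

for (mode in c("uncorrected", "tissue", "grand")) {
  asg_df <- data.table::fread(file.path(mod, paste0(mode,
                                                    "_assignment.tsv")))
  asg <- structure(setNames(asg_df$module, asg_df$gene),
                   class = "module_assignment")
  res <- run_ora(asg, pathways, universe = asg_df$gene, alpha = 0.05)
  hits <- res[res$significant, ]
  message(sprintf(
    "%-11s %d significant (module, pathway) pairs; planted pathways hit: %d",
    mode, nrow(hits), sum(grepl("^planted", hits$pathway_id))))
  data.table::fwrite(res, file.path(out, paste0(mode, "_ora.tsv")),
                     sep = "\t")
}
message("enrichment tables written under ", out)
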