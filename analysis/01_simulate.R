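#!/usr/bin/env Rscript
# Simulate the study cohort: four primary sites with matched tumour and
# normal samples, three planted co-expression modules whose activation
# differs across four latent tumour clusters, and two sites whose tumours
# split across clusters (the ground-truth "stratified" sites). Writes the
# cohort in the pipeline's input dialects plus the ground truth.

suppressPackageStartupMessages(library(pancanstrat))

out <- "results/data"
cfg <- generator_config(seed = 1)
co <- generate_cohort(cfg)

paths <- write_cohort(co, out)
write_truth(co$truth, out)
write_gmt(synthetic_pathways(co$truth, n_random = 10, seed = 1),
          file.path(out, "pathways.gmt"))
# annotation: all simulated genes are protein-coding entries
data.table::fwrite(
  data.frame(gene_id = rownames(co$tumour), biotype = "protein_coding"),
  file.path(out, "annotation.tsv"), sep = "\t")

message(sprintf("cohort: %d genes x %d tumours + %d normals across %d sites",
                nrow(co$tumour), ncol(co$tumour), ncol(co$normal),
                length(cfg$sites)))
message(sprintf("planted: %d module genes in %d modules; %d latent clusters;",
                sum(co$truth$modules != "background"),
                nrow(co$truth$activation), cfg$n_clusters))
message("stratified sites: ",
        paste(co$truth$sites$site[co$truth$sites$stratified],
              collapse = ", "))
message("written under ", out)
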