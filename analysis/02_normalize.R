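#!/usr/bin/env Rscript
# Ingest the simulated cohort exactly as a Xena-dialect data set would be
# ingested (log2(TPM+1) on disk -> TPM+1 in memory), restrict to
# protein-coding genes and matched primary sites, and produce the two
# corrected matrices: tissue-corrected (per-site normal mean) and grand
# mean-corrected (unweighted mean of per-site means).

suppressPackageStartupMessages(library(pancanstrat))

dat <- "results/data"
out <- "results/normalized"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tumour <- read_expression(file.path(dat, "tumour_expression.tsv"),
                          declared_scale = "log2_tpm_plus1")
normal <- read_expression(file.path(dat, "normal_expression.tsv"),
                          declared_scale = "log2_tpm_plus1")
sheet <- read_sample_sheet(file.path(dat, "phenotype.tsv"))
ann <- read_gene_annotation(file.path(dat, "annotation.tsv"))

fc <- filter_protein_coding(tumour, ann)
message(sprintf("biotype filter: %d of %d entries retained (%.1f%% removed)",
                fc$report$retained, fc$report$total, fc$report$pct_removed))
normal <- filter_protein_coding(normal, ann)$matrix

cohort <- restrict_matched_cohort(fc$matrix, normal, sheet,
                                  min_samples = 20)
message("matched sites: ", paste(cohort$sites, collapse = ", "),
        " (", ncol(cohort$tumour), " tumours, ",
        ncol(cohort$normal), " normals)")

sm <- site_mean_normal(cohort$normal, cohort$sheet)
gm <- grand_mean_normal(cohort$normal, cohort$sheet)
lt <- tissue_correct(cohort$tumour, cohort$sheet, sm)
lg <- grand_correct(cohort$tumour, gm)

write_corrected(lt, sm, file.path(out, "tissue_corrected.tsv"))
write_corrected(lg, sm, file.path(out, "grand_corrected.tsv"))
write_expression(cohort$tumour, file.path(out, "uncorrected.tsv"))
data.table::fwrite(as.data.frame(cohort$sheet),
                   file.path(out, "cohort_sheet.tsv"), sep = "\t")

message(sprintf("tissue-corrected values span [%.2f, %.2f] ln units",
                min(as.matrix(lt)), max(as.matrix(lt))))
message("corrected matrices written under ", out)
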