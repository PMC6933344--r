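#' Restrict the expression table to protein-coding genes
#'
#' Keeps only genes positively annotated with the \code{protein_coding}
#' biotype. Genes absent from the annotation are treated as non-coding and
#' removed, mirroring a filter that retains only entries with an explicit
#' coding annotation.
#'
#' @param m an [expression_matrix()].
#' @param annotation data.frame with columns \code{gene_id},
#'   \code{biotype} (see [read_gene_annotation()]).
#' @return a list with elements \code{matrix} (the filtered
#'   [expression_matrix()]) and \code{report} (a one-row data.frame with
#'   \code{total}, \code{removed}, \code{retained}, \code{pct_removed}).
#' @export
filter_protein_coding <- function(m, annotation) {
  coding <- annotation$gene_id[annotation$biotype == "protein_coding"]
  keep <- rownames(m) %in% coding
  total <- nrow(m)
  retained <- sum(keep)
  if (retained == 0L)
    stop("empty cohort: no protein-coding genes retained")
  report <- data.frame(
    total = total,
    removed = total - retained,
    retained = retained,
    pct_removed = 100 * (total - retained) / total)
  list(matrix = expr_subset(m, genes = which(keep)), report = report)
}

#' Filter accounting for a biotype filter
#'
#' Pure bookkeeping on printed totals: given the number of input entries
#' and the number removed as non-coding, returns the retained count and
#' the removal percentage (rounded to one decimal, the precision such
#' counts are usually reported at).
#'
#' @param total total entries before filtering.
#' @param removed entries removed as non-coding.
#' @return a one-row data.frame with \code{total}, \code{removed},
#'   \code{retained}, \code{pct_removed}.
#' @export
filter_accounting <- function(total, removed) {
  stopifnot(total >= removed, removed >= 0)
  data.frame(total = total, removed = removed, retained = total - removed,
             pct_removed = round(100 * removed / total, 1))
}

#' Restrict tumour and normal matrices to matched primary sites
#'
#' Retains exactly the primary sites that have at least \code{min_samples}
#' tumour samples and at least \code{min_samples} normal samples and are
#' not explicitly excluded; all samples of dropped sites are removed from
#' both matrices. Sites of uncertain histological tumour/normal
#' equivalence (for example blood) are not decided algorithmically and are
#' passed via \code{exclude_sites}.
#'
#' @param tumour,normal [expression_matrix()] objects sharing gene ids.
#' @param sheet a [sample_sheet()] covering all columns of both matrices.
#' @param min_samples minimum per-site sample count on each side.
#' @param exclude_sites character vector of primary sites to drop
#'   regardless of counts.
#' @return a \code{cohort_pair} list: \code{tumour}, \code{normal} (column
#'   subsets), \code{sheet} (rows of retained samples), \code{sites}
#'   (ordered retained sites).
#' @export
restrict_matched_cohort <- function(tumour, normal, sheet, min_samples = 20,
                                    exclude_sites = character()) {
  stopifnot(min_samples >= 1)
  sheet <- sample_sheet(as.data.frame(sheet))
  if (!identical(rownames(tumour), rownames(normal)))
    stop("tumour and normal matrices must share identical gene ids in order")
  missing <- setdiff(c(colnames(tumour), colnames(normal)), sheet$sample)
  if (length(missing))
    stop("samples absent from sheet: ", paste(missing, collapse = ", "))
  site_of <- stats::setNames(sheet$primary_site, sheet$sample)
  t_sites <- site_of[colnames(tumour)]
  n_sites <- site_of[colnames(normal)]
  t_counts <- table(t_sites)
  n_counts <- table(n_sites)
  common <- intersect(names(t_counts), names(n_counts))
  keep_sites <- common[t_counts[common] >= min_samples &
                       n_counts[common] >= min_samples]
  keep_sites <- setdiff(keep_sites, exclude_sites)
  # preserve first-appearance order from the tumour matrix
  keep_sites <- unique(t_sites)[unique(t_sites) %in% keep_sites]
  if (length(keep_sites) == 0L)
    stop("empty cohort: no primary site meets the matched-sample threshold")
  t_keep <- colnames(tumour)[t_sites %in% keep_sites]
  n_keep <- colnames(normal)[n_sites %in% keep_sites]
  sheet_keep <- sheet[sheet$sample %in% c(t_keep, n_keep), , drop = FALSE]
  rownames(sheet_keep) <- NULL
  structure(
    list(tumour = expr_subset(tumour, samples = t_keep),
         normal = expr_subset(normal, samples = n_keep),
         sheet = sheet_keep,
         sites = keep_sites),
    class = "cohort_pair")
}

#' Read pathway gene sets in GMT format
#'
#' One pathway per line: \code{name <TAB> description <TAB> gene ids...}.
#' Duplicate member ids within a line are de-duplicated.
#'
#' @param path path to a GMT file.
#' @return a \code{pathway_collection}: named list of character member
#'   vectors, with a \code{description} attribute (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("format error in GMT line %d: expected >= 3 tab-separated fields", i))
    id <- f[[1]]
    if (id %in% names(sets))
      stop("duplicate pathway id in GMT: ", id)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("format error in GMT line %d: empty member set", i))
    sets[[id]] <- members
    descs[[id]] <- f[[2]]
  }
  structure(sets, description = descs, class = "pathway_collection")
}

#' Write pathway gene sets in GMT format
#'
#' @param pathways a \code{pathway_collection} (see [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  descs <- attr(pathways, "description")
  if (is.null(descs)) descs <- stats::setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(id)
    paste(c(id, descs[[id]], pathways[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
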