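#' Construct an expression matrix
#'
#' A dense gene-by-sample numeric matrix carrying its measurement scale.
#' Expression is ingested on the \code{log2_tpm_plus1} scale used by
#' Xena/Toil RSEM exports and converted to \code{tpm_plus1} for analysis;
#' log-ratio matrices produced by the normalization step carry the
#' \code{log_ratio} scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   row and column names set.
#' @param scale one of \code{"tpm_plus1"}, \code{"log2_tpm_plus1"},
#'   \code{"log_ratio"}.
#' @return a numeric matrix of class \code{expr_matrix} with a
#'   \code{scale} attribute.
#' @export
expression_matrix <- function(values,
                              scale = c("tpm_plus1", "log2_tpm_plus1",
                                        "log_ratio")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale == "tpm_plus1" && any(values < 1))
    stop("tpm_plus1 values must be >= 1")
  if (scale == "log2_tpm_plus1" && any(values < 0))
    stop("log2_tpm_plus1 values must be >= 0")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

expr_scale <- function(m) attr(m, "scale")

#' @export
as.matrix.expr_matrix <- function(x, ...) {
  attr(x, "scale") <- NULL
  attr(x, "mode") <- NULL
  class(x) <- NULL
  x
}

# subset an expr_matrix keeping class and scale
expr_subset <- function(m, genes = NULL, samples = NULL) {
  v <- unclass(m)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, scale = attr(m, "scale"))
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated expression table in the Xena/Toil dialect: the
#' first column holds gene identifiers, the header row holds sample
#' identifiers. Lines starting with \code{#} are treated as comments and
#' skipped. If the declared scale is \code{log2_tpm_plus1}, values are
#' converted to the TPM+1 scale via \eqn{v \mapsto 2^v} so every stored
#' value is at least 1 and downstream log-ratios are finite.
#'
#' @param path path to a tab-separated file.
#' @param declared_scale scale of the values in the file.
#' @return an [expression_matrix()]; scale \code{tpm_plus1} when the file
#'   was declared \code{log2_tpm_plus1} (converted), otherwise the
#'   declared scale.
#' @export
read_expression <- function(path,
                            declared_scale = c("log2_tpm_plus1", "tpm_plus1",
                                               "log_ratio")) {
  declared_scale <- match.arg(declared_scale)
  n_comment <- 0L
  con <- file(path, "rt")
  while (length(l <- readLines(con, n = 1L)) && startsWith(l, "#"))
    n_comment <- n_comment + 1L
  close(con)
  # fread demotes some structural problems (ragged trailing lines, early
  # stops) to warnings; a well-formed expression table produces none, so
  # any warning is treated as a format error.
  warns <- character(0)
  dt <- tryCatch(
    withCallingHandlers(
      data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                        skip = n_comment, data.table = TRUE),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(warns))
    stop("format error reading ", path, ": ", paste(warns, collapse = "; "),
         call. = FALSE)
  if (ncol(dt) < 2) stop("format error: ", path, " has no sample columns")
  ids <- as.character(dt[[1L]])
  num <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(num)) {
    bad <- which(!vapply(dt[, -1L, drop = FALSE], is.numeric, logical(1)))[1L]
    col <- colnames(dt)[-1L][bad]
    row <- which(is.na(suppressWarnings(as.numeric(dt[[bad + 1L]]))))[1L]
    stop(sprintf("parse error: non-numeric cell at row %s, column '%s'",
                 ifelse(is.na(row), "?", row), col))
  }
  rownames(num) <- ids
  if (declared_scale == "log2_tpm_plus1") {
    num <- 2^num
    return(expression_matrix(num, scale = "tpm_plus1"))
  }
  expression_matrix(num, scale = declared_scale)
}

#' Write an expression matrix as tab-separated text
#'
#' Writes in the same dialect [read_expression()] accepts (first column
#' \code{gene_id}, sample columns). Corrected matrices may carry header
#' comment lines recording the correction mode and per-site normal counts;
#' these are written as \code{#}-prefixed lines before the header.
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @param comments optional character vector written as \code{# } comment
#'   lines before the header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, comments = NULL) {
  dt <- data.table::data.table(gene_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(as.matrix(m)))
  if (length(comments)) {
    writeLines(paste0("# ", comments), path)
    data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                       col.names = TRUE)
  } else {
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a sample phenotype sheet
#'
#' Tab-separated table with required columns \code{sample},
#' \code{condition} (\code{tumour} or \code{normal}) and
#' \code{primary_site}; an optional \code{study} column is carried along.
#'
#' @param path path to a tab-separated phenotype file.
#' @return a \code{data.frame} with columns \code{sample},
#'   \code{condition}, \code{primary_site}, \code{study}.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  sample_sheet(df)
}

#' Validate a sample sheet
#'
#' @param df data.frame with columns \code{sample}, \code{condition},
#'   \code{primary_site} and optionally \code{study}.
#' @return the validated data.frame (class \code{sample_sheet} prepended).
#' @export
sample_sheet <- function(df) {
  req <- c("sample", "condition", "primary_site")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet lacks required column(s): ", paste(miss, collapse = ", "))
  if (!"study" %in% names(df)) df$study <- NA_character_
  df$sample <- as.character(df$sample)
  df$condition <- as.character(df$condition)
  df$primary_site <- as.character(df$primary_site)
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in sample sheet")
  if (any(!nzchar(df$condition)) || any(is.na(df$condition)))
    stop("condition must be non-empty for every sample")
  if (!all(df$condition %in% c("tumour", "normal")))
    stop("condition must be 'tumour' or 'normal'")
  if (any(!nzchar(df$primary_site)) || any(is.na(df$primary_site)))
    stop("primary_site must be non-empty for every sample")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a gene annotation table
#'
#' Tab-separated table with columns \code{gene_id} and \code{biotype}
#' (one biotype per gene).
#'
#' @param path path to a tab-separated annotation file.
#' @return a \code{data.frame} with columns \code{gene_id}, \code{biotype}.
#' @export
read_gene_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!all(c("gene_id", "biotype") %in% names(df)))
    stop("annotation requires columns gene_id, biotype")
  if (anyDuplicated(df$gene_id))
    stop("annotation assigns more than one biotype to a gene")
  df$gene_id <- as.character(df$gene_id)
  df$biotype <- as.character(df$biotype)
  df
}
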