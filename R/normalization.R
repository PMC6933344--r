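#' Per-site mean normal expression
#'
#' For every gene and every primary site, the arithmetic mean of the
#' normal samples of that site on the TPM+1 scale,
#' \deqn{\hat G_{i,l} = \frac{1}{m_l} \sum_{k=1}^{m_l} Y_{i,k,l},}
#' where \eqn{m_l} is the number of normal samples at site \eqn{l}.
#'
#' @param normal an [expression_matrix()] of normal samples on the
#'   \code{tpm_plus1} scale.
#' @param sheet a [sample_sheet()] giving each normal sample's site.
#' @return a \code{site_means} list: \code{means} (genes x sites matrix,
#'   TPM+1 scale) and \code{n} (named integer, normal samples per site).
#' @export
site_mean_normal <- function(normal, sheet) {
  if (expr_scale(normal) != "tpm_plus1")
    stop("normal matrix must be on the tpm_plus1 scale")
  sheet <- sample_sheet(as.data.frame(sheet))
  site_of <- stats::setNames(sheet$primary_site, sheet$sample)
  missing <- setdiff(colnames(normal), names(site_of))
  if (length(missing))
    stop("normal samples without a site label: ",
         paste(missing, collapse = ", "))
  sites <- site_of[colnames(normal)]
  site_levels <- unique(sites)
  m_l <- vapply(site_levels, function(s) sum(sites == s), integer(1))
  if (any(m_l == 0L))
    stop("site with zero normal samples: ",
         paste(site_levels[m_l == 0L], collapse = ", "))
  means <- vapply(site_levels, function(s)
    rowMeans(unclass(normal)[, sites == s, drop = FALSE]),
    numeric(nrow(normal)))
  means <- matrix(means, nrow = nrow(normal),
                  dimnames = list(rownames(normal), site_levels))
  structure(list(means = means, n = stats::setNames(m_l, site_levels)),
            class = "site_means")
}

#' Tissue-corrected expression
#'
#' Natural-log ratio of each tumour sample's TPM+1 expression over the
#' mean normal TPM+1 expression of the same gene at the tumour's own
#' primary site:
#' \deqn{L^{tissue}_{i,j,l} = \ln\!\left(X_{i,j,l} / \hat G^{tissue}_{i,l}\right).}
#' Because both numerator and denominator are at least 1 on the TPM+1
#' scale, the output is always finite.
#'
#' @param tumour an [expression_matrix()] of tumour samples on the
#'   \code{tpm_plus1} scale.
#' @param sheet a [sample_sheet()] giving each tumour sample's site.
#' @param sm a \code{site_means} object from [site_mean_normal()].
#' @return an [expression_matrix()] on the \code{log_ratio} scale with a
#'   \code{mode = "tissue"} attribute.
#' @export
tissue_correct <- function(tumour, sheet, sm) {
  if (expr_scale(tumour) != "tpm_plus1")
    stop("tumour matrix must be on the tpm_plus1 scale")
  if (!identical(rownames(tumour), rownames(sm$means)))
    stop("gene ids of tumour matrix and site means differ")
  sheet <- sample_sheet(as.data.frame(sheet))
  site_of <- stats::setNames(sheet$primary_site, sheet$sample)
  sites <- site_of[colnames(tumour)]
  bad <- unique(sites[!(sites %in% colnames(sm$means))])
  if (length(bad))
    stop("tumour site(s) missing from site means: ",
         paste(bad, collapse = ", "))
  out <- log(unclass(tumour) / sm$means[, sites, drop = FALSE])
  dimnames(out) <- dimnames(tumour)
  res <- expression_matrix(out, scale = "log_ratio")
  attr(res, "mode") <- "tissue"
  res
}

#' Grand mean normal expression
#'
#' The per-gene unweighted mean across primary sites of the per-site mean
#' normal expression,
#' \deqn{\hat G^{grand}_i = \frac{1}{t} \sum_{l=1}^{t} \frac{1}{m_l}
#'   \sum_{k} Y_{i,k,l},}
#' which is a mean of site means, \emph{not} the pooled mean over all
#' normal samples: each site contributes equally regardless of its sample
#' count.
#'
#' @inheritParams site_mean_normal
#' @return a \code{grand_means} list: \code{mean} (named numeric per gene,
#'   TPM+1 scale) and \code{t} (number of sites averaged).
#' @export
grand_mean_normal <- function(normal, sheet) {
  sm <- site_mean_normal(normal, sheet)
  structure(list(mean = rowMeans(sm$means), t = ncol(sm$means)),
            class = "grand_means")
}

#' Grand-mean-corrected expression
#'
#' Natural-log ratio of tumour TPM+1 expression over the grand mean of
#' per-site normal means, \deqn{L^{grand}_{i,j} = \ln(C_{i,j} / \hat
#' G^{grand}_i).} Site-independent: two tumours with identical expression
#' receive identical corrected values regardless of primary site.
#'
#' @param tumour an [expression_matrix()] on the \code{tpm_plus1} scale.
#' @param gm a \code{grand_means} object from [grand_mean_normal()].
#' @return an [expression_matrix()] on the \code{log_ratio} scale with a
#'   \code{mode = "grand"} attribute.
#' @export
grand_correct <- function(tumour, gm) {
  if (expr_scale(tumour) != "tpm_plus1")
    stop("tumour matrix must be on the tpm_plus1 scale")
  if (!identical(rownames(tumour), names(gm$mean)))
    stop("gene ids of tumour matrix and grand means differ")
  out <- log(unclass(tumour) / gm$mean)
  dimnames(out) <- dimnames(tumour)
  res <- expression_matrix(out, scale = "log_ratio")
  attr(res, "mode") <- "grand"
  res
}

#' Write a corrected matrix with provenance comments
#'
#' Same dialect as [write_expression()], with header comments recording
#' the correction mode, the number of sites and the per-site normal
#' sample counts.
#'
#' @param m a corrected [expression_matrix()] (\code{log_ratio} scale).
#' @param sm the \code{site_means} used for the correction.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corrected <- function(m, sm, path) {
  comments <- c(
    paste0("mode=", attr(m, "mode")),
    paste0("t=", length(sm$n)),
    paste0("m_l ", paste(names(sm$n), sm$n, sep = "=", collapse = " ")))
  write_expression(m, path, comments = comments)
}
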