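#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the chance
#' of drawing at least k marked items in n draws without replacement from
#' a universe of N items of which K are marked. Computed via
#' [stats::phyper()], which evaluates the exact tail sum stably in log
#' space for large N.
#'
#' @param N universe size.
#' @param K marked items in the universe (e.g. pathway size).
#' @param n draws (e.g. gene-list size).
#' @param k observed overlap.
#' @return the upper-tail probability, in (0, 1].
#' @export
hypergeom_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("impossible configuration: k > min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False discovery rate adjustment
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, m\, p_{(j)} / j)} over the
#' sorted p values, returned in the input order. Thin validated wrapper
#' over [stats::p.adjust()].
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of modules against pathways
#'
#' For every (module, pathway) pair, the upper-tail hypergeometric p of
#' the overlap between the module's genes and the pathway's members,
#' counted after intersecting both with the reference universe (all
#' protein-coding genes of the analysis). Benjamini-Hochberg correction
#' is applied per module across its pathway family.
#'
#' @param modules a \code{module_assignment} (see [detect_modules()]);
#'   \code{"unassigned"} genes are ignored.
#' @param pathways a \code{pathway_collection} (see [read_gmt()]).
#' @param universe character vector of reference gene ids.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return a data.frame with one row per (module, pathway): \code{module},
#'   \code{pathway_id}, \code{description}, \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{p}, \code{p_adjusted}, \code{significant}.
#' @export
run_ora <- function(modules, pathways, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  descs <- attr(pathways, "description")
  if (is.null(descs)) descs <- stats::setNames(names(pathways), names(pathways))
  mods <- setdiff(unique(modules), "unassigned")
  N <- length(universe)
  res <- lapply(mods, function(m) {
    genes <- intersect(names(modules)[modules == m], universe)
    n <- length(genes)
    rows <- lapply(names(pathways), function(pw) {
      members <- intersect(pathways[[pw]], universe)
      K <- length(members)
      k <- length(intersect(genes, members))
      data.frame(module = m, pathway_id = pw, description = descs[[pw]],
                 N = N, K = K, n = n, k = k,
                 p = hypergeom_tail(N, K, n, k))
    })
    tab <- do.call(rbind, rows)
    tab$p_adjusted <- bh_adjust(tab$p)
    tab
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$significant <- out$p_adjusted <= alpha
  out
}
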