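#' Network detection configuration
#'
#' Parameters of the weighted co-expression network and module cut.
#' Defaults follow common practice for weighted correlation networks:
#' unsigned adjacency, soft powers 1--20 scanned against a scale-free
#' topology fit target of R^2 = 0.85 with fallback power 6, static cut of
#' the average-linkage tree of 1 - TOM at height 0.99, and a minimum
#' module size of 30 genes (smaller branches are left unassigned).
#'
#' @param powers ordered integer vector of candidate soft powers.
#' @param rsq_target scale-free topology fit target in [0, 1].
#' @param fallback_power power used when no candidate reaches the target;
#'   must be one of \code{powers}.
#' @param sign_mode \code{"unsigned"} (adjacency |cor|^beta) or
#'   \code{"signed"} (((1 + cor)/2)^beta).
#' @param min_module_size smallest branch kept as a module (>= 2).
#' @param cut_height static tree-cut height on the 1 - TOM dissimilarity,
#'   in (0, 1].
#' @param top_n_variable optional: keep only the top-N genes by variance
#'   before network construction (NULL = all genes).
#' @return a \code{network_config} list.
#' @export
network_config <- function(powers = 1:20, rsq_target = 0.85,
                           fallback_power = 6,
                           sign_mode = c("unsigned", "signed"),
                           min_module_size = 30, cut_height = 0.99,
                           top_n_variable = NULL) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(all(powers >= 1), rsq_target >= 0, rsq_target <= 1,
            fallback_power %in% powers,
            min_module_size >= 2,
            cut_height > 0, cut_height <= 1)
  structure(list(powers = as.integer(powers), rsq_target = rsq_target,
                 fallback_power = as.integer(fallback_power),
                 sign_mode = sign_mode,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, top_n_variable = top_n_variable),
            class = "network_config")
}

# soft-thresholded adjacency from the gene x sample matrix
adjacency_matrix <- function(expr, power, sign_mode = "unsigned") {
  expr <- unclass(expr)
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene row(s): ",
         paste(rownames(expr)[sds == 0], collapse = ", "))
  r <- stats::cor(t(expr))
  a <- if (sign_mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 0
  a
}

# scale-free topology fit of a connectivity vector: R^2 of the log-log
# regression of binned frequency on mean connectivity, negated when the
# slope is positive (a scale-free network has a negative slope).
scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(rsq = 0, slope = NA_real_))
  bins <- cut(k, breaks = n_breaks)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  x <- log10(mean_k[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  if (length(x) < 3) return(list(rsq = 0, slope = NA_real_))
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  rsq <- summary(fit)$r.squared
  list(rsq = -sign(slope) * rsq, slope = slope)
}

#' Choose the soft-thresholding power
#'
#' Sweeps the candidate powers and returns the smallest whose scale-free
#' topology fit (signed R^2 of the log-log regression of connectivity
#' frequency on connectivity) reaches the target. Powers at which the
#' mean connectivity falls below \code{min_mean_k} are not eligible: a
#' network whose nodes average less than one neighbour is degenerate and
#' its frequency/connectivity regression can fit a line spuriously well.
#' If no eligible power reaches the target, the fallback power is
#' returned with \code{flagged = TRUE}.
#'
#' @param expr numeric genes x samples matrix (>= 10 genes, >= 4 samples).
#' @param cfg a [network_config()].
#' @param min_mean_k smallest mean connectivity at which a power is
#'   eligible (default 1).
#' @return a list: \code{power}, \code{flagged}, and \code{fits} (a
#'   data.frame of power, rsq, slope, mean_k).
#' @export
pick_soft_power <- function(expr, cfg = network_config(), min_mean_k = 1) {
  expr <- unclass(expr)
  if (nrow(expr) < 10) stop("need >= 10 genes to assess scale-free fit")
  if (ncol(expr) < 4) stop("need >= 4 samples to assess scale-free fit")
  if (all(apply(expr, 1L, stats::sd) == 0))
    stop("degenerate input: all genes constant")
  fits <- lapply(cfg$powers, function(p) {
    a <- adjacency_matrix(expr, p, cfg$sign_mode)
    k <- rowSums(a)
    f <- scale_free_fit(k)
    data.frame(power = p, rsq = f$rsq, slope = f$slope, mean_k = mean(k))
  })
  fits <- do.call(rbind, fits)
  ok <- which(fits$rsq >= cfg$rsq_target & fits$mean_k >= min_mean_k)
  if (length(ok)) {
    list(power = fits$power[ok[1L]], flagged = FALSE, fits = fits)
  } else {
    list(power = cfg$fallback_power, flagged = TRUE, fits = fits)
  }
}

#' Topological overlap matrix
#'
#' From the soft-thresholded adjacency \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}
#' (unsigned mode), the topological overlap similarity
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},}
#' with diagonal defined as 1. Symmetric with all entries in [0, 1].
#'
#' @param expr numeric genes x samples matrix with no constant rows.
#' @param power soft-thresholding power (>= 1).
#' @param sign_mode \code{"unsigned"} or \code{"signed"}.
#' @return symmetric numeric matrix of topological overlap, genes as
#'   dimnames.
#' @export
compute_tom <- function(expr, power, sign_mode = "unsigned") {
  stopifnot(power >= 1)
  a <- adjacency_matrix(expr, power, sign_mode)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  # guard against tiny asymmetries from floating point
  tom <- (tom + t(tom)) / 2
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' statically cut at \code{cfg$cut_height}. Branches smaller than the
#' minimum module size become \code{"unassigned"}; the remaining branches
#' are labelled \code{module-1}, \code{module-2}, ... by decreasing size
#' (ties broken by first gene position, so labels are deterministic).
#'
#' @param tom a topological overlap matrix from [compute_tom()].
#' @param cfg a [network_config()].
#' @return a named character vector gene -> module label (class
#'   \code{module_assignment}).
#' @export
detect_modules <- function(tom, cfg = network_config()) {
  if (!isTRUE(all.equal(tom, t(tom), tolerance = 1e-8)))
    stop("TOM must be symmetric")
  d <- 1 - tom
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(tree, h = cfg$cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= cfg$min_module_size]
  labels <- rep("unassigned", length(raw))
  names(labels) <- names(raw)
  if (length(keep)) {
    first_pos <- vapply(keep, function(b) which(raw == b)[1L], integer(1))
    ord <- keep[order(-sizes[keep], first_pos)]
    for (i in seq_along(ord))
      labels[raw == ord[i]] <- paste0("module-", i)
  }
  structure(labels, class = "module_assignment")
}

#' Mean expression of each module per sample
#'
#' The module expression profile: for every module and sample, the
#' arithmetic mean over the module's member genes of that sample's
#' expression on the analysis scale (TPM+1 for uncorrected input,
#' ln(tumour/normal) for corrected input). \code{"unassigned"} genes are
#' excluded.
#'
#' @param expr numeric genes x samples matrix (or [expression_matrix()]).
#' @param assignment a \code{module_assignment} from [detect_modules()]
#'   whose genes are all present in \code{expr}.
#' @return numeric modules x samples matrix.
#' @export
summarize_modules <- function(expr, assignment) {
  expr <- unclass(expr)
  mods <- setdiff(unique(assignment), "unassigned")
  if (length(mods) == 0L)
    stop("no assigned modules to summarize")
  # keep module-<n> numeric order when labels are the default ones
  num <- suppressWarnings(as.integer(sub("^module-", "", mods)))
  if (!anyNA(num)) mods <- mods[order(num)]
  prof <- vapply(mods, function(m) {
    genes <- names(assignment)[assignment == m]
    miss <- setdiff(genes, rownames(expr))
    if (length(miss))
      stop("module ", m, " has member genes absent from the matrix: ",
           paste(miss, collapse = ", "))
    colMeans(expr[genes, , drop = FALSE])
  }, numeric(ncol(expr)))
  t(matrix(prof, ncol = length(mods),
           dimnames = list(colnames(expr), mods)))
}
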