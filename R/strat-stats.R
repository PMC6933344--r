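# values_list helpers: the statistics battery takes a named list of
# numeric vectors, one element per group (cluster or primary site).
check_groups <- function(values, min_groups = 2) {
  if (!is.list(values) || length(values) < min_groups)
    stop("need at least ", min_groups, " groups")
  if (any(vapply(values, length, integer(1)) == 0L))
    stop("every group must be nonempty")
  if (is.null(names(values)))
    names(values) <- paste0("group", seq_along(values))
  values
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p value (g - 1 degrees of
#' freedom), via [stats::kruskal.test()]. When every observation is
#' identical the tie-correction denominator vanishes; the limit is taken
#' as "no evidence" and H = 0, p = 1 is returned.
#'
#' @param values named list of numeric vectors, one per group.
#' @return a one-row data.frame: \code{statistic}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(values) {
  values <- check_groups(values)
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)))
  if (length(unique(x)) == 1L)
    return(data.frame(statistic = 0, df = length(values) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  data.frame(statistic = unname(kt$statistic), df = unname(kt$parameter),
             p = kt$p.value)
}

#' Dunn's post hoc test for pairwise rank differences
#'
#' For each unordered pair of groups, the standardized difference of mean
#' ranks
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left[\frac{N(N+1)}{12} - \frac{\sum_s (t_s^3 - t_s)}{12(N-1)}\right]
#'     \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with ties pooled over the full sample, two-sided p from the standard
#' normal, and multiplicity adjustment across the C(g, 2) pairs.
#'
#' @param values named list of numeric vectors, one per group.
#' @param adjust multiplicity adjustment across pairs (a
#'   [stats::p.adjust()] method; default \code{"BH"}).
#' @param alpha significance threshold on the adjusted p.
#' @return a data.frame with one row per unordered pair: \code{group1},
#'   \code{group2}, \code{z}, \code{p}, \code{p_adjusted},
#'   \code{significant}.
#' @export
dunn_posthoc <- function(values, adjust = "BH", alpha = 0.05) {
  values <- check_groups(values)
  x <- unlist(values, use.names = FALSE)
  g <- rep(names(values), lengths(values))
  N <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(values), 2)
  z <- apply(pairs, 2, function(pr) {
    denom <- sqrt(var_core * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    if (denom == 0) return(0)
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / denom
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adjusted = p_adj, significant = p_adj <= alpha)
}

#' Tukey's honest significant difference across groups
#'
#' Pairwise mean comparisons with familywise error control from the
#' studentized range distribution (Tukey-Kramer form for unequal group
#' sizes), via [stats::TukeyHSD()] on a one-way [stats::aov()] fit.
#'
#' @param values named list of numeric vectors, one per group, each with
#'   at least 2 observations.
#' @param alpha significance threshold on the familywise p.
#' @return a data.frame with one row per unordered pair: \code{group1},
#'   \code{group2}, \code{diff}, \code{p_adjusted}, \code{significant}.
#' @export
tukey_hsd <- function(values, alpha = 0.05) {
  values <- check_groups(values)
  if (any(vapply(values, length, integer(1)) < 2L))
    stop("every group needs >= 2 observations")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  if (all(vapply(values, function(v) stats::var(v) == 0, logical(1))))
    stop("zero within-group variance everywhere: MSE = 0")
  fit <- stats::aov(x ~ g)
  tk <- stats::TukeyHSD(fit)$g
  pair <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  data.frame(group1 = pair[, 2], group2 = pair[, 1],
             diff = unname(tk[, "diff"]),
             p_adjusted = unname(tk[, "p adj"]),
             significant = unname(tk[, "p adj"]) <= alpha)
}

#' Module expression tested across a grouping
#'
#' Runs the Kruskal-Wallis test and a post hoc battery (Dunn for rank
#' comparisons across clusters, Tukey for mean comparisons across sites)
#' for every module profile row against a grouping of the samples.
#'
#' @param profile modules x samples matrix (see [summarize_modules()]).
#' @param groups named vector mapping sample -> group, covering the
#'   profile's samples.
#' @param posthoc \code{"dunn"} or \code{"tukey"}.
#' @param alpha post hoc significance threshold.
#' @return a list: \code{omnibus} (data.frame, one Kruskal-Wallis row per
#'   module) and \code{pairwise} (data.frame of post hoc rows with a
#'   \code{module} column).
#' @export
module_group_tests <- function(profile, groups, posthoc = c("dunn", "tukey"),
                               alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  groups <- groups[colnames(profile)]
  if (anyNA(groups)) stop("every profiled sample needs a group")
  omnibus <- NULL
  pairwise <- NULL
  for (m in rownames(profile)) {
    vals <- split(profile[m, ], as.character(groups))
    kw <- kruskal_wallis(vals)
    kw$module <- m
    omnibus <- rbind(omnibus, kw)
    ph <- if (posthoc == "dunn") dunn_posthoc(vals, alpha = alpha)
          else tukey_hsd(vals, alpha = alpha)
    ph$module <- m
    pairwise <- rbind(pairwise, ph)
  }
  list(omnibus = omnibus[, c("module", "statistic", "df", "p")],
       pairwise = pairwise[, c("module", setdiff(names(pairwise), "module"))])
}

#' Per-site cluster enrichment and the stratification call
#'
#' For every (site, cluster) pair, the upper-tail hypergeometric p of the
#' site's tumour count in the cluster (universe = all clustered tumours,
#' marked = tumours of the site, draws = cluster size). A site is called
#' stratified when its tumours are over-represented (p <= alpha) in two
#' or more clusters.
#'
#' @param clusters a \code{cluster_assignment} (see [cut_clusters()]).
#' @param sheet a [sample_sheet()] giving each clustered sample's site.
#' @param alpha per-test threshold (default 0.05).
#' @return a list: \code{tests} (data.frame site, cluster, N, K, n, k, p,
#'   enriched) and \code{sites} (data.frame site, n_enriched_clusters,
#'   stratified).
#' @export
site_cluster_enrichment <- function(clusters, sheet, alpha = 0.05) {
  sheet <- sample_sheet(as.data.frame(sheet))
  site_of <- stats::setNames(sheet$primary_site, sheet$sample)
  if (anyNA(site_of[names(clusters)]))
    stop("clustered sample(s) without a site label")
  sites <- site_of[names(clusters)]
  k_vals <- sort(unique(as.integer(clusters)))
  if (!all(seq_len(attr(clusters, "k")) %in% k_vals))
    stop("empty cluster(s): ",
         paste(setdiff(seq_len(attr(clusters, "k")), k_vals), collapse = ", "))
  N <- length(clusters)
  tests <- NULL
  for (s in unique(sites)) {
    K <- sum(sites == s)
    for (cl in k_vals) {
      n <- sum(clusters == cl)
      k <- sum(sites == s & clusters == cl)
      p <- hypergeom_tail(N, K, n, k)
      tests <- rbind(tests, data.frame(site = s, cluster = cl, N = N, K = K,
                                       n = n, k = k, p = p,
                                       enriched = p <= alpha))
    }
  }
  counts <- tapply(tests$enriched, tests$site, sum)
  site_tab <- data.frame(site = names(counts),
                         n_enriched_clusters = as.integer(counts),
                         stratified = as.integer(counts) >= 2L,
                         row.names = NULL)
  site_tab <- site_tab[match(unique(sites), site_tab$site), , drop = FALSE]
  rownames(site_tab) <- NULL
  list(tests = tests, sites = site_tab)
}

#' Sites-by-mode matrix of enriched-cluster counts
#'
#' Collates per-mode stratification reports into an integer matrix of
#' enriched-cluster counts (sites in rows, correction modes in columns).
#'
#' @param reports named list of [site_cluster_enrichment()] results, one
#'   per correction mode.
#' @return integer matrix, sites x modes.
#' @export
stratification_matrix <- function(reports) {
  sites <- unique(unlist(lapply(reports, function(r) r$sites$site)))
  out <- sapply(reports, function(r) {
    v <- stats::setNames(r$sites$n_enriched_clusters, r$sites$site)
    as.integer(v[sites])
  })
  out <- matrix(out, nrow = length(sites),
                dimnames = list(sites, names(reports)))
  out
}
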