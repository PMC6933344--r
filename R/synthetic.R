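#' Configuration for the synthetic cohort generator
#'
#' Defines a multi-site tumour/normal cohort with planted co-expression
#' modules and latent tumour clusters, on a log-normal expression model:
#' per-gene baselines (natural-log scale) with per-site deviations,
#' additive cluster-specific module activation shifts, a shared
#' per-module latent factor that induces the configured within-module
#' member correlation, and i.i.d. Gaussian noise, all exponentiated to
#' the TPM+1 scale (floored at 1).
#'
#' Default activation pattern: Helmert-style contrasts. Module m is
#' shifted up by (1.5 ln 2)/m in clusters 1..m and down by 1.5 ln 2
#' (about 2.8-fold) in cluster m + 1, so every cluster carries a
#' distinctive module signature while distinct planted modules remain
#' mutually uncorrelated across the cohort (the contrasts are orthogonal
#' under equally occupied clusters).
#'
#' Sites listed in \code{stratified_sites} have their tumours split
#' evenly across latent clusters 1 and 2; the remaining sites are
#' assigned wholly to the later clusters (round-robin), so ground-truth
#' stratified sites occupy >= 2 clusters and unstratified sites exactly 1.
#'
#' @param seed integer seed (mandatory; the generator is fully
#'   reproducible from it).
#' @param n_sites number of primary sites.
#' @param tumours_per_site,normals_per_site per-site sample counts (the
#'   defaults satisfy the pipeline's matched-cohort threshold of 20).
#' @param n_background genes outside any module.
#' @param n_clusters latent tumour clusters.
#' @param modules list of module specs, each a list with \code{size},
#'   \code{correlation} (target within-module Pearson correlation on the
#'   log scale, in [0, 1)), and \code{activation} (numeric vector of
#'   per-cluster shifts in ln units, length \code{n_clusters}). NULL =
#'   three modules of 35 genes, correlation 0.7, default pattern above.
#' @param stratified_sites character vector of site names split across
#'   clusters (default: the first two sites).
#' @param noise_sd standard deviation of the log-scale noise.
#' @param site_sd standard deviation of per-gene per-site baseline
#'   deviations (tissue signature strength).
#' @param baseline_range range of per-gene global baselines (natural-log
#'   TPM scale).
#' @return a \code{generator_config} list.
#' @export
generator_config <- function(seed, n_sites = 4, tumours_per_site = 24,
                             normals_per_site = 24, n_background = 60,
                             n_clusters = 4, modules = NULL,
                             stratified_sites = NULL, noise_sd = 0.4,
                             site_sd = 0.2, baseline_range = c(2, 6)) {
  if (missing(seed)) stop("seed is mandatory")
  sites <- paste0("site", seq_len(n_sites))
  if (is.null(stratified_sites))
    stratified_sites <- sites[seq_len(min(2L, n_sites))]
  if (!all(stratified_sites %in% sites))
    stop("stratified_sites must be among the generated sites")
  if (is.null(modules)) {
    # Helmert-contrast activation patterns: module m contrasts cluster
    # m + 1 against clusters 1..m, scaled so the strongest shift is
    # about 2.8-fold (1.5 ln 2). Under equally occupied clusters the
    # contrasts are mutually orthogonal, so planted modules stay
    # uncorrelated with each other, and the activation variance itself
    # supplies most of the target within-module shared variance.
    M <- 3L
    s <- 1.5 * log(2)
    modules <- lapply(seq_len(M), function(m) {
      act <- numeric(n_clusters)
      if (m < n_clusters) {
        act[seq_len(m)] <- s / m
        act[m + 1L] <- -s
      }
      list(size = 35L, correlation = 0.7, activation = act)
    })
  }
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    if (mod$correlation >= 1 || mod$correlation < 0)
      stop("infeasible correlation level: must lie in [0, 1)")
    if (length(mod$activation) != n_clusters)
      stop("each module needs one activation shift per cluster")
    if (mod$size < 2) stop("module size must be >= 2")
    modules[[i]]$size <- as.integer(mod$size)
    modules[[i]]$activation <- as.numeric(mod$activation)
  }
  if (n_clusters < 1) stop("need >= 1 cluster")
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 sites = sites,
                 tumours_per_site = as.integer(tumours_per_site),
                 normals_per_site = as.integer(normals_per_site),
                 n_background = as.integer(n_background),
                 n_clusters = as.integer(n_clusters), modules = modules,
                 stratified_sites = stratified_sites, noise_sd = noise_sd,
                 site_sd = site_sd, baseline_range = baseline_range),
            class = "generator_config")
}

# latent cluster of every tumour implied by the config: stratified sites
# split evenly across clusters 1 and 2, the rest round-robin over the
# remaining clusters (or cluster n_clusters when none remain).
latent_clusters <- function(cfg) {
  out <- integer(0)
  rest <- setdiff(seq_len(cfg$n_clusters), c(1L, 2L))
  if (length(rest) == 0L) rest <- cfg$n_clusters
  ri <- 0L
  for (s in cfg$sites) {
    nt <- cfg$tumours_per_site
    if (s %in% cfg$stratified_sites) {
      cl <- rep(c(1L, min(2L, cfg$n_clusters)), length.out = nt)
      cl <- sort(cl)
    } else {
      ri <- ri + 1L
      cl <- rep(rest[(ri - 1L) %% length(rest) + 1L], nt)
    }
    out <- c(out, cl)
  }
  out
}

#' Generate a synthetic tumour/normal cohort with planted structure
#'
#' See [generator_config()] for the model. Returns matrices on the TPM+1
#' scale, a sample sheet in the pipeline's phenotype dialect, and the
#' ground truth (planted module membership, latent tumour clusters,
#' per-site stratified flags, activation matrix).
#'
#' @param cfg a [generator_config()].
#' @return a list: \code{tumour}, \code{normal}
#'   ([expression_matrix()] objects, \code{tpm_plus1}), \code{sheet}
#'   ([sample_sheet()]), \code{truth} (list \code{modules},
#'   \code{clusters}, \code{sites}, \code{activation}).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)

  M <- length(cfg$modules)
  sizes <- vapply(cfg$modules, `[[`, integer(1), "size")
  n_genes <- sum(sizes) + cfg$n_background
  genes <- sprintf("G%05d", seq_len(n_genes))
  gene_module <- rep(c(paste0("module-", seq_len(M)), "background"),
                     c(sizes, cfg$n_background))
  names(gene_module) <- genes

  n_t <- cfg$n_sites * cfg$tumours_per_site
  n_n <- cfg$n_sites * cfg$normals_per_site
  t_ids <- sprintf("T%04d", seq_len(n_t))
  n_ids <- sprintf("N%04d", seq_len(n_n))
  t_sites <- rep(cfg$sites, each = cfg$tumours_per_site)
  n_sites <- rep(cfg$sites, each = cfg$normals_per_site)
  clusters <- latent_clusters(cfg)

  baseline <- stats::runif(n_genes, cfg$baseline_range[1],
                           cfg$baseline_range[2])
  site_dev <- matrix(stats::rnorm(n_genes * cfg$n_sites, sd = cfg$site_sd),
                     nrow = n_genes,
                     dimnames = list(genes, cfg$sites))

  # activation matrix: modules x clusters, ln units
  act <- t(vapply(cfg$modules, `[[`, numeric(cfg$n_clusters), "activation"))
  rownames(act) <- paste0("module-", seq_len(M))

  # normals: baseline + site deviation + noise
  zn <- baseline + site_dev[, n_sites, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_n, sd = cfg$noise_sd), nrow = n_genes)
  dimnames(zn) <- list(genes, n_ids)

  # tumours: + cluster activation on member genes + shared module factor
  zt <- baseline + site_dev[, t_sites, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_t, sd = cfg$noise_sd), nrow = n_genes)
  dimnames(zt) <- list(genes, t_ids)
  # The configured member correlation is the realized cohort-wide
  # within-module correlation. Shared variance between two member genes
  # is Var(activation across tumours) + lambda^2; the factor picks up
  # only the part the activation does not already supply:
  # corr = S / (S + sigma^2) = rho  =>  S = sigma^2 rho / (1 - rho).
  p_cl <- tabulate(clusters, cfg$n_clusters) / n_t
  for (m in seq_len(M)) {
    rho <- cfg$modules[[m]]$correlation
    s_target <- cfg$noise_sd^2 * rho / (1 - rho)
    v_act <- sum(p_cl * act[m, ]^2) - sum(p_cl * act[m, ])^2
    lambda <- sqrt(max(0, s_target - v_act))
    members <- gene_module == paste0("module-", m)
    f <- stats::rnorm(n_t)  # one latent factor value per tumour
    shift <- act[m, clusters] + lambda * f
    zt[members, ] <- sweep(zt[members, , drop = FALSE], 2L, shift, `+`)
  }

  tumour <- expression_matrix(pmax(exp(zt), 1), scale = "tpm_plus1")
  normal <- expression_matrix(pmax(exp(zn), 1), scale = "tpm_plus1")
  sheet <- sample_sheet(data.frame(
    sample = c(t_ids, n_ids),
    condition = rep(c("tumour", "normal"), c(n_t, n_n)),
    primary_site = c(t_sites, n_sites),
    study = "synthetic"))
  truth <- list(
    modules = gene_module,
    clusters = stats::setNames(clusters, t_ids),
    sites = data.frame(site = cfg$sites,
                       stratified = cfg$sites %in% cfg$stratified_sites),
    activation = act)
  list(tumour = tumour, normal = normal, sheet = sheet, truth = truth)
}

#' Write a synthetic cohort in the pipeline's input dialects
#'
#' Expression is written on the log2(TPM+1) scale in the Xena-style
#' tab-separated dialect (so the files are valid [read_expression()]
#' input with \code{declared_scale = "log2_tpm_plus1"}), plus the
#' phenotype sheet.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tumour = file.path(dir, "tumour_expression.tsv"),
             normal = file.path(dir, "normal_expression.tsv"),
             sheet = file.path(dir, "phenotype.tsv"))
  for (side in c("tumour", "normal")) {
    m <- expression_matrix(log2(unclass(cohort[[side]])),
                           scale = "log2_tpm_plus1")
    write_expression(m, paths[[side]])
  }
  data.table::fwrite(as.data.frame(cohort$sheet), paths[["sheet"]],
                     sep = "\t")
  invisible(paths)
}

#' Write ground-truth files for a synthetic cohort
#'
#' Three tab-separated tables: \code{truth_modules.tsv} (gene, module; one
#' row per planted module gene), \code{truth_clusters.tsv} (sample,
#' cluster; one row per tumour), \code{truth_sites.tsv} (site,
#' stratified), plus \code{truth_activation.tsv} (module x cluster shift
#' matrix in ln units).
#'
#' @param truth the \code{truth} element of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  planted <- truth$modules[truth$modules != "background"]
  paths <- c(modules = file.path(dir, "truth_modules.tsv"),
             clusters = file.path(dir, "truth_clusters.tsv"),
             sites = file.path(dir, "truth_sites.tsv"),
             activation = file.path(dir, "truth_activation.tsv"))
  data.table::fwrite(data.frame(gene = names(planted), module = planted),
                     paths[["modules"]], sep = "\t")
  data.table::fwrite(data.frame(sample = names(truth$clusters),
                                cluster = truth$clusters),
                     paths[["clusters"]], sep = "\t")
  data.table::fwrite(truth$sites, paths[["sites"]], sep = "\t")
  act <- data.frame(module = rownames(truth$activation), truth$activation)
  names(act)[-1] <- paste0("cluster", seq_len(ncol(truth$activation)))
  data.table::fwrite(act, paths[["activation"]], sep = "\t")
  invisible(paths)
}

#' Read ground-truth files written by [write_truth()]
#'
#' @param dir directory containing the truth TSVs.
#' @return a truth list with \code{modules} (planted genes only),
#'   \code{clusters}, \code{sites}, \code{activation}.
#' @export
read_truth <- function(dir) {
  mods <- data.table::fread(file.path(dir, "truth_modules.tsv"))
  cls <- data.table::fread(file.path(dir, "truth_clusters.tsv"))
  sites <- as.data.frame(data.table::fread(file.path(dir, "truth_sites.tsv")))
  act <- as.data.frame(
    data.table::fread(file.path(dir, "truth_activation.tsv")))
  actm <- as.matrix(act[, -1, drop = FALSE])
  rownames(actm) <- act$module
  colnames(actm) <- NULL
  list(modules = stats::setNames(mods$module, mods$gene),
       clusters = stats::setNames(as.integer(cls$cluster), cls$sample),
       sites = sites, activation = actm)
}

#' Synthetic pathway collection matched to planted modules
#'
#' Builds a GMT-style collection in which one pathway coincides with each
#' planted module (for power checks of the over-representation analysis)
#' and additional pathways are random draws from the full gene universe
#' (for size checks).
#'
#' @param truth the \code{truth} element of [generate_cohort()].
#' @param n_random number of random pathways.
#' @param random_size genes per random pathway.
#' @param seed integer seed for the random draws.
#' @return a \code{pathway_collection} (see [read_gmt()]).
#' @export
synthetic_pathways <- function(truth, n_random = 10, random_size = 40,
                               seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  universe <- names(truth$modules)
  mods <- setdiff(unique(truth$modules), "background")
  sets <- lapply(mods, function(m) names(truth$modules)[truth$modules == m])
  names(sets) <- paste0("planted_", mods)
  for (i in seq_len(n_random))
    sets[[sprintf("random_%02d", i)]] <- sample(universe, random_size)
  descs <- stats::setNames(
    c(paste("planted module", mods), rep("random draw", n_random)),
    names(sets))
  structure(sets, description = descs, class = "pathway_collection")
}
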