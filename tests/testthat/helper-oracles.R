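# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/.

# naive O(n^3) topological overlap from an expression matrix
tom_brute <- function(expr, power) {
  r <- stats::cor(t(expr))
  a <- abs(r)^power
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      shared <- sum(a[i, ] * a[, j])
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# exact hypergeometric upper tail by direct enumeration
hyper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# mean silhouette width from the definition
sil_brute <- function(cl, d) {
  d <- as.matrix(d)
  n <- length(cl)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) { widths[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(d[i, cl == g]), numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  mean(widths)
}

# Dunn z statistic for one pair from the formula
dunn_z_brute <- function(values, g1, g2) {
  x <- unlist(values, use.names = FALSE)
  g <- rep(names(values), lengths(values))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (mean(r[g == g1]) - mean(r[g == g2])) /
    sqrt(sigma2 * (1 / sum(g == g1) + 1 / sum(g == g2)))
}

# small random expression fixture with gene/sample names
rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# tumour/normal fixture on the TPM+1 scale with a one-site sheet
tiny_cohort <- function(n_genes = 5, n_tum = 4, n_norm = 3, sites = "lung",
                        seed = 42) {
  set.seed(seed)
  n_t <- n_tum * length(sites)
  n_n <- n_norm * length(sites)
  tum <- matrix(exp(runif(n_genes * n_t, 0.5, 4)), nrow = n_genes,
                dimnames = list(sprintf("g%d", 1:n_genes),
                                sprintf("t%02d", 1:n_t)))
  nor <- matrix(exp(runif(n_genes * n_n, 0.5, 4)), nrow = n_genes,
                dimnames = list(sprintf("g%d", 1:n_genes),
                                sprintf("n%02d", 1:n_n)))
  sheet <- sample_sheet(data.frame(
    sample = c(colnames(tum), colnames(nor)),
    condition = rep(c("tumour", "normal"), c(n_t, n_n)),
    primary_site = c(rep(sites, each = n_tum), rep(sites, each = n_norm))))
  list(tumour = expression_matrix(tum, "tpm_plus1"),
       normal = expression_matrix(nor, "tpm_plus1"),
       sheet = sheet)
}
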