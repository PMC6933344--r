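# expression whose connectivity follows a truncated power law, built from
# a single hub factor with pareto-spread loadings
scale_free_expr <- function(n = 80, m = 80, seed = 23) {
  set.seed(seed)
  hub <- rnorm(m)
  u <- runif(n)
  k_target <- (1 - u * 0.97)^(-0.5)
  w <- pmin(0.98, (k_target / max(k_target))^(2 / 3) * 0.95)
  expr <- t(sapply(w, function(wi) sqrt(wi) * hub + sqrt(1 - wi) * rnorm(m)))
  dimnames(expr) <- list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:m))
  expr
}

# independent re-implementation of the power sweep (the oracle)
sweep_brute <- function(expr, powers = 1:20, target = 0.85, min_k = 1) {
  res <- sapply(powers, function(p) {
    a <- abs(cor(t(expr)))^p
    diag(a) <- 0
    k <- rowSums(a)
    kk <- k[k > 0]
    bins <- cut(kk, 10)
    fr <- tapply(kk, bins, length)
    mk <- tapply(kk, bins, mean)
    keep <- !is.na(fr) & fr > 0
    if (sum(keep) < 3) return(c(0, mean(k)))
    fit <- lm(log10(fr[keep] / sum(fr[keep])) ~ log10(mk[keep]))
    c(-sign(coef(fit)[2]) * summary(fit)$r.squared, mean(k))
  })
  ok <- which(res[1, ] >= target & res[2, ] >= min_k)
  if (length(ok)) powers[ok[1]] else NA
}

test_that("soft power selection matches the brute-force fit sweep", {
  expr <- scale_free_expr(seed = 23)
  expect_identical(sweep_brute(expr), 6L)  # frozen from the oracle
  pk <- pick_soft_power(expr)
  expect_identical(pk$power, 6L)
  expect_false(pk$flagged)

  # sweep agreement on assorted fixtures, including ones with no winner
  for (seed in c(1, 5, 7, 12)) {
    expr <- scale_free_expr(seed = seed)
    ch <- sweep_brute(expr)
    pk <- pick_soft_power(expr)
    if (is.na(ch)) {
      expect_true(pk$flagged)
      expect_identical(pk$power, 6L)  # fallback
    } else {
      expect_identical(pk$power, as.integer(ch))
      expect_false(pk$flagged)
    }
  }
})

test_that("soft power branch cases: vacuous target, unreachable target,
           degenerate input", {
  expr <- rand_expr(20, 30, seed = 2)
  cfg0 <- network_config(rsq_target = 0, fallback_power = 1)
  expect_identical(pick_soft_power(expr, cfg0)$power, 1L)

  cfg_hi <- network_config(rsq_target = 1)
  pk <- pick_soft_power(expr, cfg_hi)
  expect_true(pk$flagged)
  expect_identical(pk$power, 6L)

  cst <- matrix(1, 12, 6, dimnames = list(paste0("g", 1:12),
                                          paste0("s", 1:6)))
  expect_error(pick_soft_power(cst), "degenerate|constant")
  expect_error(pick_soft_power(expr[1:5, ]), ">= 10 genes")
})

test_that("TOM limits: perfectly correlated and uncorrelated gene pairs", {
  x <- c(1, 2, 3, 4)
  perf <- rbind(g1 = x, g2 = 2 * x + 1)
  colnames(perf) <- paste0("s", 1:4)
  expect_equal(compute_tom(perf, power = 6)["g1", "g2"], 1)

  # r exactly 0 by construction
  orth <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  colnames(orth) <- paste0("s", 1:4)
  expect_equal(abs(cor(orth["g1", ], orth["g2", ])), 0)
  expect_equal(compute_tom(orth, power = 6)["g1", "g2"], 0)

  cst <- rbind(g1 = x, g2 = rep(2, 4))
  colnames(cst) <- paste0("s", 1:4)
  expect_error(compute_tom(cst, power = 6), "g2")
})

test_that("TOM equals the naive O(n^3) oracle and satisfies its bounds", {
  for (case in list(c(genes = 20, samples = 15, seed = 1),
                    c(genes = 35, samples = 10, seed = 2),
                    c(genes = 50, samples = 25, seed = 3))) {
    expr <- rand_expr(case["genes"], case["samples"], case["seed"])
    for (power in c(1, 6)) {
      tom <- compute_tom(expr, power)
      expect_lt(max(abs(tom - tom_brute(expr, power))), 1e-10)
      expect_equal(tom, t(tom))
      expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
      expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
    }
  }
})

planted_blocks <- function(block_sizes, n_noise, m = 40, r = 0.9, seed = 1) {
  set.seed(seed)
  rows <- list()
  truth <- character(0)
  for (b in seq_along(block_sizes)) {
    f <- rnorm(m)
    w <- r  # target within-block correlation via shared factor
    for (i in seq_len(block_sizes[b])) {
      rows[[length(rows) + 1]] <- sqrt(w) * f + sqrt(1 - w) * rnorm(m)
      truth <- c(truth, paste0("block", b))
    }
  }
  for (i in seq_len(n_noise)) {
    rows[[length(rows) + 1]] <- rnorm(m)
    truth <- c(truth, "noise")
  }
  expr <- do.call(rbind, rows)
  dimnames(expr) <- list(sprintf("g%03d", seq_len(nrow(expr))),
                         sprintf("s%02d", seq_len(m)))
  names(truth) <- rownames(expr)
  list(expr = expr, truth = truth)
}

test_that("module detection recovers planted correlation blocks", {
  px <- planted_blocks(c(30, 30), n_noise = 0, seed = 4)
  tom <- compute_tom(px$expr, power = 6)
  mods <- detect_modules(tom, network_config(min_module_size = 30))
  expect_setequal(setdiff(unique(mods), "unassigned"),
                  c("module-1", "module-2"))
  expect_equal(adjusted_rand_index(mods, px$truth), 1)
})

test_that("uncorrelated genes stay unassigned; undersized blocks too", {
  noise <- rand_expr(40, 30, seed = 6)
  tom <- compute_tom(noise, power = 6)
  mods <- detect_modules(tom, network_config(min_module_size = 30))
  expect_true(all(mods == "unassigned"))

  # one block one gene short of the minimum size
  px <- planted_blocks(c(29), n_noise = 15, seed = 8)
  tom <- compute_tom(px$expr, power = 6)
  mods <- detect_modules(tom, network_config(min_module_size = 30))
  expect_true(all(mods == "unassigned"))
})

test_that("module detection is deterministic and permutation-consistent", {
  px <- planted_blocks(c(32, 30), n_noise = 10, seed = 5)
  tom <- compute_tom(px$expr, power = 6)
  cfg <- network_config(min_module_size = 30)
  m1 <- detect_modules(tom, cfg)
  m2 <- detect_modules(tom, cfg)
  expect_identical(m1, m2)

  set.seed(9)
  perm <- sample(nrow(px$expr))
  tom_p <- compute_tom(px$expr[perm, ], power = 6)
  m_p <- detect_modules(tom_p, cfg)
  # same partition up to label names
  expect_equal(adjusted_rand_index(m_p[names(m1)], m1), 1)
})

test_that("module profiles are member means on the analysis scale", {
  expr <- rbind(g1 = c(1, 5), g2 = c(3, 7), g3 = c(10, 2))
  colnames(expr) <- c("s1", "s2")
  asg <- structure(c(g1 = "module-1", g2 = "module-1", g3 = "module-2"),
                   class = "module_assignment")
  prof <- summarize_modules(expr, asg)
  expect_equal(prof["module-1", ], c(s1 = 2, s2 = 6))   # mean(1,3), mean(5,7)
  expect_equal(prof["module-2", ], c(s1 = 10, s2 = 2))  # singleton = gene row

  # permuting gene order leaves the profile unchanged
  prof2 <- summarize_modules(expr[c(3, 1, 2), ], asg)
  expect_equal(prof2, prof)

  asg_bad <- structure(c(g1 = "module-1", gX = "module-1"),
                       class = "module_assignment")
  expect_error(summarize_modules(expr, asg_bad), "gX")
  asg_none <- structure(c(g1 = "unassigned"), class = "module_assignment")
  expect_error(summarize_modules(expr, asg_none), "no assigned modules")
})
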