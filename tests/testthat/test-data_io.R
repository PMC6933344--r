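test_that("read_expression converts declared log2(TPM+1) values to TPM+1", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "g1\t0.0\t3.0",
               "g2\t1.0\t2.0"), f)
  m <- read_expression(f, declared_scale = "log2_tpm_plus1")
  expect_identical(attr(m, "scale"), "tpm_plus1")
  expect_equal(unclass(m)["g1", "s1"], 1)   # 2^0
  expect_equal(unclass(m)["g1", "s2"], 8)   # 2^3
  expect_equal(unclass(m)["g2", ], c(s1 = 2, s2 = 4))
})

test_that("expression files round-trip byte-identically", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA\tsB",
               "g1\t1.5\t2.25",
               "g2\t3\t4.125",
               "g3\t1\t7.5"), f1)
  m1 <- read_expression(f1, declared_scale = "tpm_plus1")
  write_expression(m1, f2)
  m2 <- read_expression(f2, declared_scale = "tpm_plus1")
  expect_identical(unclass(m1), unclass(m2))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed expression files fail with context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3"), f)
  expect_error(read_expression(f, "tpm_plus1"), "format error")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\tx\t4"), f)
  expect_error(read_expression(f, "tpm_plus1"), "s1")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_expression(f, "tpm_plus1"), "duplicate gene")
})

test_that("protein-coding filter keeps annotated coding genes only", {
  m <- expression_matrix(
    matrix(1:20 + 0.0, nrow = 10,
           dimnames = list(paste0("g", 1:10), c("s1", "s2"))),
    "tpm_plus1")
  ann <- data.frame(gene_id = paste0("g", 1:8),
                    biotype = c(rep("protein_coding", 4), "lncRNA",
                                "pseudogene", "miRNA", "antisense"))
  # g9, g10 absent from the annotation: treated as non-coding
  res <- filter_protein_coding(m, ann)
  expect_identical(rownames(res$matrix), paste0("g", 1:4))
  expect_equal(res$report$retained, 4)
  expect_equal(res$report$pct_removed, 60)

  all_coding <- data.frame(gene_id = paste0("g", 1:10),
                           biotype = "protein_coding")
  res2 <- filter_protein_coding(m, all_coding)
  expect_identical(unclass(res2$matrix), unclass(m))
  expect_equal(res2$report$pct_removed, 0)

  none <- data.frame(gene_id = "g1", biotype = "lncRNA")
  expect_error(filter_protein_coding(m, none), "empty cohort")
})

test_that("matched-cohort restriction enforces the per-site threshold", {
  set.seed(7)
  counts <- list(a = c(25, 19), b = c(20, 20), c = c(40, 5),
                 d = c(30, 30), e = c(3, 50))
  t_ids <- n_ids <- character(0)
  site_t <- site_n <- character(0)
  for (s in names(counts)) {
    t_ids <- c(t_ids, sprintf("%s_t%02d", s, seq_len(counts[[s]][1])))
    n_ids <- c(n_ids, sprintf("%s_n%02d", s, seq_len(counts[[s]][2])))
    site_t <- c(site_t, rep(s, counts[[s]][1]))
    site_n <- c(site_n, rep(s, counts[[s]][2]))
  }
  genes <- paste0("g", 1:3)
  tum <- expression_matrix(matrix(exp(1), 3, length(t_ids),
                                  dimnames = list(genes, t_ids)), "tpm_plus1")
  nor <- expression_matrix(matrix(exp(1), 3, length(n_ids),
                                  dimnames = list(genes, n_ids)), "tpm_plus1")
  sheet <- sample_sheet(data.frame(
    sample = c(t_ids, n_ids),
    condition = rep(c("tumour", "normal"), c(length(t_ids), length(n_ids))),
    primary_site = c(site_t, site_n)))
  cp <- restrict_matched_cohort(tum, nor, sheet, min_samples = 20)
  # a: 19 normals (below), c and e: one side below, b: exactly at threshold
  expect_identical(cp$sites, c("b", "d"))
  expect_true(all(grepl("^[bd]_", colnames(cp$tumour))))
  tc <- table(sheet$primary_site[match(colnames(cp$tumour), sheet$sample)])
  nc <- table(sheet$primary_site[match(colnames(cp$normal), sheet$sample)])
  expect_true(all(tc[cp$sites] >= 20) && all(nc[cp$sites] >= 20))

  cp2 <- restrict_matched_cohort(tum, nor, sheet, min_samples = 20,
                                 exclude_sites = "d")
  expect_identical(cp2$sites, "b")
  expect_error(
    restrict_matched_cohort(tum, nor, sheet, min_samples = 100),
    "empty cohort")
})

test_that("gene and sample filters commute", {
  co <- tiny_cohort(n_genes = 8, n_tum = 3, n_norm = 3,
                    sites = c("lung", "liver"), seed = 11)
  ann <- data.frame(gene_id = paste0("g", 1:8),
                    biotype = rep(c("protein_coding", "lncRNA"), 4))
  a <- restrict_matched_cohort(filter_protein_coding(co$tumour, ann)$matrix,
                               filter_protein_coding(co$normal, ann)$matrix,
                               co$sheet, min_samples = 2)
  b <- restrict_matched_cohort(co$tumour, co$normal, co$sheet,
                               min_samples = 2)
  expect_identical(unclass(a$tumour),
                   unclass(filter_protein_coding(b$tumour, ann)$matrix))
  expect_identical(unclass(a$normal),
                   unclass(filter_protein_coding(b$normal, ann)$matrix))
})

test_that("matched-cohort invariant holds on random sheets", {
  for (seed in 1:10) {
    set.seed(seed)
    n_sites <- sample(2:6, 1)
    sites <- paste0("s", seq_len(n_sites))
    nt <- sample(1:8, n_sites, replace = TRUE)
    nn <- sample(1:8, n_sites, replace = TRUE)
    t_ids <- unlist(lapply(seq_len(n_sites), function(i)
      sprintf("%s_t%d", sites[i], seq_len(nt[i]))))
    n_ids <- unlist(lapply(seq_len(n_sites), function(i)
      sprintf("%s_n%d", sites[i], seq_len(nn[i]))))
    genes <- paste0("g", 1:2)
    tum <- expression_matrix(matrix(2, 2, length(t_ids),
                                    dimnames = list(genes, t_ids)),
                             "tpm_plus1")
    nor <- expression_matrix(matrix(2, 2, length(n_ids),
                                    dimnames = list(genes, n_ids)),
                             "tpm_plus1")
    sheet <- sample_sheet(data.frame(
      sample = c(t_ids, n_ids),
      condition = rep(c("tumour", "normal"),
                      c(length(t_ids), length(n_ids))),
      primary_site = sub("_.*", "", c(t_ids, n_ids))))
    min_s <- sample(1:5, 1)
    cp <- tryCatch(
      restrict_matched_cohort(tum, nor, sheet, min_samples = min_s),
      error = function(e) NULL)
    expected <- sites[nt >= min_s & nn >= min_s]
    if (is.null(cp)) {
      expect_length(expected, 0)
    } else {
      expect_setequal(cp$sites, expected)
      st <- table(sub("_.*", "", colnames(cp$tumour)))
      sn <- table(sub("_.*", "", colnames(cp$normal)))
      expect_true(all(st >= min_s) && all(sn >= min_s))
    }
  }
})

test_that("GMT files parse with de-duplication and fail on short lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("WP1\tdesc\tG1\tG2\tG2",
               "WP2\tother\tG3",
               "WP3\tthird\tG1\tG4\tG5"), f)
  pc <- read_gmt(f)
  expect_named(pc, c("WP1", "WP2", "WP3"))
  expect_identical(pc$WP1, c("G1", "G2"))
  expect_identical(lengths(pc), c(WP1 = 2L, WP2 = 1L, WP3 = 3L))
  expect_identical(attr(pc, "description")[["WP2"]], "other")

  writeLines(character(0), f)
  expect_length(read_gmt(f), 0)

  writeLines(c("WP1\tdesc\tG1", "WP2\tmissing-members"), f)
  expect_error(read_gmt(f), "line 2")

  # write -> read round trip
  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("WP1\tdesc\tG1\tG2", "WP2\tother\tG3"), f)
  pc <- read_gmt(f)
  write_gmt(pc, f2)
  expect_identical(read_gmt(f2), pc)
})
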