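test_that("variable-gene selection ranks by dispersion with stable ties", {
  set.seed(9)
  x <- matrix(rnorm(1000 * 20), 1000, 20,
              dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:20)))
  hi <- sample(rownames(x), 100)
  x[hi, ] <- x[hi, ] * 8  # planted high-dispersion genes, well separated
  sel <- select_variable_genes(x, 100)
  expect_setequal(sel, hi)
  # constant gene never beats any non-constant gene
  x["g0001", ] <- 5
  expect_false("g0001" %in% select_variable_genes(x, 999))
  # n = all genes returns all genes
  expect_setequal(select_variable_genes(x, 1000), rownames(x))
  expect_error(select_variable_genes(x, 0), "positive")
  expect_error(select_variable_genes(x, 1001), "exceeds")
  # the alternative score is accepted
  expect_length(select_variable_genes(x, 10, method = "max_abs_dev"), 10)
})

test_that("non-negative fold doubles rows and is exactly invertible", {
  set.seed(2)
  z <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  v <- to_nonnegative(z)
  expect_equal(nrow(v), 2 * nrow(z))
  expect_true(all(v >= 0))
  expect_equal(unname(v[1:10, ] - v[11:20, ]), unname(z))
  # all-non-negative input: top block is the input, bottom all zero
  zp <- abs(z)
  vp <- to_nonnegative(zp)
  expect_equal(unname(vp[1:10, ]), unname(zp))
  expect_true(all(vp[11:20, ] == 0))
  z[1, 1] <- NA
  expect_error(to_nonnegative(z), "non-finite")
})

test_that("NMF reconstructs an exact low-rank matrix and consensus is valid", {
  set.seed(4)
  w <- matrix(runif(60 * 3), 60, 3)
  h <- matrix(0, 3, 15)
  for (j in 1:15) h[((j - 1) %/% 5) + 1, j] <- runif(1, 0.5, 2)
  v <- w %*% h
  dimnames(v) <- list(paste0("g", 1:60), paste0("s", 1:15))
  fit <- nmf_consensus(v, 3, n_runs = 10, seed = 1, max_iter = 500, tol = 1e-8)
  expect_lt(sum((v - fit$W %*% fit$H)^2) / sum(v^2), 1e-4)
  # block structure -> consensus is essentially 0/1 and symmetric
  cons <- fit$consensus
  expect_equal(cons, t(cons))
  expect_true(all(diag(cons) == 1))
  expect_true(all(cons >= 0 & cons <= 1))
  expect_gt(mean(cons %in% c(0, 1)), 0.95)
  expect_error(nmf_consensus(v, 20, n_runs = 2), "k must satisfy")
  expect_error(nmf_consensus(-v, 2, n_runs = 2), "non-negative")
})

test_that("rank choice maximizes cophenetic with ties toward smaller k", {
  expect_equal(choose_rank(c(`2` = 0.90, `3` = 0.99, `4` = 0.85)), 3L)
  expect_equal(choose_rank(c(`2` = 0.95, `3` = 0.95)), 2L)
  expect_error(choose_rank(numeric()), "non-empty")
})

test_that("signature derivation recovers planted class genes", {
  cfg <- cohort_config(n_tumor = 36, n_normal = 0, n_genes = 800,
                       n_class_genes = 40, seed = 31)
  sim <- simulate_expression_cohort(cfg)
  labels <- sim$truth$class_label[colnames(sim$expression)]
  sig <- derive_signature(sim$expression, labels, top_n = 150)
  planted <- unlist(sim$truth$class_genes)  # 120 genes <= top_n
  expect_gte(mean(planted %in% sig), 0.95)
  expect_lte(length(sig), 150)
  expect_equal(length(derive_signature(sim$expression, labels, top_n = 5000)),
               800)
  expect_error(derive_signature(sim$expression, rep(1, 36)), "two classes")
  expect_error(derive_signature(sim$expression[, 1:3], c(1, 1, 2)),
               "at least 2 samples")
})

test_that("shuffled labels give uniform-ish adjusted p-values", {
  cfg <- cohort_config(n_tumor = 30, n_normal = 0, n_genes = 400,
                       n_class_genes = 30, seed = 32)
  sim <- simulate_expression_cohort(cfg)
  set.seed(1)
  shuffled <- sample(sim$truth$class_label[colnames(sim$expression)])
  sig <- derive_signature(sim$expression, shuffled, top_n = 50)
  ranking <- attr(sig, "ranking")
  # under the null, BH-adjusted p-values pile up near 1
  expect_gt(min(ranking$p_adjusted), 0.01)
})

test_that("recall matches labelings up to permutation", {
  expect_equal(signature_recall(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(signature_recall(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(signature_recall(rep(1:2, each = 10),
                                c(rep(2, 9), 1, rep(1, 10))), 0.95)
  a <- setNames(c(1, 2), c("x", "y"))
  b <- setNames(c("B", "A"), c("y", "x"))  # name-matched, permuted labels
  expect_equal(signature_recall(a, b), 1)
  expect_error(signature_recall(a, setNames(1:2, c("x", "z"))),
               "different samples")
})

test_that("transfer classification is self-consistent and rank-invariant", {
  cfg <- cohort_config(n_tumor = 30, n_normal = 0, n_genes = 400,
                       n_class_genes = 30, seed = 33)
  sim <- simulate_expression_cohort(cfg)
  labels <- sim$truth$class_label[colnames(sim$expression)]
  sig <- derive_signature(sim$expression, labels, top_n = 60)
  query <- sim$expression
  colnames(query) <- paste0("Q", colnames(query))
  tr <- transfer_classify(sim$expression, labels, query, sig)
  got <- tr$labels[tr$labels$cohort == "query", ]
  expect_equal(adjusted_rand_index(got$class,
                                   labels[sub("^Q", "", got$sample_id)]), 1)
  # distances live in [0, 2] and equal 1 - correlation
  expect_true(all(tr$distance >= -1e-12 & tr$distance <= 2 + 1e-12))
  expect_equal(tr$distance, 1 - tr$correlation)
  # strictly monotone per-sample transform leaves Spearman assignments alone
  query2 <- query^3
  tr2 <- transfer_classify(sim$expression, labels, query2, sig)
  expect_equal(tr2$labels$class, tr$labels$class)
  # insufficient overlap errors
  expect_error(
    transfer_classify(sim$expression, labels,
                      query[setdiff(rownames(query), sig[1:30]), ], sig),
    "insufficient gene overlap")
})

test_that("full pipeline recovers a planted 3-class cohort on a small run", {
  cfg <- cohort_config(n_tumor = 30, n_normal = 0, n_genes = 600,
                       n_class_genes = 60, seed = 35)
  sim <- simulate_expression_cohort(cfg)
  fit <- fit_subtypes(sim$expression, n_genes = 300, ranks = 2:4,
                      n_runs = 15, top_n = 60, seed = 35)
  expect_equal(fit$k, 3L)
  truth <- sim$truth$class_label[names(fit$class_labels)]
  expect_gte(adjusted_rand_index(fit$class_labels, truth), 0.9)
  expect_gte(fit$recall, 0.9)
  expect_lte(length(fit$signature), 60)
  g <- glance(fit)
  expect_equal(g$k, 3L)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("consensus clustering is invariant to sample order", {
  cfg <- cohort_config(n_tumor = 24, n_normal = 0, n_genes = 400,
                       n_class_genes = 40, seed = 36)
  sim <- simulate_expression_cohort(cfg)
  lx <- log2(sim$expression + 1)
  z <- zscore_genes(lx[select_variable_genes(lx, 200), ])
  v <- to_nonnegative(z)
  set.seed(8)
  perm <- sample(ncol(v))
  f1 <- nmf_consensus(v, 3, n_runs = 12, seed = 2)
  f2 <- nmf_consensus(v[, perm], 3, n_runs = 12, seed = 2)
  expect_equal(adjusted_rand_index(f1$labels[colnames(v)[perm]], f2$labels), 1)
})
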