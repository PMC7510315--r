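small_cfg <- function(...) {
  cohort_config(n_tumor = 24, n_normal = 6, n_genes = 400,
                n_class_genes = 30, ...)
}

test_that("expression generator is seed-deterministic and non-negative", {
  s1 <- simulate_expression_cohort(small_cfg(seed = 7))
  s2 <- simulate_expression_cohort(small_cfg(seed = 7))
  s3 <- simulate_expression_cohort(small_cfg(seed = 8))
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$metadata, s2$metadata)
  expect_false(identical(s1$expression, s3$expression))
  expect_true(all(s1$expression >= 0))
  expect_equal(dim(s1$expression), c(400, 30))
  # truth aligns with samples
  expect_identical(names(s1$truth$class_label), colnames(s1$expression))
  expect_true(all(is.na(s1$truth$class_label[s1$metadata$tissue == "normal"])))
  expect_true(all(s1$truth$immune_tier[s1$metadata$tissue == "normal"] == "normal"))
})

test_that("zero class effect plants no class signal", {
  sim <- simulate_expression_cohort(small_cfg(class_effect_size = 0, seed = 21))
  tum <- sim$metadata$tissue == "tumor"
  cls <- factor(sim$truth$class_label[tum])
  lx <- log2(sim$expression[, tum] + 1)
  # one-way ANOVA across truth classes, per gene: p roughly uniform
  pvals <- apply(lx[seq_len(200), ], 1, function(v) {
    stats::anova(stats::lm(v ~ cls))[["Pr(>F)"]][1]
  })
  expect_lt(mean(pvals < 0.05), 0.12)
  # and downstream clustering recovers nothing
  z <- zscore_genes(lx)
  lab <- stats::cutree(stats::hclust(stats::as.dist(1 - cor(z)), "average"), 3)
  expect_lt(abs(adjusted_rand_index(lab, cls)), 0.2)
})

test_that("config validation catches bad settings", {
  expect_error(cohort_config(k_classes = 10, n_tumor = 5), "insufficient samples")
  expect_error(cohort_config(k_classes = 1), "k_classes")
  expect_error(cohort_config(somatic_rate = 1.3), "rates")
  expect_error(cohort_config(somatic_rate = 0.6, germline_rate = 0.6), "rates")
  expect_error(cohort_config(hazard = c(0, 1, 1)), "hazard")
  expect_error(cohort_config(n_genes = 100), "n_genes too small")
})

test_that("variant generator plants the advertised kind mix", {
  cfg <- cohort_config(n_tumor = 2, n_normal = 0, n_genes = 400,
                       k_classes = 2, n_class_genes = 30,
                       variants_per_sample = 100,
                       somatic_rate = 0.4, germline_rate = 0.3,
                       artifact_rate = 0.3, seed = 3)
  vs <- simulate_variant_records(cfg, panel = c("VHL", "PBRM1"))
  # 40 somatic + 30 germline + 30 artifact planted per sample
  per_sample <- table(vs$truth$sample_id, vs$truth$kind)
  expect_true(all(per_sample[, "somatic"] == 40L))
  expect_true(all(per_sample[, "germline"] == 30L))
  expect_true(all(per_sample[, "artifact"] == 30L))
  expect_equal(nrow(vs$variants), nrow(vs$truth))
  # determinism
  vs2 <- simulate_variant_records(cfg, panel = c("VHL", "PBRM1"))
  expect_identical(vs$variants, vs2$variants)
  # no artifacts/germline -> cascade retains everything
  cfg0 <- cohort_config(n_tumor = 3, n_normal = 0, n_genes = 400,
                        k_classes = 2, n_class_genes = 30,
                        variants_per_sample = 50,
                        somatic_rate = 1, germline_rate = 0,
                        artifact_rate = 0, seed = 4)
  vs0 <- simulate_variant_records(cfg0, panel = c("VHL", "PBRM1"))
  fr0 <- filter_variants(vs0$variants, panel = c("VHL", "PBRM1"))
  expect_equal(nrow(fr0$retained), nrow(vs0$variants))
})

test_that("mixture profiles obey the linear model", {
  ref <- make_reference()
  # identity fractions, no noise -> columns equal reference profiles
  id <- diag(ncol(ref))
  dimnames(id) <- list(paste0("P", seq_len(ncol(ref))), colnames(ref))
  mix <- simulate_mixture_profiles(ref, id, noise_sd = 0)
  expect_equal(unname(mix), unname(ref), tolerance = 1e-12)
  # dimension mismatch errors
  expect_error(simulate_mixture_profiles(ref, id[, 1:3]), "dimension mismatch")
  bad <- id; bad[1, ] <- 0.5
  expect_error(simulate_mixture_profiles(ref, bad), "row sums")
})

test_that("recovery error grows with mixture noise on average", {
  ref <- make_reference()
  fr <- make_fractions(20, colnames(ref))
  errs <- vapply(c(0.1, 0.6, 2.5), function(ns) {
    e <- vapply(1:5, function(r) {
      mix <- simulate_mixture_profiles(ref, fr, noise_sd = ns, seed = 100 * ns + r)
      dec <- deconvolve_fractions(mix, ref)
      mean(abs(as.matrix(dec[, colnames(ref)]) - fr))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("survival generator censors as requested", {
  sv <- simulate_survival(rep("A", 40), c(A = 0.001),
                          censor_fraction = 1, seed = 5)
  expect_true(all(sv$event == 0))
  km <- km_curve(sv)
  expect_true(all(km$survival == 1))
  expect_error(simulate_survival(rep("A", 5), c(A = -1)), "positive")
  expect_error(simulate_survival(rep(c("A", "B"), 5), c(A = 0.1)),
               "one hazard per distinct label")
})
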