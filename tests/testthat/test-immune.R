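test_that("phenotype assignment recovers planted tiers and pins normals", {
  sim <- simulate_expression_cohort(cohort_config(seed = 51))
  ph <- assign_immune_phenotypes(sim$expression, sim$truth$markers,
                                 sim$metadata)
  lab <- ph$labels
  expect_true(all(lab$phenotype[!lab$is_tumor] == "normal"))
  tum <- lab[lab$is_tumor, ]
  truth <- sim$truth$immune_tier[tum$sample_id]
  expect_gte(adjusted_rand_index(tum$phenotype, truth), 0.9)
  # mean marker z ordering active > tolerant > inactive holds by construction
  z <- zscore_genes(log2(sim$expression[sim$truth$markers, ] + 1))
  means <- tapply(colMeans(z)[tum$sample_id], tum$phenotype, mean)
  expect_true(means["active"] > means["tolerant"])
  expect_true(means["tolerant"] > means["inactive"])
})

test_that("all-tumor cohorts fall back with a warning", {
  sim <- simulate_expression_cohort(
    cohort_config(n_tumor = 40, n_normal = 0, seed = 52))
  expect_warning(
    ph <- assign_immune_phenotypes(sim$expression, sim$truth$markers,
                                   rep(TRUE, 40)),
    "no normal samples")
  expect_true(all(ph$labels$phenotype %in% c("active", "tolerant", "inactive")))
})

test_that("marker coverage is enforced", {
  sim <- simulate_expression_cohort(
    cohort_config(n_tumor = 12, n_normal = 3, n_genes = 400,
                  n_class_genes = 20, seed = 53))
  expect_error(assign_immune_phenotypes(sim$expression, paste0("NOPE", 1:66),
                                        sim$metadata), "no marker genes")
  few <- c(sim$truth$markers[1:20], paste0("NOPE", 1:46))
  expect_error(assign_immune_phenotypes(sim$expression, few, sim$metadata),
               "50%")
})

test_that("deconvolution is exact on noiseless mixtures", {
  ref <- make_reference()
  # pure sample equals one reference column
  pure <- diag(ncol(ref))[1, , drop = FALSE]
  dimnames(pure) <- list("P1", colnames(ref))
  mix <- simulate_mixture_profiles(ref, pure, noise_sd = 0)
  dec <- deconvolve_fractions(mix, ref)
  expect_equal(dec$B, 1, tolerance = 1e-8)
  expect_equal(dec$other, 0, tolerance = 1e-8)

  fr <- make_fractions(25, colnames(ref))
  mix2 <- simulate_mixture_profiles(ref, fr, noise_sd = 0)
  dec2 <- deconvolve_fractions(mix2, ref)
  est <- as.matrix(dec2[, colnames(ref)])
  expect_lt(max(abs(est - fr)), 1e-6)
  # fractions non-negative, unit sum including "other"
  full <- as.matrix(dec2[, -1])
  expect_true(all(full >= -1e-12))
  expect_equal(unname(rowSums(full)), rep(1, 25), tolerance = 1e-9)
})

test_that("deconvolution rejects thin overlap and collinear references", {
  ref <- make_reference()
  expect_error(deconvolve_fractions(
    simulate_mixture_profiles(ref, make_fractions(2, colnames(ref)))[1:10, ],
    ref), ">= 30")
  bad <- cbind(ref, DUP = ref[, "B"] * 2)
  mix <- simulate_mixture_profiles(ref, make_fractions(2, colnames(ref)))
  expect_error(deconvolve_fractions(mix, bad), "collinear.*DUP")
})

test_that("fraction comparison flags a planted macrophage elevation", {
  ref <- make_reference()
  hit <- 0
  for (r in 1:10) {
    set.seed(60 + r)
    n <- 30
    # tight baseline around 10%, doubled (2x effect) in group A
    mac <- runif(n, 0.08, 0.12)
    mac[1:15] <- mac[1:15] * 2
    others <- make_fractions(n, setdiff(colnames(ref), "Mac"),
                             max_total = 0.7, seed = 600 + r)
    fr <- cbind(others, Mac = mac)[, colnames(ref)]
    mix <- simulate_mixture_profiles(ref, fr, noise_sd = 0.3, seed = 60 + r)
    dec <- deconvolve_fractions(mix, ref)
    cmp <- compare_fractions(dec, group_a = rownames(fr)[1:15],
                             group_b = rownames(fr)[16:30])
    mac_row <- cmp[cmp$cell_type == "Mac", ]
    hit <- hit + (mac_row$flag == "elevated")
  }
  expect_gte(hit, 9.5)
})

test_that("identical groups give zero log-ratio and honest nulls", {
  ref <- make_reference()
  fr <- make_fractions(10, colnames(ref))
  mix <- simulate_mixture_profiles(ref, fr, noise_sd = 0)
  dec <- deconvolve_fractions(mix, ref)
  dup <- dplyr::bind_rows(dec, dplyr::mutate(dec, sample_id = paste0(sample_id, "b")))
  cmp <- compare_fractions(dup, group_a = dec$sample_id,
                           group_b = paste0(dec$sample_id, "b"))
  expect_true(all(cmp$log10_ratio == 0))
  expect_true(all(cmp$flag == "ns"))
  expect_error(compare_fractions(dec, dec$sample_id[1:3], dec$sample_id[3:5]),
               "disjoint")
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("eTMB counting and correlation behave at the edges", {
  etmb0 <- estimate_etmb(make_cascade_fixture()$records[0, ],
                         samples = c("a", "b", "c"))
  expect_equal(etmb0$etmb, c(0L, 0L, 0L))
  ref <- make_reference()
  fr <- make_fractions(3, colnames(ref))
  dec <- deconvolve_fractions(simulate_mixture_profiles(ref, fr), ref)
  etmb0$sample_id <- dec$sample_id
  expect_error(correlate_etmb(etmb0, dec), "no variance")
  expect_error(correlate_etmb(etmb0[1:2, ], dec), "fewer than 3")
})

test_that("eTMB correlation tracks a planted linear relation", {
  ref <- make_reference()
  n <- 50
  set.seed(99)
  load <- rpois(n, 40)
  fr <- make_fractions(n, colnames(ref), seed = 70)
  # plant macrophage fraction as a linear function of load + noise
  fr[, "Mac"] <- 0.002 * load + rnorm(n, 0, 0.01)
  fr[, "Mac"] <- pmin(pmax(fr[, "Mac"], 0.001), 0.4)
  fr <- fr / pmax(1, rowSums(fr) + 0.02)
  gen_cor <- cor(load, fr[, "Mac"])
  mix <- simulate_mixture_profiles(ref, fr, noise_sd = 0.05, seed = 71)
  dec <- deconvolve_fractions(mix, ref)
  etmb <- tibble::tibble(sample_id = dec$sample_id, etmb = load)
  res <- correlate_etmb(etmb, dec)
  got <- res$correlation[res$cell_type == "Mac"]
  expect_lt(abs(got - gen_cor), 0.1)
  # self-correlation sanity
  self <- correlate_etmb(etmb, dplyr::mutate(dec, self = load / max(load)))
  expect_equal(self$correlation[self$cell_type == "self"], 1, tolerance = 1e-9)
})
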