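#' Assign immune phenotypes from a marker panel
#'
#' Z-scores the marker genes across samples, clusters samples
#' hierarchically on the Euclidean distance between their marker z-score
#' profiles (average linkage; the distance used when clustering z-scored
#' heatmaps), and cuts the dendrogram into four groups when normal samples
#' are present (three otherwise).  Euclidean distance is the default
#' because the phenotype axis is one of overall marker *magnitude*
#' (active > tolerant > inactive/normal); a correlation distance centers
#' every sample profile and is blind to a tier that raises all markers
#' together.  The group
#' holding the majority of the normal samples defines the inactive pole:
#' tumors inside it are labeled `inactive`.  The remaining tumor groups are
#' ranked by mean marker z-score and labeled `active` (highest),
#' `tolerant`, and - when a third remains - `inactive` (lowest).  Normal
#' samples are always labeled `normal`.
#'
#' @param x Genes x samples non-negative abundance matrix.
#' @param markers Character vector of marker gene ids; at least half must
#'   be present in `x`.
#' @param is_tumor Logical vector, one per sample (TRUE = tumor), or a
#'   metadata tibble with `sample_id` and `tissue` columns
#'   (`"tumor"`/`"normal"`).
#' @param dist_method `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson between sample marker profiles).
#' @return Object of class `"immune_phenotype"`: list with `labels`
#'   (tibble `sample_id`, `is_tumor`, `cluster`, `phenotype`),
#'   `group_means` (mean marker z-score per cluster), `markers` used.
#' @examples
#' sim <- simulate_expression_cohort(
#'   cohort_config(n_tumor = 20, n_normal = 5, n_genes = 400,
#'                 n_class_genes = 20, seed = 3))
#' ph <- assign_immune_phenotypes(sim$expression, sim$truth$markers,
#'                                sim$metadata)
#' table(ph$labels$phenotype)
#' @export
assign_immune_phenotypes <- function(x, markers, is_tumor,
                                     dist_method = c("euclidean",
                                                     "correlation")) {
  dist_method <- match.arg(dist_method)
  check_expression_matrix(x)
  if (is.data.frame(is_tumor)) {
    meta <- as_tibble(is_tumor)
    if (!all(c("sample_id", "tissue") %in% names(meta))) {
      abort("metadata must carry sample_id and tissue columns")
    }
    is_tumor <- setNames(meta$tissue == "tumor", meta$sample_id)
  }
  if (!is.null(names(is_tumor))) is_tumor <- is_tumor[colnames(x)]
  if (length(is_tumor) != ncol(x) || anyNA(is_tumor)) {
    abort("is_tumor must flag every sample of x")
  }
  found <- intersect(markers, rownames(x))
  if (length(found) == 0) abort("no marker genes found in the matrix")
  if (length(found) < length(markers) / 2) {
    abort(sprintf("only %d of %d marker genes present (need >= 50%%)",
                  length(found), length(markers)))
  }
  z <- zscore_genes(log2(x[found, , drop = FALSE] + 1))

  have_normals <- any(!is_tumor)
  n_groups <- if (have_normals) 4 else 3
  if (!have_normals) {
    warn("no normal samples: labeling the lowest-scoring group inactive")
  }
  d <- switch(dist_method,
    euclidean = stats::dist(t(z)),
    correlation = as.dist(1 - cor(z))
  )
  cl <- cutree(hclust(d, method = "average"), k = n_groups)

  group_means <- vapply(seq_len(n_groups),
                        function(g) mean(z[, cl == g, drop = FALSE]),
                        numeric(1))

  phenotype <- rep(NA_character_, ncol(x))
  normal_cluster <- if (have_normals) {
    as.integer(names(sort(table(cl[!is_tumor]), decreasing = TRUE))[1])
  } else {
    NA_integer_
  }
  tumor_groups <- setdiff(seq_len(n_groups), normal_cluster)
  # keep only clusters that actually contain tumors
  tumor_groups <- tumor_groups[vapply(tumor_groups,
                                      function(g) any(is_tumor & cl == g),
                                      logical(1))]
  # Tier the remaining clusters by mean marker score.  Clusters are grouped
  # into contiguous tiers cut at the big gaps (>= half the largest gap, at
  # most two cuts), so a phenotype split across two clusters by the
  # dendrogram still gets one label: highest tier = active, then tolerant,
  # then inactive.  A single remaining cluster is elevated relative to the
  # normal pole and is labeled active.
  ord <- tumor_groups[order(group_means[tumor_groups], decreasing = TRUE)]
  tier_names <- c("active", "tolerant", "inactive")
  tier_of <- rep(1L, length(ord))
  if (length(ord) > 1) {
    gaps <- -diff(group_means[ord])
    qual <- which(gaps >= 0.5 * max(gaps))
    cut_at <- sort(qual[order(-gaps[qual])][seq_len(min(2, length(qual)))])
    tier_of <- 1L + cumsum(seq_along(ord) %in% (cut_at + 1L))
  }
  for (i in seq_along(ord)) {
    phenotype[is_tumor & cl == ord[i]] <- tier_names[tier_of[i]]
  }
  if (!is.na(normal_cluster)) {
    phenotype[is_tumor & cl == normal_cluster] <- "inactive"
  }
  phenotype[!is_tumor] <- "normal"

  labels <- tibble(sample_id = colnames(x), is_tumor = unname(is_tumor),
                   cluster = unname(cl), phenotype = phenotype)
  structure(list(labels = labels,
                 group_means = setNames(group_means,
                                        paste0("cluster", seq_len(n_groups))),
                 markers = found),
            class = "immune_phenotype")
}

#' @export
#' @exportS3Method
tidy.immune_phenotype <- function(x, ...) x$labels

#' @export
print.immune_phenotype <- function(x, ...) {
  cat("Immune phenotypes:\n")
  print(table(x$labels$phenotype))
  invisible(x)
}

#' Deconvolve bulk profiles into reference cell-type fractions
#'
#' Per sample, solves a least-squares fit of the bulk profile against the
#' reference cell-type profiles on their shared genes, constrained to
#' non-negative weights summing to at most 1; the remainder is reported as
#' `other` (uncharacterized, mostly malignant, content assumed not to
#' express the reference genes).  Fractions including `other` sum exactly
#' to 1.  The constrained solve uses Lawson-Hanson non-negative least
#' squares on a system augmented with a heavily weighted sum-to-one row
#' and a slack column.
#'
#' @param x Genes x samples bulk matrix.
#' @param reference Genes x cell-types non-negative profile matrix; at
#'   least 30 genes must be shared with `x`, and the profiles must not be
#'   collinear.
#' @return Object of class `"cell_fractions"`: a tibble with `sample_id`,
#'   one column per reference cell type, and `other`.
#' @examples
#' ref <- matrix(runif(200, 1, 10), 50, 4,
#'               dimnames = list(paste0("g", 1:50), paste0("ct", 1:4)))
#' fr <- matrix(c(0.4, 0.3, 0.2, 0.1), 1, 4,
#'              dimnames = list("s1", colnames(ref)))
#' bulk <- simulate_mixture_profiles(ref, fr)
#' deconvolve_fractions(bulk, ref)
#' @export
deconvolve_fractions <- function(x, reference) {
  check_expression_matrix(x)
  check_expression_matrix(reference, "reference", require_nonneg = TRUE)
  genes <- intersect(rownames(x), rownames(reference))
  if (length(genes) < 30) {
    abort(sprintf("only %d genes shared with the reference (need >= 30)",
                  length(genes)))
  }
  r <- reference[genes, , drop = FALSE]
  p <- ncol(r)
  qr_r <- qr(r)
  if (qr_r$rank < p) {
    bad <- colnames(r)[qr_r$pivot[(qr_r$rank + 1):p]]
    abort(sprintf("reference profiles are collinear; offending columns: %s",
                  paste(bad, collapse = ", ")))
  }
  big <- 1e4 * max(abs(r))
  a <- cbind(rbind(r, rep(big, p)), c(rep(0, length(genes)), big))
  fractions <- t(apply(x[genes, , drop = FALSE], 2, function(col) {
    sol <- pracma::lsqnonneg(a, c(col, big))$x
    f <- sol[seq_len(p)]
    other <- sol[p + 1]
    out <- c(f, other)
    out / sum(out)  # unit sum including "other"
  }))
  colnames(fractions) <- c(colnames(r), "other")
  out <- as_tibble(fractions) %>%
    mutate(sample_id = colnames(x), .before = 1)
  class(out) <- c("cell_fractions", class(out))
  out
}

#' Compare cell-type fractions between two sample groups
#'
#' Per cell type, reports the log10 ratio of group means and a two-sided
#' Welch t-test p-value, flagging each type `elevated`, `depleted` or `ns`
#' at the chosen threshold.  A zero group mean yields a missing log-ratio
#' with a warning.
#'
#' @param fractions A [deconvolve_fractions()] result (or a tibble with
#'   `sample_id` plus fraction columns).
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   ids.
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble of class `"fraction_comparison"` with `cell_type`,
#'   `mean_a`, `mean_b`, `log10_ratio`, `p_value`, `flag`.
#' @export
compare_fractions <- function(fractions, group_a, group_b, alpha = 0.05) {
  fr <- as_tibble(fractions)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    abort("groups must be disjoint")
  }
  missing <- setdiff(c(group_a, group_b), fr$sample_id)
  if (length(missing)) {
    abort(sprintf("samples not in fractions: %s",
                  paste(missing, collapse = ", ")))
  }
  types <- setdiff(names(fr), "sample_id")
  a <- fr[fr$sample_id %in% group_a, types, drop = FALSE]
  b <- fr[fr$sample_id %in% group_b, types, drop = FALSE]
  res <- purrr::map(types, function(ct) {
    va <- a[[ct]]
    vb <- b[[ct]]
    ma <- mean(va)
    mb <- mean(vb)
    lr <- if (ma > 0 && mb > 0) log10(ma / mb) else NA_real_
    if (is.na(lr)) {
      warn(sprintf("zero group mean for %s: log-ratio reported as missing", ct))
    }
    pv <- tryCatch(stats::t.test(va, vb)$p.value, error = function(e) NA_real_)
    tibble(cell_type = ct, mean_a = ma, mean_b = mb, log10_ratio = lr,
           p_value = pv)
  }) %>% bind_rows()
  res <- res %>% mutate(flag = dplyr::case_when(
    is.na(.data$p_value) | .data$p_value >= alpha ~ "ns",
    .data$log10_ratio > 0 ~ "elevated",
    TRUE ~ "depleted"
  ))
  class(res) <- c("fraction_comparison", class(res))
  res
}

#' Volcano plot of a fraction comparison
#'
#' @param object A [compare_fractions()] result.
#' @param alpha Significance threshold drawn as a dashed line.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @exportS3Method
autoplot.fraction_comparison <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$log10_ratio, y = -log10(.data$p_value),
                 color = .data$flag)) +
    geom_point(size = 2) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed",
               color = "grey50") +
    geom_text(aes(label = .data$cell_type), vjust = -0.8, size = 3,
              show.legend = FALSE) +
    scale_color_manual(values = c(elevated = "firebrick",
                                  depleted = "steelblue", ns = "grey60")) +
    labs(x = "log10 mean ratio (A / B)", y = "-log10 p",
         title = "Cell-fraction comparison") +
    theme_minimal()
}

#' Estimate tumor mutational burden from paired-filtered variants
#'
#' eTMB is simply the number of somatic variants per sample that survive
#' the filter cascade including the matched-normal stage.
#'
#' @param retained Tibble of retained variant records (or a
#'   [filter_variants()] result).
#' @param samples Character vector of the paired sample ids (zero-count
#'   samples appear with 0).
#' @return Tibble with `sample_id` and `etmb`.
#' @export
estimate_etmb <- function(retained, samples) {
  ml <- mutation_load(retained, samples)
  ml$per_sample %>% rename(etmb = "n_variants")
}

#' Correlate eTMB with deconvolved cell fractions
#'
#' @param etmb An [estimate_etmb()] tibble.
#' @param fractions A [deconvolve_fractions()] result covering the same
#'   samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble with `cell_type`, `correlation`, `p_value`, `n`.
#' @export
correlate_etmb <- function(etmb, fractions,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  fr <- as_tibble(fractions)
  merged <- dplyr::inner_join(as_tibble(etmb), fr, by = "sample_id")
  if (nrow(merged) < 3) {
    abort("correlation refused: fewer than 3 paired samples")
  }
  if (sd(merged$etmb) == 0) {
    abort("correlation refused: eTMB has no variance across samples")
  }
  types <- setdiff(names(fr), "sample_id")
  purrr::map(types, function(ct) {
    ok <- sd(merged[[ct]]) > 0
    ct_res <- if (ok) {
      stats::cor.test(merged$etmb, merged[[ct]], method = method,
                      exact = FALSE)
    }
    tibble(cell_type = ct,
           correlation = if (ok) unname(ct_res$estimate) else NA_real_,
           p_value = if (ok) ct_res$p.value else NA_real_,
           n = nrow(merged))
  }) %>% bind_rows()
}
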