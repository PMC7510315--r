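#' Select the most variable genes
#'
#' Ranks genes by a robust dispersion score and returns the top `n`.  The
#' default score is the median absolute deviation (MAD) of each gene's
#' values; `method = "max_abs_dev"` uses the maximum absolute deviation
#' from the gene mean instead.  Ties are broken lexicographically by gene
#' id, so the selection is deterministic.
#'
#' @param x Genes x samples numeric matrix with gene rownames.
#' @param n Number of genes to keep (1 <= n <= nrow(x)).
#' @param method Dispersion score: `"mad"` (default) or `"max_abs_dev"`.
#' @return Character vector of `n` gene ids, ordered by decreasing score.
#' @examples
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' select_variable_genes(m, 5)
#' @export
select_variable_genes <- function(x, n, method = c("mad", "max_abs_dev")) {
  method <- match.arg(method)
  check_expression_matrix(x)
  if (n <= 0) abort("n must be positive")
  if (n > nrow(x)) abort("n exceeds the number of genes")
  score <- switch(method,
    mad = apply(x, 1, mad),
    max_abs_dev = apply(x, 1, function(v) max(abs(v - mean(v))))
  )
  ord <- order(-score, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Fold a z-scored matrix into a non-negative matrix
#'
#' Stacks the positive part over the negative part
#' (`rbind(pmax(z, 0), pmax(-z, 0))`), doubling the rows; the original
#' matrix is recoverable as top block minus bottom block.  This is the
#' standard way to feed signed z-scores to NMF.
#'
#' @param z Numeric matrix with finite entries.
#' @return Non-negative matrix with `2 * nrow(z)` rows; row names carry
#'   `_pos` / `_neg` suffixes.
#' @examples
#' to_nonnegative(matrix(c(-1, 2), 1, 2,
#'                dimnames = list("g1", c("a", "b"))))
#' @export
to_nonnegative <- function(z) {
  stopifnot(is.matrix(z))
  if (!all(is.finite(z))) abort("non-finite entries are not allowed")
  v <- rbind(pmax(z, 0), pmax(-z, 0))
  rownames(v) <- c(paste0(rownames(z), "_pos"), paste0(rownames(z), "_neg"))
  v
}

# One multiplicative-update NMF run from a random uniform start.
nmf_single <- function(v, k, max_iter = 200, tol = 1e-4, check_every = 10) {
  m <- nrow(v)
  n <- ncol(v)
  scale <- sqrt(mean(v) / k)
  w0 <- matrix(runif(m * k, 0.1, 1), m, k) * scale
  h0 <- matrix(runif(k * n, 0.1, 1), k, n) * scale
  fit <- nmf_mu_cpp(v, w0, h0, as.integer(max_iter), tol,
                    as.integer(check_every))
  dimnames(fit$W) <- list(rownames(v), NULL)
  dimnames(fit$H) <- list(NULL, colnames(v))
  fit
}

#' Consensus NMF at a fixed rank
#'
#' Runs `n_runs` non-negative matrix factorizations from random uniform
#' starts (multiplicative updates minimizing the Frobenius reconstruction
#' error), labels each sample by its dominant coefficient per run (ties go
#' to the lowest factor index), and averages the run-wise co-clustering
#' indicators into a consensus matrix.  Stability is summarized by the
#' cophenetic correlation between the consensus-derived distances
#' (1 - consensus) and their average-linkage dendrogram; final class labels
#' come from cutting that dendrogram into `k` groups.
#'
#' @param v Non-negative genes x samples matrix.
#' @param k Factorization rank, `2 <= k < ncol(v)`.
#' @param n_runs Number of random restarts (default 50).
#' @param seed Integer seed; run starts are drawn sequentially from it, so
#'   results are reproducible.
#' @param max_iter,tol Per-run convergence controls.
#' @return Object of class `"nmf_consensus"`: list with `W`, `H` (best run
#'   by reconstruction error), `consensus` (samples x samples, entries in
#'   \[0, 1\], unit diagonal), `cophenetic`, `labels` (named integer
#'   vector), `k`, `loss` per run.
#' @examples
#' v <- abs(matrix(rnorm(300), 30, 10,
#'          dimnames = list(paste0("g", 1:30), paste0("s", 1:10))))
#' fit <- nmf_consensus(v, k = 2, n_runs = 5, seed = 1)
#' fit$cophenetic
#' @export
nmf_consensus <- function(v, k, n_runs = 50, seed = 1, max_iter = 200,
                          tol = 1e-4) {
  check_expression_matrix(v, "v", require_nonneg = TRUE)
  n <- ncol(v)
  if (k < 2 || k >= n) abort("k must satisfy 2 <= k < n_samples")
  set.seed(seed)
  conn <- matrix(0, n, n)
  best <- NULL
  losses <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_single(v, k, max_iter = max_iter, tol = tol)
    losses[r] <- fit$loss
    lab <- apply(fit$H, 2, which.max)
    conn <- conn + outer(lab, lab, "==")
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  consensus <- conn / n_runs
  dimnames(consensus) <- list(colnames(v), colnames(v))
  d <- as.dist(1 - consensus)
  hc <- hclust(d, method = "average")
  dc <- cophenetic(hc)
  coph <- if (sd(as.vector(d)) == 0 || sd(as.vector(dc)) == 0) 1
          else cor(as.vector(d), as.vector(dc))
  labels <- cutree(hc, k = k)
  structure(list(W = best$W, H = best$H, consensus = consensus,
                 cophenetic = coph, labels = labels, k = k,
                 loss = losses),
            class = "nmf_consensus")
}

#' Pick the factorization rank by cophenetic correlation
#'
#' Returns the rank with the highest cophenetic coefficient; ties break
#' toward the smaller rank.
#'
#' @param cophenetics Named numeric vector, names = candidate ranks.
#' @return Integer rank.
#' @examples
#' choose_rank(c(`2` = 0.90, `3` = 0.99, `4` = 0.85))
#' @export
choose_rank <- function(cophenetics) {
  if (length(cophenetics) == 0) abort("cophenetics must be non-empty")
  ks <- as.integer(names(cophenetics))
  if (any(is.na(ks))) abort("cophenetics must be named by rank")
  ord <- order(-cophenetics, ks)
  ks[ord][1]
}

# Vectorized Welch t-test of in-group vs out-group, per row.
welch_rows <- function(x, in_cols) {
  a <- x[, in_cols, drop = FALSE]
  b <- x[, -in_cols, drop = FALSE]
  n1 <- ncol(a)
  n2 <- ncol(b)
  m1 <- rowMeans(a)
  m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  se2[se2 == 0] <- .Machine$double.eps
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  df[!is.finite(df) | df <= 0] <- n1 + n2 - 2
  2 * pt(-abs(tstat), df)
}

#' Derive a differential-expression signature from class labels
#'
#' For every class, tests each gene one-vs-rest (Welch t on
#' `log2(x + 1)`-scale values), adjusts p-values by Benjamini-Hochberg
#' within the comparison, pools all comparisons, ranks by adjusted then raw
#' p (ties by gene id), deduplicates genes keeping each gene's best rank,
#' and returns the top `top_n` genes.
#'
#' @param x Genes x samples matrix of non-negative abundances (or
#'   already-log values with `log_transform = FALSE`).
#' @param labels Class labels, one per column of `x` (>= 2 classes, each
#'   with >= 2 samples).
#' @param top_n Signature size cap (default 300).
#' @param log_transform Apply `log2(x + 1)` before testing (default TRUE).
#' @return Character vector of signature gene ids (length <= `top_n`),
#'   with the pooled ranking table in `attr(, "ranking")`.
#' @examples
#' m <- matrix(2^rnorm(400), 40, 10,
#'             dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
#' sig <- derive_signature(m, rep(1:2, each = 5), top_n = 10)
#' @export
derive_signature <- function(x, labels, top_n = 300, log_transform = TRUE) {
  check_expression_matrix(x)
  labels <- as.vector(labels)
  if (length(labels) != ncol(x)) abort("one label per sample is required")
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("at least two classes are required")
  if (any(table(labels) < 2)) abort("every class needs at least 2 samples")
  lx <- if (log_transform) log2(x + 1) else x

  ranking <- purrr::map(classes, function(cl) {
    p <- welch_rows(lx, which(labels == cl))
    tibble(gene_symbol = rownames(lx), class = as.character(cl),
           p_value = p, p_adjusted = p.adjust(p, "BH"))
  }) %>%
    bind_rows() %>%
    arrange(.data$p_adjusted, .data$p_value, .data$gene_symbol) %>%
    distinct(.data$gene_symbol, .keep_all = TRUE)

  sig <- head(ranking$gene_symbol, top_n)
  attr(sig, "ranking") <- ranking
  sig
}

#' Agreement between two labelings after optimal label matching
#'
#' Maximum fraction of samples on which the two labelings agree, over all
#' one-to-one relabelings of the second onto the first.  1 means identical
#' partitions up to renaming.
#'
#' @param labels_a,labels_b Label vectors over the same samples; if both
#'   are named the names must match (order-insensitive).
#' @return Fraction in \[0, 1\].
#' @examples
#' signature_recall(c(1, 1, 2, 2), c("b", "b", "a", "a"))  # 1
#' @export
signature_recall <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      abort("labelings cover different samples")
    }
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b)) {
    abort("labelings cover different samples")
  }
  best_label_agreement(labels_a, labels_b)
}

#' Transfer a class assignment to an external cohort via signature genes
#'
#' Restricts reference and query to the signature genes, computes pairwise
#' Spearman correlations between all samples of the combined cohort, turns
#' them into the distance `1 - cor`, clusters hierarchically
#' (average linkage by default), cuts into `k` clusters, and maps every
#' cluster to the class holding the majority of its reference samples.
#' Query samples inherit their cluster's class.  A cluster without any
#' reference sample is assigned to the class whose reference mean profile
#' it correlates with best, with a warning.
#'
#' @param x_ref Reference genes x samples matrix.
#' @param ref_labels Class labels of the reference samples (named by sample
#'   id or in column order of `x_ref`).
#' @param x_query Query genes x samples matrix.
#' @param signature Character vector of signature gene ids; at least 80%
#'   must be present in each matrix.
#' @param k Number of clusters; default the number of distinct reference
#'   classes.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return Object of class `"transfer_result"`: list with `labels` (tibble
#'   `sample_id`, `cohort`, `cluster`, `class`), `correlation` and
#'   `distance` matrices over the combined cohort, `k`, `mapping`.
#' @export
transfer_classify <- function(x_ref, ref_labels, x_query, signature,
                              k = NULL, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  check_expression_matrix(x_ref, "x_ref")
  check_expression_matrix(x_query, "x_query")
  if (!is.null(names(ref_labels))) {
    ref_labels <- ref_labels[colnames(x_ref)]
  }
  if (length(ref_labels) != ncol(x_ref)) {
    abort("one reference label per reference sample is required")
  }
  ov_ref <- mean(signature %in% rownames(x_ref))
  ov_query <- mean(signature %in% rownames(x_query))
  if (ov_ref < 0.8 || ov_query < 0.8) {
    abort(sprintf(
      "insufficient gene overlap: %.0f%% of signature in reference, %.0f%% in query (need >= 80%%)",
      100 * ov_ref, 100 * ov_query))
  }
  genes <- intersect(signature, intersect(rownames(x_ref),
                                          rownames(x_query)))
  combined <- cbind(x_ref[genes, , drop = FALSE],
                    x_query[genes, , drop = FALSE])
  cohort <- c(rep("reference", ncol(x_ref)), rep("query", ncol(x_query)))
  if (is.null(k)) k <- n_distinct(ref_labels)

  cors <- cor(combined, method = "spearman")
  d <- 1 - cors
  hc <- hclust(as.dist(d), method = linkage)
  cl <- cutree(hc, k = k)

  ref_idx <- which(cohort == "reference")
  mapping <- vapply(seq_len(k), function(g) {
    members <- intersect(which(cl == g), ref_idx)
    if (length(members) == 0) return(NA_character_)
    names(sort(table(as.character(ref_labels)[members]),
               decreasing = TRUE))[1]
  }, character(1))

  if (anyNA(mapping)) {
    warn("cluster(s) without reference samples assigned by nearest reference-class centroid")
    # rank-transform per sample, then correlate cluster mean with class mean
    rk <- apply(combined, 2, rank)
    class_means <- vapply(sort(unique(as.character(ref_labels))),
                          function(cls) {
      rowMeans(rk[, ref_idx[as.character(ref_labels)[ref_idx] == cls],
                  drop = FALSE])
    }, numeric(nrow(rk)))
    for (g in which(is.na(mapping))) {
      cm <- rowMeans(rk[, cl == g, drop = FALSE])
      mapping[g] <- colnames(class_means)[which.max(cor(cm, class_means))]
    }
  }

  labels <- tibble(
    sample_id = colnames(combined),
    cohort = cohort,
    cluster = unname(cl),
    class = mapping[cl]
  )
  structure(list(labels = labels, correlation = cors, distance = d,
                 k = k, mapping = mapping, linkage = linkage),
            class = "transfer_result")
}

#' @export
#' @exportS3Method
tidy.transfer_result <- function(x, ...) x$labels

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("Transfer classification: %d samples into %d classes (%s linkage)\n",
              nrow(x$labels), x$k, x$linkage))
  print(table(x$labels$cohort, x$labels$class))
  invisible(x)
}

#' Fit the full consensus-NMF subtyping pipeline
#'
#' The end-to-end molecular classification: log2-transform, select the
#' `n_genes` most variable genes, z-score them, fold into a non-negative
#' matrix, survey consensus NMF over `ranks` (50 restarts each by
#' default), pick the rank with the best cophenetic correlation, take the
#' consensus class labels at that rank, compress to a `top_n`-gene
#' differential-expression signature, and report the signature's recall of
#' the full clustering (agreement after optimal label matching between the
#' full-matrix labels and a 1 - Spearman-correlation hierarchical
#' relabeling on signature genes alone).
#'
#' @param x Genes x samples non-negative abundance matrix.
#' @param n_genes Variable genes to select (default 3000).
#' @param ranks Candidate ranks (default `2:8`).
#' @param n_runs NMF restarts per rank (default 50).
#' @param top_n Signature size (default 300).
#' @param seed Integer seed.
#' @param select_method Dispersion score for gene selection, see
#'   [select_variable_genes()].
#' @param max_iter,tol Per-run NMF convergence controls.
#' @return Object of class `"subtype_model"`: list with `selected_genes`,
#'   `cophenetic` (named by rank), `k`, `fit` (the [nmf_consensus()] object
#'   at `k`), `class_labels` (named), `signature`, `recall`, and the call
#'   parameters.
#' @examples
#' \donttest{
#' sim <- simulate_expression_cohort(
#'   cohort_config(n_tumor = 18, n_normal = 0, n_genes = 400,
#'                 n_class_genes = 40, seed = 2))
#' fit <- fit_subtypes(sim$expression, n_genes = 200, ranks = 2:4,
#'                     n_runs = 10, top_n = 50, seed = 2)
#' fit$k
#' }
#' @export
fit_subtypes <- function(x, n_genes = 3000, ranks = 2:8, n_runs = 50,
                         top_n = 300, seed = 1,
                         select_method = c("mad", "max_abs_dev"),
                         max_iter = 200, tol = 1e-4) {
  select_method <- match.arg(select_method)
  check_expression_matrix(x, require_nonneg = TRUE)
  lx <- log2(x + 1)
  selected <- select_variable_genes(lx, n_genes, method = select_method)
  z <- zscore_genes(lx[selected, , drop = FALSE])
  v <- to_nonnegative(z)

  fits <- list()
  coph <- setNames(numeric(length(ranks)), ranks)
  for (i in seq_along(ranks)) {
    fits[[i]] <- nmf_consensus(v, ranks[i], n_runs = n_runs,
                               seed = seed + i - 1,
                               max_iter = max_iter, tol = tol)
    coph[i] <- fits[[i]]$cophenetic
  }
  k <- choose_rank(coph)
  fit_k <- fits[[match(k, ranks)]]
  class_labels <- fit_k$labels

  signature <- derive_signature(lx, class_labels, top_n = top_n,
                                log_transform = FALSE)
  sig_labels <- relabel_by_signature(lx, signature, k)
  recall <- signature_recall(class_labels, sig_labels)

  structure(list(
    selected_genes = selected, cophenetic = coph, k = k, fit = fit_k,
    class_labels = class_labels, signature = as.character(signature),
    recall = recall,
    params = list(n_genes = n_genes, ranks = ranks, n_runs = n_runs,
                  top_n = top_n, seed = seed,
                  select_method = select_method)
  ), class = "subtype_model")
}

# Re-label samples using signature genes only: 1 - Spearman correlation,
# average-linkage hierarchical clustering, cut at k.
relabel_by_signature <- function(lx, signature, k,
                                 linkage = "average") {
  genes <- intersect(signature, rownames(lx))
  d <- as.dist(1 - cor(lx[genes, , drop = FALSE], method = "spearman"))
  cutree(hclust(d, method = linkage), k = k)
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf(
    "Consensus-NMF subtype model: k = %d (cophenetic %.3f), %d samples\n",
    x$k, x$cophenetic[as.character(x$k)], length(x$class_labels)))
  cat(sprintf("signature: %d genes, recall of full clustering = %.3f\n",
              length(x$signature), x$recall))
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.subtype_model <- function(x, ...) {
  tibble(sample_id = names(x$class_labels),
         class = unname(x$class_labels))
}

#' @export
#' @exportS3Method
glance.subtype_model <- function(x, ...) {
  tibble(k = x$k,
         cophenetic = unname(x$cophenetic[as.character(x$k)]),
         n_samples = length(x$class_labels),
         n_selected_genes = length(x$selected_genes),
         n_signature_genes = length(x$signature),
         recall = x$recall)
}

#' Cophenetic-correlation profile of a subtype model
#'
#' @param object A [fit_subtypes()] model.
#' @param ... Ignored.
#' @return A ggplot of cophenetic correlation against candidate rank, the
#'   chosen rank highlighted.
#' @export
#' @exportS3Method
autoplot.subtype_model <- function(object, ...) {
  df <- tibble(k = as.integer(names(object$cophenetic)),
               cophenetic = unname(object$cophenetic))
  ggplot(df, aes(x = .data$k, y = .data$cophenetic)) +
    geom_line(color = "grey40") +
    geom_point(aes(color = .data$k == object$k), size = 2,
               show.legend = FALSE) +
    scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    labs(x = "rank k", y = "cophenetic correlation",
         title = "Consensus NMF rank survey") +
    theme_minimal()
}
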