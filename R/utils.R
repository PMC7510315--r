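#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero,
#' the convention used when printing one-decimal mutation frequencies.
#' (Base [round()] uses round-half-to-even.)
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.25, -0.25, 76.35), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b Vectors of group labels for the same samples, same length.
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must label the same samples (lengths differ).")
  }
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(0)
  }
  (sum_ij - expected) / (max_index - expected)
}

# All permutations of seq_len(n); n is small (<= number of classes).
permutations <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

# Best one-to-one matching of labelings: maximum agreement fraction over
# bijections of b's labels onto a's.  Label sets are padded so the brute
# force works with unequal cardinalities (k is small, <= 8 here).
best_label_agreement <- function(a, b) {
  la <- sort(unique(as.character(a)))
  lb <- sort(unique(as.character(b)))
  k <- max(length(la), length(lb))
  if (k > 9) {
    abort("label matching supports at most 9 distinct labels")
  }
  tab <- matrix(0, k, k)
  tt <- table(factor(as.character(a), levels = la),
              factor(as.character(b), levels = lb))
  tab[seq_along(la), seq_along(lb)] <- tt
  perms <- permutations(k)
  agree <- apply(perms, 1, function(p) sum(tab[cbind(seq_len(k), p)]))
  max(agree) / length(a)
}

# Row-wise z-score: (x - mean) / sd per gene.  Constant rows become 0.
#' Z-score a gene-by-sample matrix gene-wise
#'
#' Centers and scales each gene (row) to mean 0 and unit standard deviation
#' across samples.  Genes with zero variance are set to all-zero rows rather
#' than NaN.
#'
#' @param x Numeric matrix, genes in rows.
#' @return Matrix of the same shape, tagged with `attr(, "scale") = "zscore"`.
#' @export
zscore_genes <- function(x) {
  stopifnot(is.matrix(x))
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / max(1, ncol(x) - 1))
  z <- (x - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  attr(z, "scale") <- "zscore"
  z
}

# Validate a genes-by-samples expression matrix.
check_expression_matrix <- function(x, arg = "x", require_nonneg = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("`%s` has duplicated gene ids.", arg))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  if (require_nonneg && any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", arg))
  }
  invisible(x)
}
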