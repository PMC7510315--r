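#' Reconstruct an integer count from a printed one-decimal percentage
#'
#' Published frequency tables often print `100 * k / n` to one decimal
#' without the underlying count `k`.  This inverts the rounding: it returns
#' the unique integer `k` in `[0, n]` whose one-decimal percentage (half
#' rounded away from zero) equals `percent`, and fails loudly when no such
#' integer exists (`"inconsistent"`) or several do (`"ambiguous"`).
#'
#' @param percent Printed percentage, one decimal, in \[0, 100\].
#' @param n Cohort size (>= 1).
#' @return The integer count.
#' @examples
#' reconstruct_count(76.4, 55)   # 42
#' reconstruct_count(52.8, 451)  # 238
#' @export
reconstruct_count <- function(percent, n) {
  if (n < 1) abort("n must be >= 1")
  if (percent < 0 || percent > 100) abort("percent must lie in [0, 100]")
  k <- 0:n
  hits <- k[round_half_up(100 * k / n, 1) == round_half_up(percent, 1)]
  if (length(hits) == 0) {
    abort(sprintf("inconsistent: no integer count in [0, %d] prints as %.1f%%",
                  n, percent), class = "ccrcc_inconsistent_percent")
  }
  if (length(hits) > 1) {
    abort(sprintf("ambiguous: counts %s all print as %.1f%% of %d",
                  paste(hits, collapse = ", "), percent, n),
          class = "ccrcc_ambiguous_percent")
  }
  hits
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null, using the
#' minimum-likelihood convention: the sum of the point probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table.  A small relative slack (default `1e-7`) guards
#' the comparison against floating-point ties, matching the convention of
#' mainstream statistical software.
#'
#' @param x Either a 2x2 matrix `rbind(c(a, b), c(c, d))` laid out as
#'   `[[mutated1, wildtype1], [mutated2, wildtype2]]`, or the count `a`
#'   with `b`, `c`, `d` given separately.
#' @param b,c,d Remaining cell counts when `x` is scalar.
#' @param rel_tol Relative slack for the probability comparison.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(rbind(c(42, 13), c(238, 213)))
#' @export
fisher_exact_2x2 <- function(x, b = NULL, c = NULL, d = NULL,
                             rel_tol = 1e-7) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
    a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  } else {
    a <- x
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("all four cells must be non-negative integers")
  }
  n1 <- a + b
  n2 <- c + d
  m <- a + c
  if (m == 0 || m == n1 + n2 || n1 == 0 || n2 == 0) {
    return(1)
  }
  support <- max(0, m - n2):min(m, n1)
  probs <- dhyper(support, n1, n2, m)
  p_obs <- dhyper(a, n1, n2, m)
  p <- sum(probs[probs <= p_obs * (1 + rel_tol)])
  min(p, 1)
}

#' Compare per-gene driver-mutation frequencies between two cohorts
#'
#' Reconstructs integer mutation counts from printed one-decimal
#' percentages in each cohort, then tests each gene's 2x2 table
#' (mutated/wildtype by cohort) with the two-sided Fisher exact test.
#' Genes present in only one table get 0.0% in the other.  Genes whose
#' printed percentage cannot be reconstructed propagate an explanatory
#' `note` instead of aborting the remaining genes.
#'
#' @param freq1,freq2 Tibbles with columns `gene_symbol` and `percent`
#'   (e.g. from [gene_frequency()]).
#' @param n1,n2 Cohort sizes.
#' @param alpha Significance threshold for the `significant` flag
#'   (unadjusted, default 0.05).
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"` an additional
#'   `p_adjusted` column is reported (the flag still uses the raw p).
#' @return Tibble with `gene_symbol`, `percent_1`, `percent_2`, `count_1`,
#'   `count_2`, `p_value`, `significant`, `note`.
#' @examples
#' f1 <- tibble::tibble(gene_symbol = "VHL", percent = 76.4)
#' f2 <- tibble::tibble(gene_symbol = "VHL", percent = 52.8)
#' compare_driver_frequencies(f1, 55, f2, 451)
#' @export
compare_driver_frequencies <- function(freq1, n1, freq2, n2, alpha = 0.05,
                                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  freq1 <- as_tibble(freq1) %>% select("gene_symbol", percent_1 = "percent")
  freq2 <- as_tibble(freq2) %>% select("gene_symbol", percent_2 = "percent")
  merged <- full_join(freq1, freq2, by = "gene_symbol") %>%
    mutate(percent_1 = dplyr::coalesce(.data$percent_1, 0),
           percent_2 = dplyr::coalesce(.data$percent_2, 0))

  res <- purrr::pmap(merged, function(gene_symbol, percent_1, percent_2) {
    k1 <- tryCatch(reconstruct_count(percent_1, n1),
                   error = function(e) conditionMessage(e))
    k2 <- tryCatch(reconstruct_count(percent_2, n2),
                   error = function(e) conditionMessage(e))
    if (is.character(k1) || is.character(k2)) {
      note <- paste(stats::na.omit(c(
        if (is.character(k1)) paste0("cohort 1: ", k1),
        if (is.character(k2)) paste0("cohort 2: ", k2))), collapse = "; ")
      return(tibble(gene_symbol = gene_symbol,
                    percent_1 = percent_1, percent_2 = percent_2,
                    count_1 = NA_integer_, count_2 = NA_integer_,
                    p_value = NA_real_, note = note))
    }
    p <- fisher_exact_2x2(k1, n1 - k1, k2, n2 - k2)
    tibble(gene_symbol = gene_symbol,
           percent_1 = percent_1, percent_2 = percent_2,
           count_1 = as.integer(k1), count_2 = as.integer(k2),
           p_value = p, note = NA_character_)
  }) %>% bind_rows()

  res <- res %>% mutate(significant = !is.na(.data$p_value) &
                          .data$p_value < alpha)
  if (adjust == "BH") {
    res <- res %>% mutate(p_adjusted = p.adjust(.data$p_value, "BH"))
  }
  res %>% select("gene_symbol", "percent_1", "percent_2", "count_1",
                 "count_2", "p_value", "significant",
                 dplyr::any_of("p_adjusted"), "note")
}

#' Published driver-gene frequency table shipped with the package
#'
#' Loads the bundled comparison table of driver-mutation frequencies
#' reported for a Chinese ccRCC cohort (n = 55) versus white TCGA KIRC
#' patients: 84 genes with one-decimal percentages in each cohort and the
#' published Fisher p-value.  The published percentages are consistent with
#' a TCGA-white denominator of 451 patients with mutation data (the
#' clinical summary counts 462 white patients overall).
#'
#' @return Tibble with `gene_symbol`, `percent_chinese`,
#'   `percent_tcga_white`, `p_published`.
#' @export
driver_frequency_table <- function() {
  path <- system.file("extdata", "driver_gene_frequencies.tsv",
                      package = "ccrcctools")
  readr::read_tsv(path, show_col_types = FALSE)
}
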