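#' Four-stage somatic-variant filter cascade
#'
#' Filters RNA-seq variant calls down to putative somatic driver events:
#'
#' 1. **quality** - drop calls not tagged `PASS`, with alternative allele
#'    depth below 5, or indels that fall in a poly-N run or have an
#'    alternative allele rate below 20% (SNVs are not subject to the
#'    poly-N/rate clause);
#' 2. **population** - drop calls observed in either population panel
#'    (1000 Genomes, 6500 exomes) at a frequency strictly greater than
#'    0.5%; a missing frequency means "not observed" and is kept;
#' 3. **functional** - keep only exonic, protein-changing calls;
#' 4. **panel** - keep only calls in the supplied cancer-gene panel;
#' 5. optionally, **matched normal** - drop tumor calls whose
#'    `(chrom, pos, ref, alt)` recurs in that sample's matched normal.
#'
#' The cascade is idempotent and order-stable; the report counts records
#' surviving after every stage.
#'
#' @param variants Tibble/data frame of variant records with columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `filter_status`,
#'   `alt_depth`, `alt_rate`, `is_indel`, `in_polyN_region`,
#'   `pop_freq_1kg`, `pop_freq_esp`, `region_class`, `consequence`,
#'   `gene_symbol`.
#' @param panel Character vector of cancer-gene symbols (non-empty).
#' @param normals Optional tibble of matched-normal records with columns
#'   `tumor_sample_id`, `chrom`, `pos`, `ref`, `alt`; tumor records keyed
#'   identically are removed in the final stage.
#' @param pop_freq_cutoff Population-frequency exclusion threshold
#'   (strictly greater than; default 0.005).
#' @param min_alt_depth Minimum alternative allele depth (default 5).
#' @param min_indel_alt_rate Minimum alternative allele rate for indels
#'   (default 0.20).
#'
#' @return An object of class `"filter_result"`: a list with `retained`
#'   (tibble of surviving records) and `report` (tibble of stage names and
#'   record counts, starting at `input`).
#' @examples
#' vs <- simulate_variant_records(
#'   cohort_config(n_tumor = 4, n_normal = 0, n_genes = 500,
#'                 n_class_genes = 20, variants_per_sample = 20),
#'   panel = c("VHL", "PBRM1"))
#' fr <- filter_variants(vs$variants, panel = c("VHL", "PBRM1"))
#' fr$report
#' @export
filter_variants <- function(variants, panel, normals = NULL,
                            pop_freq_cutoff = 0.005, min_alt_depth = 5,
                            min_indel_alt_rate = 0.20) {
  if (length(panel) == 0) abort("panel must be non-empty")
  variants <- as_tibble(variants)
  stages <- character()
  counts <- integer()
  note <- function(stage, x) {
    stages <<- c(stages, stage)
    counts <<- c(counts, nrow(x))
    x
  }
  x <- note("input", variants)

  pass_quality <- x$filter_status == "PASS" &
    x$alt_depth >= min_alt_depth &
    !(x$is_indel & (x$in_polyN_region |
                      dplyr::coalesce(x$alt_rate, 0) < min_indel_alt_rate))
  x <- note("quality", x[which(pass_quality), ])

  pop1 <- dplyr::coalesce(x$pop_freq_1kg, 0)
  pop2 <- dplyr::coalesce(x$pop_freq_esp, 0)
  x <- note("population",
            x[which(!(pop1 > pop_freq_cutoff | pop2 > pop_freq_cutoff)), ])

  x <- note("functional",
            x[which(x$region_class == "exonic" &
                      x$consequence == "protein-changing"), ])

  x <- note("panel", x[which(x$gene_symbol %in% panel), ])

  if (!is.null(normals)) {
    normals <- as_tibble(normals)
    needed <- c("tumor_sample_id", "chrom", "pos", "ref", "alt")
    if (!all(needed %in% names(normals))) {
      abort("normals must carry tumor_sample_id, chrom, pos, ref, alt")
    }
    key <- normals %>%
      select(sample_id = "tumor_sample_id", "chrom", "pos", "ref", "alt") %>%
      distinct()
    x <- note("matched_normal",
              anti_join(x, key, by = c("sample_id", "chrom", "pos",
                                       "ref", "alt")))
  }

  structure(list(
    retained = x,
    report = tibble(stage = stages, n = counts)
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Somatic-variant filter cascade\n")
  print(x$report)
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.filter_result <- function(x, ...) x$report

#' Stage-count bar chart for a filter cascade
#'
#' @param object A [filter_variants()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @exportS3Method
autoplot.filter_result <- function(object, ...) {
  df <- object$report %>%
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot(df, aes(x = .data$stage, y = .data$n)) +
    geom_col(fill = "grey35") +
    geom_text(aes(label = .data$n), vjust = -0.4, size = 3) +
    labs(x = NULL, y = "records retained",
         title = "Variant filter cascade") +
    theme_minimal()
}

#' Per-sample mutation load and cohort median
#'
#' Counts retained variants per sample (samples with no surviving call are
#' reported with 0) and summarizes the cohort by its median load.  For an
#' even number of samples the default convention takes the lower of the two
#' middle values, so the reported median is always an observed count.
#'
#' @param retained Tibble of retained variant records (or a
#'   [filter_variants()] result).
#' @param samples Character vector of all sample ids, including those with
#'   zero retained calls.
#' @param median_rule `"lower"` (default, lower middle value for even n) or
#'   `"midpoint"` (the usual mean-of-middles).
#' @return Object of class `"mutation_load"`: list with `per_sample`
#'   (tibble `sample_id`, `n_variants`) and `median`.
#' @examples
#' ml <- mutation_load(
#'   tibble::tibble(sample_id = c("a", "a", "b")),
#'   samples = c("a", "b", "c"))
#' ml$median
#' @export
mutation_load <- function(retained, samples,
                          median_rule = c("lower", "midpoint")) {
  median_rule <- match.arg(median_rule)
  if (inherits(retained, "filter_result")) retained <- retained$retained
  retained <- as_tibble(retained)
  if (length(samples) == 0) abort("samples must be listed explicitly")
  tab <- table(factor(retained$sample_id, levels = samples))
  per_sample <- tibble(sample_id = samples,
                       n_variants = as.integer(tab))
  v <- sort(per_sample$n_variants)
  n <- length(v)
  med <- if (median_rule == "lower") {
    v[ceiling(n / 2)]
  } else {
    median(v)
  }
  structure(list(per_sample = per_sample, median = med,
                 median_rule = median_rule),
            class = "mutation_load")
}

#' @export
print.mutation_load <- function(x, ...) {
  cat(sprintf("Mutation load over %d samples; median = %s (%s rule)\n",
              nrow(x$per_sample), format(x$median), x$median_rule))
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.mutation_load <- function(x, ...) x$per_sample

#' @export
#' @exportS3Method
glance.mutation_load <- function(x, ...) {
  tibble(n_samples = nrow(x$per_sample),
         total_variants = sum(x$per_sample$n_variants),
         median_load = x$median)
}

#' Per-gene mutation frequency
#'
#' A sample counts at most once per gene, regardless of how many distinct
#' variants it carries there.  Percentages are reported to one decimal,
#' rounding half away from zero (the printing convention of published
#' frequency tables).
#'
#' @param retained Tibble of retained variant records (or a
#'   [filter_variants()] result) with `sample_id` and `gene_symbol`.
#' @param n_samples Cohort size used as the denominator (>= 1).
#' @return Tibble with `gene_symbol`, `n_mutated` and `percent`, sorted by
#'   decreasing frequency.
#' @examples
#' gene_frequency(
#'   tibble::tibble(sample_id = c("a", "a", "b"),
#'                  gene_symbol = c("VHL", "VHL", "VHL")),
#'   n_samples = 55)
#' @export
gene_frequency <- function(retained, n_samples) {
  if (inherits(retained, "filter_result")) retained <- retained$retained
  if (n_samples < 1) abort("n_samples must be >= 1")
  as_tibble(retained) %>%
    distinct(.data$gene_symbol, .data$sample_id) %>%
    count(.data$gene_symbol, name = "n_mutated") %>%
    mutate(percent = round_half_up(100 * .data$n_mutated / n_samples, 1)) %>%
    arrange(dplyr::desc(.data$n_mutated), .data$gene_symbol)
}
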