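#' Simulation settings for a synthetic ccRCC-style cohort
#'
#' Bundles every tunable of the synthetic-cohort generators.  The defaults
#' emulate the study design the package targets: 55 tumors of which 11 have
#' matched normals, three expression-defined molecular classes, a 66-gene
#' immune-marker panel with an active/tolerant/inactive tier structure whose
#' inactive tier is drawn from the normal-tissue marker distribution, and
#' per-sample variant calls that are a known mixture of somatic, germline
#' and low-quality events.
#'
#' Expression is modeled log-normally: each gene has a log2 baseline drawn
#' uniformly from \[3, 10\] and a gene-specific noise SD drawn uniformly from
#' 0.5-1.5 times `noise_sd`.  Class and marker effects are additive mean
#' shifts on the log2 scale expressed in units of the gene's own SD
#' (z-units), then exponentiated, so values are non-negative and
#' right-skewed like RSEM-style abundances.
#'
#' @param n_tumor,n_normal Numbers of tumor and matched-normal samples.
#' @param n_genes Total genes, including the 66 marker genes and the
#'   `k_classes * n_class_genes` class-program genes.
#' @param k_classes Number of planted molecular classes (>= 2).
#' @param class_effect_size Mean shift of a class-program gene in its class,
#'   in z-units (multiples of the gene's own noise SD on the log2 scale).
#' @param n_class_genes Genes in each class-specific program.
#' @param marker_effect_size Marker-gene shift of the immune-active tier in
#'   z-units; the tolerant tier gets half of it, the inactive tier and the
#'   normals none (so inactive tumors co-cluster with normals).
#' @param noise_sd Baseline log2-scale noise SD multiplier.
#' @param somatic_rate,germline_rate,artifact_rate Per-sample mixture
#'   proportions of planted variant kinds; each in \[0, 1\], summing to at
#'   most 1.
#' @param variants_per_sample Planted variant calls per tumor sample.
#' @param hazard Event hazard per class (events/day), length `k_classes`.
#'   Default mirrors a cohort whose middle class has markedly worse
#'   survival (median about 1230 days) than the others.
#' @param censor_fraction Fraction of samples right-censored.
#' @param tier_prob Tumor immune-tier probabilities, named
#'   `active`/`tolerant`/`inactive`.  Default 17:34:4.
#' @param seed Default integer seed used by the generators.
#'
#' @return A list of settings with class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_tumor = 12, n_normal = 3, n_genes = 500,
#'                      n_class_genes = 20)
#' @export
cohort_config <- function(n_tumor = 55, n_normal = 11, n_genes = 5000,
                          k_classes = 3, class_effect_size = 2,
                          n_class_genes = 300, marker_effect_size = 2,
                          noise_sd = 1,
                          somatic_rate = 0.5, germline_rate = 0.25,
                          artifact_rate = 0.25, variants_per_sample = 100,
                          hazard = NULL, censor_fraction = 0.3,
                          tier_prob = c(active = 17, tolerant = 34,
                                        inactive = 4) / 55,
                          seed = 1L) {
  if (n_tumor < 1 || n_normal < 0 || n_genes < 1 || variants_per_sample < 0) {
    abort("all counts must be positive")
  }
  if (k_classes < 2) abort("k_classes must be >= 2")
  if (k_classes > n_tumor) abort("insufficient samples: k_classes > n_tumor")
  rates <- c(somatic_rate, germline_rate, artifact_rate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1 + 1e-9) {
    abort("variant rates must lie in [0, 1] and sum to at most 1")
  }
  if (censor_fraction < 0 || censor_fraction > 1) {
    abort("censor_fraction must lie in [0, 1]")
  }
  if (n_genes < 66 + k_classes * n_class_genes) {
    abort("n_genes too small for 66 markers plus the class programs")
  }
  if (is.null(hazard)) {
    hazard <- log(2) / c(2500, 1230, 4000)
    hazard <- hazard[((seq_len(k_classes) - 1) %% 3) + 1]
  }
  if (length(hazard) != k_classes) {
    abort("hazard must have one entry per class")
  }
  if (any(hazard <= 0)) abort("hazard must be positive")
  structure(list(
    n_tumor = n_tumor, n_normal = n_normal, n_genes = n_genes,
    k_classes = k_classes, class_effect_size = class_effect_size,
    n_class_genes = n_class_genes, marker_effect_size = marker_effect_size,
    noise_sd = noise_sd, somatic_rate = somatic_rate,
    germline_rate = germline_rate, artifact_rate = artifact_rate,
    variants_per_sample = variants_per_sample, hazard = hazard,
    censor_fraction = censor_fraction, tier_prob = tier_prob,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default 66-gene immune-marker panel used by the simulator
#'
#' A synthetic stand-in marker panel (ids `IMM001`-`IMM066`).  Real analyses
#' supply their own marker list; the phenotyping functions take the panel as
#' an argument throughout.
#'
#' @return Character vector of 66 gene ids.
#' @export
immune_marker_panel <- function() {
  sprintf("IMM%03d", 1:66)
}

#' Simulate an expression cohort with planted classes and immune tiers
#'
#' Generates a genes-by-samples abundance matrix in which a configurable set
#' of genes carries class-specific mean shifts (the molecular-subtype
#' programs) and the 66 marker genes carry immune-tier-dependent shifts that
#' are independent of class.  Normal samples carry neither class programs
#' nor marker activation, and the inactive tier is drawn from the same
#' marker distribution as the normals.
#'
#' @param config A [cohort_config()].
#' @param markers Character vector of 66 marker gene ids;
#'   default [immune_marker_panel()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param gene_params Optional `truth$gene_params` from a previous cohort:
#'   reuses its per-gene baselines, noise SDs and class programs so the new
#'   samples are drawn from the *same* generating process (e.g. an external
#'   query cohort for transfer classification).  Default: drawn fresh.
#'
#' @return A list of class `"cohort_sim"` with elements
#'   * `expression`: non-negative matrix, `n_genes` x (`n_tumor + n_normal`);
#'   * `metadata`: tibble with `sample_id`, `tissue`, `class_label`
#'     (NA for normals), `immune_tier`;
#'   * `truth`: list with per-sample `class_label` and `immune_tier`,
#'     the planted `class_genes` (list per class), `markers`, and the seed.
#' @examples
#' sim <- simulate_expression_cohort(
#'   cohort_config(n_tumor = 12, n_normal = 3, n_genes = 400,
#'                 n_class_genes = 20, seed = 7))
#' dim(sim$expression)
#' @export
simulate_expression_cohort <- function(config, markers = immune_marker_panel(),
                                       seed = config$seed,
                                       gene_params = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(markers) != 66) abort("markers must list 66 gene ids")
  set.seed(seed)
  k <- config$k_classes
  n_t <- config$n_tumor
  n_n <- config$n_normal
  n_g <- config$n_genes

  sample_ids <- c(sprintf("T%03d", seq_len(n_t)),
                  if (n_n > 0) sprintf("N%03d", seq_len(n_n)))
  tissue <- c(rep("tumor", n_t), rep("normal", n_n))

  # balanced-ish random class assignment for tumors
  class_label <- sample(rep_len(seq_len(k), n_t))
  tier_names <- names(config$tier_prob)
  immune_tier <- sample(tier_names, n_t, replace = TRUE,
                        prob = config$tier_prob)
  class_full <- c(class_label, rep(NA_integer_, n_n))
  tier_full <- c(immune_tier, rep("normal", n_n))

  if (is.null(gene_params)) {
    gene_ids <- c(markers,
                  sprintf("G%05d", seq_len(n_g - length(markers))))
    mu <- runif(n_g, 3, 10)
    gene_sd <- runif(n_g, 0.5, 1.5) * config$noise_sd
    # class programs occupy the genes right after the marker block
    class_genes <- lapply(seq_len(k), function(cl) {
      idx <- length(markers) + (cl - 1) * config$n_class_genes +
        seq_len(config$n_class_genes)
      gene_ids[idx]
    })
  } else {
    if (length(gene_params$mu) != n_g) {
      abort("gene_params were built for a different n_genes")
    }
    if (length(gene_params$class_genes) != k) {
      abort("gene_params were built for a different k_classes")
    }
    gene_ids <- gene_params$gene_ids
    mu <- gene_params$mu
    gene_sd <- gene_params$gene_sd
    class_genes <- gene_params$class_genes
    markers <- gene_params$markers
  }

  logx <- matrix(rnorm(n_g * length(sample_ids), mean = mu, sd = gene_sd),
                 nrow = n_g, ncol = length(sample_ids))
  rownames(logx) <- gene_ids
  colnames(logx) <- sample_ids

  for (cl in seq_len(k)) {
    cols <- which(!is.na(class_full) & class_full == cl)
    rows <- match(class_genes[[cl]], gene_ids)
    logx[rows, cols] <- logx[rows, cols] +
      config$class_effect_size * gene_sd[rows]
  }

  tier_shift <- c(active = 1, tolerant = 0.5, inactive = 0, normal = 0)
  mrow <- match(markers, gene_ids)
  for (tier in c("active", "tolerant")) {
    cols <- which(tier_full == tier)
    if (length(cols)) {
      logx[mrow, cols] <- logx[mrow, cols] +
        config$marker_effect_size * tier_shift[[tier]] * gene_sd[mrow]
    }
  }

  expr <- 2^logx
  metadata <- tibble(
    sample_id = sample_ids, tissue = tissue,
    class_label = class_full, immune_tier = tier_full
  )
  structure(list(
    expression = expr,
    metadata = metadata,
    truth = list(class_label = setNames(class_full, sample_ids),
                 immune_tier = setNames(tier_full, sample_ids),
                 class_genes = class_genes, markers = markers,
                 gene_params = list(gene_ids = gene_ids, mu = mu,
                                    gene_sd = gene_sd,
                                    class_genes = class_genes,
                                    markers = markers),
                 seed = seed)
  ), class = "cohort_sim")
}

# deterministic per-kind counts from mixture proportions
variant_kind_counts <- function(config) {
  n <- config$variants_per_sample
  c(somatic = round(config$somatic_rate * n),
    germline = round(config$germline_rate * n),
    artifact = round(config$artifact_rate * n))
}

#' Simulate per-sample variant records with known truth
#'
#' Emits tumor variant calls of three planted kinds: true somatic events
#' (PASS, alt depth >= 5, absent from population panels, exonic and
#' protein-changing, on the gene panel), germline events (identical quality
#' but population frequency above 0.5%), and artifacts (failing exactly one
#' quality rule: non-PASS, alt depth < 5, indel in a poly-N run, or indel
#' alt rate < 20%).  Kinds are disjoint in the rules they violate, so the
#' filter cascade recovers the somatic truth set exactly.  Optionally,
#' `n_shared_per_sample` rare germline events (quality-passing, absent from
#' population panels) are planted in tumors with a matched normal and
#' duplicated into that normal, exercising the matched-normal stage.
#'
#' @param config A [cohort_config()]; the first `n_normal` tumors are the
#'   matched pairs.
#' @param panel Character vector of cancer-gene symbols (non-empty).
#' @param n_shared_per_sample Rare germline events per matched tumor that
#'   recur in its normal (default 0).
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A list of class `"variant_sim"` with
#'   * `variants`: tibble of tumor records (one row per call) with the
#'     fields consumed by [filter_variants()];
#'   * `normal_variants`: tibble of matched-normal records carrying
#'     `tumor_sample_id` (empty unless `n_shared_per_sample > 0`);
#'   * `truth`: tibble aligned row-by-row with `variants`, with `kind` and
#'     `somatic_flag`.
#' @examples
#' vs <- simulate_variant_records(
#'   cohort_config(n_tumor = 3, n_normal = 1, n_genes = 500,
#'                 n_class_genes = 20, variants_per_sample = 10),
#'   panel = c("VHL", "PBRM1", "SETD2"))
#' nrow(vs$variants)
#' @export
simulate_variant_records <- function(config, panel,
                                     n_shared_per_sample = 0,
                                     seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(panel) == 0) abort("panel must be non-empty")
  set.seed(seed)
  counts <- variant_kind_counts(config)
  n_t <- config$n_tumor
  sample_ids <- sprintf("T%03d", seq_len(n_t))
  paired <- if (config$n_normal > 0) sample_ids[seq_len(config$n_normal)]
            else character()

  kinds <- c(rep(names(counts), counts),
             rep("rare_germline", n_shared_per_sample))
  per_sample <- lapply(sample_ids, function(sid) {
    kk <- if (sid %in% paired) kinds else kinds[kinds != "rare_germline"]
    if (!length(kk)) return(NULL)
    tibble(sample_id = sid, kind = kk)
  })
  rec <- bind_rows(per_sample)
  m <- nrow(rec)
  if (m == 0) {
    empty <- empty_variant_tibble()
    return(structure(list(
      variants = empty[, setdiff(names(empty), "tumor_sample_id")],
      normal_variants = empty,
      truth = tibble(sample_id = character(), kind = character(),
                     somatic_flag = logical())
    ), class = "variant_sim"))
  }

  gene <- sample(panel, m, replace = TRUE)
  gene_idx <- match(gene, panel)
  bases <- c("A", "C", "G", "T")
  is_indel <- runif(m) < 0.2
  ref <- sample(bases, m, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1),
                       character(1)))
  ins <- sample(bases, m, replace = TRUE)
  ref[is_indel] <- ref[is_indel]
  alt[is_indel] <- paste0(ref[is_indel], ins[is_indel])

  # unique 1-based positions inside per-gene dummy windows; offsets drawn
  # without replacement so (chrom, pos) pairs never collide
  pos <- gene_idx * 100000L + sample.int(99999L, m)
  out <- tibble(
    sample_id = rec$sample_id,
    chrom = paste0("chr", (gene_idx %% 22) + 1),
    pos = pos,
    ref = ref, alt = alt,
    filter_status = "PASS",
    alt_depth = sample(5:80, m, replace = TRUE),
    alt_rate = runif(m, 0.25, 1),
    is_indel = is_indel,
    in_polyN_region = FALSE,
    pop_freq_1kg = NA_real_,
    pop_freq_esp = NA_real_,
    region_class = "exonic",
    consequence = "protein-changing",
    gene_symbol = gene
  )

  germ <- rec$kind == "germline"
  if (any(germ)) {
    out$pop_freq_1kg[germ] <- runif(sum(germ), 0.006, 0.5)
    esp <- germ & runif(m) < 0.5
    out$pop_freq_esp[esp] <- runif(sum(esp), 0.006, 0.5)
  }

  art <- which(rec$kind == "artifact")
  if (length(art)) {
    mode <- sample(c("nonpass", "lowdepth", "polyN", "lowrate"),
                   length(art), replace = TRUE)
    out$filter_status[art[mode == "nonpass"]] <- "LowQual"
    out$alt_depth[art[mode == "lowdepth"]] <- sample(0:4,
      sum(mode == "lowdepth"), replace = TRUE)
    pn <- art[mode == "polyN"]
    out$is_indel[pn] <- TRUE
    out$in_polyN_region[pn] <- TRUE
    out$alt[pn] <- paste0(out$ref[pn], "A")
    lr <- art[mode == "lowrate"]
    out$is_indel[lr] <- TRUE
    out$alt[lr] <- paste0(out$ref[lr], "T")
    out$alt_rate[lr] <- runif(length(lr), 0.01, 0.19)
  }

  normals <- out[rec$kind == "rare_germline", ]
  if (nrow(normals)) {
    normals <- normals %>%
      mutate(tumor_sample_id = .data$sample_id,
             sample_id = sub("^T", "N", .data$sample_id))
  } else {
    normals <- out[0, ] %>% mutate(tumor_sample_id = character(0))
  }

  structure(list(
    variants = out,
    normal_variants = normals,
    truth = tibble(sample_id = rec$sample_id, kind = rec$kind,
                   somatic_flag = rec$kind == "somatic")
  ), class = "variant_sim")
}

empty_variant_tibble <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), filter_status = character(),
    alt_depth = integer(), alt_rate = numeric(), is_indel = logical(),
    in_polyN_region = logical(), pop_freq_1kg = numeric(),
    pop_freq_esp = numeric(), region_class = character(),
    consequence = character(), gene_symbol = character(),
    tumor_sample_id = character()
  )
}

#' Simulate bulk mixtures of reference cell-type profiles
#'
#' Builds each sample column as `reference %*% fractions[s, ] +
#' (1 - sum(fractions[s, ])) * other_profile + noise`, clipped at zero.
#' With `other_profile = NULL` the uncharacterized remainder contributes no
#' signal on the reference genes, the assumption under which constrained
#' deconvolution is exact.
#'
#' @param reference Genes x cell-types non-negative matrix with dimnames.
#' @param fractions Samples x cell-types matrix; row sums must be <= 1 and
#'   columns must match `reference`'s cell types.
#' @param noise_sd SD of additive Gaussian noise (linear scale).
#' @param other_profile Optional expression vector (length = genes) of the
#'   remainder compartment; default zero.
#' @param seed Optional integer seed.
#' @return Genes x samples matrix of mixed profiles.
#' @examples
#' ref <- matrix(runif(40, 1, 10), 10, 4,
#'               dimnames = list(paste0("g", 1:10), paste0("ct", 1:4)))
#' fr <- matrix(0.25, 2, 4, dimnames = list(NULL, paste0("ct", 1:4)))
#' mix <- simulate_mixture_profiles(ref, fr)
#' @export
simulate_mixture_profiles <- function(reference, fractions, noise_sd = 0,
                                      other_profile = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(reference) || !is.matrix(fractions) ||
      ncol(reference) != ncol(fractions)) {
    abort("dimension mismatch: fractions must have one column per reference cell type")
  }
  if (!is.null(colnames(fractions)) && !is.null(colnames(reference)) &&
      !identical(colnames(fractions), colnames(reference))) {
    abort("dimension mismatch: cell-type names differ between reference and fractions")
  }
  if (any(fractions < 0) || any(rowSums(fractions) > 1 + 1e-9)) {
    abort("fractions must be non-negative with row sums <= 1")
  }
  if (is.null(other_profile)) other_profile <- rep(0, nrow(reference))
  if (length(other_profile) != nrow(reference)) {
    abort("dimension mismatch: other_profile length must equal the gene count")
  }
  n_s <- nrow(fractions)
  x <- reference %*% t(fractions) +
    outer(other_profile, 1 - rowSums(fractions))
  if (noise_sd > 0) {
    x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
  }
  x <- pmax(x, 0)
  rownames(x) <- rownames(reference)
  colnames(x) <- if (!is.null(rownames(fractions))) rownames(fractions)
                 else sprintf("S%03d", seq_len(n_s))
  x
}

#' Simulate group-dependent exponential survival with censoring
#'
#' Event times are exponential with the hazard of each sample's group; a
#' fixed fraction of samples is right-censored at a uniform time before its
#' event.
#'
#' @param labels Vector of group labels (optionally named by sample id).
#' @param hazard Named vector of hazards (events/day), one per distinct
#'   label, or an unnamed vector in `sort(unique(labels))` order.
#' @param censor_fraction Fraction of samples censored, in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Tibble with `sample_id`, `time`, `event` (1 = death observed,
#'   0 = censored) and `group`.
#' @examples
#' simulate_survival(rep(c("A", "B"), each = 5),
#'                   hazard = c(A = 0.001, B = 0.003), seed = 1)
#' @export
simulate_survival <- function(labels, hazard, censor_fraction = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- sort(unique(as.character(labels)))
  if (is.null(names(hazard))) {
    if (length(hazard) != length(groups)) {
      abort("one hazard per distinct label is required")
    }
    names(hazard) <- groups
  }
  if (!all(groups %in% names(hazard))) {
    abort("one hazard per distinct label is required")
  }
  if (any(hazard <= 0)) abort("hazard must be positive")
  n <- length(labels)
  time <- rexp(n, rate = hazard[as.character(labels)])
  event <- rep(1L, n)
  n_cens <- round(censor_fraction * n)
  if (n_cens > 0) {
    idx <- sample.int(n, n_cens)
    time[idx] <- runif(n_cens, 0, time[idx])
    event[idx] <- 0L
  }
  ids <- if (!is.null(names(labels))) names(labels)
         else sprintf("S%03d", seq_len(n))
  tibble(sample_id = ids, time = time, event = event,
         group = as.character(labels))
}
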