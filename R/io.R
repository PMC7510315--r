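#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header of sample ids, a first column of gene ids and a
#' numeric body.  Duplicated gene or sample ids and (for raw-scale input)
#' negative values are rejected with descriptive errors.
#'
#' @param path TSV file path.
#' @param scale `"raw"` (default; negatives rejected) or `"log"`/`"zscore"`
#'   (negatives allowed).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, scale = c("raw", "log", "zscore")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2) abort(sprintf("%s: expected gene column plus samples", path))
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    abort(sprintf("%s: duplicate gene id(s): %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  body <- df[, -1, drop = FALSE]
  bad <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("%s: non-numeric column(s): %s", path,
                  paste(bad, collapse = ", ")))
  }
  x <- as.matrix(body)
  rownames(x) <- genes
  if (anyNA(x)) {
    line <- which(rowSums(is.na(x)) > 0)[1] + 1
    abort(sprintf("%s: missing/ragged value around line %d", path, line))
  }
  if (scale == "raw" && any(x < 0)) {
    line <- which(rowSums(x < 0) > 0)[1] + 1
    abort(sprintf("%s: negative value in raw-scale input around line %d",
                  path, line))
  }
  attr(x, "scale") <- scale
  x
}

#' Write an expression matrix as TSV
#'
#' @param x Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param gene_col Name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, gene_col = "gene_id") {
  check_expression_matrix(x)
  df <- as_tibble(x)
  df <- dplyr::bind_cols(tibble(!!gene_col := rownames(x)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

# INFO/FORMAT keys used when round-tripping variant records through VCF.
default_vcf_field_map <- function() {
  list(gene = "GENE", consequence = "CSQ", region = "REGION",
       pop_freq_1kg = "AF1KG", pop_freq_esp = "AFESP", polyN = "PN",
       alt_depth = "AO", alt_rate = "AF")
}

#' Write variant records as a multi-sample VCF
#'
#' One VCF row per (chrom, pos, ref, alt) site; each sample carrying the
#' call gets genotype `0/1` with its alt depth and alt rate in the
#' per-sample FORMAT fields, all other samples `0/0`.  Annotation
#' (gene, consequence, region, population frequencies, poly-N flag) is
#' stored in INFO under the keys of `field_map`.  Positions are 1-based as
#' in VCF.
#'
#' @param variants Tibble of variant records (see [filter_variants()] for
#'   the columns).
#' @param path Output `.vcf` path.
#' @param field_map Named list of INFO/FORMAT keys;
#'   see `ccrcctools:::default_vcf_field_map()`.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path,
                               field_map = default_vcf_field_map()) {
  v <- as_tibble(variants)
  samples <- sort(unique(v$sample_id))
  fm <- field_map
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", fm$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence\">", fm$consequence),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Region class\">", fm$region),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">", fm$pop_freq_1kg),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"6500 exomes allele frequency\">", fm$pop_freq_esp),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Poly-N region\">", fm$polyN),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Alt allele depth\">", fm$alt_depth),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"Alt allele rate\">", fm$alt_rate),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  rows <- vapply(split(seq_len(nrow(v)), key), function(idx) {
    first <- v[idx[1], ]
    info <- c(
      sprintf("%s=%s", fm$gene, first$gene_symbol),
      sprintf("%s=%s", fm$consequence, first$consequence),
      sprintf("%s=%s", fm$region, first$region_class),
      if (!is.na(first$pop_freq_1kg))
        sprintf("%s=%.6g", fm$pop_freq_1kg, first$pop_freq_1kg),
      if (!is.na(first$pop_freq_esp))
        sprintf("%s=%.6g", fm$pop_freq_esp, first$pop_freq_esp),
      if (isTRUE(first$in_polyN_region)) fm$polyN
    )
    gt <- setNames(rep("0/0:.:.", length(samples)), samples)
    for (i in idx) {
      gt[v$sample_id[i]] <- sprintf("0/1:%d:%.6g", v$alt_depth[i],
                                    v$alt_rate[i])
    }
    paste(c(first$chrom, first$pos, ".", first$ref, first$alt, ".",
            first$filter_status, paste(info, collapse = ";"),
            sprintf("GT:%s:%s", fm$alt_depth, fm$alt_rate), gt),
          collapse = "\t")
  }, character(1))
  # keep genomic order
  ord <- order(vapply(split(seq_len(nrow(v)), key),
                      function(idx) idx[1], integer(1)))
  writeLines(c(header, unname(rows[ord])), path)
  invisible(path)
}

#' Read variant records from a VCF
#'
#' Parses a VCF 4.x file into the flat per-sample record tibble the filter
#' cascade consumes.  Multi-allelic sites are split into one record per
#' alternative allele; a sample yields a record for every alt allele its
#' genotype carries.  Missing mapped annotation fields become `"missing"`
#' (consequence, region) or `NA` (population frequencies, treated as "not
#' observed" downstream).
#'
#' @param path VCF file path.
#' @param field_map Named list mapping record fields to INFO/FORMAT keys;
#'   see `ccrcctools:::default_vcf_field_map()`.
#' @return Tibble of variant records.
#' @export
read_variants_vcf <- function(path, field_map = default_vcf_field_map()) {
  fm <- field_map
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_site <- nrow(fix)
  info_get <- function(key, numeric = FALSE) {
    out <- vcfR::extract.info(vcf, element = key)
    if (is.null(out)) out <- rep(NA_character_, n_site)
    if (numeric) suppressWarnings(as.numeric(out)) else out
  }
  gene <- info_get(fm$gene)
  csq <- info_get(fm$consequence)
  region <- info_get(fm$region)
  af1 <- info_get(fm$pop_freq_1kg, numeric = TRUE)
  af2 <- info_get(fm$pop_freq_esp, numeric = TRUE)
  # flags carry no value, so grep the raw INFO strings
  info_raw <- vcf@fix[, "INFO"]
  polyn <- grepl(paste0("(^|;)", fm$polyN, "(;|$)"), info_raw)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  ao <- vcfR::extract.gt(vcf, element = fm$alt_depth)
  af <- vcfR::extract.gt(vcf, element = fm$alt_rate)
  samples <- colnames(gt)

  recs <- list()
  for (s in seq_len(n_site)) {
    alts <- strsplit(fix[s, "ALT"], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      alt <- alts[j]
      for (sm in samples) {
        g <- gt[s, sm]
        if (is.na(g)) next
        alleles <- strsplit(g, "[/|]")[[1]]
        if (!any(alleles == as.character(j))) next
        depth <- suppressWarnings(as.integer(
          strsplit(ifelse(is.na(ao[s, sm]), ".", ao[s, sm]),
                   ",", fixed = TRUE)[[1]][j]))
        rate <- suppressWarnings(as.numeric(
          strsplit(ifelse(is.na(af[s, sm]), ".", af[s, sm]),
                   ",", fixed = TRUE)[[1]][j]))
        ref <- unname(fix[s, "REF"])
        filt <- unname(fix[s, "FILTER"])
        recs[[length(recs) + 1]] <- tibble(
          sample_id = sm,
          chrom = unname(fix[s, "CHROM"]),
          pos = as.integer(unname(fix[s, "POS"])),
          ref = ref, alt = unname(alt),
          filter_status = ifelse(is.na(filt), "missing", filt),
          alt_depth = depth,
          alt_rate = rate,
          is_indel = nchar(ref) != nchar(alt),
          in_polyN_region = polyn[s],
          pop_freq_1kg = af1[s],
          pop_freq_esp = af2[s],
          region_class = unname(ifelse(is.na(region[s]), "missing",
                                       region[s])),
          consequence = unname(ifelse(is.na(csq[s]), "missing", csq[s])),
          gene_symbol = unname(ifelse(is.na(gene[s]), "missing", gene[s]))
        )
      }
    }
  }
  if (length(recs) == 0) {
    empty <- empty_variant_tibble()
    return(empty[, setdiff(names(empty), "tumor_sample_id")])
  }
  bind_rows(recs)
}
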