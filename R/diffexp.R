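# Simplified tumor-vs-normal differential expression on count matrices.
#
# The pipeline's primary route is importing DE tables computed by any engine
# (schema: gene, lfc, pvalue, padj). The internal stage below is a documented
# simplified procedure: median-of-ratios normalization followed by a Welch
# two-sample test on log2(normalized + 1) values. Downstream axis analyses
# depend only on the DE-table contract, not on the engine.

#' Construct a count-matrix object with sample metadata
#'
#' @param counts Integer matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). Counts must be >= 0.
#' @param sample_meta Tibble with columns `sample`, `cohort`
#'   (`"tumor"`/`"normal"`), `tissue`, and optional `subtype`; one row per
#'   column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  sample_meta <- as_tibble(sample_meta)
  check_columns(sample_meta, c("sample", "cohort", "tissue"), "sample_meta")
  if (!"subtype" %in% names(sample_meta)) sample_meta$subtype <- NA_character_
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_schema("counts must have gene rownames and sample colnames")
  }
  if (any(counts < 0) || any(is.na(counts))) {
    stop_schema("counts must be nonnegative and non-missing")
  }
  if (!setequal(colnames(counts), sample_meta$sample) ||
      ncol(counts) != nrow(sample_meta)) {
    stop_schema("sample_meta rows must match count matrix columns one-to-one")
  }
  bad <- setdiff(unique(sample_meta$cohort), c("tumor", "normal"))
  if (length(bad) > 0) {
    stop_schema("cohort labels must be tumor/normal; found: %s",
                paste(bad, collapse = ", "))
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ]
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$sample_meta$cohort == "tumor"),
              sum(x$sample_meta$cohort == "normal")))
  invisible(x)
}

#' Read a count matrix and its sample sheet from TSV
#'
#' @param counts_path TSV whose first column is `gene`, remaining columns one
#'   per sample.
#' @param meta_path TSV with columns `sample`, `cohort`, `tissue`, `subtype`.
#' @return A `count_matrix`.
#' @export
read_counts <- function(counts_path, meta_path) {
  tab <- read_tsv_quiet(counts_path)
  check_columns(tab, "gene", "counts table")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  count_matrix(m, read_tsv_quiet(meta_path))
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed the DESeq way: reference genes are those
#' with a nonzero count in every sample; each gene's counts are divided by
#' its geometric mean across samples; a sample's factor is the median of
#' those ratios over reference genes.
#'
#' @param counts A `count_matrix` or a plain nonnegative matrix.
#' @return Named numeric vector of strictly positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    stop_schema(paste("no gene has nonzero counts in all samples;",
                      "consider adding a pseudocount before normalization"))
  }
  logm <- log(m[ref, , drop = FALSE])
  log_geomean <- rowMeans(logm)
  apply(exp(logm - log_geomean), 2, median)
}

#' Normalized log2 expression
#'
#' Counts divided by median-of-ratios size factors, then `log2(x + pseudocount)`.
#'
#' @param counts A `count_matrix`.
#' @param pseudocount Added before the log; default 1.
#' @return Numeric matrix, same dimensions as the counts.
#' @export
normalized_log2 <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  sf <- size_factors(counts)
  log2(sweep(counts$counts, 2, sf, "/") + pseudocount)
}

# Vectorised Welch two-sample test on the rows of two matrices.
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(diff = m1 - m2, t = tstat, df = df, p = p)
}

#' Simplified tumor-vs-normal differential expression
#'
#' Subsets the cohort to one tissue (and optionally one tumor subtype;
#' normals are matched on tissue only), normalizes by median-of-ratios,
#' and per gene computes the mean difference of `log2(normalized + 1)`
#' between tumor and normal samples (the log2 fold change) with a Welch
#' two-sample p-value, BH-adjusted across all genes tested in the contrast.
#' Genes with zero counts in every retained sample are reported with missing
#' statistics and excluded from the adjustment.
#'
#' @param counts A `count_matrix`.
#' @param tissue Tissue label to subset on.
#' @param subtype Tumor subtype label, or `NULL`/`"all"` for all tumor
#'   samples of the tissue.
#' @param pseudocount Pseudocount for the log transform; default 1.
#' @return A DE table: tibble with columns `gene`, `lfc`, `pvalue`, `padj`.
#' @export
differential_expression <- function(counts, tissue, subtype = NULL,
                                    pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  meta <- counts$sample_meta
  in_tissue <- meta$tissue == tissue
  is_tumor <- in_tissue & meta$cohort == "tumor"
  if (!is.null(subtype) && !identical(subtype, "all")) {
    is_tumor <- is_tumor & !is.na(meta$subtype) & meta$subtype == subtype
  }
  is_normal <- in_tissue & meta$cohort == "normal"
  if (sum(is_tumor) < 2) stop_schema("fewer than 2 tumor samples in contrast")
  if (sum(is_normal) < 2) stop_schema("fewer than 2 normal samples in contrast")

  keep <- is_tumor | is_normal
  sub <- count_matrix(counts$counts[, keep, drop = FALSE],
                      meta[keep, , drop = FALSE])
  expr <- normalized_log2(sub, pseudocount)
  tum <- expr[, sub$sample_meta$cohort == "tumor", drop = FALSE]
  nor <- expr[, sub$sample_meta$cohort == "normal", drop = FALSE]

  all_zero <- rowSums(sub$counts) == 0
  w <- welch_rows(tum, nor)
  lfc <- w$diff
  pvalue <- w$p
  lfc[all_zero] <- NA_real_
  pvalue[all_zero] <- NA_real_
  tibble(gene = rownames(sub$counts), lfc = unname(lfc),
         pvalue = unname(pvalue),
         padj = unname(adjust_pvalues(pvalue)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. Missing values are ignored (and returned missing).
#'
#' @param pvalues Numeric vector in `[0, 1]`; `NA` allowed.
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(pvalues) {
  check_prob(pvalues, "pvalues")
  p.adjust(pvalues, method = "BH")
}

#' Partition a DE table into significantly up- and downregulated genes
#'
#' A gene is called up when `lfc > lfc_cut` and `padj < padj_cut`, down when
#' `lfc < -lfc_cut` and `padj < padj_cut`; both inequalities are strict.
#'
#' @param de A DE table (`gene`, `lfc`, `pvalue`, `padj`).
#' @param lfc_cut Absolute log2-fold-change threshold; default 1.
#' @param padj_cut Adjusted-p threshold; default 0.01.
#' @return List with character vectors `up` and `down`.
#' @export
significant_genes <- function(de, lfc_cut = 1, padj_cut = 0.01) {
  de <- as_tibble(de)
  check_columns(de, c("gene", "lfc", "padj"), "DE table")
  ok <- !is.na(de$lfc) & !is.na(de$padj) & de$padj < padj_cut
  list(up = de$gene[ok & de$lfc > lfc_cut],
       down = de$gene[ok & de$lfc < -lfc_cut])
}

#' Read a DE table from TSV
#'
#' @param path TSV with columns `gene`, `lfc`, `pvalue`, `padj`.
#' @return Tibble in the DE-table schema.
#' @export
read_de_table <- function(path) {
  de <- read_tsv_quiet(path)
  check_columns(de, c("gene", "lfc", "pvalue", "padj"), "DE table")
  check_prob(de$pvalue, "pvalue")
  check_prob(de$padj, "padj")
  de
}
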