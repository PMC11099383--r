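# Co-differential-expression scoring of axis pairs across cancer subtypes.

#' Five-level co-differential-expression score for one axis pair
#'
#' Encodes joint differential regulation of a receptor and its partner
#' (ligand precursor or biosynthetic enzyme) in one subtype:
#' * `+2` / `-2`: both `|lfc| > lfc_cut` in the same direction and both
#'   adjusted p-values significant;
#' * `+1` / `-1`: both `|lfc| > lfc_cut` in the same direction, exactly one
#'   significant;
#' * `0`: anti-regulation, sub-threshold fold change, no significant member,
#'   or missing statistics.
#'
#' Vectorised over its inputs.
#'
#' @param lfc_r,padj_r Receptor log2 fold change and adjusted p.
#' @param lfc_p,padj_p Partner log2 fold change and adjusted p.
#' @param lfc_cut,padj_cut Thresholds, strict inequalities; defaults 1 and
#'   0.01.
#' @return Integer score(s) in `{-2, -1, 0, 1, 2}`.
#' @export
code_score <- function(lfc_r, padj_r, lfc_p, padj_p,
                       lfc_cut = 1, padj_cut = 0.01) {
  n <- max(length(lfc_r), length(lfc_p))
  lfc_r <- rep_len(lfc_r, n); padj_r <- rep_len(padj_r, n)
  lfc_p <- rep_len(lfc_p, n); padj_p <- rep_len(padj_p, n)
  big_r <- !is.na(lfc_r) & abs(lfc_r) > lfc_cut
  big_p <- !is.na(lfc_p) & abs(lfc_p) > lfc_cut
  same <- big_r & big_p & sign(lfc_r) == sign(lfc_p)
  sig_r <- !is.na(padj_r) & padj_r < padj_cut
  sig_p <- !is.na(padj_p) & padj_p < padj_cut
  n_sig <- sig_r + sig_p
  magnitude <- ifelse(same & n_sig == 2, 2L,
               ifelse(same & n_sig == 1, 1L, 0L))
  as.integer(magnitude * ifelse(same, sign(lfc_r), 0))
}

#' Build the co-DE score matrix of axis pairs across subtypes
#'
#' Scores every axis pair in every subtype with [code_score()] and flags the
#' "affected" pairs: those with a nonzero score in at least
#' `recurrence_fraction` of the subtypes (inclusive boundary). Pairs whose
#' genes are absent from a subtype's DE table score 0 there.
#'
#' @param de_tables Named list of DE tables, one per subtype.
#' @param pairs Axis pairs, e.g. from [axis_pairs()]: tibble with `receptor`,
#'   `partner`, `partner_kind`.
#' @param recurrence_fraction Fraction of subtypes in which a pair must be
#'   nonzero to be retained; default 0.25.
#' @param lfc_cut,padj_cut Score thresholds passed to [code_score()].
#' @return A `code_matrix`: tibble with `receptor`, `partner`,
#'   `partner_kind`, logical `affected`, then one integer column per
#'   subtype.
#' @export
build_code_matrix <- function(de_tables, pairs, recurrence_fraction = 0.25,
                              lfc_cut = 1, padj_cut = 0.01) {
  stopifnot(length(de_tables) >= 1, !is.null(names(de_tables)))
  pairs <- as_tibble(pairs)
  check_columns(pairs, c("receptor", "partner", "partner_kind"), "pairs")
  pairs <- distinct(pairs)

  score_cols <- imap(de_tables, function(de, subtype) {
    de <- as_tibble(de)
    ir <- match(pairs$receptor, de$gene)
    ip <- match(pairs$partner, de$gene)
    n_absent <- sum(is.na(ir) | is.na(ip))
    if (n_absent > 0) {
      rlang::inform(sprintf(
        "build_code_matrix: %d pair(s) with gene(s) absent from DE table '%s' scored 0",
        n_absent, subtype))
    }
    code_score(de$lfc[ir], de$padj[ir], de$lfc[ip], de$padj[ip],
               lfc_cut = lfc_cut, padj_cut = padj_cut) |>
      tidyr::replace_na(0L)
  })
  scores <- as_tibble(score_cols)
  nonzero_frac <- rowMeans(scores != 0)
  out <- bind_cols(pairs,
                   tibble(affected = nonzero_frac >= recurrence_fraction),
                   scores)
  class(out) <- c("code_matrix", class(out))
  out
}

#' @export
print.code_matrix <- function(x, ...) {
  cat(sprintf("<code_matrix> %d pairs x %d subtypes (%d affected)\n",
              nrow(x), length(code_matrix_subtypes(x)), sum(x$affected)))
  NextMethod()
}

code_matrix_subtypes <- function(matrix) {
  setdiff(names(matrix), c("receptor", "partner", "partner_kind", "affected"))
}

code_matrix_scores <- function(matrix) {
  m <- as.matrix(matrix[, code_matrix_subtypes(matrix), drop = FALSE])
  rownames(m) <- paste(matrix$receptor, matrix$partner, sep = "|")
  m
}

#' Keep only the recurrently affected pairs of a score matrix
#'
#' @param matrix A `code_matrix`.
#' @return The affected rows, same columns.
#' @export
affected_pairs <- function(matrix) {
  stopifnot(inherits(matrix, "code_matrix"))
  matrix[matrix$affected, , drop = FALSE]
}

#' Ward clustering of axis-pair co-DE profiles
#'
#' Agglomerative hierarchical clustering of the pairs' score vectors across
#' subtypes, Ward linkage on Euclidean distances (the `ward.D2` criterion:
#' merges minimise the within-cluster sum of squares), cut into
#' `n_clusters` groups.
#'
#' @param matrix A `code_matrix` (typically filtered with
#'   [affected_pairs()]).
#' @param n_clusters Number of clusters; default 2.
#' @return Tibble with `receptor`, `partner`, `partner_kind`, integer
#'   `cluster`; the `hclust` object is attached as attribute `"hclust"`.
#' @export
cluster_pairs <- function(matrix, n_clusters = 2) {
  stopifnot(inherits(matrix, "code_matrix"))
  if (nrow(matrix) < n_clusters) {
    stop_schema("cannot form %d clusters from %d pairs", n_clusters,
                nrow(matrix))
  }
  m <- code_matrix_scores(matrix)
  hc <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  labels <- cutree(hc, k = n_clusters)
  out <- tibble(receptor = matrix$receptor, partner = matrix$partner,
                partner_kind = matrix$partner_kind,
                cluster = as.integer(labels))
  attr(out, "hclust") <- hc
  out
}

default_subtype_tissue <- function(subtypes) {
  setNames(stringr::str_split_i(subtypes, stringr::fixed("_"), 1), subtypes)
}

mean_pairwise_dist <- function(m) {
  # rows are profiles; 0 when fewer than two rows
  if (nrow(m) < 2) return(0)
  mean(dist(m, method = "euclidean"))
}

#' Receptor-level similarity summaries of co-DE profiles
#'
#' For each receptor: the partner-wise (ligand-wise) similarity is the mean
#' pairwise Euclidean distance between its partners' score vectors across
#' subtypes (0 for single-partner receptors); the tissue-wise similarity is
#' the analogous metric across tissues, obtained by averaging the receptor's
#' pair-by-subtype score matrix column-wise within each tissue and taking the
#' mean pairwise distance between the per-tissue profile vectors. The
#' up/down balance is the mean over partners of (number of +2 entries minus
#' number of -2 entries).
#'
#' @param matrix A `code_matrix`.
#' @param subtype_tissue Named character vector mapping subtype label to
#'   tissue. Defaults to the subtype label up to the first underscore.
#' @return Tibble with one row per receptor: `receptor`, `n_ligands`,
#'   `ligand_wise`, `tissue_wise`, `updown_balance`.
#' @export
similarity_profiles <- function(matrix, subtype_tissue = NULL) {
  stopifnot(inherits(matrix, "code_matrix"))
  subtypes <- code_matrix_subtypes(matrix)
  subtype_tissue <- subtype_tissue %||% default_subtype_tissue(subtypes)
  missing_map <- setdiff(subtypes, names(subtype_tissue))
  if (length(missing_map) > 0) {
    stop_schema("subtype(s) without tissue mapping: %s",
                paste(missing_map, collapse = ", "))
  }
  scores <- code_matrix_scores(matrix)
  tissues <- unname(subtype_tissue[subtypes])

  split(seq_len(nrow(matrix)), matrix$receptor) |>
    imap(function(idx, receptor) {
      m <- scores[idx, , drop = FALSE]
      per_tissue <- vapply(unique(tissues), function(tis) {
        rowMeans(m[, tissues == tis, drop = FALSE])
      }, numeric(nrow(m)))
      per_tissue <- matrix(per_tissue, ncol = length(unique(tissues)))
      tibble(receptor = receptor,
             n_ligands = nrow(m),
             ligand_wise = mean_pairwise_dist(m),
             tissue_wise = mean_pairwise_dist(t(per_tissue)),
             updown_balance = mean(rowSums(m == 2) - rowSums(m == -2)))
    }) |>
    list_rbind() |>
    arrange(.data$receptor)
}

#' Test axis-pair expression correlation against a random-pair background
#'
#' Computes the Pearson correlation of each axis pair across samples of one
#' subtype and compares it to a background distribution of correlations from
#' `n_background` randomly drawn gene pairs (one shared background per call,
#' drawn without replacement from the matrix's genes, excluding the tested
#' pairs). Each pair's r is located within the background distribution with
#' a two-sided t-score, `t = (r - mean(background)) / sd(background)` on
#' `n_background - 1` degrees of freedom — i.e. the p-value asks how likely
#' a background pair is to show a correlation as extreme as the tested one,
#' so the subsequent FDR filter retains discriminating power. P-values are
#' BH-adjusted across tested pairs; a pair is called correlated when
#' `q < 0.05` and `|r| > 0.25`.
#'
#' @param expr Numeric matrix of normalized expression, genes in rows,
#'   samples (>= 3) in columns.
#' @param pairs Tibble with `receptor`, `partner` (and optionally
#'   `partner_kind`).
#' @param n_background Number of background gene pairs; default 1000.
#' @param seed Integer seed for the background draw (required).
#' @param q_cut,r_cut Call thresholds; defaults 0.05 and 0.25.
#' @return Tibble with `receptor`, `partner`, `r`, `t_p`, `q`, `correlated`.
#'   Pairs with a zero-variance or absent gene have missing statistics.
#' @export
correlation_calls <- function(expr, pairs, n_background = 1000, seed,
                              q_cut = 0.05, r_cut = 0.25) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3, !missing(seed))
  pairs <- distinct(as_tibble(pairs))
  check_columns(pairs, c("receptor", "partner"), "pairs")

  genes <- rownames(expr)
  gene_sd <- apply(expr, 1, sd)
  usable <- genes[gene_sd > 0]

  pair_r <- map2_dbl(pairs$receptor, pairs$partner, function(r, p) {
    if (!(r %in% usable) || !(p %in% usable)) return(NA_real_)
    cor(expr[r, ], expr[p, ])
  })

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    code
  }
  tested_key <- paste(pmin(pairs$receptor, pairs$partner),
                      pmax(pairs$receptor, pairs$partner))
  background <- withr_seed({
    draw <- function(k) {
      a <- sample(usable, k, replace = TRUE)
      b <- sample(usable, k, replace = TRUE)
      keep <- a != b & !paste(pmin(a, b), pmax(a, b)) %in% tested_key
      unique(tibble(a = a[keep], b = b[keep]))
    }
    bg <- draw(3 * n_background)
    while (nrow(bg) < n_background) bg <- distinct(bind_rows(bg, draw(n_background)))
    bg[seq_len(n_background), ]
  })
  bg_r <- map2_dbl(background$a, background$b,
                   function(a, b) cor(expr[a, ], expr[b, ]))

  bg_mean <- mean(bg_r)
  bg_sd <- sd(bg_r)
  t_p <- map_dbl(pair_r, function(r) {
    if (is.na(r)) return(NA_real_)
    tstat <- (r - bg_mean) / bg_sd
    2 * pt(abs(tstat), df = length(bg_r) - 1, lower.tail = FALSE)
  })
  q <- adjust_pvalues(t_p)
  tibble(receptor = pairs$receptor, partner = pairs$partner,
         r = pair_r, t_p = t_p, q = q,
         correlated = !is.na(q) & q < q_cut & abs(pair_r) > r_cut)
}

#' Prevalence of concordant vs discordant axis regulation per subtype
#'
#' Among axis pairs whose two members both pass `|lfc| > lfc_cut` in a
#' subtype, counts pairs with the same log2-fold-change direction
#' (concordant) vs opposite directions (discordant), and flags subtypes
#' where concordant regulation prevails.
#'
#' @inheritParams build_code_matrix
#' @param lfc_cut Absolute fold-change threshold; default 1.
#' @return Tibble with `subtype`, `n_concordant`, `n_discordant`,
#'   `prevalence_flag`.
#' @export
concordance_prevalence <- function(de_tables, pairs, lfc_cut = 1) {
  pairs <- distinct(as_tibble(pairs))
  check_columns(pairs, c("receptor", "partner"), "pairs")
  imap(de_tables, function(de, subtype) {
    de <- as_tibble(de)
    lr <- de$lfc[match(pairs$receptor, de$gene)]
    lp <- de$lfc[match(pairs$partner, de$gene)]
    qual <- !is.na(lr) & !is.na(lp) & abs(lr) > lfc_cut & abs(lp) > lfc_cut
    conc <- sum(qual & sign(lr) == sign(lp))
    disc <- sum(qual & sign(lr) != sign(lp))
    tibble(subtype = subtype, n_concordant = conc, n_discordant = disc,
           prevalence_flag = conc > disc)
  }) |>
    list_rbind()
}

#' Associate recurrently mutated cancer genes with axis co-regulation
#'
#' Per subtype, the mutation frequency of a cancer gene is the fraction of
#' the subtype's samples carrying at least one mutation in it (a sample
#' counts once regardless of multiplicity). The `top_k` genes by frequency
#' are kept per subtype, with ties at rank `top_k` all included. Each
#' retained gene is then scored by the mean, over the subtypes where it is a
#' top mutated gene, of the number of axis pairs with a score of |2| in that
#' subtype.
#'
#' @param mutations Tibble with columns `gene`, `sample`, `subtype` (one row
#'   per mutation event).
#' @param cancer_genes Tibble with `gene`, `role` (`oncogene`/`TSG`/`both`);
#'   mutations are restricted to these genes.
#' @param matrix A `code_matrix` covering the mutation subtypes.
#' @param top_k Number of top mutated genes per subtype; default 5.
#' @param subtype_sizes Optional tibble `subtype`, `n_samples` giving cohort
#'   sizes; defaults to the distinct samples observed in `mutations`.
#' @return Tibble sorted by descending `avg_coregulated`: `gene`, `role`,
#'   `n_subtypes`, `avg_coregulated`.
#' @export
mutation_axis_association <- function(mutations, cancer_genes, matrix,
                                      top_k = 5, subtype_sizes = NULL) {
  stopifnot(inherits(matrix, "code_matrix"))
  mutations <- as_tibble(mutations)
  cancer_genes <- as_tibble(cancer_genes)
  check_columns(mutations, c("gene", "sample", "subtype"), "mutations")
  check_columns(cancer_genes, c("gene", "role"), "cancer_genes")

  mutations <- mutations |>
    filter(.data$gene %in% cancer_genes$gene) |>
    distinct(.data$gene, .data$sample, .data$subtype)
  sizes <- subtype_sizes %||%
    (mutations |> group_by(.data$subtype) |>
       summarise(n_samples = n_distinct(.data$sample), .groups = "drop"))

  matrix_subtypes <- code_matrix_subtypes(matrix)
  scores <- code_matrix_scores(matrix)
  coreg_counts <- colSums(abs(scores) == 2)

  freq <- mutations |>
    group_by(.data$subtype, .data$gene) |>
    summarise(n_mutated = n_distinct(.data$sample), .groups = "drop") |>
    inner_join(sizes, by = "subtype") |>
    mutate(frequency = .data$n_mutated / .data$n_samples)

  known <- freq$subtype %in% matrix_subtypes
  if (any(!known)) {
    rlang::inform(sprintf(
      "mutation_axis_association: subtype(s) absent from the score matrix skipped: %s",
      paste(unique(freq$subtype[!known]), collapse = ", ")))
    freq <- freq[known, , drop = FALSE]
  }

  top <- freq |>
    group_by(.data$subtype) |>
    filter(dplyr::min_rank(desc(.data$frequency)) <= top_k) |>
    ungroup()

  top |>
    mutate(coregulated = coreg_counts[.data$subtype]) |>
    group_by(.data$gene) |>
    summarise(n_subtypes = n(),
              avg_coregulated = mean(.data$coregulated), .groups = "drop") |>
    left_join(distinct(cancer_genes, .data$gene, .keep_all = TRUE),
              by = "gene") |>
    select("gene", "role", "n_subtypes", "avg_coregulated") |>
    arrange(desc(.data$avg_coregulated), .data$gene)
}
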