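# Pathway abundance score and transcript-metabolite concordance.

#' Pathway abundance score
#'
#' Sign-balance statistic over the log2 fold changes of a pathway's members:
#' `pas = (I - D) / S`, where `I` is the number of upregulated members
#' (`lfc > 0`), `D` the number downregulated (`lfc < 0`), and
#' `S = I + D`, or 1 when `I + D = 0`. Zero and missing fold changes count
#' toward neither direction. A positive score marks a pathway enriched in
#' cancer, a negative one enrichment in normal tissue.
#'
#' @param member_lfcs Numeric vector of member log2 fold changes; may be
#'   empty or contain `NA`.
#' @return One-row tibble with columns `I`, `D`, `S`, `pas`.
#' @export
pas <- function(member_lfcs) {
  x <- member_lfcs[!is.na(member_lfcs)]
  I <- sum(x > 0)
  D <- sum(x < 0)
  S <- if (I + D == 0) 1L else I + D
  tibble(I = as.integer(I), D = as.integer(D), S = as.integer(S),
         pas = (I - D) / S)
}

#' Transcript-metabolite concordance code
#'
#' Compares the sign of an externally computed gene-set enrichment score
#' (ES) with the sign of the pathway abundance score (PAS): `+1` when both
#' are positive (co-enrichment in cancer), `-1` when both are negative
#' (co-enrichment in normal), `0` otherwise. The ES significance flag
#' (`es_padj < padj_cut`) is reported alongside but does not gate the sign.
#'
#' @param es Enrichment score(s).
#' @param es_padj Adjusted p-value(s) of the enrichment, in `[0, 1]`.
#' @param pas_value Pathway abundance score(s).
#' @param padj_cut Significance threshold for the flag; default 0.01.
#' @return Tibble with integer `concord` and logical `significant`.
#' @export
concordance <- function(es, es_padj, pas_value, padj_cut = 0.01) {
  check_prob(es_padj, "es_padj")
  concord <- ifelse(is.na(es) | is.na(pas_value), NA_integer_,
             ifelse(es > 0 & pas_value > 0, 1L,
             ifelse(es < 0 & pas_value < 0, -1L, 0L)))
  tibble(concord = as.integer(concord),
         significant = !is.na(es_padj) & es_padj < padj_cut)
}

#' Read a GMT gene-set file
#'
#' @param path Standard GMT file: one set per line, tab-separated
#'   `name`, `description`, members.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Per-pathway transcript-metabolite concordance table
#'
#' For each pathway, computes the PAS over its metabolite members (from the
#' metabolite differential-abundance table) and, as a companion column, over
#' its enzyme/gene members (from the DE table), joins the externally
#' supplied enrichment scores, and emits the concordance code. Pathway
#' members absent from the respective tables are logged and ignored;
#' pathways absent from the ES table keep a missing `es` and `concord`.
#'
#' @param de A DE table (`gene`, `lfc`, ...).
#' @param metabolite_lfcs Tibble with `metabolite`, `lfc`.
#' @param gene_sets Named list: pathway -> gene members (see [read_gmt()]).
#' @param metabolite_sets Named list: pathway -> metabolite members.
#' @param es_table Tibble with `pathway`, `es`, `es_padj`.
#' @param padj_cut Significance threshold for the ES flag; default 0.01.
#' @return Tibble with one row per pathway: `pathway`, `pas_met`,
#'   `pas_gene`, `es`, `es_padj`, `concord`, `significant`.
#' @export
pathway_concordance_table <- function(de, metabolite_lfcs, gene_sets,
                                      metabolite_sets, es_table,
                                      padj_cut = 0.01) {
  de <- as_tibble(de)
  metabolite_lfcs <- as_tibble(metabolite_lfcs)
  es_table <- as_tibble(es_table)
  check_columns(de, c("gene", "lfc"), "DE table")
  check_columns(metabolite_lfcs, c("metabolite", "lfc"), "metabolite_lfcs")
  check_columns(es_table, c("pathway", "es", "es_padj"), "es_table")

  pathways <- union(names(metabolite_sets), names(gene_sets))
  rows <- map(pathways, function(pw) {
    mets <- metabolite_sets[[pw]] %||% character()
    genes <- gene_sets[[pw]] %||% character()
    missing_members <- c(setdiff(mets, metabolite_lfcs$metabolite),
                         setdiff(genes, de$gene))
    if (length(missing_members) > 0) {
      rlang::inform(sprintf(
        "pathway_concordance_table: %d member(s) of '%s' not found and ignored",
        length(missing_members), pw))
    }
    pas_met <- pas(metabolite_lfcs$lfc[metabolite_lfcs$metabolite %in% mets])
    pas_gene <- pas(de$lfc[de$gene %in% genes])
    tibble(pathway = pw, pas_met = pas_met$pas, pas_gene = pas_gene$pas)
  })
  out <- list_rbind(rows) |>
    left_join(es_table, by = "pathway")
  cc <- concordance(out$es, out$es_padj, out$pas_met, padj_cut = padj_cut)
  out$concord <- cc$concord
  out$significant <- cc$significant
  out
}
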