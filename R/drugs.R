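# Growth-inhibitory drug calling from pooled viability screens.

#' Sarle's bimodality coefficient
#'
#' Sample-adjusted moment statistic
#' `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))`, with `g1` the
#' bias-corrected sample skewness (G1) and `g2` the bias-corrected sample
#' excess kurtosis (G2). For a normal distribution the coefficient tends to
#' 1/3; a balanced two-point mixture drives it toward 1; the conventional
#' bimodality call threshold is values above 5/9 (the uniform's value),
#' though the drug-activity filter in this package uses 0.35. The statistic
#' is invariant to affine transforms of the data.
#'
#' @param values Numeric vector, `n >= 4`, positive variance; `NA` dropped.
#' @return The coefficient (positive scalar).
#' @export
bimodality_coefficient <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 4) stop_schema("bimodality_coefficient needs >= 4 values, got %d", n)
  if (var(x) == 0) stop_schema("bimodality_coefficient needs positive variance")
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Construct a drug-response panel
#'
#' @param panel Tibble with columns `drug`, `cell_line`, `replicate` (1/2,
#'   ...), `lfc` (log2 fold change in cell count; `NA` allowed).
#' @param drug_meta Tibble with `drug`, `targets` (semicolon-joined gene
#'   symbols), `moa`, `action`; one row per drug in `panel`.
#' @param cell_meta Tibble with `cell_line`, `tissue`; one row per cell line
#'   in `panel`.
#' @return Object of class `drug_panel`.
#' @export
drug_panel <- function(panel, drug_meta, cell_meta) {
  panel <- as_tibble(panel)
  drug_meta <- as_tibble(drug_meta)
  cell_meta <- as_tibble(cell_meta)
  check_columns(panel, c("drug", "cell_line", "replicate", "lfc"), "panel")
  check_columns(drug_meta, c("drug", "targets", "moa", "action"), "drug_meta")
  check_columns(cell_meta, c("cell_line", "tissue"), "cell_meta")
  no_meta <- setdiff(unique(panel$drug), drug_meta$drug)
  if (length(no_meta) > 0) {
    stop_schema("drug(s) without metadata: %s",
                paste(utils::head(no_meta, 3), collapse = ", "))
  }
  no_tissue <- setdiff(unique(panel$cell_line), cell_meta$cell_line)
  if (length(no_tissue) > 0) {
    stop_schema("cell line(s) without tissue label: %s",
                paste(utils::head(no_tissue, 3), collapse = ", "))
  }
  structure(list(panel = panel, drug_meta = drug_meta,
                 cell_meta = cell_meta),
            class = "drug_panel")
}

#' @export
print.drug_panel <- function(x, ...) {
  cat(sprintf("<drug_panel> %d drugs x %d cell lines, %d replicate(s)\n",
              n_distinct(x$panel$drug), n_distinct(x$panel$cell_line),
              n_distinct(x$panel$replicate)))
  invisible(x)
}

#' Call growth-inhibitory (active) drugs
#'
#' A drug is active when its replicate-replicate Pearson correlation of
#' per-cell-line LFC profiles exceeds `corr_threshold` and the bimodality
#' coefficient of its (replicate-averaged) LFC distribution across cell
#' lines exceeds `bc_threshold` — both strict inequalities. Drugs with
#' fewer than 4 scored cell lines get a missing call.
#'
#' @param panel A [drug_panel()] with two or more replicates.
#' @param corr_threshold Correlation threshold; default 0.2.
#' @param bc_threshold Bimodality threshold; default 0.35.
#' @return Tibble with `drug`, `correlation`, `bimodality`, `active`,
#'   `n_cell_lines`.
#' @export
activity_calls <- function(panel, corr_threshold = 0.2, bc_threshold = 0.35) {
  stopifnot(inherits(panel, "drug_panel"))
  reps <- sort(unique(panel$panel$replicate))
  if (length(reps) < 2) {
    stop_schema("activity_calls needs >= 2 replicates for the correlation")
  }
  wide <- panel$panel |>
    tidyr::pivot_wider(id_cols = c("drug", "cell_line"),
                       names_from = "replicate", values_from = "lfc",
                       names_prefix = "rep_")
  rep_cols <- paste0("rep_", reps[1:2])
  rows <- wide |>
    group_by(.data$drug) |>
    group_split() |>
    map(function(d) {
      r1 <- d[[rep_cols[1]]]
      r2 <- d[[rep_cols[2]]]
      mean_lfc <- rowMeans(cbind(r1, r2), na.rm = TRUE)
      mean_lfc[is.nan(mean_lfc)] <- NA_real_
      n_scored <- sum(!is.na(mean_lfc))
      if (n_scored < 4) {
        return(tibble(drug = d$drug[1], correlation = NA_real_,
                      bimodality = NA_real_, active = NA,
                      n_cell_lines = n_scored))
      }
      correlation <- cor(r1, r2, use = "pairwise.complete.obs")
      bc <- bimodality_coefficient(mean_lfc)
      tibble(drug = d$drug[1], correlation = correlation, bimodality = bc,
             active = !is.na(correlation) & correlation > corr_threshold &
               bc > bc_threshold,
             n_cell_lines = n_scored)
    })
  list_rbind(rows) |> arrange(.data$drug)
}

#' Rank top growth-inhibiting drugs per cell line
#'
#' Per cell line, drugs are ranked by ascending replicate-averaged LFC (most
#' negative = strongest growth inhibition, ties broken by drug id) and the
#' first `k` retained. Per-tissue aggregations count, for each mechanism of
#' action and each target, the number of cell lines whose top-`k` list
#' includes a drug with that annotation; target counts also carry the
#' fraction normalized by the tissue's total top-`k` cell-line-drug pairs.
#'
#' @param panel A [drug_panel()].
#' @param k List length per cell line; default 10.
#' @return List with tibbles `top` (`cell_line`, `tissue`, `rank`, `drug`,
#'   `lfc`), `by_moa` (`tissue`, `moa`, `n_cell_lines`), and `by_target`
#'   (`tissue`, `target`, `n_cell_lines`, `fraction`).
#' @export
top_inhibitors <- function(panel, k = 10) {
  stopifnot(inherits(panel, "drug_panel"))
  prof <- panel$panel |>
    group_by(.data$drug, .data$cell_line) |>
    summarise(lfc = mean(.data$lfc, na.rm = TRUE), .groups = "drop") |>
    filter(is.finite(.data$lfc))
  top <- prof |>
    left_join(panel$cell_meta, by = "cell_line") |>
    group_by(.data$cell_line) |>
    arrange(.data$lfc, .data$drug, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= k) |>
    ungroup() |>
    select("cell_line", "tissue", "rank", "drug", "lfc")

  annotated <- top |> left_join(panel$drug_meta, by = "drug")
  by_moa <- annotated |>
    distinct(.data$tissue, .data$cell_line, .data$moa) |>
    group_by(.data$tissue, .data$moa) |>
    summarise(n_cell_lines = n(), .groups = "drop") |>
    arrange(.data$tissue, desc(.data$n_cell_lines), .data$moa)

  pair_totals <- top |>
    group_by(.data$tissue) |>
    summarise(n_pairs = n(), .groups = "drop")
  by_target <- annotated |>
    mutate(target = split_terms(.data$targets)) |>
    tidyr::unnest_longer("target") |>
    distinct(.data$tissue, .data$cell_line, .data$target) |>
    group_by(.data$tissue, .data$target) |>
    summarise(n_cell_lines = n(), .groups = "drop") |>
    left_join(pair_totals, by = "tissue") |>
    mutate(fraction = .data$n_cell_lines / .data$n_pairs) |>
    select("tissue", "target", "n_cell_lines", "fraction") |>
    arrange(.data$tissue, desc(.data$n_cell_lines), .data$target)

  list(top = top, by_moa = by_moa, by_target = by_target)
}

#' Overlap of active-drug targets with survival-associated receptors
#'
#' For each active drug, reports the subset of its targets that are also
#' receptors mediating survival-associated axes, plus the two-set Venn
#' region sizes (targets only, receptors only, intersection) over the
#' pooled target set of active drugs.
#'
#' @param active An [activity_calls()] table (only `active == TRUE` rows are
#'   used).
#' @param drug_meta Drug metadata with `drug`, `targets`.
#' @param survival_receptors Non-empty character vector of receptor ids.
#' @return List with `per_drug` (tibble `drug`, `targets`,
#'   `overlapping_targets`, `n_overlap`) and `venn` (tibble
#'   `targets_only`, `receptors_only`, `intersection`).
#' @export
survival_target_overlap <- function(active, drug_meta, survival_receptors) {
  stopifnot(length(survival_receptors) > 0)
  active <- as_tibble(active)
  drug_meta <- as_tibble(drug_meta)
  check_columns(active, c("drug", "active"), "activity calls")
  check_columns(drug_meta, c("drug", "targets"), "drug_meta")
  act <- active |>
    filter(!is.na(.data$active), .data$active) |>
    left_join(drug_meta, by = "drug")
  target_sets <- split_terms(act$targets)
  per_drug <- tibble(
    drug = act$drug,
    targets = map_chr(target_sets, paste, collapse = ";"),
    overlapping_targets = map_chr(target_sets, function(t) {
      paste(intersect(t, survival_receptors), collapse = ";")
    }),
    n_overlap = map_int(target_sets, function(t) {
      length(intersect(t, survival_receptors))
    }))
  pooled <- unique(unlist(target_sets))
  venn <- tibble(
    targets_only = length(setdiff(pooled, survival_receptors)),
    receptors_only = length(setdiff(survival_receptors, pooled)),
    intersection = length(intersect(pooled, survival_receptors)))
  list(per_drug = per_drug, venn = venn)
}
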