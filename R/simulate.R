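# Synthetic cohort generators: every pipeline input with planted structure.
#
# All generators are pure functions of the configuration: each one seeds the
# RNG from config$seed plus a fixed per-generator offset, so a given config
# reproduces byte-identical outputs, and every generator emits a truth table
# describing the planted effects.

SEED_OFFSETS <- c(network = 1L, counts = 2L, survival = 3L,
                  metabolites = 4L, drugs = 5L)

#' Default planted axes
#'
#' A mix of receptor-ligand and receptor-enzyme axes, half co-upregulated
#' (`lfc = +2`) and half co-downregulated (`lfc = -2`).
#'
#' @param n Number of planted axes; default 10.
#' @param lfc Magnitude of the planted log2 fold change; default 2.
#' @return Tibble with `receptor`, `partner`, `kind`, `lfc_r`, `lfc_p`.
#' @export
default_planted_axes <- function(n = 10, lfc = 2) {
  kind <- rep(c("ligand", "enzyme"), length.out = n)
  direction <- rep(c(1, -1), each = ceiling(n / 2))[seq_len(n)]
  tibble(
    receptor = sprintf("RCP%02d", seq_len(n)),
    partner = ifelse(kind == "ligand", sprintf("LIG%02d", seq_len(n)),
                     sprintf("ENZ%02d", seq_len(n))),
    kind = kind,
    lfc_r = direction * lfc,
    lfc_p = direction * lfc)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults define
#' the reference synthetic study: negative-binomial expression for 2000
#' genes in 8 subtypes (50 tumor vs 50 normal samples each, dispersion
#' 0.05), 10 planted axes at |LFC| = 2 among 20 decoy axes, exponential
#' survival with a 3-fold both-high hazard multiplier and 30% censoring,
#' 20 pathways with 70% transcript-metabolite concordance, and a 60-drug
#' by 100-cell-line viability panel with 25% planted active drugs
#' (bimodal separation 3, replicate noise 0.1).
#'
#' @param seed Integer seed (mandatory).
#' @param n_genes Total genes in each count matrix.
#' @param n_samples_tumor,n_samples_normal Samples per subtype and cohort.
#' @param n_subtypes Number of cancer subtypes (grouped two per tissue).
#' @param nb_mean_log_range Range of per-gene log2 mean expression; means
#'   are drawn log-uniformly over `2^range`.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`).
#' @param planted_axes Tibble as returned by [default_planted_axes()].
#' @param n_decoy_axes Unplanted axes added to the network.
#' @param survival List: `baseline_hazard`, `censoring_fraction`,
#'   `axis_multiplier` (both-high hazard multiplier, recycled over planted
#'   axes), `individual_multiplier` (per-gene high-group multiplier,
#'   default 1 = pure interaction).
#' @param drug List: `n_drugs`, `n_cell_lines`, `active_fraction`,
#'   `bimodal_separation`, `replicate_noise_sd`.
#' @param pathways List: `n_pathways`, `members_per_pathway`,
#'   `concordant_fraction`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 2000,
                       n_samples_tumor = 50,
                       n_samples_normal = 50,
                       n_subtypes = 8,
                       nb_mean_log_range = c(3, 10),
                       nb_dispersion = 0.05,
                       planted_axes = default_planted_axes(),
                       n_decoy_axes = 20,
                       survival = list(),
                       drug = list(),
                       pathways = list()) {
  if (missing(seed)) stop_schema("sim_config requires an explicit seed")
  survival <- modifyList(
    list(baseline_hazard = 0.1, censoring_fraction = 0.3,
         axis_multiplier = 3, individual_multiplier = 1), survival)
  drug <- modifyList(
    list(n_drugs = 60, n_cell_lines = 100, active_fraction = 0.25,
         bimodal_separation = 3, replicate_noise_sd = 0.1), drug)
  pathways <- modifyList(
    list(n_pathways = 20, members_per_pathway = 8,
         concordant_fraction = 0.7), pathways)
  planted_axes <- as_tibble(planted_axes)
  check_columns(planted_axes, c("receptor", "partner", "kind", "lfc_r",
                                "lfc_p"), "planted_axes")
  if (anyDuplicated(planted_axes[, c("receptor", "partner")]) > 0) {
    stop_schema("duplicate planted axis pair")
  }
  stopifnot(n_genes > 0, n_samples_tumor > 0, n_samples_normal > 0,
            n_subtypes > 0, nb_dispersion > 0,
            survival$censoring_fraction >= 0,
            survival$censoring_fraction < 1)
  if (any(survival$axis_multiplier <= 0)) {
    stop_schema("axis hazard multipliers must be positive")
  }
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_samples_tumor = n_samples_tumor,
                 n_samples_normal = n_samples_normal,
                 n_subtypes = n_subtypes,
                 nb_mean_log_range = nb_mean_log_range,
                 nb_dispersion = nb_dispersion,
                 planted_axes = planted_axes,
                 n_decoy_axes = n_decoy_axes,
                 survival = survival, drug = drug, pathways = pathways),
            class = "sim_config")
}

sim_subtype_labels <- function(config) {
  tissue <- sprintf("TIS%d", ceiling(seq_len(config$n_subtypes) / 2))
  sprintf("%s_S%d", tissue, seq_len(config$n_subtypes))
}

decoy_axes <- function(config) {
  n <- config$n_decoy_axes
  if (n == 0) {
    return(tibble(receptor = character(), partner = character(),
                  kind = character()))
  }
  kind <- rep(c("ligand", "enzyme"), length.out = n)
  tibble(receptor = sprintf("DRCP%02d", seq_len(n)),
         partner = ifelse(kind == "ligand", sprintf("DLIG%02d", seq_len(n)),
                          sprintf("DENZ%02d", seq_len(n))),
         kind = kind)
}

#' Generate a schema-valid axis-network fixture
#'
#' Emits component and edge tables containing every planted axis plus decoy
#' axes, loadable by [axis_network()]. Receptor-enzyme axes get a mediating
#' metabolite ligand with enzyme-ligand and ligand-receptor edges plus a
#' derived receptor-enzyme edge; the functional-interaction confidence
#' scores (all planted above the default 150 cutoff) are returned alongside.
#'
#' @param config A [sim_config()].
#' @return List: `network` (an `axis_network`), `confidence` (tibble
#'   `receptor`, `enzyme`, `confidence`), `truth` (planted axes tibble).
#' @export
generate_network_fixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["network"]])
  axes <- bind_rows(
    config$planted_axes |> select("receptor", "partner", "kind") |>
      mutate(planted = TRUE),
    decoy_axes(config) |> mutate(planted = FALSE))

  receptors <- axes |>
    distinct(id = .data$receptor) |>
    mutate(family = sample(c("classA", "classB", "classC"), n(),
                           replace = TRUE),
           coupling = sample(c("Gi/o", "Gq/11", "Gs", "Gs;Gq/11"), n(),
                             replace = TRUE),
           orphan = FALSE)

  lig_axes <- axes[axes$kind == "ligand", , drop = FALSE]
  enz_axes <- axes[axes$kind == "enzyme", , drop = FALSE]
  mediators <- tibble(id = sprintf("MET_%s", enz_axes$partner),
                      name = sprintf("metabolite of %s", enz_axes$partner),
                      ligand_type = "metabolite",
                      external_refs = sprintf("chebi:%05d",
                                              seq_len(nrow(enz_axes))))
  ligands <- bind_rows(
    tibble(id = unique(lig_axes$partner)) |>
      mutate(name = .data$id, ligand_type = "peptide",
             external_refs = NA_character_),
    mediators)

  enzymes <- tibble(id = unique(enz_axes$partner)) |>
    mutate(cc_terms = "plasma membrane",
           class_terms = "acyltransferase",
           literature_count = sample(10:500, n(), replace = TRUE))

  confidence <- tibble(receptor = enz_axes$receptor,
                       enzyme = enz_axes$partner,
                       confidence = sample(150:900, nrow(enz_axes),
                                           replace = TRUE))

  edges <- bind_rows(
    tibble(source = lig_axes$partner, target = lig_axes$receptor,
           edge_kind = "ligand_receptor",
           action = sample(c("agonist", "antagonist"), nrow(lig_axes),
                           replace = TRUE, prob = c(0.8, 0.2)),
           direction = NA_character_, confidence = NA_integer_),
    tibble(source = enz_axes$partner, target = mediators$id,
           edge_kind = "enzyme_ligand", action = NA_character_,
           direction = sample(c("LR", "RL", "UN"), nrow(enz_axes),
                              replace = TRUE, prob = c(0.8, 0.1, 0.1)),
           confidence = NA_integer_),
    tibble(source = mediators$id, target = enz_axes$receptor,
           edge_kind = "ligand_receptor", action = "agonist",
           direction = NA_character_, confidence = NA_integer_),
    tibble(source = enz_axes$receptor, target = enz_axes$partner,
           edge_kind = "receptor_enzyme", action = NA_character_,
           direction = NA_character_,
           confidence = confidence$confidence))

  network <- axis_network(receptors, ligands, enzymes, edges)
  list(network = network, confidence = confidence,
       truth = axes)
}

#' Generate negative-binomial count matrices with planted fold changes
#'
#' Per-gene mean expression is drawn log-uniformly over
#' `2^nb_mean_log_range`; counts are negative-binomial with variance
#' `mu + dispersion * mu^2`. Planted axis genes have their tumor-sample mean
#' multiplied by `2^lfc` in every subtype; all other genes are null.
#'
#' @param config A [sim_config()].
#' @return List: `counts` (named list of [count_matrix()] per subtype) and
#'   `truth` (tibble `gene`, `subtype`, `true_lfc` for all planted
#'   nonzero fold changes).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["counts"]])
  axes <- config$planted_axes
  planted_genes <- unique(c(rbind(axes$receptor, axes$partner)))
  planted_lfc <- setNames(numeric(length(planted_genes)), planted_genes)
  # a gene keeps the lfc of its first planted axis
  for (i in seq_len(nrow(axes))) {
    r <- axes$receptor[i]; p <- axes$partner[i]
    if (planted_lfc[[r]] == 0) planted_lfc[[r]] <- axes$lfc_r[i]
    if (planted_lfc[[p]] == 0) planted_lfc[[p]] <- axes$lfc_p[i]
  }
  decoy_genes <- with(decoy_axes(config), unique(c(receptor, partner)))
  n_filler <- config$n_genes - length(planted_genes) - length(decoy_genes)
  if (n_filler < 0) stop_schema("n_genes too small for the planted network")
  genes <- c(planted_genes, decoy_genes,
             sprintf("G%05d", seq_len(n_filler)))
  mu <- 2^runif(length(genes), config$nb_mean_log_range[1],
                config$nb_mean_log_range[2])
  names(mu) <- genes
  size <- 1 / config$nb_dispersion
  subtypes <- sim_subtype_labels(config)

  counts <- setNames(map(subtypes, function(st) {
    nt <- config$n_samples_tumor
    nn <- config$n_samples_normal
    tissue <- stringr::str_split_i(st, stringr::fixed("_"), 1)
    shift <- rep(1, length(genes))
    shift[match(planted_genes, genes)] <- 2^planted_lfc
    m_tumor <- matrix(rnbinom(length(genes) * nt, mu = mu * shift,
                              size = size),
                      nrow = length(genes), byrow = FALSE)
    m_normal <- matrix(rnbinom(length(genes) * nn, mu = mu, size = size),
                       nrow = length(genes), byrow = FALSE)
    m <- cbind(m_tumor, m_normal)
    rownames(m) <- genes
    colnames(m) <- c(sprintf("%s_T%03d", st, seq_len(nt)),
                     sprintf("%s_N%03d", st, seq_len(nn)))
    count_matrix(m, tibble(sample = colnames(m),
                           cohort = rep(c("tumor", "normal"), c(nt, nn)),
                           tissue = tissue, subtype = st))
  }), subtypes)

  truth <- tidyr::expand_grid(gene = planted_genes, subtype = subtypes) |>
    mutate(true_lfc = planted_lfc[.data$gene])
  list(counts = counts, truth = truth)
}

# rexp with mu = 0 -> Inf censor times (no censoring)
censor_rate_for_fraction <- function(hazards, fraction) {
  if (fraction == 0) return(0)
  f <- function(mu) mean(mu / (mu + hazards)) - fraction
  stats::uniroot(f, lower = 1e-12, upper = 1e6 * max(hazards),
                 tol = 1e-12)$root
}

#' Generate clinical survival tables linked to planted axis expression
#'
#' Patients are the tumor samples of each subtype. Event times are
#' exponential with per-patient hazard `baseline *
#' prod(axis_multiplier^both_high) * prod(individual_multiplier^high)` over
#' the planted axes, where high/both-high indicators come from median splits
#' of normalized log2 expression within the cohort (the same stratification
#' the survival screen applies). Censoring is independent exponential, with
#' its rate calibrated so the expected censored fraction equals
#' `censoring_fraction`.
#'
#' @param config A [sim_config()].
#' @param counts The `counts` list from [generate_counts()].
#' @return List: `clinical` (tibble `patient`, `time`, `event`, `cohort`),
#'   `expression` (named list of normalized log2 tumor-expression matrices
#'   per cohort), `truth` (tibble `receptor`, `partner`, `kind`,
#'   `axis_multiplier`).
#' @export
generate_survival <- function(config, counts) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["survival"]])
  sv <- config$survival
  axes <- config$planted_axes
  mult <- rep_len(sv$axis_multiplier, nrow(axes))
  ind_mult <- rep_len(sv$individual_multiplier, nrow(axes))

  per_cohort <- imap(counts, function(cm, st) {
    tumor <- cm$sample_meta$cohort == "tumor"
    expr <- normalized_log2(cm)[, tumor, drop = FALSE]
    n <- ncol(expr)
    log_h <- rep(log(sv$baseline_hazard), n)
    for (i in seq_len(nrow(axes))) {
      vr <- expr[axes$receptor[i], ]
      vp <- expr[axes$partner[i], ]
      hi_r <- vr > median(vr)
      hi_p <- vp > median(vp)
      log_h <- log_h + log(mult[i]) * (hi_r & hi_p) +
        log(ind_mult[i]) * (hi_r + hi_p)
    }
    h <- exp(log_h)
    t_event <- rexp(n, rate = h)
    mu <- censor_rate_for_fraction(h, sv$censoring_fraction)
    t_censor <- if (mu == 0) rep(Inf, n) else rexp(n, rate = mu)
    tibble(patient = colnames(expr),
           time = pmin(t_event, t_censor),
           event = as.integer(t_event <= t_censor),
           cohort = st)
  })
  expression <- map(counts, function(cm) {
    tumor <- cm$sample_meta$cohort == "tumor"
    normalized_log2(cm)[, tumor, drop = FALSE]
  })
  list(clinical = list_rbind(per_cohort),
       expression = expression,
       truth = axes |> select("receptor", "partner", "kind") |>
         mutate(axis_multiplier = mult, individual_multiplier = ind_mult))
}

#' Generate pathway sets, metabolite fold changes and enrichment scores
#'
#' Each pathway gets a planted direction (alternating up/down). Concordant
#' pathways (`concordant_fraction` of them) have metabolite fold-change
#' signs and enrichment-score sign matching their gene-member direction;
#' discordant pathways get an opposed enrichment-score sign, so their
#' expected concordance code is 0 while concordant pathways expect +/-1.
#'
#' @param config A [sim_config()].
#' @return List: `gene_sets`, `metabolite_sets` (named lists), `gene_de`
#'   (DE-table-shaped tibble for the pathway genes), `metabolite_lfcs`,
#'   `es_table`, and `truth` (tibble `pathway`, `direction`, `concordant`,
#'   `expected_code`).
#' @export
generate_metabolites_and_es <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["metabolites"]])
  pw <- config$pathways
  n <- pw$n_pathways
  m <- pw$members_per_pathway
  ids <- sprintf("PW%03d", seq_len(n))
  direction <- rep_len(c(1, -1), n)
  n_conc <- round(pw$concordant_fraction * n)
  concordant <- seq_len(n) <= n_conc

  gene_sets <- setNames(map(seq_len(n), function(i) {
    sprintf("%s_G%02d", ids[i], seq_len(m))
  }), ids)
  metabolite_sets <- setNames(map(seq_len(n), function(i) {
    sprintf("%s_M%02d", ids[i], seq_len(m))
  }), ids)

  gene_de <- list_rbind(map(seq_len(n), function(i) {
    tibble(gene = gene_sets[[i]],
           lfc = direction[i] * runif(m, 0.5, 3),
           pvalue = runif(m, 1e-6, 0.005))
  }))
  gene_de$padj <- adjust_pvalues(gene_de$pvalue)

  metabolite_lfcs <- list_rbind(map(seq_len(n), function(i) {
    tibble(metabolite = metabolite_sets[[i]],
           lfc = direction[i] * runif(m, 0.2, 2))
  }))

  es_sign <- ifelse(concordant, direction, -direction)
  es_table <- tibble(pathway = ids,
                     es = es_sign * runif(n, 0.8, 2.5),
                     es_padj = runif(n, 1e-5, 0.009))
  truth <- tibble(pathway = ids, direction = direction,
                  concordant = concordant,
                  expected_code = ifelse(concordant, direction, 0L))
  list(gene_sets = gene_sets, metabolite_sets = metabolite_sets,
       gene_de = gene_de, metabolite_lfcs = metabolite_lfcs,
       es_table = es_table, truth = truth)
}

#' Generate a drug-response viability panel with planted active drugs
#'
#' Active drugs (`active_fraction` of `n_drugs`) draw their true per-cell-
#' line log2 fold change from a balanced two-component mixture centered at 0
#' and `-bimodal_separation`; inactive drugs draw from a single broad
#' component. Two replicates add independent Gaussian noise
#' (`replicate_noise_sd`). Active drugs' target sets are seeded from the
#' planted survival receptors.
#'
#' @param config A [sim_config()].
#' @param survival_truth Optional tibble with a `receptor` column (e.g. from
#'   [generate_survival()]); defaults to the planted axes' receptors.
#' @return List: `panel` (a [drug_panel()]) and `truth` (tibble `drug`,
#'   `active`).
#' @export
generate_drug_panel <- function(config, survival_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OFFSETS[["drugs"]])
  dg <- config$drug
  receptors <- unique((survival_truth %||% config$planted_axes)$receptor)
  n_active <- round(dg$active_fraction * dg$n_drugs)
  drugs <- sprintf("DRUG%03d", seq_len(dg$n_drugs))
  active <- seq_len(dg$n_drugs) <= n_active
  cell_lines <- sprintf("CL%03d", seq_len(dg$n_cell_lines))
  tissues <- sample(c("lung", "liver", "breast", "lymphoid", "skin"),
                    dg$n_cell_lines, replace = TRUE)

  rows <- map(seq_len(dg$n_drugs), function(i) {
    if (active[i]) {
      component <- rbinom(dg$n_cell_lines, 1, 0.5)
      true_lfc <- -dg$bimodal_separation * component +
        rnorm(dg$n_cell_lines, 0, 0.1)
    } else {
      # inactive: no reproducible cell-line-specific response, so the
      # between-line signal is negligible next to the replicate noise
      true_lfc <- rnorm(dg$n_cell_lines, -0.2, 0.02)
    }
    tibble(drug = drugs[i],
           cell_line = rep(cell_lines, 2),
           replicate = rep(1:2, each = dg$n_cell_lines),
           lfc = rep(true_lfc, 2) +
             rnorm(2 * dg$n_cell_lines, 0, dg$replicate_noise_sd))
  })
  drug_meta <- tibble(
    drug = drugs,
    targets = vapply(seq_len(dg$n_drugs), function(i) {
      paste(sample(receptors, min(2, length(receptors))), collapse = ";")
    }, character(1)),
    moa = sample(c("adenosine receptor antagonist",
                   "muscarinic receptor antagonist",
                   "opioid receptor antagonist",
                   "dopamine receptor antagonist"),
                 dg$n_drugs, replace = TRUE),
    action = sample(c("antagonist", "agonist"), dg$n_drugs,
                    replace = TRUE, prob = c(0.76, 0.24)))
  panel <- drug_panel(list_rbind(rows), drug_meta,
                      tibble(cell_line = cell_lines, tissue = tissues))
  list(panel = panel, truth = tibble(drug = drugs, active = active))
}

#' Write every synthetic pipeline input to a directory
#'
#' Materialises the full set of stage inputs (network component tables,
#' per-subtype counts and sample sheets, clinical survival table, pathway
#' GMTs, metabolite/ES tables, drug panel tables) plus `truth/*.tsv` ground
#' truth, in the layout [run_pipeline()] consumes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE, recursive = TRUE)

  net <- generate_network_fixture(config)
  write_axis_network(net$network, file.path(dir, "network"))
  readr::write_tsv(net$confidence, file.path(dir, "network", "confidence.tsv"))
  readr::write_tsv(net$truth, file.path(dir, "truth", "axes.tsv"))

  cnt <- generate_counts(config)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  for (st in names(cnt$counts)) {
    cm <- cnt$counts[[st]]
    tab <- bind_cols(tibble(gene = rownames(cm$counts)),
                     as_tibble(cm$counts))
    readr::write_tsv(tab, file.path(dir, "counts",
                                    sprintf("counts_%s.tsv", st)))
    readr::write_tsv(cm$sample_meta,
                     file.path(dir, "counts", sprintf("samples_%s.tsv", st)))
  }
  readr::write_tsv(cnt$truth, file.path(dir, "truth", "lfc.tsv"))

  surv <- generate_survival(config, cnt$counts)
  readr::write_tsv(surv$clinical, file.path(dir, "clinical.tsv"))
  readr::write_tsv(surv$truth, file.path(dir, "truth", "survival.tsv"))

  met <- generate_metabolites_and_es(config)
  write_gmt <- function(sets, path) {
    lines <- vapply(names(sets), function(nm) {
      paste(c(nm, "synthetic pathway", sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  write_gmt(met$gene_sets, file.path(dir, "pathways_genes.gmt"))
  write_gmt(met$metabolite_sets, file.path(dir, "pathways_metabolites.gmt"))
  readr::write_tsv(met$gene_de, file.path(dir, "pathway_gene_de.tsv"))
  readr::write_tsv(met$metabolite_lfcs, file.path(dir, "metabolite_lfcs.tsv"))
  readr::write_tsv(met$es_table, file.path(dir, "es_table.tsv"))
  readr::write_tsv(met$truth, file.path(dir, "truth", "pathways.tsv"))

  drg <- generate_drug_panel(config, surv$truth)
  readr::write_tsv(drg$panel$panel, file.path(dir, "panel.tsv"))
  readr::write_tsv(drg$panel$drug_meta, file.path(dir, "drug_meta.tsv"))
  readr::write_tsv(drg$panel$cell_meta, file.path(dir, "cell_meta.tsv"))
  readr::write_tsv(drg$truth, file.path(dir, "truth", "drugs.tsv"))

  invisible(dir)
}
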