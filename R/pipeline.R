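# End-to-end orchestration over a directory of stage inputs.

#' Pipeline configuration
#'
#' Bundles input/output locations, the analysis thresholds (defaulting to
#' the values used throughout the axis analyses) and the seed for the one
#' randomised stage (the correlation background draw).
#'
#' @param input_dir Directory in the layout written by [write_sim_inputs()]:
#'   `network/` component tables, `counts/counts_<subtype>.tsv` +
#'   `samples_<subtype>.tsv` (or `de/de_<subtype>.tsv` to import DE tables
#'   computed elsewhere), `clinical.tsv`, pathway GMT/ES/metabolite tables,
#'   and the drug panel tables. Stages whose inputs are absent are skipped.
#' @param out_dir Output directory for stage tables and the run manifest.
#' @param seed Integer seed.
#' @param stages Character vector of stages to run, in dependency order.
#' @param lfc_cut,padj_cut DE-significance thresholds (1, 0.01).
#' @param recurrence Co-DE recurrence fraction (0.25).
#' @param logrank_alpha Axis log-rank significance bound (0.05).
#' @param fdr_cut FDR bound on axis calls (0.1).
#' @param corr_threshold,bc_threshold Drug-activity thresholds (0.2, 0.35).
#' @param min_confidence Receptor-enzyme confidence cutoff (150).
#' @param top_k Top inhibiting drugs per cell line (10).
#' @param top_mut Top mutated genes per subtype (5).
#' @param n_background Background pairs for correlation calls (1000).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1,
                            stages = c("network", "de", "coregulation",
                                       "concordance", "survival", "drugs"),
                            lfc_cut = 1, padj_cut = 0.01, recurrence = 0.25,
                            logrank_alpha = 0.05, fdr_cut = 0.1,
                            corr_threshold = 0.2, bc_threshold = 0.35,
                            min_confidence = 150, top_k = 10, top_mut = 5,
                            n_background = 1000) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), stages = stages,
                 lfc_cut = lfc_cut, padj_cut = padj_cut,
                 recurrence = recurrence, logrank_alpha = logrank_alpha,
                 fdr_cut = fdr_cut, corr_threshold = corr_threshold,
                 bc_threshold = bc_threshold,
                 min_confidence = min_confidence, top_k = top_k,
                 top_mut = top_mut, n_background = n_background),
            class = "pipeline_config")
}

read_subtype_counts <- function(input_dir) {
  files <- sort(list.files(file.path(input_dir, "counts"),
                           pattern = "^counts_.*\\.tsv$", full.names = TRUE))
  sts <- sub("^counts_(.*)\\.tsv$", "\\1", basename(files))
  setNames(map(seq_along(files), function(i) {
    read_counts(files[i],
                file.path(input_dir, "counts",
                          sprintf("samples_%s.tsv", sts[i])))
  }), sts)
}

#' Run the axis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order (network, DE,
#' coregulation, concordance, survival, drugs), writing one or more TSV
#' tables per stage plus a `manifest.json` recording the configuration
#' hash, seed, package version and per-stage record counts. Identical
#' configuration and inputs produce byte-identical outputs. Stages with
#' missing inputs are skipped (and noted in the manifest); a stage whose
#' upstream dependency was neither run nor cached on disk raises an error
#' naming the stage to run first.
#'
#' @param config A [pipeline_config()], or an `input_dir` path (then
#'   `out_dir` must be given too).
#' @param out_dir Output directory when `config` is a path.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- pipeline_config(config, out_dir %||%
                                stop_schema("out_dir required"))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- config$input_dir
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(packageVersion("gpcraxes")),
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("input_dir", "out_dir"))]),
    stages = list())
  note <- function(stage, status, counts = NULL) {
    manifest$stages[[stage]] <<- c(list(status = status), counts)
  }

  network <- NULL
  pairs <- NULL
  if ("network" %in% config$stages &&
      dir.exists(file.path(inp, "network"))) {
    network <- load_axis_network(file.path(inp, "network"))
    pairs <- axis_pairs(network)
    write_tsv_commented(pairs, out("network_pairs.tsv"),
                        "axis pairs: receptor, partner, partner_kind")
    note("network", "ok",
         list(n_receptors = nrow(network$receptors),
              n_ligands = nrow(network$ligands),
              n_enzymes = nrow(network$enzymes),
              n_edges = nrow(network$edges), n_pairs = nrow(pairs)))
  } else {
    note("network", "skipped")
  }

  de_tables <- NULL
  counts <- NULL
  if ("de" %in% config$stages) {
    de_dir <- file.path(inp, "de")
    if (dir.exists(de_dir)) {
      files <- sort(list.files(de_dir, pattern = "^de_.*\\.tsv$",
                               full.names = TRUE))
      de_tables <- setNames(map(files, read_de_table),
                            sub("^de_(.*)\\.tsv$", "\\1", basename(files)))
      note("de", "imported", list(n_contrasts = length(de_tables)))
    } else if (dir.exists(file.path(inp, "counts"))) {
      counts <- read_subtype_counts(inp)
      de_tables <- imap(counts, function(cm, st) {
        differential_expression(cm, tissue = cm$sample_meta$tissue[1],
                                subtype = st)
      })
      for (st in names(de_tables)) {
        write_tsv_commented(de_tables[[st]], out(sprintf("de_%s.tsv", st)),
                            "per-gene DE: gene, lfc, pvalue, padj")
      }
      note("de", "computed", list(n_contrasts = length(de_tables)))
    } else {
      note("de", "skipped")
    }
  }

  screen_all <- NULL
  if ("coregulation" %in% config$stages && !is.null(de_tables)) {
    if (is.null(pairs)) {
      stop_schema("coregulation requires the network stage; run it first")
    }
    cm <- build_code_matrix(de_tables, pairs,
                            recurrence_fraction = config$recurrence,
                            lfc_cut = config$lfc_cut,
                            padj_cut = config$padj_cut)
    write_tsv_commented(
      cm, out("code_matrix.tsv"),
      "co-DE scores in {-2..2} per subtype; affected = nonzero in >= recurrence fraction")
    aff <- affected_pairs(cm)
    if (nrow(aff) >= 2) {
      write_tsv_commented(cluster_pairs(aff, n_clusters = 2),
                          out("clusters.tsv"),
                          "Ward clusters of affected pair profiles")
    }
    write_tsv_commented(similarity_profiles(cm), out("similarity.tsv"),
                        "receptor-level ligand-/tissue-wise profile distances")
    write_tsv_commented(concordance_prevalence(de_tables, pairs,
                                               lfc_cut = config$lfc_cut),
                        out("prevalence.tsv"),
                        "concordant vs discordant pair counts per subtype")
    counts <- counts %||%
      (if (dir.exists(file.path(inp, "counts"))) read_subtype_counts(inp))
    if (!is.null(counts)) {
      calls <- imap(counts, function(cmx, st) {
        correlation_calls(normalized_log2(cmx), pairs,
                          n_background = config$n_background,
                          seed = config$seed) |>
          mutate(subtype = st, .before = 1)
      })
      write_tsv_commented(list_rbind(calls), out("correlation_calls.tsv"),
                          "pair correlation vs random-pair background")
    }
    note("coregulation", "ok",
         list(n_pairs = nrow(cm), n_affected = nrow(aff)))
  } else if ("coregulation" %in% config$stages) {
    note("coregulation", "skipped")
  }

  if ("concordance" %in% config$stages &&
      file.exists(file.path(inp, "es_table.tsv"))) {
    tab <- pathway_concordance_table(
      de = read_tsv_quiet(file.path(inp, "pathway_gene_de.tsv")),
      metabolite_lfcs = read_tsv_quiet(file.path(inp, "metabolite_lfcs.tsv")),
      gene_sets = read_gmt(file.path(inp, "pathways_genes.gmt")),
      metabolite_sets = read_gmt(file.path(inp, "pathways_metabolites.gmt")),
      es_table = read_tsv_quiet(file.path(inp, "es_table.tsv")),
      padj_cut = config$padj_cut)
    write_tsv_commented(tab, out("pathway_concordance.tsv"),
                        "PAS vs ES concordance per pathway")
    note("concordance", "ok", list(n_pathways = nrow(tab)))
  } else if ("concordance" %in% config$stages) {
    note("concordance", "skipped")
  }

  if ("survival" %in% config$stages &&
      file.exists(file.path(inp, "clinical.tsv"))) {
    if (is.null(pairs)) {
      stop_schema("survival requires the network stage; run it first")
    }
    clinical <- read_tsv_quiet(file.path(inp, "clinical.tsv"))
    counts <- counts %||% read_subtype_counts(inp)
    screens <- map(sort(unique(clinical$cohort)), function(co) {
      cl <- clinical[clinical$cohort == co, , drop = FALSE]
      cmx <- counts[[co]]
      if (is.null(cmx)) return(NULL)
      expr <- normalized_log2(cmx)[, cl$patient, drop = FALSE]
      ds <- survival_dataset(cl, expr, cohort = co)
      axis_screen(ds, pairs, logrank_alpha = config$logrank_alpha) |>
        mutate(cohort = co, .before = 1)
    })
    screen_all <- list_rbind(keep(screens, ~ !is.null(.x)))
    write_tsv_commented(
      screen_all, out("survival_screen.tsv"),
      "combined-stratification axis screen; passes_filter per the HR-fold + log-rank criteria")
    note("survival", "ok",
         list(n_axes_tested = nrow(screen_all),
              n_pass = sum(screen_all$passes_filter)))
  } else if ("survival" %in% config$stages) {
    note("survival", "skipped")
  }

  if ("drugs" %in% config$stages &&
      file.exists(file.path(inp, "panel.tsv"))) {
    panel <- drug_panel(read_tsv_quiet(file.path(inp, "panel.tsv")),
                        read_tsv_quiet(file.path(inp, "drug_meta.tsv")),
                        read_tsv_quiet(file.path(inp, "cell_meta.tsv")))
    calls <- activity_calls(panel, corr_threshold = config$corr_threshold,
                            bc_threshold = config$bc_threshold)
    write_tsv_commented(calls, out("activity_calls.tsv"),
                        "drug activity: replicate correlation + bimodality filter")
    ranks <- top_inhibitors(panel, k = config$top_k)
    write_tsv_commented(ranks$by_moa, out("top_moa.tsv"),
                        "per-tissue MOA counts among top-k inhibitors")
    write_tsv_commented(ranks$by_target, out("top_targets.tsv"),
                        "per-tissue target counts among top-k inhibitors")
    surv_receptors <- if (!is.null(screen_all)) {
      unique(screen_all$receptor[screen_all$passes_filter &
                                   !is.na(screen_all$q) &
                                   screen_all$q < config$fdr_cut])
    } else character()
    if (length(surv_receptors) > 0) {
      ov <- survival_target_overlap(calls, panel$drug_meta, surv_receptors)
      write_tsv_commented(ov$per_drug, out("target_overlap.tsv"),
                          "active-drug targets vs survival-associated receptors")
      write_tsv_commented(ov$venn, out("target_overlap_venn.tsv"),
                          "two-set Venn region sizes")
    }
    note("drugs", "ok",
         list(n_drugs = nrow(calls),
              n_active = sum(calls$active, na.rm = TRUE),
              n_survival_receptors = length(surv_receptors)))
  } else if ("drugs" %in% config$stages) {
    note("drugs", "skipped")
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
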