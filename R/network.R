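# Construction and validation of the GPCR receptor-ligand-enzyme axis network.

EDGE_KINDS <- c("ligand_receptor", "enzyme_ligand", "receptor_enzyme")
LIGAND_TYPES <- c("peptide", "metabolite", "synthetic organic", "inorganic",
                  "natural product")

#' Assemble and validate a GPCR axis network from component tables
#'
#' An axis network ties together three component classes: receptors (GPCRs,
#' with G-protein coupling and family annotations), their endogenous ligands
#' (peptides or small molecules), and the enzymes that biosynthesise the
#' small-molecule ligands. Edges are typed: `ligand_receptor` edges carry an
#' action mode (agonist/antagonist/mixed/unknown), `enzyme_ligand` edges a
#' reaction direction (LR/RL/UN), and derived `receptor_enzyme` edges a
#' functional-interaction confidence score.
#'
#' @param receptors Tibble with columns `id`, `family`, `coupling`
#'   (semicolon-joined transducer labels), `orphan` (0/1 or logical).
#' @param ligands Tibble with columns `id`, `name`, `ligand_type`,
#'   `external_refs` (`key:value` pairs, semicolon-joined; may be `NA`).
#' @param enzymes Tibble with columns `id`, `cc_terms`, `class_terms`
#'   (semicolon-joined) and optional `literature_count`.
#' @param edges Tibble with columns `source`, `target`, `edge_kind`, and the
#'   kind-specific columns `action`, `direction`, `confidence` (NA where not
#'   applicable). May have zero rows.
#' @return An object of class `axis_network`: a list of the four validated
#'   tibbles.
#' @export
axis_network <- function(receptors, ligands, enzymes, edges) {
  receptors <- as_tibble(receptors)
  ligands <- as_tibble(ligands)
  enzymes <- as_tibble(enzymes)
  edges <- as_tibble(edges)

  check_columns(receptors, c("id", "family", "coupling", "orphan"), "receptors")
  check_columns(ligands, c("id", "name", "ligand_type"), "ligands")
  check_columns(enzymes, c("id", "cc_terms", "class_terms"), "enzymes")
  for (col in c("source", "target", "edge_kind", "action", "direction",
                "confidence")) {
    if (!col %in% names(edges)) edges[[col]] <- NA
  }
  receptors$orphan <- as.logical(receptors$orphan)
  receptors$coupling <- dplyr::coalesce(receptors$coupling, "")
  if (!"external_refs" %in% names(ligands)) ligands$external_refs <- NA_character_
  if (!"literature_count" %in% names(enzymes)) {
    enzymes$literature_count <- NA_integer_
  }

  for (tab in list(receptors = receptors, ligands = ligands,
                   enzymes = enzymes)) {
    if (any(is.na(tab$id) | !nzchar(tab$id))) {
      stop_schema("component ids must be non-empty")
    }
  }
  dup <- c(receptors$id[duplicated(receptors$id)],
           ligands$id[duplicated(ligands$id)],
           enzymes$id[duplicated(enzymes$id)])
  if (length(dup) > 0) {
    stop_schema("duplicate component id(s): %s",
                paste(unique(dup), collapse = ", "))
  }

  bad_type <- setdiff(unique(ligands$ligand_type), LIGAND_TYPES)
  if (length(bad_type) > 0) {
    stop_schema("unknown ligand_type(s): %s", paste(bad_type, collapse = ", "))
  }
  lc <- enzymes$literature_count
  if (any(!is.na(lc) & lc < 0)) {
    stop_schema("literature_count must be nonnegative")
  }
  no_coupling <- !receptors$orphan &
    lengths(split_terms(receptors$coupling)) == 0
  if (any(no_coupling)) {
    stop_schema("non-orphan receptor(s) without coupling: %s",
                paste(receptors$id[no_coupling], collapse = ", "))
  }

  if (nrow(edges) > 0) {
    bad_kind <- setdiff(unique(edges$edge_kind), EDGE_KINDS)
    if (length(bad_kind) > 0) {
      stop_schema("unknown edge_kind(s): %s", paste(bad_kind, collapse = ", "))
    }
    if (any(edges$source == edges$target)) {
      stop_schema("self-edges are not allowed")
    }
    expected_source <- c(ligand_receptor = "ligand",
                         enzyme_ligand = "enzyme",
                         receptor_enzyme = "receptor")
    expected_target <- c(ligand_receptor = "receptor",
                         enzyme_ligand = "ligand",
                         receptor_enzyme = "enzyme")
    pools <- list(receptor = receptors$id, ligand = ligands$id,
                  enzyme = enzymes$id)
    for (i in seq_len(nrow(edges))) {
      kind <- edges$edge_kind[i]
      for (side in c("source", "target")) {
        pool_name <- if (side == "source") expected_source[[kind]] else expected_target[[kind]]
        endpoint <- edges[[side]][i]
        if (!endpoint %in% pools[[pool_name]]) {
          stop_schema(
            "edge row %d (%s): %s '%s' is not a declared %s",
            i, kind, side, endpoint, pool_name)
        }
      }
    }
    re <- edges[edges$edge_kind == "receptor_enzyme", , drop = FALSE]
    if (nrow(re) > 0) {
      linked <- ligand_connected_pairs(edges)
      orphan_re <- !paste(re$source, re$target) %in%
        paste(linked$receptor, linked$enzyme)
      if (any(orphan_re)) {
        stop_schema(
          "receptor_enzyme edge(s) without a mediating ligand: %s",
          paste(paste(re$source[orphan_re], re$target[orphan_re], sep = "-"),
                collapse = ", "))
      }
    }
  }

  structure(list(receptors = receptors, ligands = ligands, enzymes = enzymes,
                 edges = edges),
            class = "axis_network")
}

#' @export
print.axis_network <- function(x, ...) {
  kinds <- table(factor(x$edges$edge_kind, levels = EDGE_KINDS))
  cat(sprintf(
    "<axis_network> %d receptors, %d ligands, %d enzymes\n",
    nrow(x$receptors), nrow(x$ligands), nrow(x$enzymes)))
  cat(sprintf("  edges: %d ligand-receptor, %d enzyme-ligand, %d receptor-enzyme\n",
              kinds[["ligand_receptor"]], kinds[["enzyme_ligand"]],
              kinds[["receptor_enzyme"]]))
  invisible(x)
}

# (receptor, enzyme) pairs joined through at least one shared ligand,
# with the number of mediating ligands.
ligand_connected_pairs <- function(edges) {
  el <- edges[edges$edge_kind == "enzyme_ligand", c("source", "target")]
  lr <- edges[edges$edge_kind == "ligand_receptor", c("source", "target")]
  names(el) <- c("enzyme", "ligand")
  names(lr) <- c("ligand", "receptor")
  inner_join(el, lr, by = "ligand", relationship = "many-to-many") |>
    group_by(.data$receptor, .data$enzyme) |>
    summarise(n_ligands = n_distinct(.data$ligand), .groups = "drop")
}

#' Load an axis network from a directory of TSV component tables
#'
#' Expects `receptors.tsv`, `ligands.tsv`, `enzymes.tsv` and `edges.tsv`
#' in `dir`, in the schemas documented under [axis_network()].
#'
#' @param dir Directory containing the four component tables.
#' @return A validated `axis_network`.
#' @export
load_axis_network <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("receptors.tsv", "ligands.tsv", "enzymes.tsv", "edges.tsv")) {
    if (!file.exists(path(f))) stop_schema("missing component table: %s", f)
  }
  axis_network(
    receptors = read_tsv_quiet(path("receptors.tsv"),
                               col_types = readr::cols(.default = "c",
                                                       orphan = "i")),
    ligands = read_tsv_quiet(path("ligands.tsv"),
                             col_types = readr::cols(.default = "c")),
    enzymes = read_tsv_quiet(path("enzymes.tsv"),
                             col_types = readr::cols(.default = "c",
                                                     literature_count = "i")),
    edges = read_tsv_quiet(path("edges.tsv"),
                           col_types = readr::cols(.default = "c",
                                                   confidence = "i")))
}

#' Write an axis network back to TSV component tables
#'
#' Inverse of [load_axis_network()]: writing then re-loading reproduces the
#' network exactly.
#'
#' @param network An `axis_network`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_axis_network <- function(network, dir) {
  stopifnot(inherits(network, "axis_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- network
  out$receptors$orphan <- as.integer(out$receptors$orphan)
  readr::write_tsv(out$receptors, file.path(dir, "receptors.tsv"))
  readr::write_tsv(out$ligands, file.path(dir, "ligands.tsv"))
  readr::write_tsv(out$enzymes, file.path(dir, "enzymes.tsv"))
  readr::write_tsv(out$edges, file.path(dir, "edges.tsv"))
  invisible(dir)
}

#' Filter candidate ligand-biosynthetic enzymes by annotation
#'
#' Retains an enzyme iff at least one of its cellular-component terms is in
#' `keep_cc_terms` (exact, case-insensitive match) and none of its
#' class/domain/name annotations contains any `exclude_class_terms` entry as
#' a case-insensitive substring. This reproduces the composite keep/exclude
#' annotation filter used to prune the raw enzyme candidate list (keeping
#' e.g. plasma-membrane and axon-terminus localised enzymes while dropping
#' kinases, channels, transporters and cytochromes).
#'
#' @param enzymes Tibble with `id`, `cc_terms`, `class_terms`
#'   (semicolon-joined strings).
#' @param keep_cc_terms Character vector of cellular-component terms; an
#'   enzyme must match at least one.
#' @param exclude_class_terms Character vector of class keywords; matching
#'   any (substring, case-insensitive) removes the enzyme.
#' @return The retained rows of `enzymes`, input order preserved.
#' @export
filter_enzymes <- function(enzymes, keep_cc_terms, exclude_class_terms) {
  stopifnot(length(keep_cc_terms) > 0, length(exclude_class_terms) > 0)
  enzymes <- as_tibble(enzymes)
  check_columns(enzymes, c("id", "cc_terms", "class_terms"), "enzymes")
  cc <- split_terms(enzymes$cc_terms)
  cls <- split_terms(enzymes$class_terms)
  keep_lc <- tolower(keep_cc_terms)
  excl_lc <- tolower(exclude_class_terms)
  keep_cc <- vapply(cc, function(v) any(tolower(v) %in% keep_lc), logical(1))
  hit_excl <- vapply(cls, function(v) {
    any(vapply(excl_lc, function(e) any(grepl(e, tolower(v), fixed = TRUE)),
               logical(1)))
  }, logical(1))
  enzymes[keep_cc & !hit_excl, , drop = FALSE]
}

#' Derive ligand-mediated receptor-enzyme edges
#'
#' Connects a receptor to an enzyme when at least one ligand is both a
#' product of the enzyme (`enzyme_ligand` edge) and a binder of the receptor
#' (`ligand_receptor` edge), and the pair's functional-interaction
#' confidence score reaches `min_confidence`. One edge is emitted per
#' (receptor, enzyme) pair regardless of how many ligands mediate it.
#'
#' @param network An `axis_network` with ligand-receptor and enzyme-ligand
#'   edges.
#' @param confidence_scores Tibble with columns `receptor`, `enzyme`,
#'   `confidence` (nonnegative integers).
#' @param min_confidence Minimum admitted confidence (inclusive); default 150.
#' @return Tibble of `receptor_enzyme` edges (`source` = receptor,
#'   `target` = enzyme, `edge_kind`, `confidence`).
#' @export
derive_receptor_enzyme_edges <- function(network, confidence_scores,
                                         min_confidence = 150) {
  stopifnot(inherits(network, "axis_network"))
  confidence_scores <- as_tibble(confidence_scores)
  check_columns(confidence_scores, c("receptor", "enzyme", "confidence"),
                "confidence_scores")
  pairs <- ligand_connected_pairs(network$edges)
  scored <- inner_join(pairs, confidence_scores,
                       by = c("receptor", "enzyme"))
  unscored <- anti_join(pairs, confidence_scores,
                        by = c("receptor", "enzyme"))
  if (nrow(unscored) > 0) {
    rlang::inform(sprintf(
      "derive_receptor_enzyme_edges: %d ligand-connected pair(s) had no confidence score and were excluded",
      nrow(unscored)))
  }
  scored |>
    filter(.data$confidence >= min_confidence) |>
    arrange(.data$receptor, .data$enzyme) |>
    mutate(source = .data$receptor, target = .data$enzyme,
           edge_kind = "receptor_enzyme",
           action = NA_character_, direction = NA_character_) |>
    select("source", "target", "edge_kind", "action", "direction",
           "confidence")
}

#' Select the rate-limiting enzyme per biosynthetic pathway
#'
#' Designates, for each pathway, the member enzyme with the largest
#' literature-evidence count (number of articles matching a
#' rate-limiting/bottleneck query) as the pathway's rate-limiting enzyme.
#' Ties break to the lexicographically smallest gene symbol so the choice is
#' deterministic.
#'
#' @param pathway_enzymes Named list: pathway id -> character vector of
#'   enzyme ids.
#' @param literature_counts Named integer vector: enzyme id -> count.
#' @return Tibble with columns `pathway`, `enzyme`, `literature_count`.
#' @export
select_rate_limiting <- function(pathway_enzymes, literature_counts) {
  stopifnot(is.list(pathway_enzymes), !is.null(names(pathway_enzymes)))
  rows <- imap(pathway_enzymes, function(enz, pw) {
    counted <- enz[enz %in% names(literature_counts)]
    if (length(counted) == 0) {
      stop_schema("pathway '%s' has no enzyme with a literature count", pw)
    }
    counts <- literature_counts[counted]
    best <- counted[counts == max(counts)]
    best <- sort(best)[1]
    tibble(pathway = pw, enzyme = best,
           literature_count = as.integer(literature_counts[[best]]))
  })
  list_rbind(rows)
}

#' Enumerate the axis pairs of a network
#'
#' An axis is a receptor paired with a direct partner: either a ligand
#' (from `ligand_receptor` edges) or a ligand-biosynthetic enzyme (from
#' derived `receptor_enzyme` edges).
#'
#' @param network An `axis_network`.
#' @return Tibble with columns `receptor`, `partner`, `partner_kind`
#'   (`"ligand"` or `"enzyme"`), unique rows.
#' @export
axis_pairs <- function(network) {
  stopifnot(inherits(network, "axis_network"))
  e <- network$edges
  lr <- e[e$edge_kind == "ligand_receptor", , drop = FALSE]
  re <- e[e$edge_kind == "receptor_enzyme", , drop = FALSE]
  bind_rows(
    tibble(receptor = lr$target, partner = lr$source,
           partner_kind = "ligand"),
    tibble(receptor = re$source, partner = re$target,
           partner_kind = "enzyme")) |>
    distinct() |>
    arrange(.data$receptor, .data$partner_kind, .data$partner)
}
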