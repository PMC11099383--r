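# Small in-code fixtures shared across test files.

tiny_network_tables <- function() {
  list(
    receptors = tibble::tibble(
      id = c("R1", "R2", "R3"),
      family = "classA",
      coupling = c("Gi/o", "Gq/11", ""),
      orphan = c(FALSE, FALSE, TRUE)),
    ligands = tibble::tibble(
      id = c("L1", "L2"),
      name = c("ligand one", "ligand two"),
      ligand_type = c("peptide", "metabolite"),
      external_refs = c(NA, "chebi:00001")),
    enzymes = tibble::tibble(
      id = c("E1", "E2"),
      cc_terms = c("plasma membrane", "plasma membrane;axon terminus"),
      class_terms = c("acyltransferase", "decarboxylase"),
      literature_count = c(10L, NA)),
    edges = tibble::tibble(
      source = c("L1", "L2", "E1", "E2", "R1"),
      target = c("R1", "R1", "L2", "L2", "E1"),
      edge_kind = c("ligand_receptor", "ligand_receptor", "enzyme_ligand",
                    "enzyme_ligand", "receptor_enzyme"),
      action = c("agonist", "antagonist", NA, NA, NA),
      direction = c(NA, NA, "LR", "UN", NA),
      confidence = c(NA, NA, NA, NA, 300L)))
}

tiny_network <- function() {
  tabs <- tiny_network_tables()
  axis_network(tabs$receptors, tabs$ligands, tabs$enzymes, tabs$edges)
}

# Independent step-up BH oracle (vector in, vector out; NA passed through).
bh_reference <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(out)
  x <- p[ok]
  m <- length(x)
  o <- order(x, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (i in seq_along(o)) {
    rank_i <- m - i + 1
    running <- min(running, x[o[i]] * m / rank_i)
    adj[o[i]] <- min(running, 1)
  }
  out[ok] <- adj
  out
}

# Exhaustive-case oracle for the five-level co-DE score: explicit case
# analysis, written independently of the vectorised implementation.
code_score_oracle <- function(lfc_r, padj_r, lfc_p, padj_p,
                              lfc_cut = 1, padj_cut = 0.01) {
  if (is.na(lfc_r) || is.na(lfc_p)) return(0L)
  if (abs(lfc_r) <= lfc_cut || abs(lfc_p) <= lfc_cut) return(0L)
  if (sign(lfc_r) != sign(lfc_p)) return(0L)
  s_r <- !is.na(padj_r) && padj_r < padj_cut
  s_p <- !is.na(padj_p) && padj_p < padj_cut
  if (s_r && s_p) return(as.integer(2 * sign(lfc_r)))
  if (s_r || s_p) return(as.integer(1 * sign(lfc_r)))
  0L
}

# Brute-force PAS counter.
pas_oracle <- function(lfcs) {
  I <- 0L; D <- 0L
  for (x in lfcs) {
    if (is.na(x)) next
    if (x > 0) I <- I + 1L
    if (x < 0) D <- D + 1L
  }
  S <- I + D
  if (S == 0L) S <- 1L
  list(I = I, D = D, S = S, pas = (I - D) / S)
}

# Brute-force Ward agglomeration via the Lance-Williams update on squared
# Euclidean distances (the ward.D2 criterion); returns cluster labels for k
# groups. Independent of stats::hclust.
ward_oracle <- function(m, k) {
  n <- nrow(m)
  d2 <- as.matrix(dist(m))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  while (sum(alive) > k) {
    idx <- which(alive)
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1)) {
        i <- idx[a]; j <- idx[b]
        if (d2[i, j] < best_d) { best_d <- d2[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (l in which(alive)) {
      if (l == i || l == j) next
      nl <- sizes[l]
      d2new <- ((ni + nl) * d2[i, l] + (nj + nl) * d2[j, l] -
                  nl * d2[i, j]) / (ni + nj + nl)
      d2[i, l] <- d2new; d2[l, i] <- d2new
    }
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    alive[j] <- FALSE
  }
  labels <- integer(n)
  for (g in seq_along(which(alive))) {
    labels[active[[which(alive)[g]]]] <- g
  }
  labels
}

# Two partitions equal up to label permutation?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Small survival cohort with exponential times and a known two-group HR.
sim_two_group <- function(n, hr, censor_frac = 0, seed = 1) {
  set.seed(seed)
  group <- factor(rep(c("low", "high"), each = n / 2),
                  levels = c("low", "high"))
  h <- ifelse(group == "high", hr, 1)
  t_event <- rexp(n, rate = h)
  if (censor_frac > 0) {
    mu <- censor_frac / (1 - censor_frac) * mean(h)
    t_cens <- rexp(n, rate = mu)
  } else {
    t_cens <- rep(Inf, n)
  }
  tibble::tibble(time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 group = group)
}
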