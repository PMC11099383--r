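test_that("co-DE score reproduces the documented joint cases", {
  expect_equal(code_score(1.5, 0.001, 2.0, 0.004), 2L)
  expect_equal(code_score(1.5, 0.001, 1.2, 0.20), 1L)
  expect_equal(code_score(-1.5, 0.001, -1.2, 0.20), -1L)
  expect_equal(code_score(1.5, 0.001, -1.5, 0.001), 0L)
  expect_equal(code_score(0.5, 0.001, 2.0, 0.001), 0L)
  expect_equal(code_score(1.5, 0.05, 1.5, 0.05), 0L)  # neither significant
  expect_equal(code_score(NA, NA, 2.0, 0.001), 0L)
  expect_equal(code_score(1.0, 0.001, 2.0, 0.001), 0L)  # boundary |lfc| = 1
})

test_that("co-DE score is symmetric and odd under joint sign flip", {
  set.seed(1)
  for (i in 1:200) {
    lr <- runif(1, -3, 3); lp <- runif(1, -3, 3)
    pr <- runif(1); pp <- runif(1)
    a <- code_score(lr, pr, lp, pp)
    expect_identical(a, code_score(lp, pp, lr, pr))
    expect_identical(code_score(-lr, pr, -lp, pp), -a)
  }
})

test_that("recurrence filter uses the inclusive 25% boundary", {
  genes <- c("R", "P")
  de_hit <- tibble::tibble(gene = genes, lfc = 2, pvalue = 1e-5, padj = 1e-4)
  de_null <- tibble::tibble(gene = genes, lfc = 0, pvalue = 0.5, padj = 0.9)
  pairs <- tibble::tibble(receptor = "R", partner = "P",
                          partner_kind = "ligand")
  # nonzero in 1 of 8 subtypes (12.5%) -> dropped
  des <- c(list(s1 = de_hit), setNames(rep(list(de_null), 7),
                                       paste0("s", 2:8)))
  cm <- build_code_matrix(des, pairs)
  expect_false(cm$affected[1])
  # nonzero in 2 of 8 (25%) -> retained
  des2 <- c(list(s1 = de_hit, s2 = de_hit),
            setNames(rep(list(de_null), 6), paste0("s", 3:8)))
  cm2 <- build_code_matrix(des2, pairs)
  expect_true(cm2$affected[1])
  expect_equal(nrow(affected_pairs(cm2)), 1)
  # all-zero pair -> dropped
  cm3 <- build_code_matrix(setNames(rep(list(de_null), 8),
                                    paste0("s", 1:8)), pairs)
  expect_equal(nrow(affected_pairs(cm3)), 0)
})

test_that("filtered matrix size is non-increasing in the recurrence fraction", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:40)
  des <- lapply(1:8, function(i) {
    tibble::tibble(gene = genes,
                   lfc = sample(c(-2, 0, 2), 40, replace = TRUE),
                   pvalue = 1e-4, padj = 1e-3)
  })
  names(des) <- paste0("s", 1:8)
  pairs <- tibble::tibble(receptor = genes[1:20], partner = genes[21:40],
                          partner_kind = "ligand")
  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                  function(f) nrow(affected_pairs(
                    build_code_matrix(des, pairs, recurrence_fraction = f))),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("Ward clustering separates pure blocks and matches the oracle", {
  scores <- rbind(matrix(2L, 10, 8), matrix(-2L, 10, 8))
  cm <- tibble::tibble(receptor = sprintf("r%02d", 1:20),
                       partner = sprintf("p%02d", 1:20),
                       partner_kind = "ligand", affected = TRUE)
  cm <- dplyr::bind_cols(cm, tibble::as_tibble(
    `colnames<-`(scores, paste0("s", 1:8))))
  class(cm) <- c("code_matrix", class(cm))
  # two perfectly separated blocks -> two pure clusters
  lab <- cluster_pairs(cm, 2)$cluster
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_true(lab[1] != lab[20])
  # identical rows merge at height zero first
  hc <- attr(cluster_pairs(cm, 2), "hclust")
  expect_equal(hc$height[1], 0)
  expect_error(cluster_pairs(cm[1, ], 2), "clusters")
})

test_that("Ward labels agree with a brute-force Lance-Williams oracle", {
  set.seed(9)
  for (rep_i in 1:5) {
    n <- sample(6:12, 1)
    scores <- matrix(sample(-2:2, n * 8, replace = TRUE), n, 8)
    cm <- tibble::tibble(receptor = sprintf("r%02d", 1:n),
                         partner = sprintf("p%02d", 1:n),
                         partner_kind = "ligand", affected = TRUE)
    cm <- dplyr::bind_cols(cm, tibble::as_tibble(
      `colnames<-`(scores, paste0("s", 1:8))))
    class(cm) <- c("code_matrix", class(cm))
    for (k in 2:3) {
      expect_true(same_partition(cluster_pairs(cm, k)$cluster,
                                 ward_oracle(scores, k)),
                  info = sprintf("rep %d k %d", rep_i, k))
    }
  }
})

test_that("similarity profiles reproduce hand-computed distances", {
  build_cm <- function(scores, receptor) {
    n <- nrow(scores)
    out <- tibble::tibble(receptor = receptor,
                          partner = sprintf("p%d", seq_len(n)),
                          partner_kind = "ligand", affected = TRUE)
    out <- dplyr::bind_cols(out, tibble::as_tibble(
      `colnames<-`(scores, c("TA_S1", "TA_S2"))))
    class(out) <- c("code_matrix", class(out))
    out
  }
  # identical profiles -> zero distance
  sp <- similarity_profiles(build_cm(rbind(c(2L, 2L), c(2L, 2L)), "R"))
  expect_equal(sp$ligand_wise, 0)
  # profiles (2,2) and (-2,-2): distance sqrt(32)
  sp2 <- similarity_profiles(build_cm(rbind(c(2L, 2L), c(-2L, -2L)), "R"))
  expect_equal(sp2$ligand_wise, sqrt(32))
  expect_equal(sp2$updown_balance, mean(c(2, -2)))
  # three ligands: mean of the three pairwise distances
  scores <- rbind(c(2L, 2L), c(-2L, -2L), c(2L, 0L))
  sp3 <- similarity_profiles(build_cm(scores, "R"))
  d <- as.matrix(dist(scores))
  expect_equal(sp3$ligand_wise, mean(d[lower.tri(d)]))
  expect_equal(sp3$n_ligands, 3L)
  # single subtype-group per tissue: tissue_wise over two tissues
  one <- tibble::tibble(receptor = "R", partner = "p1",
                        partner_kind = "ligand", affected = TRUE,
                        TA_S1 = 2L, TA_S2 = 0L, TB_S3 = -2L)
  class(one) <- c("code_matrix", class(one))
  spt <- similarity_profiles(one)
  # tissue profiles: mean(2,0) = 1 for TA, -2 for TB -> distance 3
  expect_equal(spt$tissue_wise, 3)
  expect_equal(spt$ligand_wise, 0)
})

test_that("correlation calls recover a planted pair and are reproducible", {
  set.seed(21)
  n_genes <- 200; n_samples <- 50
  expr <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  rownames(expr) <- sprintf("g%03d", seq_len(n_genes))
  # plant r ~ 0.9 between g001 and g002
  expr[2, ] <- 0.9 * expr[1, ] + sqrt(1 - 0.81) * rnorm(n_samples)
  expr[3, ] <- 0  # constant gene
  pairs <- tibble::tibble(receptor = c("g001", "g003"),
                          partner = c("g002", "g004"))
  calls <- correlation_calls(expr, pairs, n_background = 500, seed = 99)
  expect_true(calls$correlated[1])
  expect_gt(abs(calls$r[1]), 0.25)
  expect_true(is.na(calls$r[2]))      # constant gene -> missing call
  calls2 <- correlation_calls(expr, pairs, n_background = 500, seed = 99)
  expect_identical(calls, calls2)
  # sub-threshold correlation is never called
  pairs3 <- tibble::tibble(receptor = "g010", partner = "g011")
  c3 <- correlation_calls(expr, pairs3, n_background = 500, seed = 99)
  expect_false(c3$correlated[1] && abs(c3$r[1]) <= 0.25)
})

test_that("planted correlation recovery holds across seeds with few null calls", {
  n_samples <- 50
  hits <- 0; null_rates <- numeric(0)
  for (s in 1:10) {
    set.seed(1000 + s)
    expr <- matrix(rnorm(210 * n_samples), 210, n_samples)
    rownames(expr) <- sprintf("g%03d", 1:210)
    expr[2, ] <- 0.8 * expr[1, ] + sqrt(1 - 0.64) * rnorm(n_samples)
    pairs <- tibble::tibble(
      receptor = sprintf("g%03d", seq(1, 199, by = 2)),
      partner = sprintf("g%03d", seq(2, 200, by = 2)))
    calls <- correlation_calls(expr, pairs, n_background = 400,
                               seed = 1000 + s)
    hits <- hits + calls$correlated[1]
    null_rates <- c(null_rates, mean(calls$correlated[-1]))
  }
  expect_gte(hits, 9)
  expect_lte(median(null_rates), 0.05)
})

test_that("concordance prevalence counts directional agreement", {
  pairs <- tibble::tibble(receptor = sprintf("r%d", 1:7),
                          partner = sprintf("p%d", 1:7))
  de <- tibble::tibble(
    gene = c(pairs$receptor, pairs$partner),
    lfc = c(2, 2, 2, 2, 2, -2, 0.5,   # receptors
            2, 2, 2, 2, 2, 2, 2),     # partners
    pvalue = 1e-4, padj = 1e-3)
  out <- concordance_prevalence(list(s1 = de), pairs)
  expect_equal(out$n_concordant, 5)
  expect_equal(out$n_discordant, 1)   # r6 vs p6 opposite signs
  expect_true(out$prevalence_flag)
  empty <- concordance_prevalence(
    list(s1 = dplyr::mutate(de, lfc = 0)), pairs)
  expect_equal(empty$n_concordant + empty$n_discordant, 0)
  expect_false(empty$prevalence_flag)
})

test_that("mutation association ranks genes by average co-regulated axis count", {
  cmx <- tibble::tibble(
    receptor = c("r1", "r2", "r3", "r4", "r5", "r6"),
    partner = paste0("p", 1:6), partner_kind = "ligand", affected = TRUE,
    s1 = c(2L, 2L, 2L, 2L, 0L, 1L),   # 4 strong pairs in s1
    s2 = c(2L, 2L, 0L, 0L, 0L, 0L),   # 2 strong pairs in s2
    s3 = c(2L, 2L, 2L, 2L, 2L, 2L))   # 6 strong pairs in s3
  class(cmx) <- c("code_matrix", class(cmx))
  cg <- tibble::tibble(gene = c("KRAS", "TP53"), role = c("oncogene", "TSG"))
  # KRAS top-mutated in s1 and s3 (counts 4 and 6), TP53 only in s2
  muts <- dplyr::bind_rows(
    tidyr::expand_grid(gene = "KRAS", sample = paste0("a", 1:5),
                       subtype = c("s1", "s3")),
    tidyr::expand_grid(gene = "TP53", sample = paste0("b", 1:5),
                       subtype = "s2"))
  out <- mutation_axis_association(muts, cg, cmx, top_k = 1)
  expect_equal(out$avg_coregulated[out$gene == "KRAS"], 5)
  expect_equal(out$avg_coregulated[out$gene == "TP53"], 2)
  expect_equal(out$gene[1], "KRAS")

  # tie at the rank-k boundary keeps both genes
  muts_tie <- tidyr::expand_grid(gene = c("KRAS", "TP53"),
                                 sample = paste0("c", 1:4), subtype = "s1")
  out_tie <- mutation_axis_association(muts_tie, cg, cmx, top_k = 1)
  expect_setequal(out_tie$gene, c("KRAS", "TP53"))

  # unknown subtype is skipped with a log
  muts_bad <- dplyr::bind_rows(
    muts, tibble::tibble(gene = "KRAS", sample = "z1", subtype = "sX"))
  expect_message(mutation_axis_association(muts_bad, cg, cmx, top_k = 1),
                 "skipped")
})
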