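test_that("PCA ranking saturates, finds dominant genes, ignores cell order", {
  set.seed(21)
  base <- matrix(rnorm(10 * 30, 5, 0.2), 10)
  base[3, ] <- 5 + rnorm(30, 0, 4)  # one gene with far larger variance
  x <- toy_matrix(pmax(fpkm_for_log2(base), 0))
  ranked <- rank_genes_by_pca(x, k = 100)
  expect_length(ranked, 10)
  expect_identical(ranked[1], "g3")
  perm <- sample(30)
  x2 <- ExpressionMatrix(x$values[, perm], spikein = x$spikein)
  expect_identical(rank_genes_by_pca(x2, k = 5), rank_genes_by_pca(x, k = 5))
})

test_that("PCA gene score agrees with a direct eigendecomposition on a toy", {
  set.seed(22)
  lx <- matrix(rnorm(5 * 40), 5)
  lx[1, ] <- lx[1, ] * 6
  x <- toy_matrix(pmax(fpkm_for_log2(lx + 8), 0))
  ranked <- rank_genes_by_pca(x, k = 5, var_explained = 0.85)
  lmat <- log2p1(x$values)
  cc <- stats::cov(t(lmat))
  eig <- eigen(cc)
  nc <- which(cumsum(eig$values) / sum(eig$values) >= 0.85)[1]
  score <- apply(abs(eig$vectors[, 1:nc, drop = FALSE]), 1, max)
  expect_identical(ranked, rownames(lmat)[order(-score, rownames(lmat))])
})

test_that("hierarchical clustering separates two synthetic blobs perfectly", {
  skip_if_not_installed("mclust")
  set.seed(23)
  a <- matrix(rlnorm(40 * 15, log(5), 0.3), 40)
  b <- matrix(rlnorm(40 * 15, log(5), 0.3), 40)
  a[1:10, ] <- a[1:10, ] * 50
  b[11:20, ] <- b[11:20, ] * 50
  x <- toy_matrix(cbind(a, b))
  cl <- hierarchical_cluster(x, n_clusters = 2)
  truth <- rep(1:2, each = 15)
  names(truth) <- colnames(x$values)
  expect_equal(mclust::adjustedRandIndex(cl$cluster[names(truth)], truth), 1)
})

test_that("duplicating every cell leaves per-cell assignments unchanged", {
  set.seed(24)
  a <- matrix(rlnorm(30 * 10, log(5), 0.3), 30)
  a[1:8, 1:5] <- a[1:8, 1:5] * 40
  x <- toy_matrix(a)
  cl1 <- hierarchical_cluster(x, n_clusters = 2)
  dup <- cbind(x$values, x$values)
  colnames(dup) <- c(colnames(x$values), paste0(colnames(x$values), "_dup"))
  cl2 <- hierarchical_cluster(toy_matrix(dup), n_clusters = 2)
  m1 <- cl1$cluster
  m2 <- cl2$cluster[names(m1)]
  # same partition up to label switching
  expect_equal(length(unique(paste(m1, m2))), length(unique(m1)))
})

test_that("cluster annotation scores equal a brute-force computation", {
  genes <- c("Afp", "Alb", "Lyve1", "Kdr", "Vim")
  set.seed(25)
  v <- matrix(rlnorm(5 * 9, log(2), 0.2), 5, dimnames = list(genes, paste0("c", 1:9)))
  v[c("Afp", "Alb"), 1:3] <- 60
  v[c("Lyve1", "Kdr"), 4:6] <- 60
  v["Vim", 7:9] <- 60
  x <- ExpressionMatrix(v, spikein = rep(FALSE, 5))
  cl <- hierarchical_cluster(x, n_clusters = 3)
  panels <- list(hepatoblast = c("Afp", "Alb"), endothelial = c("Lyve1", "Kdr"),
                 mesenchymal = "Vim")
  ann <- annotate_clusters(x, cl, panels)
  lx <- log2p1(v)
  z <- t(scale(t(lx)))
  manual <- sapply(sort(unique(cl$cluster)), function(k) {
    cm <- rowMeans(z[, names(cl$cluster)[cl$cluster == k], drop = FALSE])
    sapply(panels, function(g) mean(cm[g]))
  })
  expect_equal(unname(ann$scores), unname(t(manual)))
  # each pure cluster gets its own panel
  expect_setequal(unname(ann$labels), names(panels))
})

test_that("an exact two-way tie yields unassigned", {
  v <- matrix(c(8, 8, 1, 1), 2, 2,
              dimnames = list(c("A", "B"), c("c1", "c2")))
  x <- ExpressionMatrix(v, spikein = c(FALSE, FALSE))
  cl <- list(cluster = setNames(c(1L, 2L), c("c1", "c2")), tree = NULL,
             labels = NULL, scores = NULL)
  class(cl) <- "Clustering"
  ann <- annotate_clusters(x, cl, panels = list(p1 = c("A", "B"),
                                                p2 = c("A", "B")))
  expect_true(all(ann$labels == "unassigned"))
})

test_that("two-pass decomposition recovers the six types and merges macrophages", {
  skip_if_not_installed("mclust")
  cc <- cached_sim(1)
  dec <- two_pass_decomposition(cc$sim$matrix)
  truth <- setNames(cc$sim$annotation$true_type, cc$sim$annotation$cell_id)
  ari <- mclust::adjustedRandIndex(dec$cell_labels, truth[names(dec$cell_labels)])
  expect_gte(ari, 0.9)
  expect_equal(length(unique(dec$cell_labels)), 6)
  expect_true("macrophage" %in% names(dec$merged))
})

test_that("an all-hepatoblast composition short-circuits pass 2", {
  tp <- matrix(rep(c(1, 0, 0, 0, 0, 0), each = 2), 2,
               dimnames = list(default_stages()[1:2], liver_cell_types()))
  cfg <- sim_config(n_genes = 300, stages = default_stages()[1:2],
                    cells_per_stage = 20, type_proportions = tp,
                    n_trajectory_genes = 10, n_marker_genes_per_type = 3,
                    seed = 12)
  sim <- simulate_fetal_liver(cfg)
  dec <- suppressMessages(two_pass_decomposition(sim$matrix))
  expect_true(all(dec$cell_labels == "hepatoblast"))
  expect_null(dec$pass2)
})

test_that("ANOVA display ranking puts null genes last and perfect separators first", {
  lab <- rep(c("x", "y", "z"), each = 4)
  lx <- rbind(rep(3, 12),                          # flat gene
              rep(c(1, 5, 9), each = 4),           # perfect separation
              rnorm(12, 4, 0.1))
  x <- toy_matrix(pmax(fpkm_for_log2(lx), 0))
  names(lab) <- colnames(x$values)
  ranked <- anova_rank_display_genes(x, lab, k = 3)
  expect_identical(ranked[1], "g2")
  expect_identical(ranked[3], "g1")
})

test_that("row F statistics agree with aov on random small cases", {
  set.seed(26)
  for (i in 1:5) {
    g <- factor(sample(letters[1:3], 12, replace = TRUE, prob = c(.4, .3, .3)))
    while (min(table(g)) < 2) g <- factor(sample(letters[1:3], 12, replace = TRUE))
    x <- matrix(rnorm(5 * 12), 5)
    f_pkg <- scFetalLiver:::row_f_stats(x, g)
    f_aov <- apply(x, 1, function(r)
      summary(aov(r ~ g))[[1]]$`F value`[1])
    expect_equal(f_pkg, unname(f_aov), tolerance = 1e-10)
  }
})

test_that("t-SNE embedding is reproducible and separates true types", {
  skip_if_not_installed("cluster")
  cc <- cached_sim(1)
  sub_cells <- cc$sim$annotation$cell_id[cc$sim$annotation$stage %in%
                                           c("E12.5", "E13.5")]
  x <- ExpressionMatrix(cc$sim$matrix$values[, sub_cells],
                        spikein = cc$sim$matrix$spikein)
  genes <- rank_genes_by_pca(x, k = 100)
  e1 <- embed_tsne(x, genes, seed = 7)
  e2 <- embed_tsne(x, genes, seed = 7)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), length(sub_cells))
  truth <- setNames(cc$sim$annotation$true_type, cc$sim$annotation$cell_id)
  sil <- cluster::silhouette(as.integer(factor(truth[e1$cell_id])),
                             dist(as.matrix(e1[, c("tsne1", "tsne2")])))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("cell type proportions sum to one and match hand counts", {
  labels <- setNames(c("a", "a", "b", "a", "b", "b", "b", "a", "a", "a"),
                     paste0("c", 1:10))
  stages <- setNames(rep(c("s1", "s2"), each = 5), paste0("c", 1:10))
  pr <- cell_type_proportions(labels, stages)
  expect_equal(sum(pr$proportion[pr$stage == "s1"]), 1, tolerance = 1e-9)
  expect_equal(pr$proportion[pr$stage == "s1" & pr$type == "a"], 3 / 5)
  expect_equal(pr$proportion[pr$stage == "s2" & pr$type == "b"], 2 / 5)
  single <- cell_type_proportions(setNames(rep("a", 3), paste0("d", 1:3)),
                                  setNames(rep("s", 3), paste0("d", 1:3)))
  expect_equal(single$proportion, 1)
})

test_that("the configured mesenchymal decline is recovered across stages", {
  skip_if_not_installed("mclust")
  cc <- cached_sim(1)
  dec <- two_pass_decomposition(cc$sim$matrix)
  stv <- setNames(cc$sim$annotation$stage, cc$sim$annotation$cell_id)
  pr <- cell_type_proportions(dec$cell_labels, stv[names(dec$cell_labels)])
  mes <- pr$proportion[pr$type == "mesenchymal"][order(match(
    pr$stage[pr$type == "mesenchymal"], default_stages()))]
  # stepwise decrease within sampling error: rank correlation strongly negative
  expect_lt(cor(seq_along(mes), mes, method = "spearman"), -0.8)
})

test_that("co-expression counting matches a manual quadrant tally", {
  v <- rbind(c(5, 5, 0, 0, 5, 2),
             c(3, 0, 3, 0, 3, 0),
             c(0, 0, 0, 0, 0, 0))
  x <- toy_matrix(v, gene_ids = c("Krt8", "Krt7", "Never"))
  res <- count_coexpressing_cells(x, "Krt8", "Krt7")
  expect_equal(res$count, 2)
  expect_setequal(res$cells, c("c1", "c5"))
  expect_equal(count_coexpressing_cells(x, "Krt8", "Never")$count, 0)
  expect_error(count_coexpressing_cells(x, "Krt8", "nope"), "nope")
})

test_that("a fixture with exactly four double-positive cells counts four", {
  set.seed(27)
  n <- 40
  hep <- pmax(matrix(rlnorm(2 * n, log(0.2), 0.3), 2), 0)
  chl <- pmax(matrix(rlnorm(2 * n, log(0.2), 0.3), 2), 0)
  hep[, 1:20] <- 50   # hepatocyte markers on in cells 1..20
  chl[, 17:24] <- 50  # cholangiocyte markers on in cells 17..24 -> overlap 17..20
  x <- toy_matrix(rbind(hep, chl),
                  gene_ids = c("Krt8", "Krt18", "Krt7", "Krt19"))
  res <- count_coexpressing_cells(x, c("Krt8", "Krt18"), c("Krt7", "Krt19"))
  expect_equal(res$count, 4)
})

test_that("hypergeometric over-representation matches independent arithmetic", {
  universe <- paste0("g", 1:20)
  query <- paste0("g", 1:5)
  ann <- list(term1 = paste0("g", c(1:4, 10)),   # overlap 4 of term size 5
              none = paste0("g", 15:18))         # overlap 0
  res <- go_overrepresentation(query, universe, ann)
  manual <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(res$p[res$term == "term1"], manual)
  expect_equal(res$p[res$term == "none"], 1)
  expect_equal(res$p_adjusted, pmin(1, res$p * 2))
  one <- go_overrepresentation(query, universe, ann["term1"])
  expect_equal(one$p_adjusted, one$p)
})

test_that("panel config files round-trip and reject bad overlap", {
  p <- withr::local_tempfile()
  writeLines(c("hepatoblast: Afp, Alb", "erythrocyte: Hba-a1",
               "exclude: Hba-a1"), p)
  mp <- read_marker_panels(p)
  expect_equal(mp$panels$hepatoblast, c("Afp", "Alb"))
  expect_equal(mp$exclude, "Hba-a1")
  writeLines(c("hepatoblast: Afp, Alb", "exclude: Afp"), p)
  expect_error(read_marker_panels(p), "exclusion list")
})
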