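test_that("marker positivity is strict at the threshold", {
  x <- toy_matrix(rbind(c(1, 1.01, 0.99, 0), c(0, 0, 0, 0)),
                  gene_ids = c("m", "silent"))
  pos <- marker_positive(x, "m")
  expect_identical(unname(pos), c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(!marker_positive(x, "silent")))
  expect_error(marker_positive(x, "nope"), "unknown gene")
  # hand-set five-cell vector equals a manual comparison
  y <- toy_matrix(matrix(c(0.5, 2, 1, 7, 0), 1), gene_ids = "g")
  expect_identical(unname(marker_positive(y, "g")), c(0.5, 2, 1, 7, 0) > 1)
})

# one stage, 10 target cells (1..10) and 10 others (11..20); the marker is
# positive in 8 targets and 2 non-targets
two_group_fixture <- function() {
  v <- matrix(0.1, 2, 20, dimnames = list(c("mk", "other"), paste0("c", 1:20)))
  v["mk", c(1:8, 11:12)] <- 10
  x <- ExpressionMatrix(v, spikein = c(FALSE, FALSE))
  labels <- setNames(rep(c("hepatoblast", "mesenchymal"), each = 10),
                     colnames(v))
  stages <- setNames(rep("E13.5", 20), colnames(v))
  list(x = x, labels = labels, stages = stages)
}

test_that("sensitivity and specificity come out as direct counts", {
  f <- two_group_fixture()
  perf <- assess_markers(f$x, f$labels, f$stages, "mk", "hepatoblast")
  expect_equal(perf$sensitivity, 0.8)
  expect_equal(perf$specificity, 0.8)
  expect_equal(perf$pos_target, 8)
  expect_equal(perf$pos_other, 2)
  expect_equal(perf$tnr, 0.8)
})

test_that("a perfect marker scores 1.0 on both axes", {
  f <- two_group_fixture()
  v <- f$x$values
  v["mk", ] <- 0.1
  v["mk", 1:10] <- 50
  x <- ExpressionMatrix(v, spikein = c(FALSE, FALSE))
  perf <- assess_markers(x, f$labels, f$stages, "mk", "hepatoblast")
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
})

test_that("a stage without target cells reports missing sensitivity", {
  f <- two_group_fixture()
  stages <- f$stages
  stages[] <- rep(c("E13.5", "E14.5"), each = 10)  # all targets in E13.5
  perf <- assess_markers(f$x, f$labels, stages, "mk", "hepatoblast")
  expect_true(is.na(perf$sensitivity[perf$stage == "E14.5"]))
})

test_that("adding marker-negative non-target cells changes neither score", {
  f <- two_group_fixture()
  perf0 <- assess_markers(f$x, f$labels, f$stages, "mk", "hepatoblast")
  extra <- matrix(0.1, 2, 5,
                  dimnames = list(rownames(f$x$values), paste0("n", 1:5)))
  x2 <- ExpressionMatrix(cbind(f$x$values, extra), spikein = c(FALSE, FALSE))
  labels2 <- c(f$labels, setNames(rep("mesenchymal", 5), paste0("n", 1:5)))
  stages2 <- c(f$stages, setNames(rep("E13.5", 5), paste0("n", 1:5)))
  perf2 <- assess_markers(x2, labels2, stages2, "mk", "hepatoblast")
  expect_equal(perf2$sensitivity, perf0$sensitivity)
  expect_equal(perf2$specificity, perf0$specificity)
})

test_that("adding marker-positive non-target cells lowers specificity only", {
  set.seed(51)
  for (i in 1:10) {
    n_t <- sample(5:15, 1); n_o <- sample(5:15, 1)
    v <- matrix(0.1, 1, n_t + n_o,
                dimnames = list("mk", paste0("c", seq_len(n_t + n_o))))
    pos_t <- sample(n_t, sample(2:n_t, 1))
    v["mk", pos_t] <- 20
    labels <- setNames(c(rep("hepatoblast", n_t), rep("other", n_o)),
                       colnames(v))
    stages <- setNames(rep("E13.5", n_t + n_o), colnames(v))
    x <- ExpressionMatrix(v, spikein = FALSE)
    p0 <- assess_markers(x, labels, stages, "mk", "hepatoblast")
    extra <- matrix(20, 1, 3, dimnames = list("mk", paste0("p", 1:3)))
    x2 <- ExpressionMatrix(cbind(v, extra), spikein = FALSE)
    labels2 <- c(labels, setNames(rep("other", 3), paste0("p", 1:3)))
    stages2 <- c(stages, setNames(rep("E13.5", 3), paste0("p", 1:3)))
    p2 <- assess_markers(x2, labels2, stages2, "mk", "hepatoblast")
    expect_equal(p2$sensitivity, p0$sensitivity)
    expect_lt(p2$specificity, p0$specificity)
  }
})

test_that("the best joint marker ranks first by min(sens, spec)", {
  set.seed(52)
  n <- 60
  labels <- setNames(rep(c("hepatoblast", "mesenchymal", "endothelial"),
                         each = n / 3), paste0("c", 1:n))
  stages <- setNames(rep(c("E12.5", "E13.5", "E16.5"), n / 3), paste0("c", 1:n))
  genes <- c("Cdh1l", paste0("mk", 1:10))
  v <- matrix(0.1, length(genes), n, dimnames = list(genes, names(labels)))
  tgt <- labels == "hepatoblast"
  # Cdh1-like: positive in 95% of targets, 2% of others
  v["Cdh1l", tgt] <- ifelse(runif(sum(tgt)) < 0.95, 30, 0.1)
  v["Cdh1l", !tgt] <- ifelse(runif(sum(!tgt)) < 0.02, 30, 0.1)
  for (g in paste0("mk", 1:10)) {
    v[g, tgt] <- ifelse(runif(sum(tgt)) < 0.6, 30, 0.1)
    v[g, !tgt] <- ifelse(runif(sum(!tgt)) < 0.3, 30, 0.1)
  }
  x <- ExpressionMatrix(v, spikein = rep(FALSE, length(genes)))
  perf <- assess_markers(x, labels, stages, genes, "hepatoblast")
  agg <- aggregate(pmin(sensitivity, specificity) ~ gene, data = perf, FUN = min)
  expect_identical(agg$gene[which.max(agg[, 2])], "Cdh1l")
})

test_that("quadrant counts partition the cells and match a manual tally", {
  v <- rbind(c(5, 5, 0, 0, 5, 0, 5, 2),
             c(5, 0, 5, 0, 5, 0, 0, 5))
  x <- toy_matrix(v, gene_ids = c("Dlk1l", "Lgr5l"))
  q <- marker_pair_quadrants(x, "Dlk1l", "Lgr5l")
  expect_equal(unname(q), c(3, 2, 1, 2))
  expect_equal(sum(q), 8)
  # overlapping-but-unequal positive pools
  expect_true(q["both"] > 0 && q["a_only"] > 0 && q["b_only"] > 0)
  # one gene never positive collapses two quadrants
  v2 <- rbind(c(5, 5, 0), c(0, 0, 0))
  x2 <- toy_matrix(v2, gene_ids = c("a", "b"))
  q2 <- marker_pair_quadrants(x2, "a", "b")
  expect_equal(unname(q2[c("both", "b_only")]), c(0, 0))
})

test_that("marker prediction applies the cutoff at every stage and the membrane list", {
  perf <- expand.grid(gene = c("Gcgrl", "Cdhr2l", "NotMembrane", "Weak"),
                      stage = c("E12.5", "E13.5"), stringsAsFactors = FALSE)
  perf$type <- "hepatoblast"
  perf$sensitivity <- c(0.9, 0.8, 0.95, 0.9, 0.85, 0.9, 0.9, 0.9)
  perf$specificity <- c(0.7, 0.9, 0.9, 0.4, 0.8, 0.85, 0.9, 0.9)
  membrane <- c("Gcgrl", "Cdhr2l", "Weak")
  pred <- predict_markers(perf, membrane)
  # Weak fails one stage (spec 0.4); NotMembrane passes but is not a receptor
  expect_setequal(pred$gene, c("Gcgrl", "Cdhr2l"))
  expect_true(all(pred$membrane))
  # a perfect membrane gene everywhere is predicted
  perf2 <- data.frame(gene = "Star", stage = c("E12.5", "E13.5"),
                      type = "hepatoblast", sensitivity = 1, specificity = 1)
  expect_identical(predict_markers(perf2, "Star")$gene, "Star")
  expect_warning(none <- predict_markers(perf2, character(0)), "membrane")
  expect_equal(nrow(none), 0)
})

test_that("generator marker genes perform for their own type and not others", {
  cc <- cached_sim(1)
  ann <- cc$sim$annotation
  labels <- setNames(ann$true_type, ann$cell_id)
  stages <- setNames(ann$stage, ann$cell_id)
  roles <- cc$sim$truth$genes
  # pooled across stages so rare types are not dominated by 1-cell stages;
  # erythrocyte genes leak into all cell types by design and are excluded
  # from the marker-performance property, as they are from the analysis
  pooled <- stages
  pooled[] <- "all"
  for (tp in c("hepatoblast", "endothelial", "mesenchymal", "megakaryocyte")) {
    genes <- roles$gene_id[roles$role == "marker" & roles$marker_type == tp]
    perf <- assess_markers(cc$sim$matrix, labels, pooled, genes, tp)
    expect_true(all(pmin(perf$sensitivity, perf$specificity) > 0.8))
    other <- assess_markers(cc$sim$matrix, labels, pooled, genes, "erythrocyte")
    expect_true(all(pmin(other$sensitivity, other$specificity) < 0.5))
  }
})
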