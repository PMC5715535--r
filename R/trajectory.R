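#' Stage-wise one-way ANOVA over hepatoblasts
#'
#' Restricts to genes expressed (FPKM > 1) in at least `min_cells` cells,
#' runs one-way ANOVA of log2(FPKM+1) across developmental stages, ranks by
#' the F statistic and keeps the top `top_k` genes for trajectory
#' construction. Each gene also gets a monotone-trend call from
#' [classify_trend()].
#'
#' @param matrix an [ExpressionMatrix] restricted to the cells of interest
#'   (typically hepatoblasts).
#' @param stages named character vector of per-cell stage labels.
#' @param stage_order ordered stage labels; defaults to the sorted unique
#'   stages present.
#' @param min_cells minimum cells with FPKM > 1 for eligibility (default 3).
#' @param top_k genes kept for the track (default 30).
#' @return a `StageSeries` list: `table` (gene_id, f, p, trend, selected),
#'   `stage_means` (genes x stages, log2 scale, selected genes),
#'   `stage_order`, `top_genes`.
#' @export
stage_anova <- function(matrix, stages, stage_order = NULL, min_cells = 3,
                        top_k = 30) {
  x <- as_expression_matrix(matrix)
  v <- gene_values(x)
  stages <- stages[colnames(v)]
  if (is.null(stage_order)) stage_order <- sort(unique(stages))
  stopifnot(all(stages %in% stage_order))
  tab <- table(stages)
  if (sum(tab >= 2) < 2) stop("need at least 2 stages with at least 2 cells")
  keep_st <- names(tab)[tab >= 2]
  sel <- stages %in% keep_st
  v <- v[, sel, drop = FALSE]; stages <- stages[sel]
  eligible <- rowSums(v > 1) >= min_cells
  if (!any(eligible)) stop("no gene is expressed in at least ", min_cells, " cells")
  ve <- v[eligible, , drop = FALSE]
  lx <- log2p1(ve)
  f <- row_f_stats(lx, stages)
  p <- row_f_pvalues(f, k = length(unique(stages)), n = ncol(lx))
  ord <- order(-f, rownames(ve))
  top <- rownames(ve)[ord][seq_len(min(top_k, nrow(ve)))]
  st_levels <- stage_order[stage_order %in% stages]
  means <- vapply(st_levels, function(s)
    rowMeans(lx[, stages == s, drop = FALSE]), numeric(nrow(lx)))
  means <- matrix(means, nrow = nrow(lx),
                  dimnames = list(rownames(lx), st_levels))
  trend <- vapply(rownames(ve), function(g)
    trend_from_means(means[g, ], seq_along(st_levels)), character(1))
  series <- list(
    table = data.frame(gene_id = rownames(ve), f = f, p = p, trend = trend,
                       selected = rownames(ve) %in% top,
                       stringsAsFactors = FALSE),
    stage_means = means, stage_order = st_levels, top_genes = top)
  class(series) <- "StageSeries"
  series
}

trend_from_means <- function(means, ordinals) {
  if (length(means) < 3) return("none")
  if (stats::sd(means) == 0) return("none")
  rho <- suppressWarnings(stats::cor(ordinals, means, method = "spearman"))
  if (is.na(rho)) return("none")
  if (rho >= 0.8) "up" else if (rho <= -0.8) "down" else "none"
}

#' Classify a gene's developmental trend
#'
#' Spearman correlation between stage ordinal and per-stage mean log
#' expression: "up" for rho >= 0.8, "down" for rho <= -0.8, otherwise
#' "none". With fewer than 3 stages, "none" is returned with a warning.
#'
#' @param series a `StageSeries` from [stage_anova()].
#' @param gene gene id present in the series.
#' @return one of "up", "down", "none".
#' @export
classify_trend <- function(series, gene) {
  if (!gene %in% rownames(series$stage_means))
    stop("gene not in the ANOVA-eligible set: ", gene)
  if (length(series$stage_order) < 3) {
    warning("fewer than 3 stages; trend is 'none'")
    return("none")
  }
  trend_from_means(series$stage_means[gene, ], seq_along(series$stage_order))
}

#' Build the hepatoblast developmental track
#'
#' Hierarchical tree (1 - Pearson, average linkage) and t-SNE embedding of
#' the cells on the top trajectory genes, plus per-stage centroid coordinates
#' ordered along the track. With a single stage no track ordering is emitted.
#'
#' @param matrix the [ExpressionMatrix] used in [stage_anova()].
#' @param series a `StageSeries`.
#' @param stages named per-cell stage labels.
#' @param seed integer seed for the embedding.
#' @return list: `tree` (hclust), `embedding` (data.frame), `centroids`
#'   (stage x 2 matrix or NULL), `centroid_order` (stages ordered by the
#'   first embedding axis, NULL for a single stage).
#' @export
build_track <- function(matrix, series, stages, seed = 1L) {
  x <- as_expression_matrix(matrix)
  genes <- series$top_genes
  if (length(genes) == 0) stop("empty top gene set")
  stages <- stages[colnames(x$values)]
  cl <- hierarchical_cluster(x, genes,
                             n_clusters = min(2L, ncol(x$values)))
  emb <- embed_tsne(x, genes, seed = seed)
  single <- length(unique(stages)) < 2
  centroids <- NULL; centroid_order <- NULL
  if (!single) {
    sts <- series$stage_order
    centroids <- t(vapply(sts, function(s) {
      cells <- names(stages)[stages == s]
      colMeans(emb[emb$cell_id %in% cells, c("tsne1", "tsne2"), drop = FALSE])
    }, numeric(2)))
    # order stages along the dominant axis of the centroid cloud
    pc1 <- stats::prcomp(centroids)$x[, 1]
    centroid_order <- sts[order(pc1)]
  }
  list(tree = cl$tree, embedding = emb, centroids = centroids,
       centroid_order = centroid_order)
}

#' Assign query cells to their nearest developmental stage
#'
#' For each query cell, the Pearson correlation (log2(FPKM+1), top trajectory
#' genes) to each stage centroid of the reference series; the assigned stage
#' is the argmax. Query cells with zero variance on the gene set are left
#' unassigned (NA).
#'
#' @param query an [ExpressionMatrix] of query cells (e.g. cholangiocytes);
#'   must share the reference gene space.
#' @param reference the [ExpressionMatrix] the series was built from.
#' @param series a `StageSeries`.
#' @param stages named per-cell stages of the reference cells.
#' @return list: `assignments` (data.frame cell_id, stage, cor), `modal_stage`,
#'   `fractions` (named vector over stages).
#' @export
nearest_stage_assignment <- function(query, reference, series, stages) {
  qx <- as_expression_matrix(query)
  rx <- as_expression_matrix(reference)
  genes <- series$top_genes
  missing <- setdiff(genes, rownames(qx$values))
  if (length(missing) > 0)
    stop("query matrix lacks trajectory gene(s): ", paste(missing, collapse = ", "))
  stages <- stages[colnames(rx$values)]
  lref <- log2p1(rx$values[genes, , drop = FALSE])
  centroids <- vapply(series$stage_order, function(s)
    rowMeans(lref[, names(stages)[stages == s], drop = FALSE]),
    numeric(length(genes)))
  lq <- log2p1(qx$values[genes, , drop = FALSE])
  res <- lapply(colnames(lq), function(cid) {
    prof <- lq[, cid]
    if (stats::sd(prof) == 0)
      return(data.frame(cell_id = cid, stage = NA_character_, cor = NA_real_,
                        stringsAsFactors = FALSE))
    r <- suppressWarnings(stats::cor(prof, centroids))[1, ]
    best <- which.max(r)
    data.frame(cell_id = cid, stage = colnames(centroids)[best],
               cor = unname(r[best]), stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, res)
  assigned <- assignments$stage[!is.na(assignments$stage)]
  fractions <- stats::setNames(rep(0, length(series$stage_order)),
                               series$stage_order)
  if (length(assigned) > 0) {
    tt <- table(factor(assigned, levels = series$stage_order))
    fractions <- tt / sum(tt)
  }
  modal <- if (length(assigned) > 0)
    names(which.max(table(factor(assigned, levels = series$stage_order))))
  else NA_character_
  list(assignments = assignments, modal_stage = modal,
       fractions = as.numeric(fractions) |> stats::setNames(series$stage_order))
}
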