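#' Default marker panels for the six fetal-liver cell types
#'
#' Named lists of canonical marker genes used to annotate clusters, plus a
#' default exclusion list of erythrocyte-related genes (these are expressed
#' at low levels in non-erythrocytes and would otherwise distort the
#' unsupervised decomposition).
#'
#' @return list with `panels` (named list of gene-id vectors) and
#'   `exclude` (character vector).
#' @export
default_marker_panels <- function() {
  panels <- panel_seed_genes()
  list(panels = panels, exclude = panels$erythrocyte)
}

#' Read marker panels from a plain-text config file
#'
#' Each line: `panel_name: gene1, gene2, ...`. A panel named `exclude` is
#' treated as the exclusion list.
#'
#' @param path config file path.
#' @return list as in [default_marker_panels()].
#' @export
read_marker_panels <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  panels <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed panel line: ", ln)
    panels[[trimws(parts[1])]] <- trimws(strsplit(parts[2], ",")[[1]])
  }
  exclude <- panels[["exclude"]] %||% character(0)
  panels[["exclude"]] <- NULL
  # the exclusion list conventionally holds erythrocyte-related genes, which
  # are removed from clustering input but still used to annotate clusters;
  # overlap with any other panel is a configuration error
  other <- unlist(panels[setdiff(names(panels), "erythrocyte")])
  overlap <- intersect(other, exclude)
  if (length(overlap) > 0)
    stop("panel gene(s) also on the exclusion list: ", paste(overlap, collapse = ", "))
  list(panels = panels, exclude = exclude)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank genes by PCA loading score
#'
#' Principal components are computed on cells x genes log2(FPKM+1); each
#' gene's score is its maximum absolute loading across the components that
#' together explain `var_explained` of the variance. Genes are returned in
#' decreasing score order (ties broken alphabetically for determinism).
#'
#' @param matrix an [ExpressionMatrix]; spike-in rows are excluded.
#' @param k number of top genes to return (default 400); larger than the
#'   gene count returns all genes.
#' @param var_explained cumulative variance fraction selecting the
#'   components scored (default 0.85).
#' @param exclude gene ids removed before ranking (e.g. erythrocyte genes).
#' @return character vector of gene ids, best first.
#' @export
rank_genes_by_pca <- function(matrix, k = 400, var_explained = 0.85,
                              exclude = character(0)) {
  x <- as_expression_matrix(matrix)
  v <- gene_values(x)
  v <- v[!(rownames(v) %in% exclude), , drop = FALSE]
  if (ncol(v) < 2) stop("need at least 2 cells")
  lx <- log2p1(v)
  keep <- apply(lx, 1, stats::sd) > 0
  lx <- lx[keep, , drop = FALSE]
  p <- stats::prcomp(t(lx), center = TRUE, scale. = FALSE)
  varfrac <- cumsum(p$sdev^2) / sum(p$sdev^2)
  n_comp <- max(1L, which(varfrac >= var_explained)[1])
  score <- apply(abs(p$rotation[, seq_len(n_comp), drop = FALSE]), 1, max)
  ord <- order(-score, names(score))
  ranked <- names(score)[ord]
  utils::head(ranked, min(k, length(ranked)))
}

#' Hierarchical clustering of cells
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` on
#' log2(FPKM+1) over the selected genes, average linkage, tree cut to exactly
#' `n_clusters`. Cells are processed in lexicographic id order so the result
#' does not depend on input order.
#'
#' @param matrix an [ExpressionMatrix].
#' @param genes gene ids used for the distance (default: all biological genes).
#' @param n_clusters number of clusters (>= 2).
#' @return a `Clustering` list: `cluster` (named integer vector per cell),
#'   `tree` (hclust object), `labels` (named character vector, initially
#'   "unassigned"), `scores` (NULL until annotated).
#' @export
hierarchical_cluster <- function(matrix, genes = NULL, n_clusters) {
  x <- as_expression_matrix(matrix)
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  v <- gene_values(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) > 0) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (ncol(v) < n_clusters) stop("fewer cells than clusters")
  v <- v[, order(colnames(v)), drop = FALSE]
  lx <- log2p1(v)
  cc <- suppressWarnings(stats::cor(lx))
  cc[is.na(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, k = n_clusters)
  structure(list(cluster = cl, tree = tree,
                 labels = stats::setNames(rep("unassigned", n_clusters),
                                          as.character(seq_len(n_clusters))),
                 scores = NULL),
            class = "Clustering")
}

#' Score clusters against marker panels and assign type labels
#'
#' Each gene's log2(FPKM+1) expression is z-scored across all cells; a
#' cluster's score for a panel is the mean of its cluster-mean z-scores over
#' the panel genes present in the matrix. A panel is only eligible to label a
#' cluster when its genes are actually expressed there (cluster-mean
#' log2(FPKM+1) above `min_expr`); among eligible panels the top score wins,
#' an exact tie or no eligible panel yields "unassigned".
#'
#' @param matrix an [ExpressionMatrix].
#' @param clustering a `Clustering` from [hierarchical_cluster()].
#' @param panels named list of marker-gene vectors.
#' @param min_expr eligibility floor on the cluster-mean log2(FPKM+1) of the
#'   panel genes (default 2.5, i.e. mean FPKM around 4.7): a panel that is
#'   essentially unexpressed in a cluster cannot label it.
#' @return the `Clustering` with `labels` and `scores`
#'   (clusters x panels matrix) filled in, and `cell_labels` (per cell).
#' @export
annotate_clusters <- function(matrix, clustering, panels, min_expr = 2.5) {
  x <- as_expression_matrix(matrix)
  lx <- log2p1(gene_values(x))
  present <- lapply(panels, intersect, x = rownames(lx))
  if (all(lengths(present) == 0)) {
    warning("no panel gene present in the matrix; all clusters unassigned")
    clustering$cell_labels <- stats::setNames(
      rep("unassigned", length(clustering$cluster)), names(clustering$cluster))
    return(clustering)
  }
  sds <- apply(lx, 1, stats::sd)
  z <- (lx - rowMeans(lx)) / ifelse(sds > 0, sds, 1)
  cl <- clustering$cluster
  ids <- sort(unique(cl))
  scores <- matrix(NA_real_, nrow = length(ids), ncol = length(panels),
                   dimnames = list(as.character(ids), names(panels)))
  eligible <- scores
  for (i in seq_along(ids)) {
    members <- names(cl)[cl == ids[i]]
    cmean <- rowMeans(z[, members, drop = FALSE])
    emean <- rowMeans(lx[, members, drop = FALSE])
    for (p in names(panels)) {
      g <- present[[p]]
      if (length(g) > 0) {
        scores[i, p] <- mean(cmean[g])
        eligible[i, p] <- mean(emean[g]) > min_expr
      }
    }
  }
  labels <- vapply(seq_along(ids), function(i) {
    s <- scores[i, ]
    s <- s[!is.na(s) & eligible[i, ] == 1]
    if (length(s) == 0) return("unassigned")
    top <- names(s)[s == max(s)]
    if (length(top) > 1) "unassigned" else top
  }, character(1))
  names(labels) <- as.character(ids)
  clustering$labels <- labels
  clustering$scores <- scores
  clustering$cell_labels <- stats::setNames(labels[as.character(cl)], names(cl))
  clustering
}

#' Two-pass marker-free decomposition of liver cells
#'
#' Pass 1 cuts the cell tree at 2 clusters and identifies the
#' hepatoblast-scoring branch. Pass 2 re-clusters the remaining cells into
#' `n_second_pass` clusters and merges any clusters whose top-scoring panel
#' coincides (e.g. two macrophage sub-clusters). If both pass-1 branches
#' score hepatoblast, all cells are labelled hepatoblast and pass 2 is
#' skipped.
#'
#' @param matrix an [ExpressionMatrix].
#' @param panels named list of marker panels; must include `hepatoblast`.
#' @param exclude gene ids removed before PCA ranking.
#' @param k_pca number of PCA-ranked genes used for clustering (default 400).
#' @param n_second_pass clusters in the second pass (default 6).
#' @return list: `cell_labels` (named character vector), `pass1`, `pass2`
#'   (`Clustering` objects; `pass2` NULL when skipped), `merged` (named list
#'   of merged pass-2 cluster ids per label), `genes` (ranked genes used).
#' @export
two_pass_decomposition <- function(matrix, panels = default_marker_panels()$panels,
                                   exclude = default_marker_panels()$exclude,
                                   k_pca = 400, n_second_pass = 6) {
  if (!"hepatoblast" %in% names(panels))
    stop("panels must include a 'hepatoblast' panel")
  x <- as_expression_matrix(matrix)
  genes <- rank_genes_by_pca(x, k = k_pca, exclude = exclude)
  p1 <- hierarchical_cluster(x, genes, n_clusters = 2)
  p1 <- annotate_clusters(x, p1, panels)
  hb_clusters <- names(p1$labels)[p1$labels == "hepatoblast"]
  cell_labels <- stats::setNames(rep(NA_character_, length(p1$cluster)),
                                 names(p1$cluster))
  if (length(hb_clusters) == 0) {
    # neither branch looks hepatoblast-like: take the higher-scoring branch
    hb_clusters <- rownames(p1$scores)[which.max(p1$scores[, "hepatoblast"])]
  }
  hb_cells <- names(p1$cluster)[as.character(p1$cluster) %in% hb_clusters]
  cell_labels[hb_cells] <- "hepatoblast"
  rest <- setdiff(names(p1$cluster), hb_cells)
  p2 <- NULL; merged <- list()
  if (length(hb_clusters) == 2 || length(rest) == 0) {
    message("both pass-1 branches score hepatoblast; pass 2 skipped")
  } else {
    sub <- ExpressionMatrix(x$values[, rest, drop = FALSE], spikein = x$spikein)
    k2 <- min(n_second_pass, length(rest))
    p2 <- hierarchical_cluster(sub, genes, n_clusters = k2)
    p2 <- annotate_clusters(sub, p2, panels)
    for (lab in unique(p2$labels)) {
      ids <- names(p2$labels)[p2$labels == lab]
      if (length(ids) > 1) merged[[lab]] <- ids
    }
    cell_labels[names(p2$cell_labels)] <- p2$cell_labels
  }
  list(cell_labels = cell_labels, pass1 = p1, pass2 = p2, merged = merged,
       genes = genes)
}

#' Rank genes for the display heatmap by one-way ANOVA across type labels
#'
#' One-way ANOVA F statistic of log2(FPKM+1) across cell-type labels; the
#' top `k` genes are returned in decreasing F order. Labels with fewer than
#' 2 cells are dropped with a warning.
#'
#' @param matrix an [ExpressionMatrix].
#' @param labels named character vector of per-cell labels.
#' @param k number of genes to return (default 400).
#' @return character vector of gene ids, highest F first.
#' @export
anova_rank_display_genes <- function(matrix, labels, k = 400) {
  x <- as_expression_matrix(matrix)
  v <- gene_values(x)
  labels <- labels[colnames(v)]
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("dropping label(s) with < 2 cells: ", paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    v <- v[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stop("need at least 2 labels with >= 2 cells")
  f <- row_f_stats(log2p1(v), labels)
  ord <- order(-f, rownames(v))
  utils::head(rownames(v)[ord], min(k, nrow(v)))
}

#' t-SNE embedding of cells on a selected gene set
#'
#' Standard Barnes-Hut t-SNE on log2(FPKM+1) over the given genes. The
#' perplexity is reduced automatically (with a warning) when the cell count
#' is too small for the requested value; a fixed seed makes coordinates
#' reproducible.
#'
#' @param matrix an [ExpressionMatrix].
#' @param genes gene ids used for the embedding.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @return data.frame: cell_id, tsne1, tsne2.
#' @export
embed_tsne <- function(matrix, genes, seed = 1L, perplexity = 30) {
  x <- as_expression_matrix(matrix)
  v <- gene_values(x)[genes, , drop = FALSE]
  lx <- t(log2p1(v))
  n <- nrow(lx)
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning(sprintf("perplexity reduced from %g to %d for %d cells",
                    perplexity, max_perp, n))
    perplexity <- max_perp
  }
  set.seed(as.integer(seed))
  emb <- Rtsne::Rtsne(lx, perplexity = perplexity, check_duplicates = FALSE,
                      pca = TRUE, verbose = FALSE)$Y
  data.frame(cell_id = rownames(lx), tsne1 = emb[, 1], tsne2 = emb[, 2],
             stringsAsFactors = FALSE)
}

#' Cell-type proportions per developmental stage
#'
#' @param labels named character vector of per-cell type labels.
#' @param stages named character vector of per-cell stages (same cells).
#' @return data.frame: stage, type, n, proportion; proportions sum to 1
#'   within each stage.
#' @export
cell_type_proportions <- function(labels, stages) {
  stopifnot(length(labels) == length(stages))
  if (!is.null(names(labels)) && !is.null(names(stages)))
    stages <- stages[names(labels)]
  tab <- table(stage = stages, type = labels)
  if (any(rowSums(tab) == 0)) stop("empty stage")
  prop <- prop.table(tab, margin = 1)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$proportion <- as.data.frame(prop)$Freq
  names(df) <- c("stage", "type", "n", "proportion")
  df
}

#' Count cells co-expressing two gene sets
#'
#' A cell counts if at least one gene of `set_a` and at least one gene of
#' `set_b` exceed the FPKM threshold (strict).
#'
#' @param matrix an [ExpressionMatrix].
#' @param set_a,set_b non-empty character vectors of gene ids.
#' @param threshold strict FPKM threshold (default 1).
#' @return list: `count`, `cells` (ids of co-expressing cells).
#' @export
count_coexpressing_cells <- function(matrix, set_a, set_b, threshold = 1) {
  x <- as_expression_matrix(matrix)
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  v <- x$values
  unknown <- setdiff(c(set_a, set_b), rownames(v))
  if (length(unknown) > 0)
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  pos_a <- colSums(v[set_a, , drop = FALSE] > threshold) > 0
  pos_b <- colSums(v[set_b, , drop = FALSE] > threshold) > 0
  both <- pos_a & pos_b
  list(count = sum(both), cells = colnames(v)[both])
}

#' GO-style over-representation test
#'
#' Hypergeometric upper-tail test of each term's overlap with the query set
#' against the gene universe, with Bonferroni correction across the tested
#' terms. Terms with no universe genes are skipped.
#'
#' @param query gene set of interest (must be a subset of `universe`).
#' @param universe background gene set.
#' @param annotation named list: term -> gene-id vector.
#' @return data.frame: term, overlap, term_size, p, p_adjusted (Bonferroni),
#'   significant (adjusted p < 0.05), sorted by p.
#' @export
go_overrepresentation <- function(query, universe, annotation) {
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  ann <- lapply(annotation, intersect, x = universe)
  ann <- ann[lengths(ann) > 0]
  if (length(ann) == 0) stop("no annotation term overlaps the universe")
  n_u <- length(universe); n_q <- length(query)
  rows <- lapply(names(ann), function(term) {
    g <- ann[[term]]
    ov <- length(intersect(g, query))
    p <- stats::phyper(ov - 1, length(g), n_u - length(g), n_q,
                       lower.tail = FALSE)
    data.frame(term = term, overlap = ov, term_size = length(g), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- pmin(1, res$p * nrow(res))
  res$significant <- res$p_adjusted < 0.05
  res[order(res$p, res$term), ]
}

#' Read a GMT gene-set annotation file
#'
#' @param path GMT file path (term, description, genes... per tab-separated line).
#' @return named list: term -> gene-id vector.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, character(1), 1))
}
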