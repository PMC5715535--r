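#' Screen differentially expressed transcription factors
#'
#' Two-sided Wilcoxon rank-sum test on log2(FPKM+1) per TF between two cell
#' groups; a TF is retained at raw p < `alpha` (no multiple-testing
#' correction: the threshold is applied on raw p-values). The direction is
#' the sign of the median difference (group with the larger median).
#'
#' @param matrix an [ExpressionMatrix].
#' @param group_a,group_b cell-id vectors (>= 5 cells each).
#' @param tf_list character vector of TF gene ids; absent TFs are skipped
#'   with a warning.
#' @param alpha raw significance threshold (default 0.01).
#' @return data.frame: tf, p, median_a, median_b, direction ("a"/"b"),
#'   retained; one row per tested TF.
#' @export
screen_de_tfs <- function(matrix, group_a, group_b, tf_list, alpha = 0.01) {
  x <- as_expression_matrix(matrix)
  if (length(group_a) < 5 || length(group_b) < 5)
    stop("both groups need at least 5 cells")
  if (length(tf_list) == 0) stop("tf_list is empty")
  present <- intersect(tf_list, rownames(x$values))
  absent <- setdiff(tf_list, present)
  if (length(absent) > 0)
    warning("TF(s) absent from matrix, skipped: ", paste(absent, collapse = ", "))
  la <- log2p1(x$values[present, group_a, drop = FALSE])
  lb <- log2p1(x$values[present, group_b, drop = FALSE])
  rows <- lapply(present, function(tf) {
    a <- la[tf, ]; b <- lb[tf, ]
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    if (is.na(p)) p <- 1  # all values tied
    ma <- stats::median(a); mb <- stats::median(b)
    data.frame(tf = tf, p = p, median_a = ma, median_b = mb,
               direction = if (ma >= mb) "a" else "b",
               retained = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlation between transcription factors
#'
#' Correlations on log2(FPKM+1) across the given cells. TFs with zero
#' variance get NA correlations (undefined, not zero); the diagonal is 1 for
#' TFs with positive variance.
#'
#' @param matrix an [ExpressionMatrix].
#' @param tfs TF gene ids (>= 2).
#' @param cells cell ids (>= 3); defaults to all cells.
#' @return symmetric correlation matrix (TFs x TFs).
#' @export
tf_correlation_matrix <- function(matrix, tfs, cells = NULL) {
  x <- as_expression_matrix(matrix)
  if (is.null(cells)) cells <- colnames(x$values)
  if (length(cells) < 3) stop("need at least 3 cells")
  if (length(tfs) < 2) stop("need at least 2 TFs")
  missing <- setdiff(tfs, rownames(x$values))
  if (length(missing) > 0) stop("unknown TF(s): ", paste(missing, collapse = ", "))
  lx <- t(log2p1(x$values[tfs, cells, drop = FALSE]))
  sds <- apply(lx, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(lx))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  cc
}

#' Build a thresholded TF covariance network
#'
#' Edges connect TF pairs with Pearson correlation strictly greater than
#' `r_min` (signed coefficient, NA pairs excluded). A TF is retained iff its
#' degree in this thresholded graph is at least `min_partners`; the criterion
#' is evaluated once on the full thresholded graph, not iteratively, so a
#' retained node's degree within the final network may drop below
#' `min_partners`. The network consists of the retained nodes and all
#' threshold edges between retained pairs.
#'
#' @param corr symmetric correlation matrix from [tf_correlation_matrix()].
#' @param r_min correlation threshold, strict (default 0.35).
#' @param min_partners minimum number of threshold partners (default 3).
#' @param group optional group tag stored on the network.
#' @return a `TFNetwork` list: `nodes` (data.frame tf, degree — partner count
#'   in the thresholded graph — and network_degree), `edges` (data.frame
#'   tf_a, tf_b, r), `group`.
#' @export
build_covariance_network <- function(corr, r_min = 0.35, min_partners = 3,
                                     group = NA_character_) {
  if (is.null(dim(corr)) || nrow(corr) == 0) stop("empty correlation table")
  tfs <- rownames(corr)
  adj <- !is.na(corr) & corr > r_min
  diag(adj) <- FALSE
  degree <- rowSums(adj)
  retained <- tfs[degree >= min_partners]
  edges <- data.frame(tf_a = character(0), tf_b = character(0), r = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(retained) >= 2) {
    sub <- adj[retained, retained, drop = FALSE]
    idx <- which(sub & upper.tri(sub), arr.ind = TRUE)
    if (nrow(idx) > 0) {
      edges <- data.frame(tf_a = retained[idx[, 1]], tf_b = retained[idx[, 2]],
                          r = corr[cbind(match(retained[idx[, 1]], tfs),
                                         match(retained[idx[, 2]], tfs))],
                          stringsAsFactors = FALSE)
      # canonical edge order for determinism
      swap <- edges$tf_a > edges$tf_b
      tmp <- edges$tf_a[swap]; edges$tf_a[swap] <- edges$tf_b[swap]
      edges$tf_b[swap] <- tmp
      edges <- edges[order(edges$tf_a, edges$tf_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  net_degree <- stats::setNames(rep(0L, length(retained)), retained)
  if (nrow(edges) > 0) {
    tt <- table(c(edges$tf_a, edges$tf_b))
    net_degree[names(tt)] <- as.integer(tt)
  }
  nodes <- data.frame(tf = retained,
                      degree = as.integer(degree[retained]),
                      network_degree = as.integer(net_degree),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$tf), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, group = group,
                 r_min = r_min, min_partners = min_partners),
            class = "TFNetwork")
}

#' @export
print.TFNetwork <- function(x, ...) {
  cat(sprintf("TFNetwork%s: %d TFs, %d edges (r > %g, >= %d partners)\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$nodes), nrow(x$edges), x$r_min, x$min_partners))
  invisible(x)
}

#' Rank network TFs by partner count
#'
#' Stable descending sort by degree (partner count in the thresholded
#' graph), ties broken alphabetically.
#'
#' @param network a `TFNetwork`.
#' @return data.frame: tf, degree; best-connected first.
#' @export
hub_ranking <- function(network) {
  nodes <- network$nodes
  if (nrow(nodes) == 0) return(nodes[, c("tf", "degree")])
  nodes <- nodes[order(-nodes$degree, nodes$tf), c("tf", "degree")]
  rownames(nodes) <- NULL
  nodes
}

#' Export a TF network as an edge list with optional layout
#'
#' Writes a TSV edge list (tf_a, tf_b, r) plus a node table (tf, degree) and,
#' when `layout_seed` is given, seed-reproducible Fruchterman-Reingold 2-D
#' coordinates.
#'
#' @param network a `TFNetwork`.
#' @param path edge-list output path; nodes go to `<path>.nodes`, layout to
#'   `<path>.layout`.
#' @param layout_seed integer seed for the force-directed layout, or NULL to
#'   skip the layout.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, layout_seed = NULL) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, paste0(path, ".nodes"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(layout_seed) && nrow(network$nodes) > 0) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes$tf)
    set.seed(as.integer(layout_seed))
    xy <- igraph::layout_with_fr(g)
    layout <- data.frame(tf = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                         stringsAsFactors = FALSE)
    utils::write.table(layout, paste0(path, ".layout"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a TF network edge list written by [export_network()]
#'
#' @param path edge-list path.
#' @return list with `edges` and `nodes` data.frames.
#' @export
read_network <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paste0(path, ".nodes"), stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}
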