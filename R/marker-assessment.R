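#' Marker positivity of cells for a gene
#'
#' A cell is marker-positive iff the gene's FPKM strictly exceeds the
#' threshold (default 1, the detection convention).
#'
#' @param matrix an [ExpressionMatrix].
#' @param gene gene id.
#' @param threshold strict FPKM threshold (default 1).
#' @return named logical vector over cells.
#' @export
marker_positive <- function(matrix, gene, threshold = 1) {
  x <- as_expression_matrix(matrix)
  if (!gene %in% rownames(x$values)) stop("unknown gene id: ", gene)
  x$values[gene, ] > threshold
}

#' Isolation sensitivity and specificity of candidate markers
#'
#' For each gene and developmental stage, within that stage's cells only:
#' sensitivity = marker-positive target cells / all target cells (does
#' sorting on the marker capture most target cells?); specificity =
#' marker-positive target cells / all marker-positive cells (is the sorted
#' pool pure?). Note this "specificity" is positive-pool purity (precision);
#' the classical true-negative rate is reported as `tnr` for reference.
#' Scores with a zero denominator are NA.
#'
#' @param matrix an [ExpressionMatrix].
#' @param labels named character vector of per-cell type labels.
#' @param stages named character vector of per-cell stages.
#' @param genes candidate marker gene ids.
#' @param target_type the cell type to be isolated (e.g. "hepatoblast").
#' @param threshold strict FPKM positivity threshold (default 1).
#' @return data.frame: gene, type, stage, n_target, n_positive,
#'   pos_target, pos_other, sensitivity, specificity, tnr.
#' @export
assess_markers <- function(matrix, labels, stages, genes,
                           target_type, threshold = 1) {
  x <- as_expression_matrix(matrix)
  cells <- colnames(x$values)
  labels <- labels[cells]; stages <- stages[cells]
  unknown <- setdiff(genes, rownames(x$values))
  if (length(unknown) > 0)
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  stage_levels <- unique(stages)
  rows <- list()
  for (st in stage_levels) {
    in_stage <- stages == st
    tgt <- in_stage & labels == target_type
    for (g in genes) {
      pos <- x$values[g, ] > threshold
      pt <- sum(pos & tgt)
      po <- sum(pos & in_stage & !tgt)
      n_t <- sum(tgt)
      n_p <- pt + po
      n_neg_other <- sum(in_stage & !tgt & !pos)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, type = target_type, stage = st,
        n_target = n_t, n_positive = n_p, pos_target = pt, pos_other = po,
        sensitivity = if (n_t > 0) pt / n_t else NA_real_,
        specificity = if (n_p > 0) pt / n_p else NA_real_,
        tnr = if (sum(in_stage & !tgt) > 0)
          n_neg_other / sum(in_stage & !tgt) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Co-expression quadrant counts for a marker pair
#'
#' Partitions the given cells into the four positivity quadrants of two
#' genes: both positive, a-only, b-only, neither. The counts always sum to
#' the number of cells.
#'
#' @param matrix an [ExpressionMatrix].
#' @param gene_a,gene_b gene ids.
#' @param cells cell ids to consider; defaults to all cells.
#' @param threshold strict FPKM threshold (default 1).
#' @return named integer vector: both, a_only, b_only, neither.
#' @export
marker_pair_quadrants <- function(matrix, gene_a, gene_b, cells = NULL,
                                  threshold = 1) {
  x <- as_expression_matrix(matrix)
  if (is.null(cells)) cells <- colnames(x$values)
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(x$values)) stop("unknown gene id: ", g)
  a <- x$values[gene_a, cells] > threshold
  b <- x$values[gene_b, cells] > threshold
  c(both = sum(a & b), a_only = sum(a & !b), b_only = sum(!a & b),
    neither = sum(!a & !b))
}

#' Predict new isolation markers from performance scores
#'
#' A gene is a candidate iff its sensitivity and specificity both strictly
#' exceed `cutoff` at every required stage (or at least `min_stages` of them)
#' and the gene is on the membrane-receptor list — only surface proteins can
#' serve as FACS isolation markers. Candidates are returned in a
#' deterministic order: descending minimum score across required stages,
#' ties alphabetical.
#'
#' @param perf performance table from [assess_markers()] covering all
#'   candidate genes at all required stages.
#' @param membrane_list character vector of membrane-receptor gene ids.
#' @param cutoff strict score cutoff (default 0.5).
#' @param stages_required stages at which the cutoff must hold; defaults to
#'   all stages in `perf`.
#' @param min_stages minimum number of required stages at which the cutoff
#'   must hold (default: all of them).
#' @return data.frame: gene, min_score, n_stages_passed, membrane (TRUE).
#' @export
predict_markers <- function(perf, membrane_list, cutoff = 0.5,
                            stages_required = NULL, min_stages = NULL) {
  if (length(membrane_list) == 0) {
    warning("empty membrane list; no candidates")
    return(data.frame(gene = character(0), min_score = numeric(0),
                      n_stages_passed = integer(0), membrane = logical(0)))
  }
  if (is.null(stages_required)) stages_required <- unique(perf$stage)
  if (is.null(min_stages)) min_stages <- length(stages_required)
  perf <- perf[perf$stage %in% stages_required, , drop = FALSE]
  rows <- lapply(unique(perf$gene), function(g) {
    sub <- perf[perf$gene == g, ]
    if (!all(stages_required %in% sub$stage)) return(NULL)
    ok <- !is.na(sub$sensitivity) & !is.na(sub$specificity) &
      sub$sensitivity > cutoff & sub$specificity > cutoff
    data.frame(gene = g,
               min_score = min(pmin(sub$sensitivity, sub$specificity)),
               n_stages_passed = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(gene = character(0), min_score = numeric(0),
                                      n_stages_passed = integer(0))
  res <- res[res$n_stages_passed >= min_stages & res$gene %in% membrane_list, ,
             drop = FALSE]
  res$membrane <- rep(TRUE, nrow(res))
  res <- res[order(-res$min_score, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}
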