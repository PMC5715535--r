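#' Adjust FPKM values by mapped-read proportions
#'
#' Re-weights each cell's FPKM values by the share of its sequencing reads
#' that mapped to the genome versus the spike-in reference: gene rows are
#' multiplied by `genome_reads / (genome_reads + spikein_reads)` and spike-in
#' rows by `spikein_reads / (genome_reads + spikein_reads)`. This restores
#' the relative library share the two reference sets consumed. Zeros stay
#' zero and within-cell value ordering is preserved.
#'
#' @param matrix an [ExpressionMatrix].
#' @param stats data.frame with columns `cell_id`, `genome_reads`,
#'   `spikein_reads`; every cell of the matrix must be present with positive
#'   total reads.
#' @return adjusted [ExpressionMatrix].
#' @export
adjust_fpkm <- function(matrix, stats) {
  x <- as_expression_matrix(matrix)
  req <- c("cell_id", "genome_reads", "spikein_reads")
  if (!all(req %in% names(stats))) stop("stats needs columns: ", paste(req, collapse = ", "))
  cells <- colnames(x$values)
  missing <- setdiff(cells, stats$cell_id)
  if (length(missing) > 0)
    stop("read stats missing for cell(s): ", paste(missing, collapse = ", "))
  idx <- match(cells, stats$cell_id)
  g <- stats$genome_reads[idx]; s <- stats$spikein_reads[idx]
  if (any(g < 0) || any(s < 0)) stop("read counts must be non-negative")
  tot <- g + s
  if (any(tot == 0)) stop("cell(s) with zero total reads: ",
                          paste(cells[tot == 0], collapse = ", "))
  v <- x$values
  gene_fac <- g / tot
  spike_fac <- s / tot
  v[!x$spikein, ] <- sweep(v[!x$spikein, , drop = FALSE], 2, gene_fac, "*")
  v[x$spikein, ] <- sweep(v[x$spikein, , drop = FALSE], 2, spike_fac, "*")
  ExpressionMatrix(v, spikein = x$spikein)
}

#' Detected-gene counts per cell
#'
#' Number of biological (non-spike-in) genes exceeding an FPKM threshold in
#' each cell; "detected" follows the FPKM > 1 convention by default.
#'
#' @param matrix an [ExpressionMatrix].
#' @param threshold strict FPKM threshold (default 1).
#' @return named integer vector over cells.
#' @export
detected_genes <- function(matrix, threshold = 1) {
  x <- as_expression_matrix(matrix)
  colSums(gene_values(x) > threshold)
}

#' Spike-in cross-cell correlation QC
#'
#' For every cell, the median pairwise Pearson correlation of its spike-in
#' profile (on log2(FPKM+1)) with all other cells. High values indicate low
#' technical noise. Cells whose spike-in vector has zero variance get `NA`
#' (their correlations are undefined, not zero).
#'
#' @param matrix an [ExpressionMatrix] with at least 2 cells and 3 spike-in rows.
#' @return named numeric vector of per-cell median correlations.
#' @export
spikein_correlation_qc <- function(matrix) {
  x <- as_expression_matrix(matrix)
  sp <- spikein_values(x)
  if (ncol(sp) < 2) stop("need at least 2 cells")
  if (nrow(sp) < 3) stop("need at least 3 spike-in rows")
  lx <- log2p1(sp)
  sds <- apply(lx, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(lx))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- NA_real_
  res <- apply(cc, 2, stats::median, na.rm = TRUE)
  res[sds == 0] <- NA_real_
  res[is.nan(res)] <- NA_real_
  res
}

#' Retention percentage, rounded half-up to one decimal
#'
#' @param n_in cells entering QC.
#' @param n_retained cells retained.
#' @return percentage retained, one decimal.
#' @export
retention_percentage <- function(n_in, n_retained) {
  stopifnot(n_in > 0, n_retained >= 0, n_retained <= n_in)
  round_half_up(100 * n_retained / n_in, 1)
}

#' Flag outlier cells by library complexity and spike-in agreement
#'
#' A cell is flagged if its detected-gene count falls below
#' `median - mad_k * MAD` (scaled MAD) of all cells, or if its median
#' spike-in correlation to the other cells drops below `spikein_corr_min`
#' (the spike-in criterion is skipped when the matrix carries fewer than 3
#' spike-in rows). The rule uses only in-matrix information and is invariant
#' to cell and gene order.
#'
#' @param matrix an [ExpressionMatrix] with at least 8 cells.
#' @param fpkm_threshold detection threshold (default 1).
#' @param mad_k MAD multiplier (default 3).
#' @param spikein_corr_min floor on median spike-in correlation (default 0.5).
#' @return a `QcReport` list: per-cell table (`cells`: cell_id,
#'   detected_genes, spikein_cor, outlier), `n_in`, `n_retained`,
#'   `retention_pct`.
#' @export
identify_outlier_cells <- function(matrix, fpkm_threshold = 1, mad_k = 3,
                                   spikein_corr_min = 0.5) {
  x <- as_expression_matrix(matrix)
  n <- ncol(x$values)
  if (n < 8) stop("need at least 8 cells for robust outlier statistics")
  det <- detected_genes(x, fpkm_threshold)
  cutoff <- stats::median(det) - mad_k * stats::mad(det)
  flag <- det < cutoff
  sp_cor <- rep(NA_real_, n)
  if (sum(x$spikein) >= 3) {
    sp_cor <- spikein_correlation_qc(x)
    flag <- flag | (!is.na(sp_cor) & sp_cor < spikein_corr_min) | is.na(sp_cor)
  }
  cells <- data.frame(cell_id = colnames(x$values),
                      detected_genes = as.integer(det),
                      spikein_cor = as.numeric(sp_cor),
                      outlier = unname(flag), stringsAsFactors = FALSE)
  qc_report(cells)
}

qc_report <- function(cells) {
  n_in <- nrow(cells)
  n_ret <- sum(!cells$outlier)
  structure(list(cells = cells, n_in = n_in, n_retained = n_ret,
                 retention_pct = retention_percentage(n_in, n_ret)),
            class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport: %d cells in, %d retained (%.1f%%)\n",
              x$n_in, x$n_retained, x$retention_pct))
  invisible(x)
}

#' Two-stage QC for a sorted cell population
#'
#' Stage 1 applies [identify_outlier_cells()]. Stage 2 computes, for each
#' stage-1 survivor, the Pearson correlation (log2(FPKM+1), gene rows) to the
#' median profile of all stage-1 survivors, and removes cells below
#' `profile_cor_min`. Designed for FACS-sorted populations (e.g.
#' Epcam-positive cells) expected to be transcriptionally homogeneous.
#'
#' @param matrix an [ExpressionMatrix].
#' @param profile_cor_min stage-2 correlation floor (default 0.6).
#' @param ... passed to [identify_outlier_cells()].
#' @return a `QcReport` with extra fields `stage1_removed`, `stage2_removed`
#'   and a `status` string; if stage 1 removes every cell, stage 2 is skipped
#'   with `status = "stage2_skipped"`.
#' @export
two_stage_population_qc <- function(matrix, profile_cor_min = 0.6, ...) {
  x <- as_expression_matrix(matrix)
  s1 <- identify_outlier_cells(x, ...)
  keep1 <- s1$cells$cell_id[!s1$cells$outlier]
  status <- "ok"
  removed2 <- character(0)
  if (length(keep1) == 0) {
    warning("all cells removed at stage 1; stage 2 skipped")
    status <- "stage2_skipped"
  } else {
    lx <- log2p1(gene_values(x)[, keep1, drop = FALSE])
    med_profile <- apply(lx, 1, stats::median)
    r <- suppressWarnings(stats::cor(lx, med_profile))[, 1]
    removed2 <- keep1[is.na(r) | r < profile_cor_min]
  }
  cells <- s1$cells
  cells$stage <- ifelse(cells$outlier, "stage1",
                        ifelse(cells$cell_id %in% removed2, "stage2", "retained"))
  cells$outlier <- cells$stage != "retained"
  rep <- qc_report(cells)
  rep$stage1_removed <- s1$n_in - s1$n_retained
  rep$stage2_removed <- length(removed2)
  rep$status <- status
  rep
}

#' Write a QC report to disk
#'
#' Writes the per-cell table as TSV and a machine-readable `key=value`
#' run summary alongside it.
#'
#' @param report a `QcReport`.
#' @param path TSV output path; the summary is written to `<path>.summary`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_lines <- c(
    sprintf("cells_in=%d", report$n_in),
    sprintf("cells_retained=%d", report$n_retained),
    sprintf("retention_pct=%.1f", report$retention_pct))
  writeLines(summary_lines, paste0(path, ".summary"))
  invisible(path)
}
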