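#' Expression matrix container
#'
#' A light S3 wrapper around a genes x cells numeric matrix of FPKM values
#' with a logical spike-in row mask. Spike-in rows hold the synthetic RNA
#' controls (ids prefixed `"ERCC-"` by convention) that are added to every
#' cell at fixed amounts and therefore carry technical noise only.
#'
#' @param values numeric matrix, genes in rows and cells in columns, with
#'   unique row and column names and no negative entries.
#' @param spikein logical vector flagging spike-in rows; defaults to rows
#'   whose id starts with `"ERCC-"`.
#' @return an object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, spikein = startsWith(rownames(values), "ERCC-")) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    if (nrow(values) > 0 && is.null(rownames(values)))
      stop("gene ids (rownames) are required")
    if (ncol(values) > 0 && is.null(colnames(values)))
      stop("cell ids (colnames) are required")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0)
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c) > 0)
    stop("duplicate cell id(s): ", paste(dup_c, collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at gene '%s', cell '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (is.null(spikein)) spikein <- rep(FALSE, nrow(values))
  spikein <- as.logical(spikein)
  if (length(spikein) != nrow(values))
    stop("spike-in mask length must equal gene count")
  structure(list(values = values, spikein = spikein), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes (%d spike-ins) x %d cells\n",
              nrow(x$values), sum(x$spikein), ncol(x$values)))
  invisible(x)
}

#' Gene (biological) rows of an expression matrix
#' @param x an [ExpressionMatrix].
#' @return numeric matrix of non-spike-in rows.
#' @export
gene_values <- function(x) x$values[!x$spikein, , drop = FALSE]

#' Spike-in rows of an expression matrix
#' @param x an [ExpressionMatrix].
#' @return numeric matrix of spike-in rows.
#' @export
spikein_values <- function(x) x$values[x$spikein, , drop = FALSE]

as_expression_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x else ExpressionMatrix(x)
}

#' Read an expression matrix from disk
#'
#' Supports a dense tab-separated layout (genes in rows, a header row of cell
#' ids, first column of gene ids) and MatrixMarket coordinate format. The
#' MatrixMarket form is a triple of files: `<path>` (`.mtx`), `<path>.rownames`
#' and `<path>.colnames`, one id per line.
#'
#' @param path file path (the `.mtx` file itself for `format = "mtx"`).
#' @param format `"tsv"` or `"mtx"`.
#' @return an [ExpressionMatrix].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    gene_ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    mode(values) <- "numeric"
    rownames(values) <- gene_ids
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    m <- Matrix::readMM(path)
    values <- as.matrix(m)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(values) || length(cn) != ncol(values))
      stop("row/col name files do not match matrix dimensions")
    dimnames(values) <- list(rn, cn)
  }
  ExpressionMatrix(values)
}

#' Write an expression matrix to disk
#'
#' Values are written with full double precision so that a read/write
#' round-trip is exact. See [read_matrix()] for the on-disk layout.
#'
#' @param x an [ExpressionMatrix] or plain matrix.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx")) {
  x <- as_expression_matrix(x)
  format <- match.arg(format)
  v <- x$values
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
    if (nrow(v) > 0) {
      body <- vapply(seq_len(nrow(v)), function(i) {
        paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t")
      }, character(1))
      writeLines(body, con)
    }
  } else {
    # coordinate MatrixMarket written directly to keep full precision
    nz <- which(v != 0)
    con <- file(path, "w")
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(sprintf("%d %d %d", nrow(v), ncol(v), length(nz)), con)
    if (length(nz) > 0) {
      ri <- ((nz - 1) %% nrow(v)) + 1
      ci <- ((nz - 1) %/% nrow(v)) + 1
      writeLines(sprintf("%d %d %.17g", ri, ci, v[nz]), con)
    }
    close(con)
    writeLines(rownames(v), paste0(path, ".rownames"))
    writeLines(colnames(v), paste0(path, ".colnames"))
  }
  invisible(path)
}
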