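# internal helpers shared across modules

#' Log2-transform FPKM values with a pseudocount of 1
#'
#' All correlation and clustering computations in the package operate on
#' `log2(FPKM + 1)`. The pseudocount of 1 matches the FPKM > 1 detection
#' convention used throughout.
#'
#' @param x numeric vector or matrix of non-negative FPKM values.
#' @return transformed values, same shape as `x`.
#' @export
log2p1 <- function(x) log2(x + 1)

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

# Per-row one-way ANOVA F statistics for an expression matrix.
# Vectorised over rows; groups with < 2 observations must be dropped by the
# caller. Rows with zero within-group variance and distinct group means get
# F = Inf; rows constant everywhere get F = 0.
row_f_stats <- function(x, groups) {
  groups <- as.factor(groups)
  stopifnot(ncol(x) == length(groups))
  k <- nlevels(groups)
  n <- ncol(x)
  if (k < 2) stop("need at least 2 groups for ANOVA")
  counts <- as.vector(table(groups))
  # group means: rows x groups
  gsum <- x %*% stats::model.matrix(~ groups - 1)
  gmean <- sweep(gsum, 2, counts, "/")
  grand <- rowMeans(x)
  ss_between <- as.vector((gmean - grand)^2 %*% counts)
  ss_total <- rowSums((x - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (n - k)
  f <- ms_between / ms_within
  # 0/0 (flat gene) -> 0 ; positive/0 (perfect separation) -> Inf
  f[ms_within == 0 & ms_between == 0] <- 0
  f[ms_within == 0 & ms_between > 0] <- Inf
  unname(f)
}

# p-values for the F statistics above
row_f_pvalues <- function(f, k, n) {
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  p
}

# derive a deterministic sub-seed from a master seed; keeps the result a
# valid 32-bit integer
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}
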