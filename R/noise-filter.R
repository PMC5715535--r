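#' Per-gene expression moments
#'
#' Sample mean, unbiased sample variance and squared coefficient of variation
#' (CV^2 = variance / mean^2) of every biological gene across cells, on the
#' raw FPKM scale. CV^2 is undefined (NA) for genes with zero mean. Spike-in
#' rows are excluded by default.
#'
#' @param matrix an [ExpressionMatrix] (or plain matrix) with >= 2 cells.
#' @param include_spikeins if TRUE, spike-in rows are kept (default FALSE).
#' @return data.frame: gene_id, mu, var, cv2.
#' @export
estimate_moments <- function(matrix, include_spikeins = FALSE) {
  x <- as_expression_matrix(matrix)
  v <- if (include_spikeins) x$values else gene_values(x)
  if (ncol(v) < 2) stop("variance is undefined with fewer than 2 cells")
  mu <- rowMeans(v)
  va <- apply(v, 1, stats::var)
  cv2 <- ifelse(mu > 0, va / mu^2, NA_real_)
  data.frame(gene_id = rownames(v), mu = unname(mu), var = unname(va),
             cv2 = unname(cv2), stringsAsFactors = FALSE)
}

#' Choose the minimum-mean floor for the noise regression
#'
#' mu_th is the smallest observed mean such that, among genes with mean
#' strictly greater than mu_th, at most `max_frac` have CV^2 > `cv2_cut`.
#' If the full gene set already satisfies the condition, mu_th = 0. Genes
#' above this floor are dominated by technical rather than sampling noise
#' and are safe to fit the regression on.
#'
#' @param moments data.frame from [estimate_moments()].
#' @param cv2_cut CV^2 ceiling defining a "noisy" gene (default 0.3).
#' @param max_frac maximum tolerated fraction of noisy genes above the floor
#'   (default 0.05).
#' @return mu_th, a single numeric value.
#' @export
select_mu_threshold <- function(moments, cv2_cut = 0.3, max_frac = 0.05) {
  m <- moments[moments$mu > 0 & !is.na(moments$cv2), , drop = FALSE]
  if (nrow(m) == 0) stop("no genes with positive mean")
  frac_noisy <- function(th) {
    above <- m$cv2[m$mu > th]
    if (length(above) == 0) return(NA_real_)
    mean(above > cv2_cut)
  }
  if (frac_noisy(0) <= max_frac) return(0)
  for (th in sort(unique(m$mu))) {
    f <- frac_noisy(th)
    if (!is.na(f) && f <= max_frac) return(th)
  }
  stop("no mean threshold satisfies the CV^2 condition; ",
       "more genes or a larger max_frac are needed")
}

#' Fit the technical-noise model CV^2 = a1/mu + a0
#'
#' Gamma-family generalized linear regression of CV^2 on 1/mu with identity
#' link, restricted to genes with mean above `mu_th`; the intercept estimates
#' a0 and the slope a1. If the GLM does not converge, an ordinary
#' least-squares fit of the same design is used as a documented fallback.
#' Negative estimates are clipped at 0 with a warning.
#'
#' @param moments data.frame from [estimate_moments()].
#' @param mu_th minimum-mean floor from [select_mu_threshold()].
#' @param z confidence-interval multiplier stored with the model
#'   (default 1.96, a two-sided normal 95\% interval).
#' @return a `NoiseModel` list: a0, a1, mu_th, z, n_genes_fit, method.
#' @export
fit_noise_model <- function(moments, mu_th, z = 1.96) {
  stopifnot(mu_th >= 0, z > 0)
  m <- moments[moments$mu > mu_th & !is.na(moments$cv2), , drop = FALSE]
  if (nrow(m) < 10) stop("need at least 10 genes above mu_th to fit the model")
  inv_mu <- 1 / m$mu
  ols <- stats::lm(cv2 ~ inv_mu, data = data.frame(cv2 = m$cv2, inv_mu = inv_mu))
  start <- stats::coef(ols)
  method <- "glm_gamma_identity"
  fit <- tryCatch({
    g <- suppressWarnings(stats::glm(
      cv2 ~ inv_mu, family = stats::Gamma(link = "identity"),
      data = data.frame(cv2 = m$cv2, inv_mu = inv_mu),
      start = pmax(start, c(1e-6, 1e-6))))
    if (!g$converged) stop("GLM did not converge")
    stats::coef(g)
  }, error = function(e) {
    method <<- "ols_fallback"
    stats::coef(ols)
  })
  a0 <- unname(fit[1]); a1 <- unname(fit[2])
  if (a0 < 0 || a1 < 0) {
    warning("negative noise-constant estimate clipped at 0")
    a0 <- max(a0, 0); a1 <- max(a1, 0)
  }
  structure(list(a0 = a0, a1 = a1, mu_th = mu_th, z = z,
                 n_genes_fit = nrow(m), method = method),
            class = "NoiseModel")
}

#' @export
print.NoiseModel <- function(x, ...) {
  cat(sprintf("NoiseModel: CV^2 = %.4g/mu + %.4g  (mu_th = %.4g, %d genes, %s)\n",
              x$a1, x$a0, x$mu_th, x$n_genes_fit, x$method))
  invisible(x)
}

#' Technical-noise variance for a given mean
#'
#' sigma0^2 = a0 * mu^2 + a1 * mu, the noise variance implied by the fitted
#' CV^2 law for a transcript of mean `mu`.
#'
#' @param model a `NoiseModel`.
#' @param mu non-negative mean FPKM (vectorised).
#' @return numeric vector of noise variances.
#' @export
noise_variance <- function(model, mu) {
  if (any(mu < 0)) stop("mu must be non-negative")
  model$a0 * mu^2 + model$a1 * mu
}

#' Two-criterion technical-noise gene filter
#'
#' A gene is retained iff it fulfils both criteria simultaneously:
#' criterion 1, the normal 95% confidence interval built from mu and the
#' noise variance excludes zero (`mu - z * sqrt(sigma0^2) > 0`), guaranteeing
#' expression rises above the noise floor; criterion 2, the observed variance
#' strictly exceeds the noise variance (`var > sigma0^2`), keeping only genes
#' that can plausibly be differentially expressed. Genes with zero mean fail
#' criterion 1.
#'
#' @param moments data.frame from [estimate_moments()].
#' @param model a `NoiseModel`.
#' @return data.frame: gene_id, mu, var, cv2, sigma0_sq, pass1, pass2,
#'   retained, failing ("1", "2", or NA for retained genes; criterion 1 is
#'   reported when both fail).
#' @export
filter_genes <- function(moments, model) {
  s0 <- noise_variance(model, moments$mu)
  pass1 <- moments$mu - model$z * sqrt(s0) > 0
  pass2 <- !is.na(moments$var) & moments$var > s0
  retained <- pass1 & pass2
  failing <- ifelse(retained, NA_character_, ifelse(!pass1, "1", "2"))
  data.frame(gene_id = moments$gene_id, mu = moments$mu, var = moments$var,
             cv2 = moments$cv2, sigma0_sq = s0, pass1 = pass1, pass2 = pass2,
             retained = retained, failing = failing, stringsAsFactors = FALSE)
}

#' Run the full noise-filter stage on a matrix
#'
#' Convenience wrapper: moments, mu_th selection, model fit and gene filter
#' in one call, excluding spike-in rows throughout.
#'
#' @param matrix an [ExpressionMatrix].
#' @param cv2_cut,max_frac passed to [select_mu_threshold()].
#' @param z passed to [fit_noise_model()].
#' @return list with `moments`, `model` and `result` (the filter table).
#' @export
noise_filter_pipeline <- function(matrix, cv2_cut = 0.3, max_frac = 0.05,
                                  z = 1.96) {
  moments <- estimate_moments(matrix)
  mu_th <- select_mu_threshold(moments, cv2_cut, max_frac)
  model <- fit_noise_model(moments, mu_th, z)
  list(moments = moments, model = model, result = filter_genes(moments, model))
}
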