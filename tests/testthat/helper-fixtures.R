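# shared fixtures and independent oracles for the test suite

# small expression matrix with explicit values; rows named g1..gn unless ids
# are supplied
toy_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                       spikein = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(gene_ids, cell_ids)
  if (is.null(spikein)) return(ExpressionMatrix(values))
  ExpressionMatrix(values, spikein = spikein)
}

# FPKM values whose log2(FPKM + 1) equals the given numbers exactly
fpkm_for_log2 <- function(y) 2^y - 1

# a vector of cells with an exact sample Pearson correlation `r` to profile
# `p` on the log2(FPKM+1) scale; `ortho_seed` picks the orthogonal direction
cells_with_exact_cor <- function(p, r, center = 6, scale = 0.5,
                                 ortho_seed = 1) {
  u <- (p - mean(p)) / stats::sd(p)
  set.seed(ortho_seed)
  w <- stats::rnorm(length(p))
  w <- stats::residuals(stats::lm(w ~ u))
  v <- (w - mean(w)) / stats::sd(w)
  y <- center + scale * (r * u + sqrt(1 - r^2) * v)
  stopifnot(all(y > 1))
  fpkm_for_log2(y)
}

# brute-force evaluator for the two noise-filter criteria
brute_force_filter <- function(moments, a0, a1, z) {
  out <- logical(nrow(moments))
  failing <- rep(NA_character_, nrow(moments))
  for (i in seq_len(nrow(moments))) {
    mu <- moments$mu[i]
    s0 <- a0 * mu^2 + a1 * mu
    crit1 <- (mu - z * sqrt(s0)) > 0
    crit2 <- moments$var[i] > s0
    out[i] <- crit1 && crit2
    if (!out[i]) failing[i] <- if (!crit1) "1" else "2"
  }
  list(retained = out, failing = failing)
}

# exhaustive-scan oracle for the mu_th rule
brute_force_mu_threshold <- function(mu, cv2, cv2_cut = 0.3, max_frac = 0.05) {
  keep <- mu > 0 & !is.na(cv2)
  mu <- mu[keep]; cv2 <- cv2[keep]
  for (th in c(0, sort(unique(mu)))) {
    above <- cv2[mu > th]
    if (length(above) == 0) return(NA_real_)
    if (mean(above > cv2_cut) <= max_frac) return(th)
  }
  NA_real_
}

# brute-force TF network construction by explicit loops
brute_force_network <- function(corr, r_min = 0.35, min_partners = 3) {
  n <- nrow(corr)
  tfs <- rownames(corr)
  partners <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && !is.na(corr[i, j]) && corr[i, j] > r_min)
        partners[i] <- partners[i] + 1L
    }
  }
  retained <- which(partners >= min_partners)
  edges <- data.frame(tf_a = character(0), tf_b = character(0), r = numeric(0))
  for (i in retained) {
    for (j in retained) {
      if (i < j && !is.na(corr[i, j]) && corr[i, j] > r_min)
        edges <- rbind(edges, data.frame(tf_a = min(tfs[i], tfs[j]),
                                         tf_b = max(tfs[i], tfs[j]),
                                         r = corr[i, j]))
    }
  }
  edges <- edges[order(edges$tf_a, edges$tf_b), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(tfs[retained]), edges = edges,
       degree = stats::setNames(partners[retained], tfs[retained]))
}

# random symmetric correlation-like table with weights from a fixed set
random_weight_table <- function(n, weights, seed) {
  set.seed(seed)
  m <- matrix(0, n, n, dimnames = list(paste0("TF", seq_len(n)),
                                       paste0("TF", seq_len(n))))
  w <- sample(weights, n * (n - 1) / 2, replace = TRUE)
  m[upper.tri(m)] <- w
  m <- m + t(m)
  diag(m) <- 1
  m
}

# small default simulation reused across tests (cached per session)
cached_sim <- local({
  store <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(store[[key]])) {
      cfg <- sim_config(seed = seed)
      store[[key]] <- list(cfg = cfg, sim = simulate_fetal_liver(cfg))
    }
    store[[key]]
  }
})
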