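#' Default per-stage cell-type proportions
#'
#' Six cell types across developmental stages, with a stepwise decrease in
#' mesenchymal cells and a gradual rise of hepatoblasts and erythrocytes,
#' emulating the temporal composition of the developing fetal liver.
#'
#' @param stages character vector of stage labels (max 7 defaults provided).
#' @return matrix stages x 6 types, each row summing to 1.
#' @export
default_type_proportions <- function(stages = default_stages()) {
  types <- liver_cell_types()
  full <- rbind(
    c(0.30, 0.30, 0.10, 0.15, 0.10, 0.05),
    c(0.32, 0.25, 0.10, 0.18, 0.10, 0.05),
    c(0.34, 0.20, 0.10, 0.21, 0.10, 0.05),
    c(0.36, 0.16, 0.10, 0.23, 0.10, 0.05),
    c(0.38, 0.12, 0.10, 0.25, 0.10, 0.05),
    c(0.40, 0.08, 0.10, 0.27, 0.10, 0.05),
    c(0.42, 0.05, 0.10, 0.28, 0.10, 0.05)
  )
  rownames(full) <- default_stages()
  colnames(full) <- types
  if (!all(stages %in% rownames(full)))
    stop("no default proportions for stage(s): ",
         paste(setdiff(stages, rownames(full)), collapse = ", "))
  full[stages, , drop = FALSE]
}

#' The six fetal-liver cell types modelled by the generator
#' @return character vector of type names.
#' @export
liver_cell_types <- function() {
  c("hepatoblast", "mesenchymal", "endothelial",
    "erythrocyte", "macrophage", "megakaryocyte")
}

#' Default developmental stage labels
#' @return ordered character vector of stages.
#' @export
default_stages <- function() {
  c("E11.5", "E12.5", "E13.5", "E14.5", "E16.5", "E18.5", "P2.5")
}

#' Simulation configuration
#'
#' Parameters of the synthetic fetal-liver generator. The per-gene noise law
#' is CV^2 = a1/mu + a0 (gamma-distributed expression compounded with
#' logistic drop-out in mu), matching the technical-noise model fitted by the
#' analysis side of the package.
#'
#' @param n_genes number of biological genes (marker + trajectory + neutral).
#' @param n_spikeins number of spike-in control rows (default 92).
#' @param stages ordered developmental stage labels.
#' @param cells_per_stage cells simulated at each stage.
#' @param type_proportions stages x types matrix of simplex rows; default
#'   [default_type_proportions()].
#' @param noise_a0 dimensionless intercept of the CV^2 law (default 0.05).
#' @param noise_a1 FPKM-scaled slope of the CV^2 law (default 1, reflecting
#'   the low technical noise that spike-in QC shows for plate-based
#'   full-length scRNA-seq).
#' @param dropout_midpoint FPKM value at which drop-out probability is 0.5;
#'   0 disables drop-out (default 0.25).
#' @param n_trajectory_genes genes with monotone stage trends in hepatoblasts,
#'   split evenly between up and down (default 30, matching the top-30
#'   track-gene convention).
#' @param trajectory_effect log2-fold change per stage step (default 1).
#' @param n_marker_genes_per_type type-specific marker genes per cell type
#'   (default 10); canonical panel genes are named first.
#' @param outlier_fraction fraction of cells degraded into low-quality
#'   outliers by [inject_outliers()] (default 0).
#' @param macrophage_subpops if TRUE, macrophages carry two transcriptional
#'   sub-states that cluster apart but share the macrophage marker panel,
#'   exercising the marker-based cluster merge (default TRUE).
#' @param seed master integer seed; all randomness derives from it.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_spikeins = 92,
                       stages = default_stages(),
                       cells_per_stage = 60,
                       type_proportions = default_type_proportions(stages),
                       noise_a0 = 0.05,
                       noise_a1 = 1,
                       dropout_midpoint = 0.25,
                       n_trajectory_genes = 30,
                       trajectory_effect = 1,
                       n_marker_genes_per_type = 10,
                       outlier_fraction = 0,
                       macrophage_subpops = TRUE,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_spikeins = n_spikeins, stages = stages,
              cells_per_stage = cells_per_stage,
              type_proportions = type_proportions,
              noise_a0 = noise_a0, noise_a1 = noise_a1,
              dropout_midpoint = dropout_midpoint,
              n_trajectory_genes = n_trajectory_genes,
              trajectory_effect = trajectory_effect,
              n_marker_genes_per_type = n_marker_genes_per_type,
              outlier_fraction = outlier_fraction,
              macrophage_subpops = macrophage_subpops,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_spikeins > 0, cfg$cells_per_stage > 0)
  if (cfg$noise_a0 < 0 || cfg$noise_a1 < 0)
    stop("noise constants must be non-negative")
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  tp <- cfg$type_proportions
  if (!is.matrix(tp) || nrow(tp) != length(cfg$stages) ||
      ncol(tp) != length(liver_cell_types()))
    stop("type_proportions must be a stages x 6-types matrix")
  sums <- rowSums(tp)
  if (any(abs(sums - 1) > 1e-9))
    stop("type_proportions rows must each sum to 1 (non-simplex row: ",
         paste(rownames(tp)[abs(sums - 1) > 1e-9], collapse = ", "), ")")
  if (any(tp < 0)) stop("type_proportions must be non-negative")
  n_marker <- length(liver_cell_types()) * cfg$n_marker_genes_per_type
  n_special <- n_marker + cfg$n_trajectory_genes + length(cholangiocyte_marker_genes())
  if (n_special > cfg$n_genes)
    stop("n_genes too small for the requested marker/trajectory gene roles")
  invisible(cfg)
}

# canonical marker genes used to seed the named panels; the generator gives
# these genes the expression pattern their panel implies so that marker-based
# annotation works out of the box
panel_seed_genes <- function() {
  list(
    hepatoblast  = c("Afp", "Alb", "Hnf4a", "Krt18", "Krt8", "Gpc3", "Dlk1"),
    mesenchymal  = c("Vim", "Col1a2", "Mest", "Mmp2", "Pdgfra", "Ncam1", "Lhx2"),
    endothelial  = c("Lyve1", "Kdr"),
    erythrocyte  = c("Hba-a1", "Hbb-bt"),
    macrophage   = c("Ptprc", "Cd68", "Cd52"),
    megakaryocyte = c("Itga2b", "Itgb3")
  )
}

# cholangiocyte-specific genes: silent in the fetal-liver types, activated by
# simulate_cholangiocytes()
cholangiocyte_marker_genes <- function() {
  c("Sox9", "Spp1", "Krt7", "Krt19", "Epcam")
}

# build the per-gene role table for a configuration
gene_roles <- function(cfg) {
  types <- liver_cell_types()
  seeds <- panel_seed_genes()
  ids <- character(0); role <- character(0); type <- character(0)
  dir <- character(0)
  for (t in types) {
    base <- seeds[[t]]
    n <- cfg$n_marker_genes_per_type
    g <- if (length(base) >= n) base[seq_len(n)] else
      c(base, sprintf("Mk.%s.%d", t, seq_len(n - length(base))))
    ids <- c(ids, g)
    role <- c(role, rep("marker", length(g)))
    type <- c(type, rep(t, length(g)))
    dir <- c(dir, rep("none", length(g)))
  }
  chol <- cholangiocyte_marker_genes()
  ids <- c(ids, chol)
  role <- c(role, rep("cholangiocyte_marker", length(chol)))
  type <- c(type, rep("cholangiocyte", length(chol)))
  dir <- c(dir, rep("none", length(chol)))
  n_up <- ceiling(cfg$n_trajectory_genes / 2)
  n_dn <- cfg$n_trajectory_genes - n_up
  if (n_up > 0) {
    ids <- c(ids, sprintf("Traj.up.%d", seq_len(n_up)))
    role <- c(role, rep("trajectory", n_up))
    type <- c(type, rep(NA_character_, n_up))
    dir <- c(dir, rep("up", n_up))
  }
  if (n_dn > 0) {
    ids <- c(ids, sprintf("Traj.down.%d", seq_len(n_dn)))
    role <- c(role, rep("trajectory", n_dn))
    type <- c(type, rep(NA_character_, n_dn))
    dir <- c(dir, rep("down", n_dn))
  }
  n_neutral <- cfg$n_genes - length(ids)
  if (n_neutral > 0) {
    ids <- c(ids, sprintf("Gene%04d", seq_len(n_neutral)))
    role <- c(role, rep("neutral", n_neutral))
    type <- c(type, rep(NA_character_, n_neutral))
    dir <- c(dir, rep("none", n_neutral))
  }
  data.frame(gene_id = ids, role = role, marker_type = type,
             trend = dir, stringsAsFactors = FALSE)
}

# drop-out probability: logistic decrease with mean expression, probability
# 0.5 at the midpoint; midpoint 0 disables drop-out
dropout_prob <- function(mu, midpoint) {
  if (midpoint <= 0) return(rep(0, length(mu)))
  midpoint / (midpoint + mu)
}

# draw realized FPKM for a vector of per-observation means under the
# CV^2 = a1/mu + a0 gamma law, then apply drop-out
draw_noisy <- function(mu, a0, a1, dropout_midpoint) {
  out <- numeric(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    m <- mu[pos]
    cv2 <- if (a0 == 0 && a1 == 0) rep(0, length(m)) else a1 / m + a0
    vals <- ifelse(cv2 == 0, m,
                   stats::rgamma(length(m), shape = 1 / cv2, scale = m * cv2))
    if (dropout_midpoint > 0) {
      keep <- stats::runif(length(m)) >= dropout_prob(m, dropout_midpoint)
      vals <- vals * keep
    }
    out[pos] <- vals
  }
  out
}

# per-gene per-type mean FPKM matrix for one stage (genes x types);
# trajectory genes vary with the stage index in hepatoblasts only
stage_mean_matrix <- function(roles, neutral_mu, cfg, stage_idx,
                              traj_base = NULL, traj_slope = NULL) {
  types <- liver_cell_types()
  mu <- matrix(rep(neutral_mu, length(types)), ncol = length(types),
               dimnames = list(roles$gene_id, types))
  # marker on-level: liver markers (Afp, Alb, Hba-a1 ...) sit at the top of
  # the FPKM distribution in their own type
  on_fpkm <- 200; off_fpkm <- 0.05
  is_marker <- roles$role == "marker"
  mu[is_marker, ] <- off_fpkm
  # erythrocyte genes leak at low levels into every cell type, which is why
  # the typing stage exposes an exclusion switch for them
  mu[is_marker & roles$marker_type == "erythrocyte", ] <- 3
  for (t in types) {
    sel <- is_marker & roles$marker_type == t
    mu[sel, t] <- on_fpkm
  }
  mu[roles$role == "cholangiocyte_marker", ] <- 0.05
  traj <- roles$role == "trajectory"
  if (any(traj)) {
    # log2 means: base + slope * (stage - 1), slope signed by trend; each
    # gene has its own baseline and slope so stage profiles are not affine
    # images of one another
    lvl <- traj_base[roles$gene_id[traj]] +
      traj_slope[roles$gene_id[traj]] * (stage_idx - 1)
    mu[traj, ] <- 2^(traj_base[roles$gene_id[traj]])  # stage-1 level elsewhere
    mu[traj, "hepatoblast"] <- 2^lvl
  }
  mu
}

# fixed per-gene baseline means and spike-in profile for a config
generator_profiles <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 11L))
  roles <- gene_roles(cfg)
  neutral_mu <- stats::rlnorm(nrow(roles), meanlog = log(10), sdlog = 1.2)
  # a housekeeping component: ~5% of neutral genes sit at very high FPKM
  # with low CV^2, like ribosomal/mitochondrial transcripts; they anchor the
  # upper tail of the mean distribution the noise regression is fitted on
  hk <- stats::runif(nrow(roles)) < 0.05
  neutral_mu[hk] <- stats::rlnorm(sum(hk), meanlog = log(800), sdlog = 0.5)
  spike_mu <- stats::rlnorm(cfg$n_spikeins, meanlog = log(30), sdlog = 1.5)
  names(spike_mu) <- sprintf("ERCC-%05d", seq_len(cfg$n_spikeins))
  # per-trajectory-gene baseline (log2) and signed slope (log2 per stage
  # step); slopes are at least the configured effect so every configured
  # step is monotone by at least trajectory_effect
  n_stage <- length(cfg$stages)
  traj <- roles$role == "trajectory"
  traj_base <- traj_slope <- stats::setNames(rep(NA_real_, sum(traj)),
                                             roles$gene_id[traj])
  if (any(traj)) {
    up <- roles$trend[traj] == "up"
    lo <- stats::runif(sum(traj), 0.5, 2.5)
    slope <- cfg$trajectory_effect * stats::runif(sum(traj), 1, 1.1)
    traj_base[up] <- lo[up]
    traj_slope[up] <- slope[up]
    traj_base[!up] <- lo[!up] + slope[!up] * (n_stage - 1)
    traj_slope[!up] <- -slope[!up]
  }
  # macrophage sub-state program: a subset of neutral genes doubles as a
  # sub-population signature
  mid <- roles$role == "neutral" & neutral_mu >= 2 & neutral_mu <= 20
  n_sub <- min(40L, sum(mid))
  sub_genes <- roles$gene_id[mid][seq_len(n_sub)]
  list(roles = roles, neutral_mu = neutral_mu, spike_mu = spike_mu,
       traj_base = traj_base, traj_slope = traj_slope,
       macrophage_sub_genes = sub_genes)
}

#' Simulate a fetal-liver single-cell expression matrix
#'
#' Generates a genes x cells FPKM matrix across developmental stages with six
#' cell types in configured per-stage proportions, type-specific marker genes,
#' hepatoblast trajectory genes with monotone stage trends, spike-in control
#' rows carrying technical noise only, and per-gene noise following
#' CV^2 = a1/mu + a0 with logistic drop-out. The same configuration (including
#' seed) reproduces the output exactly.
#'
#' @param config a [sim_config()] object.
#' @return list with `matrix` ([ExpressionMatrix]), `annotation` (data.frame:
#'   cell_id, stage, batch, sorted_population, true_type, outlier), and
#'   `truth` (list with per-gene roles, generating noise constants and the
#'   per-stage type proportions used).
#' @export
simulate_fetal_liver <- function(config) {
  cfg <- validate_sim_config(config)
  prof <- generator_profiles(cfg)
  roles <- prof$roles
  types <- liver_cell_types()
  n_stage <- length(cfg$stages)

  set.seed(derive_seed(cfg$seed, 23L))
  cell_type <- character(0); cell_stage <- character(0)
  for (s in seq_len(n_stage)) {
    draw <- sample(types, cfg$cells_per_stage, replace = TRUE,
                   prob = cfg$type_proportions[s, ])
    cell_type <- c(cell_type, draw)
    cell_stage <- c(cell_stage, rep(cfg$stages[s], cfg$cells_per_stage))
  }
  n_cells <- length(cell_type)
  cell_id <- sprintf("cell_%03d_%s", seq_len(n_cells), cell_stage)

  # macrophage sub-state assignment (two halves)
  sub_state <- rep(NA_character_, n_cells)
  if (cfg$macrophage_subpops) {
    mac <- which(cell_type == "macrophage")
    if (length(mac) > 1) {
      half <- sample(mac, floor(length(mac) / 2))
      sub_state[mac] <- "macA"
      sub_state[half] <- "macB"
    }
  }

  vals <- matrix(0, nrow = nrow(roles), ncol = n_cells,
                 dimnames = list(roles$gene_id, cell_id))
  for (s in seq_len(n_stage)) {
    mu_st <- stage_mean_matrix(roles, prof$neutral_mu, cfg, s,
                               prof$traj_base, prof$traj_slope)
    idx <- which(cell_stage == cfg$stages[s])
    for (j in idx) {
      mu_cell <- mu_st[, cell_type[j]]
      if (identical(sub_state[j], "macB"))
        mu_cell[prof$macrophage_sub_genes] <- mu_cell[prof$macrophage_sub_genes] * 20
      vals[, j] <- draw_noisy(mu_cell, cfg$noise_a0, cfg$noise_a1,
                              cfg$dropout_midpoint)
    }
  }

  spikes <- matrix(0, nrow = cfg$n_spikeins, ncol = n_cells,
                   dimnames = list(names(prof$spike_mu), cell_id))
  for (j in seq_len(n_cells)) {
    spikes[, j] <- draw_noisy(prof$spike_mu, cfg$noise_a0, cfg$noise_a1, 0)
  }

  mat <- ExpressionMatrix(rbind(vals, spikes))
  ann <- data.frame(cell_id = cell_id, stage = cell_stage, batch = "B1",
                    sorted_population = NA_character_, true_type = cell_type,
                    outlier = FALSE, stringsAsFactors = FALSE)
  truth <- list(genes = roles, noise_a0 = cfg$noise_a0, noise_a1 = cfg$noise_a1,
                type_proportions = cfg$type_proportions,
                spike_mu = prof$spike_mu, neutral_mu = prof$neutral_mu,
                macrophage_sub_genes = prof$macrophage_sub_genes,
                config = cfg)
  if (cfg$outlier_fraction > 0) {
    inj <- inject_outliers(mat, cfg$outlier_fraction,
                           seed = derive_seed(cfg$seed, 37L))
    mat <- inj$matrix
    ann$outlier <- ann$cell_id %in% inj$outlier_cells
  }
  list(matrix = mat, annotation = ann, truth = truth)
}

#' Simulate an Epcam-positive cholangiocyte population
#'
#' Cholangiocyte cells are drawn around the earliest-stage hepatoblast
#' expression profile of the paired fetal-liver simulation: trajectory genes
#' keep their earliest-stage means, cholangiocyte markers (Sox9-, Spp1-,
#' Krt7/19-, Epcam-like roles) are activated, hepatoblast-specific markers
#' (Dlk1-, Hnf4a-like roles) are silenced, and a stronger global drop-out
#' reduces the number of detected genes per cell relative to hepatoblasts.
#'
#' @param config the [sim_config()] used for the base simulation.
#' @param n_cells number of sorted cells to generate.
#' @param base result of [simulate_fetal_liver()] on `config`; the base
#'   simulation must exist first because it supplies the earliest-stage
#'   hepatoblast centroid.
#' @param dropout_midpoint FPKM at which a transcript has a 50% chance of
#'   escaping detection in a cholangiocyte cell (default 5, much higher than
#'   the fetal-liver default of 0.25): low-expression genes drop out first,
#'   which lowers per-cell detected-gene counts while preserving the
#'   cross-cell agreement of highly expressed genes.
#' @return list with `matrix`, `annotation` and `truth` as in
#'   [simulate_fetal_liver()].
#' @export
simulate_cholangiocytes <- function(config, n_cells, base = NULL,
                                    dropout_midpoint = 5) {
  cfg <- validate_sim_config(config)
  if (is.null(base))
    stop("cholangiocytes are derived from a fetal-liver simulation; ",
         "run simulate_fetal_liver(config) first and pass it as `base`")
  prof <- generator_profiles(cfg)
  roles <- prof$roles
  mu <- stage_mean_matrix(roles, prof$neutral_mu, cfg, 1L,
                          prof$traj_base, prof$traj_slope)[, "hepatoblast"]
  mu[roles$role == "cholangiocyte_marker"] <- 300
  hb_panel <- panel_seed_genes()$hepatoblast
  mu[roles$gene_id %in% hb_panel] <- 0.05

  set.seed(derive_seed(cfg$seed, 53L))
  cell_id <- if (n_cells > 0) sprintf("chol_%03d_P3.25", seq_len(n_cells)) else character(0)
  vals <- matrix(0, nrow = nrow(roles), ncol = n_cells,
                 dimnames = list(roles$gene_id, cell_id))
  spikes <- matrix(0, nrow = cfg$n_spikeins, ncol = n_cells,
                   dimnames = list(names(prof$spike_mu), cell_id))
  for (j in seq_len(n_cells)) {
    vals[, j] <- draw_noisy(mu, cfg$noise_a0, cfg$noise_a1,
                            max(dropout_midpoint, cfg$dropout_midpoint))
    spikes[, j] <- draw_noisy(prof$spike_mu, cfg$noise_a0, cfg$noise_a1, 0)
  }
  mat <- ExpressionMatrix(rbind(vals, spikes))
  ann <- data.frame(cell_id = cell_id,
                    stage = rep("P3.25", n_cells),
                    batch = rep("B2", n_cells),
                    sorted_population = rep("Epcam+", n_cells),
                    true_type = rep("cholangiocyte", n_cells),
                    outlier = rep(FALSE, n_cells), stringsAsFactors = FALSE)
  truth <- list(genes = roles, noise_a0 = cfg$noise_a0, noise_a1 = cfg$noise_a1,
                centroid_stage = cfg$stages[1], config = cfg)
  list(matrix = mat, annotation = ann, truth = truth)
}

#' Degrade a fraction of cells into low-quality outliers
#'
#' Selected cells are globally down-scaled and hit with heavy extra drop-out
#' so that their detected-gene counts fall far below the rest, emulating the
#' failed libraries removed by single-cell outlier filtering.
#'
#' @param matrix an [ExpressionMatrix].
#' @param fraction proportion of cells to degrade, in \[0, 1).
#' @param seed integer seed.
#' @param scale global multiplier applied to outlier cells (default 0.05).
#' @param extra_dropout probability that a non-zero entry of an outlier cell
#'   is zeroed (default 0.9).
#' @return list with `matrix` (modified copy) and `outlier_cells`
#'   (character vector of degraded cell ids).
#' @export
inject_outliers <- function(matrix, fraction, seed = 1L,
                            scale = 0.05, extra_dropout = 0.9) {
  x <- as_expression_matrix(matrix)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- ncol(x$values)
  k <- round(fraction * n)
  if (k == 0) return(list(matrix = x, outlier_cells = character(0)))
  set.seed(as.integer(seed))
  pick <- sample(colnames(x$values), k)
  v <- x$values
  for (cid in pick) {
    col <- v[, cid] * scale
    col[stats::runif(length(col)) < extra_dropout] <- 0
    v[, cid] <- col
  }
  list(matrix = ExpressionMatrix(v, spikein = x$spikein), outlier_cells = pick)
}

#' Build a sorted-population QC fixture with known outlier structure
#'
#' Constructs a cholangiocyte-like matrix of `n_typical` well-behaved cells,
#' `n_outliers` cells with drastically reduced library complexity (caught by
#' detected-gene filtering), and `n_atypical` cells whose expression profile
#' is unrelated to the population median (caught by the profile-correlation
#' stage) while keeping a normal library size. Used to exercise
#' [two_stage_population_qc()].
#'
#' @param config a [sim_config()].
#' @param n_typical,n_outliers,n_atypical cell counts per category.
#' @return list with `matrix` and `annotation` (including a `category`
#'   column: typical / outlier / atypical).
#' @export
make_sorted_population_fixture <- function(config, n_typical = 35,
                                           n_outliers = 10, n_atypical = 7) {
  cfg <- validate_sim_config(config)
  base <- simulate_fetal_liver(cfg)
  n_tot <- n_typical + n_outliers + n_atypical
  chol <- simulate_cholangiocytes(cfg, n_tot, base = base)
  v <- chol$matrix$values
  spike <- chol$matrix$spikein
  category <- rep("typical", n_tot)
  set.seed(derive_seed(cfg$seed, 71L))
  if (n_outliers > 0) {
    idx_out <- n_typical + seq_len(n_outliers)
    category[idx_out] <- "outlier"
    for (j in idx_out) {
      col <- v[, j] * 0.05
      col[stats::runif(length(col)) < 0.9] <- 0
      v[, j] <- col
    }
  }
  if (n_atypical > 0) {
    idx_aty <- n_typical + n_outliers + seq_len(n_atypical)
    category[idx_aty] <- "atypical"
    gene_rows <- which(!spike)
    for (j in idx_aty) {
      # same library content, scrambled across genes: library size is
      # preserved but the profile no longer matches the population
      v[gene_rows, j] <- v[sample(gene_rows), j]
    }
  }
  ann <- chol$annotation
  ann$category <- category
  list(matrix = ExpressionMatrix(v, spikein = spike), annotation = ann)
}
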