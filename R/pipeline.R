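#' Read / write a flat key=value pipeline configuration
#'
#' Plain-text configuration: one `key=value` pair per line, `#` comments
#' allowed. Values are parsed as numbers when possible, otherwise as strings;
#' comma-separated values become vectors.
#'
#' @param path config file path.
#' @return named list of parameters.
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param config named list to write.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, "=", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate the bundled demo dataset
#'
#' Writes a desk-scale synthetic fetal-liver dataset: ~2000 genes plus 92
#' spike-ins across 5 embryonic stages (~80 cells per stage), a paired
#' 52-cell sorted (Epcam-positive-like) population with built-in QC outliers,
#' ground-truth tables, a marker-panel config, a TF list, a membrane-receptor
#' list, a GMT annotation and a ready-to-run pipeline config.
#'
#' @param dir output directory (created if needed).
#' @param seed master integer seed.
#' @return named list of written file paths, invisibly.
#' @export
make_demo <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_genes = 2000, cells_per_stage = 80,
                    stages = default_stages()[1:5], seed = as.integer(seed))
  sim <- simulate_fetal_liver(cfg)
  sorted <- make_sorted_population_fixture(cfg)
  paths <- list(
    matrix = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "cells.tsv"),
    truth = file.path(dir, "gene_truth.tsv"),
    sorted_matrix = file.path(dir, "sorted_expression.tsv"),
    sorted_annotation = file.path(dir, "sorted_cells.tsv"),
    panels = file.path(dir, "marker_panels.txt"),
    tf_list = file.path(dir, "tf_list.txt"),
    membrane = file.path(dir, "membrane_receptors.txt"),
    gmt = file.path(dir, "annotation.gmt"),
    config = file.path(dir, "pipeline.config"))
  write_matrix(sim$matrix, paths$matrix, "tsv")
  utils::write.table(sim$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(sorted$matrix, paths$sorted_matrix, "tsv")
  utils::write.table(sorted$annotation, paths$sorted_annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mp <- default_marker_panels()
  panel_lines <- c(vapply(names(mp$panels), function(p)
    paste0(p, ": ", paste(mp$panels[[p]], collapse = ", ")), character(1)),
    paste0("exclude: ", paste(mp$exclude, collapse = ", ")))
  writeLines(panel_lines, paths$panels)
  # demo TF list: hepatoblast/cholangiocyte-relevant regulators present in
  # the simulated gene space plus a spread of neutral genes
  roles <- sim$truth$genes
  tf_demo <- c("Hnf4a", "Sox9",
               roles$gene_id[roles$role == "trajectory"][1:10],
               roles$gene_id[roles$role == "neutral"][1:20])
  writeLines(tf_demo, paths$tf_list)
  membrane <- c("Dlk1", "Epcam", "Kdr", "Lyve1",
                roles$gene_id[roles$role == "marker"][1:10])
  writeLines(unique(membrane), paths$membrane)
  gmt_lines <- c(
    paste(c("liver_function", "synthetic",
            mp$panels$hepatoblast), collapse = "\t"),
    paste(c("vasculature", "synthetic", mp$panels$endothelial), collapse = "\t"),
    paste(c("housekeeping", "synthetic",
            roles$gene_id[roles$role == "neutral"][1:30]), collapse = "\t"))
  writeLines(gmt_lines, paths$gmt)
  pipe_cfg <- list(matrix = paths$matrix, annotation = paths$annotation,
                   sorted_matrix = paths$sorted_matrix, panels = paths$panels,
                   tf_list = paths$tf_list, membrane = paths$membrane,
                   gmt = paths$gmt, seed = as.integer(seed),
                   fpkm_threshold = 1, mad_k = 3, spikein_corr_min = 0.5,
                   cv2_cut = 0.3, max_frac = 0.05, z = 1.96,
                   k_pca = 400, n_second_pass = 6, min_cells = 3, top_k = 30,
                   tf_r_min = 0.35, tf_min_partners = 3, tf_alpha = 0.01,
                   marker_cutoff = 0.5)
  write_pipeline_config(pipe_cfg, paths$config)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — QC, noise filtering, cell typing,
#' hepatoblast trajectory, TF covariance network, marker assessment — on the
#' files referenced by a pipeline config, writing each stage's outputs and a
#' plain-text run report under `out_dir`. All randomness derives from the
#' configured seed, so identical config and seed reproduce identical outputs.
#'
#' @param config named list from [read_pipeline_config()] or a path to a
#'   config file.
#' @param out_dir output directory.
#' @param stages character vector of stage names to run (default all):
#'   "qc", "noise", "typing", "trajectory", "network", "markers".
#' @return run report (named list per stage), invisibly. On stage failure the
#'   report records the failing stage; outputs of earlier stages remain.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("qc", "noise", "typing", "trajectory",
                                    "network", "markers")) {
  if (is.character(config) && length(config) == 1)
    config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  report <- list(seed = seed, stages = list())
  log_path <- file.path(out_dir, "run_report.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% stages) {
      logf("[%s] skipped", name)
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch({
      out <- fun()
      logf("[%s] ok: %s", name, out$summary)
      report$stages[[name]] <<- c(list(status = "ok"), out)
    }, error = function(e) {
      logf("[%s] FAILED: %s", name, conditionMessage(e))
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    invisible(res)
  }

  mat <- read_matrix(config$matrix, "tsv")
  ann <- utils::read.delim(config$annotation, stringsAsFactors = FALSE)
  panels <- read_marker_panels(config$panels)

  run_stage("qc", function() {
    qc <- identify_outlier_cells(mat,
                                 fpkm_threshold = config$fpkm_threshold %||% 1,
                                 mad_k = config$mad_k %||% 3,
                                 spikein_corr_min = config$spikein_corr_min %||% 0.5)
    write_qc_report(qc, file.path(out_dir, "qc_cells.tsv"))
    keep <- qc$cells$cell_id[!qc$cells$outlier]
    state$mat <- ExpressionMatrix(mat$values[, keep, drop = FALSE],
                                  spikein = mat$spikein)
    state$ann <- ann[ann$cell_id %in% keep, ]
    if (!is.null(config$sorted_matrix)) {
      smat <- read_matrix(config$sorted_matrix, "tsv")
      sqc <- two_stage_population_qc(smat)
      write_qc_report(sqc, file.path(out_dir, "qc_sorted_cells.tsv"))
      skeep <- sqc$cells$cell_id[!sqc$cells$outlier]
      state$sorted <- ExpressionMatrix(smat$values[, skeep, drop = FALSE],
                                       spikein = smat$spikein)
    }
    list(summary = sprintf("%d/%d cells retained (%.1f%%)",
                           qc$n_retained, qc$n_in, qc$retention_pct),
         n_in = qc$n_in, n_retained = qc$n_retained,
         retention_pct = qc$retention_pct)
  })

  run_stage("noise", function() {
    if (is.null(state$mat)) stop("QC stage output required; run 'qc' first")
    nf <- noise_filter_pipeline(state$mat,
                                cv2_cut = config$cv2_cut %||% 0.3,
                                max_frac = config$max_frac %||% 0.05,
                                z = config$z %||% 1.96)
    utils::write.table(nf$result, file.path(out_dir, "gene_filter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    retained <- nf$result$gene_id[nf$result$retained]
    v <- state$mat$values
    # configured marker panels are exempt from the variability filter:
    # cluster annotation needs them even when their expression looks
    # noise-like at the whole-population level
    panel_genes <- unlist(panels$panels, use.names = FALSE)
    keep_rows <- rownames(v) %in% c(retained, panel_genes) | state$mat$spikein
    state$filtered <- ExpressionMatrix(v[keep_rows, , drop = FALSE],
                                       spikein = state$mat$spikein[keep_rows])
    state$noise_model <- nf$model
    list(summary = sprintf("a0=%.4g a1=%.4g mu_th=%.4g; %d/%d genes retained",
                           nf$model$a0, nf$model$a1, nf$model$mu_th,
                           length(retained), nrow(nf$result)),
         a0 = nf$model$a0, a1 = nf$model$a1, mu_th = nf$model$mu_th,
         n_retained_genes = length(retained))
  })

  run_stage("typing", function() {
    if (is.null(state$filtered)) stop("noise stage output required; run 'noise' first")
    dec <- two_pass_decomposition(state$filtered, panels = panels$panels,
                                  exclude = panels$exclude,
                                  k_pca = config$k_pca %||% 400,
                                  n_second_pass = config$n_second_pass %||% 6)
    labs <- data.frame(cell_id = names(dec$cell_labels),
                       label = unname(dec$cell_labels))
    utils::write.table(labs, file.path(out_dir, "cell_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_vec <- stats::setNames(state$ann$stage, state$ann$cell_id)
    props <- cell_type_proportions(dec$cell_labels,
                                   stages_vec[names(dec$cell_labels)])
    utils::write.table(props, file.path(out_dir, "type_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    disp <- anova_rank_display_genes(state$filtered, dec$cell_labels,
                                     k = config$k_pca %||% 400)
    emb <- embed_tsne(state$filtered, disp, seed = seed)
    utils::write.table(emb, file.path(out_dir, "tsne.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(config$gmt)) {
      ann_sets <- read_gmt(config$gmt)
      hb <- intersect(panels$panels$hepatoblast,
                      rownames(state$filtered$values))
      if (length(hb) > 0) {
        ora <- go_overrepresentation(hb, rownames(gene_values(state$filtered)),
                                     ann_sets)
        utils::write.table(ora, file.path(out_dir, "go_hepatoblast.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    state$labels <- dec$cell_labels
    list(summary = sprintf("%d groups", length(unique(dec$cell_labels))),
         n_groups = length(unique(dec$cell_labels)))
  })

  run_stage("trajectory", function() {
    if (is.null(state$labels)) stop("typing stage output required; run 'typing' first")
    hb_cells <- names(state$labels)[state$labels == "hepatoblast"]
    hb <- ExpressionMatrix(state$filtered$values[, hb_cells, drop = FALSE],
                           spikein = state$filtered$spikein)
    stages_vec <- stats::setNames(state$ann$stage, state$ann$cell_id)
    series <- stage_anova(hb, stages_vec[hb_cells],
                          min_cells = config$min_cells %||% 3,
                          top_k = config$top_k %||% 30)
    utils::write.table(series$table, file.path(out_dir, "trajectory_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    track <- build_track(hb, series, stages_vec[hb_cells], seed = seed)
    utils::write.table(track$embedding, file.path(out_dir, "track_tsne.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$series <- series
    state$hb <- hb
    state$hb_stages <- stages_vec[hb_cells]
    if (!is.null(state$sorted)) {
      nsa <- nearest_stage_assignment(state$sorted, hb, series,
                                      stages_vec[hb_cells])
      utils::write.table(nsa$assignments,
                         file.path(out_dir, "sorted_stage_assignment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      state$nsa <- nsa
    }
    list(summary = sprintf("top %d genes; modal sorted-cell stage: %s",
                           length(series$top_genes),
                           state$nsa$modal_stage %||% "n/a"),
         modal_sorted_stage = state$nsa$modal_stage %||% NA_character_)
  })

  run_stage("network", function() {
    if (is.null(state$series)) stop("trajectory stage output required; run 'trajectory' first")
    if (is.null(state$sorted)) stop("sorted population required for the network stage")
    tfs <- readLines(config$tf_list)
    # the TF list is its own gene filter; the screen runs on the QC'd matrix
    hb_cells <- colnames(state$hb$values)
    combined <- cbind(state$mat$values[, hb_cells, drop = FALSE],
                      state$sorted$values[rownames(state$mat$values), , drop = FALSE])
    comb <- ExpressionMatrix(combined, spikein = state$mat$spikein)
    de <- screen_de_tfs(comb, hb_cells,
                        colnames(state$sorted$values),
                        intersect(tfs, rownames(comb$values)),
                        alpha = config$tf_alpha %||% 0.01)
    utils::write.table(de, file.path(out_dir, "de_tfs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    de_tfs <- de$tf[de$retained]
    n_edges <- 0L; n_nodes <- 0L
    if (length(de_tfs) >= 2) {
        corr <- tf_correlation_matrix(comb, de_tfs, cells = hb_cells)
      net <- build_covariance_network(corr,
                                      r_min = config$tf_r_min %||% 0.35,
                                      min_partners = config$tf_min_partners %||% 3,
                                      group = "hepatoblast")
      export_network(net, file.path(out_dir, "tf_network_hepatoblast.tsv"),
                     layout_seed = seed)
      n_edges <- nrow(net$edges); n_nodes <- nrow(net$nodes)
    }
    list(summary = sprintf("%d DE TFs; network %d nodes / %d edges",
                           length(de_tfs), n_nodes, n_edges),
         n_de_tfs = length(de_tfs), n_nodes = n_nodes, n_edges = n_edges)
  })

  run_stage("markers", function() {
    if (is.null(state$labels)) stop("typing stage output required; run 'typing' first")
    membrane <- readLines(config$membrane)
    stages_vec <- stats::setNames(state$ann$stage, state$ann$cell_id)
    genes <- intersect(membrane, rownames(state$mat$values))
    perf <- assess_markers(state$mat, state$labels,
                           stages_vec[names(state$labels)], genes,
                           target_type = "hepatoblast",
                           threshold = config$fpkm_threshold %||% 1)
    utils::write.table(perf, file.path(out_dir, "marker_performance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pred <- predict_markers(perf, membrane,
                            cutoff = config$marker_cutoff %||% 0.5)
    utils::write.table(pred, file.path(out_dir, "marker_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(summary = sprintf("%d candidate marker(s)", nrow(pred)),
         n_candidates = nrow(pred))
  })

  logf("pipeline complete")
  invisible(report)
}
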