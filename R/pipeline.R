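#' Pipeline configuration
#'
#' Collects the thresholds and sizes used across the pipeline, with the
#' screen's conventional defaults: DSSA q cutoff 0.05, category enrichment
#' p cutoff 0.01, Holm cutoff 0.05, pathway coverage threshold 0.6 and
#' network score cutoff 700. Any entry can be overridden via `...` or
#' loaded from a YAML file with `config_file`.
#'
#' @param ... overrides of the default entries.
#' @param config_file optional YAML file whose keys override the defaults
#'   (explicit `...` arguments win over the file).
#' @return a named list of class `poolscreen_config`.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  cfg <- list(
    stages = c("simulate", "normalize", "dssa", "dosemodel", "enrichment",
               "network", "growth"),
    seed = 1L,
    out_dir = tempfile("poolscreen_run_"),
    ## generator sizes (kept modest so a full run is interactive)
    n_strains = 500L, n_controls = 12L, n_reps_per_dose = 3L,
    dose_levels = c("25", "50", "100"), generations = c(5, 15),
    n_planted = 25L, planted_defect = 0.4,
    tag_offset = 0.5, chip_sd = 0.2, noise_sd = 0.3,
    ## analysis thresholds
    dssa_alpha = 0.05, enrich_p_cutoff = 0.01, holm_alpha = 0.05,
    coverage_min = 0.6, score_cutoff = 700,
    span = 0.4, norm_tol = 0.01, norm_max_iter = 10L,
    n_perm = 9999L, n_draws = 9999L,
    n_pathways = 8L, network_nodes = 300L, module_size = 12L)
  if (!is.null(config_file)) {
    y <- yaml::read_yaml(config_file)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$dssa_alpha > 0, cfg$dssa_alpha < 1,
            cfg$coverage_min >= 0, cfg$coverage_min <= 1,
            cfg$score_cutoff >= 0, cfg$score_cutoff <= 1000)
  structure(cfg, class = "poolscreen_config")
}

#' Run the pooled-screen analysis pipeline on synthetic data
#'
#' Executes the toggled stages in order -- simulate, normalize, dssa,
#' dosemodel, enrichment, network, growth -- writing each stage's table
#' under `out_dir` and recording a manifest (seeds, file hashes, row
#' counts). Identical configurations and seeds give identical manifests.
#' Disabling a stage that a later stage needs raises an error naming the
#' missing stage.
#'
#' @param config a [pipeline_config()].
#' @return list with per-stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "poolscreen_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- function(stage) stage %in% config$stages
  need <- function(stage, from) {
    if (!on(from))
      stop("stage '", stage, "' needs output of disabled stage '", from, "'")
  }
  res <- list()
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(
      complete = TRUE, rows = rows,
      md5 = as.list(tools::md5sum(files)))
  }

  if (on("simulate")) {
    des <- pool_design(n_strains = config$n_strains,
                       n_controls = config$n_controls,
                       n_reps_per_dose = config$n_reps_per_dose,
                       dose_levels = config$dose_levels,
                       generations = config$generations,
                       tag_offset = config$tag_offset,
                       chip_sd = config$chip_sd, noise_sd = config$noise_sd,
                       seed = config$seed)
    strains <- sprintf("S%04d", seq_len(config$n_strains))
    planted <- planted_truth(strains[seq_len(config$n_planted)],
                             config$planted_defect / 5, des)
    res$pool <- generate_pool(des, planted)
    f1 <- file.path(config$out_dir, "intensity.tsv")
    f2 <- file.path(config$out_dir, "design.tsv")
    f3 <- file.path(config$out_dir, "truth.tsv")
    write_intensity_tsv(res$pool$intensity, f1)
    write_design_tsv(res$pool$design_table, f2)
    utils::write.table(res$pool$truth, f3, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    note("simulate", c(f1, f2, f3), nrow(res$pool$intensity))
  }

  if (on("normalize")) {
    need("normalize", "simulate")
    norm <- fastlo_normalize(res$pool$intensity, span = config$span,
                             max_iter = config$norm_max_iter,
                             tol = config$norm_tol)
    res$normalized <- norm
    res$strain_values <- regroup_tags(structure(norm$matrix,
                                                strain = attr(res$pool$intensity, "strain"),
                                                tag = attr(res$pool$intensity, "tag")))
    f <- file.path(config$out_dir, "normalized.tsv")
    write_intensity_tsv(norm$matrix, f)
    note("normalize", f, nrow(norm$matrix))
  }

  if (on("dssa")) {
    need("dssa", "normalize")
    res$dssa <- dssa(res$strain_values, res$pool$design_table,
                     alpha = config$dssa_alpha)
    cons <- consensus_filter(res$dssa)
    res$consensus <- cons
    f <- file.path(config$out_dir, "dssa.tsv")
    utils::write.table(res$dssa, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
    note("dssa", f, nrow(res$dssa))
  }

  if (on("dosemodel")) {
    need("dosemodel", "normalize")
    dtab <- res$pool$design_table
    fits <- lapply(unique(dtab$generation), function(g) {
      chips <- dtab$chip[dtab$generation == g]
      sub <- res$normalized$matrix[, chips, drop = FALSE]
      tag <- attr(res$pool$intensity, "tag")
      up <- sub[tag == "UP", , drop = FALSE]
      down <- sub[tag == "DOWN", , drop = FALSE]
      rownames(up) <- rownames(down) <-
        attr(res$pool$intensity, "strain")[tag == "UP"]
      fit <- lrt_dose_matrix(up, down, dtab$dose_group[dtab$generation == g])
      fit$p_holm <- holm_correct(fit$p_raw)
      fit$selected <- fit$p_holm < config$holm_alpha
      fit$generation <- g
      fit
    })
    res$dosemodel <- do.call(rbind, fits)
    f <- file.path(config$out_dir, "dosemodel.tsv")
    utils::write.table(res$dosemodel, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
    note("dosemodel", f, nrow(res$dosemodel))
  }

  if (on("enrichment")) {
    need("enrichment", "normalize")
    dtab <- res$pool$design_table
    g0 <- dtab$generation[1L]
    chips <- dtab$chip[dtab$generation == g0]
    vals <- res$strain_values[, chips, drop = FALSE]
    stats_h <- kw_statistic(vals, dtab$dose_group[dtab$generation == g0])
    names(stats_h) <- rownames(vals)
    pw <- generate_pathways(n_pathways = config$n_pathways,
                            n_genes = config$n_strains,
                            seed = config$seed + 1L)
    ## map pathway gene ids onto measured strain ids
    map <- stats::setNames(rownames(vals)[seq_along(pw$universe)], pw$universe)
    pw$pathways <- lapply(pw$pathways, function(p) {
      p$nodes <- unname(map[p$nodes])
      if (!is.null(p$edges) && nrow(p$edges))
        p$edges <- matrix(map[p$edges], ncol = 2L)
      p
    })
    kept <- coverage_filter(pw$pathways, names(stats_h), config$coverage_min)
    enr <- do.call(rbind, lapply(kept, function(p)
      cbind(pathway = p$id,
            sepea_test(p, stats_h, n_perm = config$n_perm,
                       seed = config$seed + 2L))))
    res$enrichment <- enr
    f <- file.path(config$out_dir, "enrichment.tsv")
    utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
    note("enrichment", f, nrow(enr))
  }

  if (on("network")) {
    need("network", "dosemodel")
    net_data <- generate_network(n_nodes = config$network_nodes,
                                 planted_module_size = config$module_size,
                                 seed = config$seed + 3L)
    net <- load_network(net_data$edges, cutoff = config$score_cutoff)
    sel <- res$dosemodel$gene[res$dosemodel$selected &
                                res$dosemodel$generation ==
                                  res$dosemodel$generation[1L]]
    ## selected strains map onto network node ids by index
    nodes <- igraph::V(net)$name
    sel_nodes <- nodes[match(sel, sprintf("S%04d", seq_along(nodes)))]
    sel_nodes <- sel_nodes[!is.na(sel_nodes)]
    clusters <- detect_clusters(net, sel_nodes)
    sig <- lapply(clusters, function(cl)
      cluster_significance(net, cl, sel_nodes, n_draws = config$n_draws,
                           seed = config$seed + 4L))
    res$network <- list(net = net, clusters = clusters, significance = sig)
    f <- file.path(config$out_dir, "clusters.tsv")
    ctab <- if (length(clusters))
      data.frame(cluster = vapply(clusters, `[[`, "", "id"),
                 n_members = vapply(clusters, function(cl) length(cl$members), 0L),
                 n_significant = vapply(clusters, `[[`, 0L, "n_significant"),
                 p_value = vapply(sig, `[[`, 0, "p_value"))
    else data.frame(cluster = character(), n_members = integer(),
                    n_significant = integer(), p_value = numeric())
    utils::write.table(ctab, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    note("network", f, nrow(ctab))
  }

  if (on("growth")) {
    wells <- expand.grid(rep = 1:3, dose = c(0, 1, 2, 4),
                         KEEP.OUT.ATTRS = FALSE)
    wells$well <- sprintf("W%02d", seq_len(nrow(wells)))
    curves <- generate_growth_curves(wells, dose_effect = 0.08,
                                     seed = config$seed + 5L)
    res$growth <- dose_response(curves)
    f <- file.path(config$out_dir, "growth_response.tsv")
    utils::write.table(res$growth$response, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    note("growth", f, nrow(res$growth$response))
  }

  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  res$manifest <- manifest
  res
}
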