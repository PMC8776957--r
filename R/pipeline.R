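# End-to-end pipeline: simulate -> diversity -> partition -> cluster ->
# ordinate -> permanova -> indval -> structure -> carbon -> compare,
# with a reproducibility manifest.

#' Run the full survey analysis pipeline
#'
#' Generates (or loads) a survey and chains every analysis stage,
#' writing one CSV per result table plus a Newick dendrogram and a JSON
#' run manifest with input/output digests. All stochastic stages consume
#' sub-seeds derived from the single run seed, so a repeated run is
#' byte-identical.
#'
#' @param config a [survey_config()].
#' @param seed integer run seed (defaults to the config's seed).
#' @param out_dir output directory.
#' @param n_perm permutations for PERMANOVA and IndVal.
#' @param nmds_starts random starts for the ordination.
#' @param carbon_params a [carbon_parameters()]; `NULL` (with
#'   `stages` including `"carbon"`) uses a root:shoot ratio of 0.25.
#' @param registry an [allometry_registry()].
#' @param stages character subset of
#'   `c("diversity", "cluster", "ordinate", "permanova", "indval",
#'   "structure", "carbon", "compare")`; omitted stages are skipped and
#'   their outputs absent from the manifest.
#' @return List of class `survey_run`: all stage results plus `manifest`
#'   (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = survey_config(), seed = config$seed,
                         out_dir, n_perm = 999, nmds_starts = 20,
                         carbon_params = NULL,
                         registry = default_allometry(),
                         stages = c("diversity", "cluster", "ordinate",
                                    "permanova", "indval", "structure",
                                    "carbon", "compare")) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  results <- list()
  outputs <- character(0)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    write_csv_plain(df, path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(name, code) {
    stage <<- name
    tryCatch(code, error = function(e) {
      stopf("pipeline stage '%s' failed: %s (outputs so far: %s)",
            name, conditionMessage(e),
            paste(basename(outputs), collapse = ", "))
    })
  }

  dataset <- run_stage("simulate", generate_survey(config, seed))
  survey_paths <- write_survey(dataset, file.path(out_dir, "survey"))
  outputs <- c(outputs, survey_paths)
  results$dataset <- dataset

  plot_cover <- aggregate_to_plots(dataset$cover, dataset$design)
  groups <- dataset$design[!duplicated(dataset$design$plot_id),
                           c("plot_id", "forest_type", "island")]

  if ("diversity" %in% stages) {
    run_stage("diversity", {
      pd <- plot_diversity(dataset$cover, dataset$design)
      emit(pd, "diversity.csv")
      part <- additive_partition(plot_cover,
                                 default_hierarchy(plot_cover,
                                                   dataset$design))
      emit(data.frame(
        component = c(names(part$alpha)[1], names(part$beta), "gamma"),
        value = c(part$alpha[1], part$beta, part$gamma),
        percent = c(part$percent, 100),
        stringsAsFactors = FALSE
      ), "partition.csv")
      results$diversity <- pd
      results$partition <- part
    })
  }
  if ("cluster" %in% stages) {
    run_stage("cluster", {
      sel <- select_clustering(plot_cover)
      ck <- choose_k(sel$tree, sel$dist,
                     k_max = min(10, length(sel$tree$labels) - 1))
      emit(sel$scores, "clustering_scores.csv")
      emit(ck$diagnostics, "cluster_diagnostics.csv")
      nwk <- file.path(out_dir, "dendrogram.nwk")
      writeLines(as_newick(sel$tree), nwk)
      outputs <- c(outputs, nwk)
      dpath <- file.path(out_dir, "distance.csv")
      write_distance_csv(sel$dist, dpath)
      outputs <- c(outputs, dpath)
      results$clustering <- sel
      results$k <- ck
    })
  }
  if ("ordinate" %in% stages) {
    run_stage("ordinate", {
      dmat <- results$clustering$dist %||% hellinger_distance(plot_cover)
      ord <- nmds(dmat, n_starts = nmds_starts, seed = seed)
      emit(data.frame(plot_id = rownames(ord$points), ord$points,
                      stringsAsFactors = FALSE), "ordination.csv")
      results$ordination <- ord
    })
  }
  if ("permanova" %in% stages) {
    run_stage("permanova", {
      dmat <- results$clustering$dist %||% hellinger_distance(plot_cover)
      # single-level factors (e.g. a one-island survey) carry no variance
      fac <- groups[, c("forest_type", "island"), drop = FALSE]
      fac <- fac[, vapply(fac, function(f) length(unique(f)) > 1,
                          logical(1)), drop = FALSE]
      if (ncol(fac) == 0) {
        data_error("permanova stage needs a factor with >= 2 levels")
      }
      pt <- permanova(dmat, fac, n_perm = n_perm, seed = seed)
      emit(as.data.frame(pt), "permanova.csv")
      results$permanova <- pt
    })
  }
  if ("indval" %in% stages) {
    run_stage("indval", {
      iv <- suppressWarnings(
        indval(plot_cover, groups$forest_type, n_perm = n_perm,
               seed = seed))
      emit(as.data.frame(iv), "indval.csv")
      results$indval <- iv
    })
  }
  if ("structure" %in% stages) {
    run_stage("structure", {
      st <- survey_structure(dataset)
      emit(st, "structure.csv")
      results$structure <- st
    })
  }
  if ("carbon" %in% stages) {
    run_stage("carbon", {
      params <- carbon_params %||% carbon_parameters(root_shoot_ratio = 0.25)
      cr <- carbon_report(dataset, registry, params)
      emit(cr$plots, "carbon_plots.csv")
      emit(cr$cells, "carbon_cells.csv")
      results$carbon <- cr
    })
  }
  if ("compare" %in% stages) {
    run_stage("compare", {
      pd <- results$diversity %||% plot_diversity(dataset$cover,
                                                  dataset$design)
      comp <- lapply(c(alpha = "alpha", gamma = "gamma",
                       shannon = "shannon", evenness = "evenness"),
                     function(metric) {
                       compare_groups(pd[[metric]], pd$forest_type,
                                      pd$island)
                     })
      tabs <- do.call(rbind, lapply(names(comp), function(m) {
        cells <- comp[[m]]$cells
        cells$metric <- m
        cells
      }))
      emit(tabs, "diversity_comparison.csv")
      results$comparisons <- comp
    })
  }

  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config),
                            c("dbh_lognormal_params", "height_params",
                              "litter_params", "soil_params"))],
    stages = stages,
    n_perm = n_perm,
    package_version = as.character(utils::packageVersion("forestplots")),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))),
    finished = format(t0, tz = "UTC")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  class(results) <- "survey_run"
  results
}
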