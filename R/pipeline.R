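#' Run the full c-fos functional connectivity pipeline
#'
#' Orchestrates ingest (or synthetic generation) -> regional ANOVA screen ->
#' per-group correlation matrices -> functional networks with graph measures
#' and Markov clustering -> degree-preserving null ensembles and threshold
#' sweep -> hub identification and robustness ranking, writing every stage's
#' output plus a manifest with parameters, seeds and file hashes. Reruns
#' with the same config and seed reproduce identical outputs.
#'
#' @param config A named list, or path to a YAML/JSON file. Exactly one
#'   input source must be given: \code{input$wide_csv} (analysis-ready wide
#'   table), \code{input$raw_csv} (+ optional \code{input$metadata_csv}), or
#'   \code{synthetic} (arguments for \code{\link{cohort_spec}}). Optional
#'   keys: \code{alpha}, \code{threshold_p}, \code{sweep_grid},
#'   \code{n_null}, \code{n_random}, \code{swaps_per_edge},
#'   \code{inflation_grid}, \code{prune_grid}, \code{top_fraction},
#'   \code{run_sweep}.
#' @param seed Master seed (overrides \code{config$seed}).
#' @param out_dir Output directory (overrides \code{config$out_dir}).
#' @return The manifest, invisibly (also written as \code{manifest.json}).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  config <- load_pipeline_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% stop_fosnet(
    "config must give an output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  alpha <- config$alpha %||% 0.05
  threshold_p <- config$threshold_p %||% 0.05
  sweep_grid <- config$sweep_grid %||% seq(0.005, 0.1, by = 0.005)
  n_null <- config$n_null %||% 1000
  n_random <- config$n_random %||% 100
  swaps_per_edge <- config$swaps_per_edge %||% 10
  inflation_grid <- config$inflation_grid %||% seq(1.1, 3.0, by = 0.1)
  prune_grid <- config$prune_grid %||% seq(0.005, 0.045, by = 0.005)
  top_fraction <- config$top_fraction %||% 0.2
  run_sweep <- config$run_sweep %||% TRUE

  files <- character(0)
  log_stage <- function(stage, ...) {
    message(sprintf("[fosnet:%s] %s", stage, paste0(...)))
  }
  emit <- function(path) {
    files <<- c(files, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_fosnet("pipeline stage '", stage, "' failed: ",
                  conditionMessage(e))
    })
  }

  # --- ingest / simulate ---------------------------------------------------
  sources <- c(wide = !is.null(config$input$wide_csv),
               raw = !is.null(config$input$raw_csv),
               synthetic = !is.null(config$synthetic))
  if (sum(sources) != 1) {
    stop_fosnet("config must specify exactly one input source ",
                "(input$wide_csv, input$raw_csv, or synthetic)")
  }
  exclusion_report <- NULL
  table <- run_stage("ingest", {
    if (sources["wide"]) {
      log_stage("ingest", "reading wide table ", config$input$wide_csv)
      read_count_table(config$input$wide_csv)
    } else if (sources["raw"]) {
      log_stage("ingest", "aggregating raw records ", config$input$raw_csv)
      metadata <- if (!is.null(config$input$metadata_csv))
        read_region_metadata(config$input$metadata_csv) else NULL
      agg <- aggregate_counts(read_count_records(config$input$raw_csv),
                              metadata)
      matched <- filter_matched(agg)
      exclusion_report <<- matched$report
      matched$table
    } else {
      log_stage("ingest", "generating synthetic cohort")
      spec_args <- config$synthetic
      if (isTRUE(spec_args)) spec_args <- list()
      spec_args$seed <- seed
      spec <- do.call(cohort_spec, spec_args)
      generate_cohort(spec)
    }
  })
  write_count_table(table, emit(file.path(out_dir, "counts_wide.csv")))
  if (!is.null(exclusion_report)) {
    jsonlite::write_json(exclusion_report,
                         emit(file.path(out_dir, "exclusion_report.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- regional screen -----------------------------------------------------
  log_stage("screen", "two-way ANOVA over ", ncol(table$values), " regions")
  screen <- run_stage("screen", screen_all_regions(table, alpha = alpha))
  utils::write.csv(screen$anova,
                   emit(file.path(out_dir, "anova_screen.csv")),
                   row.names = FALSE)
  utils::write.csv(screen$contrasts,
                   emit(file.path(out_dir, "planned_contrasts.csv")),
                   row.names = FALSE)

  # --- per-group network stages -------------------------------------------
  groups <- group_levels()
  group_seeds <- seed + 1000L * seq_along(groups)
  summaries <- list()
  sweeps <- list()
  hub_sets <- list()
  rankings <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    g_seed <- group_seeds[i]
    log_stage("connect", g, ": correlation matrix")
    corr <- run_stage("connect", correlation_matrix(table, g))
    write_correlation_matrix(
      corr,
      emit(file.path(out_dir, sprintf("corr_r_%s.csv", g))),
      emit(file.path(out_dir, sprintf("corr_p_%s.csv", g))))

    log_stage("network", g, ": threshold p < ", threshold_p)
    net <- run_stage("network", threshold_network(corr, threshold_p))
    utils::write.csv(as.data.frame(net$adjacency),
                     emit(file.path(out_dir, sprintf("adjacency_%s.csv", g))))
    write_network_graphml(
      net, emit(file.path(out_dir, sprintf("network_%s.graphml", g))))

    summaries[[g]] <- run_stage("network",
      graph_summary(net, n_random = n_random, seed = g_seed))
    if (n_edges(net) > 0) {
      mcl <- run_stage("network", select_inflation(net, inflation_grid))
      write_clusters(mcl$assignment,
                     emit(file.path(out_dir, sprintf("clusters_%s.csv", g))))
    }

    if (isTRUE(run_sweep)) {
      log_stage("null", g, ": threshold sweep, ", n_null,
                " nulls/threshold")
      sweeps[[g]] <- run_stage("null",
        threshold_sweep(corr, sweep_grid, n_null = n_null,
                        seed = g_seed + 100L, n_random = n_random,
                        swaps_per_edge = swaps_per_edge))
    }

    log_stage("hubs", g, ": hub identification and robustness")
    hub_sets[[g]] <- run_stage("hubs",
      identify_hubs(centrality_table(net), top_fraction))
    utils::write.csv(centrality_table(net),
                     emit(file.path(out_dir, sprintf("centrality_%s.csv", g))),
                     row.names = FALSE)
    rankings[[g]] <- run_stage("hubs", suppressWarnings(
      hub_robustness(corr, base_p = threshold_p, prune_grid = prune_grid,
                     top_fraction = top_fraction)))
    utils::write.csv(rankings[[g]]$ranking,
                     emit(file.path(out_dir,
                                    sprintf("hub_robustness_%s.csv", g))),
                     row.names = FALSE)
  }
  summary_tab <- do.call(rbind, summaries)
  utils::write.csv(summary_tab,
                   emit(file.path(out_dir, "graph_summaries.csv")),
                   row.names = FALSE)
  if (length(sweeps)) {
    utils::write.csv(do.call(rbind, sweeps),
                     emit(file.path(out_dir, "threshold_sweep.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(compare_hub_sets(hub_sets),
                   emit(file.path(out_dir, "hub_overlap.csv")),
                   row.names = FALSE)
  hub_tab <- data.frame(
    group = rep(names(hub_sets),
                vapply(hub_sets, function(h) length(h$hubs), integer(1))),
    region = unlist(lapply(hub_sets, function(h) h$hubs), use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(hub_tab, emit(file.path(out_dir, "hubs.csv")),
                   row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "fosnet",
    package_version = as.character(utils::packageVersion("fosnet")),
    r_version = as.character(getRversion()),
    seed = seed,
    group_seeds = stats::setNames(as.list(group_seeds), groups),
    parameters = list(alpha = alpha, threshold_p = threshold_p,
                      sweep_grid = sweep_grid, n_null = n_null,
                      n_random = n_random, swaps_per_edge = swaps_per_edge,
                      inflation_grid = inflation_grid,
                      prune_grid = prune_grid,
                      top_fraction = top_fraction),
    summary = screen$summary,
    top_robust_hubs = lapply(rankings, top_robust_hubs),
    files = stats::setNames(
      as.list(unname(tools::md5sum(files))), basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.json$", config)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      config <- yaml::read_yaml(config)
    }
  }
  assert_that(is.list(config), "config must be a list or a YAML/JSON path")
  config
}
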