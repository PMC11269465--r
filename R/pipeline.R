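#' Default pipeline configuration
#'
#' Returns the fully defaulted configuration list that [run_pipeline()]
#' echoes into its manifest. User configs (YAML or JSON) are merged over
#' these defaults; unknown keys or unknown option values are rejected
#' before any computation.
#'
#' @return nested configuration list.
#' @export
pipeline_defaults <- function() {
  list(
    output_dir = "trajbinde_run",
    seed = 1,
    stages = c("simulate", "bin", "fit", "evaluate"),
    simulate = list(preset = "base"),
    input = list(matrix = NULL, metadata = NULL, truth = NULL,
                 pseudotime_column = "pseudotime", path_column = "path",
                 transpose = FALSE),
    binning = list(strategy = "sturges", drop_factor = 1, split_bin = TRUE,
                   prune_bin = FALSE, drop_tails = FALSE,
                   max_iterations = 10),
    fit = list(degree = 3, alpha_screen = 0.05, p_adjust = "BH",
               alpha_step = 0.05, rsq_threshold = 0.6,
               family = "negative_binomial", use_offset = TRUE,
               workers = 1),
    cluster = list(n_clusters = NULL)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown configuration key '", paste0(path, k), "'",
           call. = FALSE)
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

.validate_pipeline_config <- function(cfg) {
  known_stages <- c("simulate", "bin", "fit", "evaluate", "cluster")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  strategies <- c("sturges", "rice", "doane", "freedman_diaconis", "scott",
                  "sqrt")
  if (!cfg$binning$strategy %in% strategies)
    stop("unknown binning strategy '", cfg$binning$strategy, "'")
  if (cfg$binning$drop_factor < 0.3)
    stop("drop_factor must be >= 0.3")
  if (!cfg$fit$family %in% c("negative_binomial", "poisson", "gaussian"))
    stop("unknown family '", cfg$fit$family, "'")
  if (!"simulate" %in% cfg$stages &&
      (is.null(cfg$input$matrix) || is.null(cfg$input$metadata)))
    stop("without a simulate stage, input$matrix and input$metadata are ",
         "required")
  invisible(cfg)
}

.stage_outputs <- function(paths) {
  lapply(paths, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order — simulate (or load), bin, fit,
#' evaluate, cluster — writing each stage's outputs as plain-text files
#' under `output_dir` together with a JSON manifest (full configuration
#' echo, per-stage output checksums, gene/cell/bin counts and wall time).
#' Rerunning with an identical configuration and seed reproduces identical
#' result tables. A stage failure writes the partial manifest and then
#' signals the error.
#'
#' @param config path to a YAML or JSON configuration file, or an
#'   equivalent nested list; see [pipeline_defaults()] for keys.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  # the simulate block accepts either a preset name or sim_config() fields
  sim_user <- config$simulate
  config$simulate <- NULL
  cfg <- .merge_config(pipeline_defaults(), config)
  if (!is.null(sim_user)) {
    allowed <- c("preset", names(formals(sim_config)))
    bad <- setdiff(names(sim_user), allowed)
    if (length(bad) > 0)
      stop("unknown configuration key 'simulate.", bad[1], "'")
    cfg$simulate <- sim_user
  }
  cfg$stages <- unlist(cfg$stages)
  .validate_pipeline_config(cfg)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "trajbinDE",
                   version = as.character(packageVersion("trajbinDE")),
                   seed = cfg$seed, config = cfg, stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    rec$status <- "complete"
    rec$elapsed_sec <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[name]] <<- rec
    write_manifest()
  }

  state <- new.env(parent = emptyenv())
  out <- function(f) file.path(cfg$output_dir, f)

  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() {
      sc <- cfg$simulate
      sim <- if (!is.null(sc$preset)) {
        simulate_bifurcation(scenario_presets(sc$preset, seed = cfg$seed))
      } else {
        sc$preset <- NULL
        sc$seed <- cfg$seed
        simulate_bifurcation(do.call(sim_config, sc))
      }
      state$ce <- sim$experiment
      state$truth <- sim$truth
      m <- assay(state$ce, "counts")
      writeMM(m, out("counts.mtx"))
      data.table::fwrite(data.frame(x = rownames(state$ce)),
                         out("genes.tsv"), col.names = FALSE)
      data.table::fwrite(data.frame(x = colnames(state$ce)),
                         out("barcodes.tsv"), col.names = FALSE)
      cd <- as.data.frame(colData(state$ce))
      cd <- cbind(cell_id = rownames(cd), cd)
      data.table::fwrite(cd, out("cell_metadata.tsv"), sep = "\t")
      data.table::fwrite(sim$truth, out("truth.tsv"), sep = "\t")
      message("simulate: ", nrow(state$ce), " genes x ", ncol(state$ce),
              " cells, sparsity ", round(100 * sparsity(state$ce), 1), "%")
      list(n_genes = nrow(state$ce), n_cells = ncol(state$ce),
           sparsity = sparsity(state$ce),
           outputs = .stage_outputs(list(out("counts.mtx"),
                                         out("cell_metadata.tsv"),
                                         out("truth.tsv"))))
    })
  } else {
    state$ce <- load_cell_experiment(cfg$input$matrix, cfg$input$metadata,
                                     cfg$input$pseudotime_column,
                                     cfg$input$path_column,
                                     transpose = isTRUE(cfg$input$transpose))
    if (!is.null(cfg$input$truth))
      state$truth <- as.data.frame(data.table::fread(cfg$input$truth))
  }

  if ("bin" %in% cfg$stages) {
    run_stage("bin", function() {
      b <- cfg$binning
      bm <- bin_pseudotime(state$ce, strategy = b$strategy,
                           drop_factor = b$drop_factor,
                           split_bin = isTRUE(b$split_bin),
                           prune_bin = isTRUE(b$prune_bin),
                           drop_tails = isTRUE(b$drop_tails),
                           max_iterations = b$max_iterations)
      state$binned <- aggregate_bins(state$ce, bm)
      cd <- as.data.frame(colData(state$binned))
      cd <- cbind(bin = rownames(cd), cd)
      data.table::fwrite(cd, out("bin_metadata.tsv"), sep = "\t")
      pb <- as.data.frame(assay(state$binned, "pseudobulk"))
      pb <- cbind(gene = rownames(state$binned), pb)
      data.table::fwrite(pb, out("pseudobulk.tsv"), sep = "\t")
      message("bin: ", ncol(state$binned), " bins (",
              bm$n_dropped, " cells dropped)")
      list(n_bins = ncol(state$binned), cells_dropped = bm$n_dropped,
           outputs = .stage_outputs(list(out("bin_metadata.tsv"),
                                         out("pseudobulk.tsv"))))
    })
  }

  if ("fit" %in% cfg$stages) {
    run_stage("fit", function() {
      f <- cfg$fit
      wc <- workflow_config(degree = f$degree, alpha_screen = f$alpha_screen,
                            p_adjust = f$p_adjust, alpha_step = f$alpha_step,
                            rsq_threshold = f$rsq_threshold,
                            family = f$family,
                            use_offset = isTRUE(f$use_offset),
                            workers = f$workers, seed = cfg$seed)
      state$results <- run_trajectory_de(state$binned, wc)
      state$wc <- wc
      write_results(state$results, out("results.tsv"))
      sel <- get_siggenes(state$results, f$rsq_threshold)
      message("fit: ", sum(state$results$screened), "/",
              nrow(state$results), " genes screened, ",
              length(sel$selected), " selected (",
              length(sel$branch_dependent), " branch-dependent, ",
              length(sel$time_only), " time-only)")
      list(n_genes = nrow(state$results),
           n_screened = sum(state$results$screened),
           n_selected = length(sel$selected),
           outputs = .stage_outputs(list(out("results.tsv"))))
    })
  }

  if ("evaluate" %in% cfg$stages && !is.null(state$truth)) {
    run_stage("evaluate", function() {
      truth <- state$truth$de[match(state$results$gene, state$truth$gene)]
      cm <- confusion_metrics(
        classify_genes(state$results, cfg$fit$alpha_screen,
                       cfg$fit$rsq_threshold), truth)
      roc <- roc_over_rsq(state$results, truth, cfg$fit$alpha_screen)
      data.table::fwrite(cm, out("metrics.tsv"), sep = "\t")
      data.table::fwrite(roc, out("roc.tsv"), sep = "\t")
      message(sprintf("evaluate: TPR %.3f FPR %.3f at R^2 >= %.2f",
                      cm$TPR, cm$FPR, cfg$fit$rsq_threshold))
      list(TPR = cm$TPR, FPR = cm$FPR,
           outputs = .stage_outputs(list(out("metrics.tsv"),
                                         out("roc.tsv"))))
    })
  }

  if ("cluster" %in% cfg$stages && !is.null(cfg$cluster$n_clusters)) {
    run_stage("cluster", function() {
      cl <- cluster_trends(state$results, state$binned,
                           cfg$cluster$n_clusters,
                           rsq_threshold = cfg$fit$rsq_threshold)
      data.table::fwrite(data.frame(gene = names(cl$labels),
                                    cluster = unname(cl$labels)),
                         out("cluster_labels.tsv"), sep = "\t")
      data.table::fwrite(cl$trends, out("cluster_trends.tsv"), sep = "\t")
      list(n_clusters = cfg$cluster$n_clusters,
           outputs = .stage_outputs(list(out("cluster_labels.tsv"),
                                         out("cluster_trends.tsv"))))
    })
  }

  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
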