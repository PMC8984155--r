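#' @importFrom yaml read_yaml
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
NULL

.defaultPipelineConfig <- function() {
  list(alpha = 0.05, fc_threshold = 0.25, n_perm = 1000,
       min_expr_fraction = 0.10, ppi_score_min = 0.7,
       risk_quantiles = c(1/3, 2/3), seed = 1L,
       scope = "significant_either", qc = FALSE,
       include_lr_edges = TRUE)
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list). Unset
#' keys take the package defaults: alpha 0.05, fc_threshold 0.25, n_perm
#' 1000, min_expr_fraction 0.10, ppi_score_min 0.7, risk_quantiles tertiles.
#' Either a \code{simulate} block (arguments to \code{synthConfig}) or an
#' \code{inputs} block (paths: matrix, barcodes, features, cells, lr_pairs,
#' and optionally ppi, survival, coefficients) must be present, plus
#' \code{outdir}; \code{state1}/\code{state2} select the dysregulation
#' contrast (defaults: last vs first state in \code{state_order}).
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- read_yaml(config)
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  .checkFraction(cfg$alpha, "alpha", open_left = TRUE, open_right = TRUE)
  if (cfg$fc_threshold <= 0) stop("config error: fc_threshold must be > 0")
  .checkFraction(cfg$min_expr_fraction, "min_expr_fraction")
  .checkFraction(cfg$ppi_score_min, "ppi_score_min")
  stopifnot(cfg$n_perm >= 1, length(cfg$risk_quantiles) == 2)
  if (is.null(cfg$outdir)) stop("config error: 'outdir' is required")
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config error: provide a 'simulate' block or an 'inputs' block")
  }
  cfg
}

.stageFiles <- function(outdir) {
  list(detect = c("cce_all.tsv", "cce_significant.tsv"),
       dysreg = "dysregulated_cces.tsv",
       enrich = c("enrichment_celltype.tsv", "enrichment_directed.tsv"),
       net = character(),
       risk = c("risk_assignments.tsv", "logrank.tsv", "km_coordinates.tsv"))
}

#' Run the full interaction-analysis pipeline
#'
#' Executes simulate (optional) -> detect -> dysreg -> enrich -> net -> risk
#' from a single configuration, writing every stage's tables under
#' \code{outdir} and a JSON manifest with the seed, per-stage row counts and
#' output-file checksums. One seed fans out to fixed per-stage child seeds,
#' so reruns with the same config are byte-identical and any stage can be
#' reproduced alone. A stage failure aborts the run with the stage named;
#' files already written by the failing stage are renamed with a
#' \code{.partial} suffix.
#'
#' @param config path to YAML config or named list (see
#'   \code{readPipelineConfig}).
#' @return manifest list, invisibly (also written to
#'   \code{outdir/manifest.json}).
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cceflow",
                   version = as.character(packageVersion("cceflow")),
                   seed = cfg$seed, stages = list())
  written <- character()
  run_stage <- function(name, files, fun) {
    paths <- file.path(outdir, files)
    res <- tryCatch(fun(), error = function(e) {
      for (p in paths[file.exists(paths)]) file.rename(p, paste0(p, ".partial"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    written <<- c(written, paths[file.exists(paths)])
    manifest$stages[[name]] <<- c(list(outputs = files), res)
    invisible(res)
  }

  # --- simulate / load ------------------------------------------------------
  env <- new.env()
  run_stage("simulate", character(), function() {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (!is.null(sim_args$planted_events)) {
        sim_args$planted_events <- as.data.frame(
          do.call(rbind, lapply(sim_args$planted_events, as.data.frame)))
      }
      if (!is.null(sim_args$risk_genes)) {
        sim_args$risk_genes <- as.data.frame(
          do.call(rbind, lapply(sim_args$risk_genes, as.data.frame)))
      }
      sim_args$seed <- .childSeed(cfg$seed, "simulate")
      ds <- do.call(synthConfig, sim_args)
      ds <- generateDataset(ds)
      writeDataset(ds, file.path(outdir, "data"))
      env$data_dir <- file.path(outdir, "data")
      list(simulated = TRUE, n_cells = ncol(ds$sce), n_genes = nrow(ds$sce))
    } else {
      env$inputs <- cfg$inputs
      list(simulated = FALSE)
    }
  })
  if (!is.null(env$data_dir)) {
    d <- env$data_dir
    inputs <- list(matrix = file.path(d, "matrix.mtx"),
                   barcodes = file.path(d, "barcodes.tsv"),
                   features = file.path(d, "features.tsv"),
                   cells = file.path(d, "cells.tsv"),
                   lr_pairs = file.path(d, "lr_pairs.tsv"),
                   ppi = file.path(d, "ppi_edges.tsv"),
                   survival = file.path(d, "survival.tsv"),
                   coefficients = file.path(d, "coefficients.tsv"))
  } else inputs <- env$inputs
  sce <- loadExpression(inputs$matrix, inputs$barcodes, inputs$features,
                        layer = if (isTRUE(cfg$normalized_input)) "normalized" else "counts")
  sce <- addCellMetadata(sce, inputs$cells, state_order = cfg$state_order)
  if (isTRUE(cfg$qc)) sce <- qcFilterCells(sce)
  if (!isTRUE(cfg$normalized_input)) sce <- logNormalize(sce)
  pairs <- markActivePairs(loadLRPairs(inputs$lr_pairs), sce)
  states <- if (is.factor(colData(sce)$state)) levels(droplevels(colData(sce)$state))
            else unique(as.character(colData(sce)$state))
  state1 <- if (!is.null(cfg$state1)) cfg$state1 else states[length(states)]
  state2 <- if (!is.null(cfg$state2)) cfg$state2 else states[1L]

  # --- detect ---------------------------------------------------------------
  run_stage("detect", .stageFiles(outdir)$detect, function() {
    res <- detectAll(sce, pairs, n_perm = cfg$n_perm, alpha = cfg$alpha,
                     min_expr_fraction = cfg$min_expr_fraction,
                     seed = .childSeed(cfg$seed, "detect"))
    env$cce <- res
    writeResultTable(cceTable(res), file.path(outdir, "cce_all.tsv"),
                     units = c(p_value = "probability",
                               interaction_score = "log1p normalized expression"))
    writeResultTable(significantCCEs(res), file.path(outdir, "cce_significant.tsv"))
    list(n_candidates = nrow(cceTable(res)),
         n_significant = nrow(significantCCEs(res)))
  })

  # --- dysreg ---------------------------------------------------------------
  run_stage("dysreg", .stageFiles(outdir)$dysreg, function() {
    dys <- dysregulatedCCEs(env$cce, state1 = state1, state2 = state2,
                            scope = cfg$scope, threshold = cfg$fc_threshold)
    env$dys <- dys
    writeResultTable(dys, file.path(outdir, "dysregulated_cces.tsv"))
    list(state1 = state1, state2 = state2, n_events = nrow(dys),
         n_dysregulated = sum(dys$dysregulated))
  })

  # --- enrich ---------------------------------------------------------------
  run_stage("enrich", .stageFiles(outdir)$enrich, function() {
    sig <- significantCCEs(env$cce)
    by_state <- split(sig, factor(sig$state, levels = states))
    by_state <- by_state[vapply(by_state, nrow, 1L) > 0]
    if (length(by_state) < 2) {
      # nothing to contrast (e.g. near-null data): write empty tables
      empty <- data.frame(focus = character(), state_a = character(),
                          state_b = character(), n_focus_a = integer(),
                          n_other_a = integer(), n_focus_b = integer(),
                          n_other_b = integer(), odds_ratio = numeric(),
                          log2_odds_ratio = numeric(), p_value = numeric(),
                          sig_05 = logical(), sig_10 = logical())
      writeResultTable(empty, file.path(outdir, "enrichment_celltype.tsv"))
      writeResultTable(empty, file.path(outdir, "enrichment_directed.tsv"))
      return(list(skipped = "fewer than two states with significant events"))
    }
    types <- sort(unique(c(sig$source_type, sig$target_type)))
    em_ct <- enrichmentMatrix(by_state, lapply(types, cellTypeFocus))
    directed <- expand.grid(source = types, target = types,
                            stringsAsFactors = FALSE)
    em_dir <- enrichmentMatrix(by_state,
                               mapply(directedPairFocus, directed$source,
                                      directed$target, SIMPLIFY = FALSE))
    writeResultTable(em_ct, file.path(outdir, "enrichment_celltype.tsv"))
    writeResultTable(em_dir, file.path(outdir, "enrichment_directed.tsv"))
    list(n_celltype_rows = nrow(em_ct), n_directed_rows = nrow(em_dir))
  })

  # --- net ------------------------------------------------------------------
  run_stage("net", character(), function() {
    if (is.null(inputs$ppi) || !file.exists(inputs$ppi)) {
      return(list(skipped = "no PPI table supplied"))
    }
    ppi <- loadPPIEdges(inputs$ppi)
    sig <- significantCCEs(env$cce)
    role_genes <- collectLRGenes(env$cce, pairs)
    n_nodes <- integer()
    for (st in unique(sig$state)) {
      net <- buildStateNetwork(role_genes, ppi, pairs, st,
                               score_min = cfg$ppi_score_min,
                               include_lr_edges = isTRUE(cfg$include_lr_edges),
                               state_pair_ids = unique(sig$pair_id[sig$state == st]))
      writeStateNetwork(net, file.path(outdir, "networks"))
      n_nodes[st] <- nrow(networkNodes(net))
    }
    writeResultTable(role_genes, file.path(outdir, "lr_genes.tsv"))
    written <<- c(written, file.path(outdir, "lr_genes.tsv"),
                  list.files(file.path(outdir, "networks"), full.names = TRUE))
    list(n_lr_genes = length(unique(role_genes$gene)),
         nodes_per_state = as.list(n_nodes))
  })

  # --- risk -----------------------------------------------------------------
  run_stage("risk", .stageFiles(outdir)$risk, function() {
    if (is.null(inputs$survival) || !file.exists(inputs$survival) ||
        is.null(inputs$coefficients) || !file.exists(inputs$coefficients)) {
      return(list(skipped = "no survival/coefficient inputs"))
    }
    surv <- loadSurvival(inputs$survival)
    model <- loadRiskCoefficients(inputs$coefficients)
    if (!length(riskCoefficients(model))) {
      return(list(skipped = "empty coefficient table"))
    }
    expr_tab <- if (!is.null(inputs$sample_expression) &&
                    file.exists(inputs$sample_expression)) {
      readResultTable(inputs$sample_expression)
    } else pseudoBulk(sce)
    scores <- riskScore(expr_tab, model)
    groups <- assignRiskGroups(scores, quantiles = cfg$risk_quantiles)
    lr <- logrankTest(groups, surv)
    out <- groups
    out$group <- as.character(out$group)
    writeResultTable(out, file.path(outdir, "risk_assignments.tsv"))
    writeResultTable(data.frame(chi_square = lr$chi_square, df = lr$df,
                                p_value = lr$p_value),
                     file.path(outdir, "logrank.tsv"))
    writeResultTable(kmCoordinates(groups, surv),
                     file.path(outdir, "km_coordinates.tsv"),
                     units = c(time = "months"))
    list(n_samples = nrow(groups), logrank_p = lr$p_value)
  })

  manifest$outputs <- lapply(sort(unique(written)), function(p) {
    list(file = sub(paste0("^", outdir, "/?"), "", p),
         md5 = unname(md5sum(p)))
  })
  write_json(manifest, file.path(outdir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
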