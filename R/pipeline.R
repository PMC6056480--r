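#' @include inference.R fixture.R synthetic.R
NULL

.readMatrixTSV <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (anyNA(m)) stop(sprintf("missing values in matrix file '%s'", path))
  m
}

.writeMatrixTSV <- function(m, path, idName = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- idName
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full discrete-modelling pipeline
#'
#' Executes, in order: (optional) log-CPM normalization, binarization with
#' the bimodality gate, topology-to-logic synthesis (undefined-sign edges
#' are set aside until integration), validation of the topology logic
#' against the binarized states, best-fit inference from the binarized
#' series, similarity-based candidate selection, integration of the
#' inferred interactions with the curated topology, synchronous simulation
#' of the integrated model, and the configured knockdown experiments. All
#' intermediate artifacts, a MANIFEST of completed stages, a run log and a
#' summary JSON are written to the output directory. Any stage failure
#' aborts with the stage name; artifacts of completed stages are retained.
#'
#' @param config a YAML file path or an equivalent nested list with entries
#'   \code{paths} (\code{edges}, \code{annotations}, \code{expression} or
#'   \code{counts}, optional \code{rules}, \code{outdir}),
#'   \code{binarization} (\code{seed}, \code{correct}), \code{inference}
#'   (\code{max_k}), \code{simulation} (\code{n_starts}, \code{seed}) and
#'   \code{knockdowns} (list of gene vectors).
#' @return invisibly, the summary list (also written as
#'   \code{summary.json})
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  paths <- config$paths
  if (is.null(paths$outdir)) stop("config must set paths$outdir")
  outdir <- paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(outdir, "MANIFEST")
  logFile <- file.path(outdir, "run.log")
  unlink(c(manifest, logFile))
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE, sep = "")
  }
  done <- function(stage) cat(stage, "\n", file = manifest, append = TRUE,
                              sep = "")
  stage <- function(name, fun) {
    note("stage %s: start", name)
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    note("stage %s: done", name)
    done(name)
    res
  }
  binCfg <- config$binarization
  infCfg <- config$inference
  simCfg <- config$simulation
  binSeed <- if (is.null(binCfg$seed)) 1L else as.integer(binCfg$seed)
  correct <- isTRUE(binCfg$correct)
  maxK <- if (is.null(infCfg$max_k)) 3L else as.integer(infCfg$max_k)
  nStarts <- if (is.null(simCfg$n_starts)) 100L else as.integer(simCfg$n_starts)
  simSeed <- if (is.null(simCfg$seed)) 1L else as.integer(simCfg$seed)

  network <- stage("load_network", function()
    readNetwork(paths$edges, paths$annotations))

  expr <- stage("normalize", function() {
    if (!is.null(paths$counts)) {
      note("normalizing raw counts (log-CPM, prior 0.5)")
      m <- logcpmNormalize(.readMatrixTSV(paths$counts))
      .writeMatrixTSV(m, file.path(outdir, "expression_logcpm.tsv"))
      m
    } else .readMatrixTSV(paths$expression)
  })

  binarized <- stage("binarize", function() {
    note("binarization seed %d", binSeed)
    b <- binarizeExpression(expr, seed = binSeed)
    .writeMatrixTSV(states(b), file.path(outdir, "binarized_states.tsv"))
    utils::write.table(
      data.frame(gene = names(thresholds(b)), rho = unname(thresholds(b)),
                 method = unname(b@method)),
      file.path(outdir, "binarization_thresholds.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    b
  })

  topoModel <- stage("logic", function() {
    if (!is.null(paths$rules)) return(readFunctions(paths$rules))
    it <- network@interactions
    und <- it$sign == "undefined"
    if (any(und))
      note("%d undefined-sign edge(s) set aside until integration", sum(und))
    defined <- signedNetwork(network@nodes, it[!und, , drop = FALSE])
    model <- synthesizeLogic(defined)
    writeModel(defined, model, file.path(outdir, "topology_model"))
    model
  })

  validation <- stage("validate", function() {
    v <- validateFunctions(topoModel, binarized, mode = "fixed_point")
    utils::write.table(
      data.frame(gene = names(v$verdicts), verdict = unname(v$verdicts)),
      file.path(outdir, "validation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    v
  })

  candidates <- stage("infer", function() {
    cs <- inferCandidateFunctions(states(binarized), maxK = maxK)
    writeCandidates(cs, file.path(outdir, "candidates.json"))
    cs
  })

  reconstructed <- stage("select", function()
    selectFunctions(candidates, topoModel))

  integrated <- stage("integrate", function() {
    inferredNet <- asSignedNetwork(reconstructed,
                                   categories = categories(network))
    net <- integrateNetworks(network, inferredNet)
    it <- net@interactions
    und <- it$sign == "undefined"
    if (any(und)) {
      note("%d edge(s) still undefined after integration (non-monotone or unresolved); set aside for logic synthesis", sum(und))
      defined <- signedNetwork(net@nodes, it[!und, , drop = FALSE])
    } else defined <- net
    model <- synthesizeLogic(defined)
    writeModel(net, model, file.path(outdir, "integrated_model"))
    list(network = net, model = model)
  })

  attractorSet <- stage("simulate", function() {
    note("simulation: %d random initial states, seed %d", nStarts, simSeed)
    as <- sampleAttractors(integrated$model, nStarts = nStarts, seed = simSeed)
    steady <- maxBasinAttractor(as)
    .writeMatrixTSV(steady@states, file.path(outdir, "steady_state.tsv"))
    as
  })

  knockdowns <- config$knockdowns
  perturbations <- stage("perturb", function() {
    res <- list()
    for (kd in knockdowns) {
      kd <- as.character(unlist(kd))
      note("knockdown {%s}: %d starts, seed %d",
           paste(kd, collapse = ","), nStarts, simSeed)
      pr <- perturbationExperiment(integrated$model, kd,
                                   nStarts = nStarts, seed = simSeed)
      writePerturbationReport(pr, file.path(
        outdir, paste0("knockdown_", paste(kd, collapse = "-"))))
      res[[paste(kd, collapse = "+")]] <- pr
    }
    res
  })

  summary <- list(
    schema_version = "1.0",
    n_genes = length(genes(network)),
    validation_fraction = validation$fraction_validated,
    attractors = lapply(attractors(attractorSet), function(a)
      list(cycle_length = ncol(a@states), basin = a@basin)),
    knockdowns = lapply(perturbations, function(pr) {
      tab <- table(factor(pr@change, levels = c("up-regulated",
        "down-regulated", "unchanged", "oscillating")))
      as.list(tab)
    }),
    seeds = list(binarization = binSeed, simulation = simSeed))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  done("summary")
  invisible(summary)
}
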