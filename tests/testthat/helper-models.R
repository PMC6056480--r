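# Shared builders and independent oracles for the test suite.

# small hand-built model: a self-sustaining target fed by a constant input
toyModel <- function() {
  booleanNetwork(list(
    booleanFunction("A", "A | C"),
    booleanFunction("B", "C"),
    booleanFunction("C", "TRUE")))
}

# random Eq-2 style model: signed topology -> OR(activators) & !OR(inhibitors)
randomModel <- function(seed, nGenes = 8L, meanInDegree = 1.5,
                        pInhibition = 0.3, nSelf = 1L) {
  net <- generateTopology(synthConfig(nGenes = nGenes,
                                      meanInDegree = meanInDegree,
                                      pInhibition = pInhibition,
                                      nSelfActivation = nSelf, seed = seed))
  list(network = net, model = synthesizeLogic(net))
}

randomState <- function(model) {
  structure(as.integer(stats::runif(length(genes(model))) > 0.5),
            names = genes(model))
}

# independent rule evaluator: recursive interpretation of the language tree,
# written without eval() so it cannot share a defect with the package path
refEval <- function(e, state) {
  if (is.logical(e)) return(as.integer(e))
  if (is.symbol(e)) return(as.integer(state[[as.character(e)]]))
  op <- as.character(e[[1L]])
  switch(op,
    "(" = refEval(e[[2L]], state),
    "!" = 1L - refEval(e[[2L]], state),
    "&" = min(refEval(e[[2L]], state), refEval(e[[3L]], state)),
    "|" = max(refEval(e[[2L]], state), refEval(e[[3L]], state)),
    stop("unexpected operator ", op))
}

refStep <- function(model, state, clamps = NULL) {
  out <- state
  for (g in genes(model)) {
    if (!is.null(clamps) && g %in% names(clamps)) out[[g]] <- clamps[[g]]
    else if (g %in% inputGenes(model)) out[[g]] <- state[[g]]
    else out[[g]] <- refEval(rules(model)[[g]]@expr, state)
  }
  out
}

# brute-force veto semantics: a target is on iff at least one activator is
# on (or it has no activators) and no inhibitor is on
vetoEval <- function(activators, inhibitors, state) {
  actOK <- if (length(activators)) any(state[activators] == 1L) else TRUE
  inhOK <- all(state[inhibitors] == 0L)
  as.integer(actOK && inhOK)
}

# exact attractor membership by pointer doubling on the successor map:
# composing the successor function 2^ceiling(log2(N)) times sends every
# state into its terminal cycle, independently of the walk-based code path
doublingAttractors <- function(model) {
  gs <- genes(model)
  n <- length(gs)
  N <- 2L^n
  env <- lapply(seq_len(n), function(i)
    as.logical(bitwAnd(seq_len(N) - 1L, 2L^(i - 1L))))
  names(env) <- gs
  nxt <- lapply(gs, function(g) {
    if (g %in% inputGenes(model)) env[[g]]
    else {
      v <- eval(rules(model)[[g]]@expr, envir = env, enclos = baseenv())
      if (length(v) == 1L) rep(v, N) else v
    }
  })
  succ <- Reduce(`+`, Map(function(v, i) 2L^(i - 1L) * v,
                          nxt, seq_len(n))) + 1L
  f <- succ
  for (i in seq_len(ceiling(log2(N)) + 1L)) f <- f[f]
  cycleStates <- sort(unique(f))          # states inside terminal cycles
  # group cycle states into cycles by following the successor map
  seen <- integer(0)
  cycles <- list()
  for (s in cycleStates) {
    if (s %in% seen) next
    cyc <- s; cur <- succ[s]
    while (cur != s) { cyc <- c(cyc, cur); cur <- succ[cur] }
    seen <- c(seen, cyc)
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycleId <- integer(N)
  for (i in seq_along(cycles)) cycleId[cycles[[i]]] <- i
  basin <- tabulate(cycleId[f], nbins = length(cycles))
  keyOf <- function(code) paste(
    as.integer(bitwAnd(code - 1L, 2L^(seq_len(n) - 1L)) != 0L),
    collapse = "")
  sets <- lapply(cycles, function(cyc) sort(vapply(cyc, keyOf, character(1))))
  list(stateSets = sets, basins = basin)
}

attractorKeySet <- function(a)
  sort(apply(a@states, 2L, paste, collapse = ""))

# transitions from every possible state of a model, as a list of 2-column
# series (full one-step coverage for inference tests)
fullCoverageSeries <- function(model) {
  gs <- genes(model)
  n <- length(gs)
  lapply(seq_len(2L^n) - 1L, function(code) {
    s <- structure(as.integer(bitwAnd(code, 2L^(seq_len(n) - 1L)) != 0L),
                   names = gs)
    cbind(t0 = s, t1 = synchronousStep(model, s))
  })
}

# full one-step coverage as a single (src, dst) pair list of 2-column
# series, computed with the package's batch stepper for speed
batchCoverageSeries <- function(model) {
  gs <- genes(model)
  n <- length(gs)
  N <- 2L^n
  env <- lapply(seq_len(n), function(i)
    as.logical(bitwAnd(seq_len(N) - 1L, 2L^(i - 1L))))
  names(env) <- gs
  nxt <- BoolGRN:::.stepEnv(model, env)
  src <- do.call(rbind, lapply(env, as.integer))
  dst <- do.call(rbind, lapply(nxt, as.integer))
  rownames(src) <- rownames(dst) <- gs
  lapply(seq_len(N), function(j) cbind(t0 = src[, j], t1 = dst[, j]))
}
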