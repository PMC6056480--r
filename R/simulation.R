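#' @include logic.R
NULL

# --- internal state machinery ----------------------------------------------
# A state is a named 0/1 integer vector over the model's ordered gene list.
# Internally, batches of states are held as a named list of logical vectors
# (one entry per gene), so one eval() per gene advances every trajectory in
# the batch at once.

.checkClamps <- function(model, clamps) {
  if (is.null(clamps) || !length(clamps)) return(NULL)
  bad <- setdiff(names(clamps), model@genes)
  if (length(bad))
    stop(sprintf("clamped gene(s) not in model: %s", paste(bad, collapse = ", ")))
  storage.mode(clamps) <- "integer"
  clamps
}

.stateEnv <- function(model, stateMatrix) {
  env <- vector("list", length(model@genes))
  names(env) <- model@genes
  for (g in model@genes) env[[g]] <- as.logical(stateMatrix[g, ])
  env
}

.stepEnv <- function(model, env, clamps = NULL) {
  nxt <- env
  m <- length(env[[1L]])
  for (g in model@genes) {
    if (!is.null(clamps) && g %in% names(clamps)) {
      nxt[[g]] <- rep(clamps[[g]] == 1L, m)
    } else if (g %in% model@inputs) {
      nxt[[g]] <- env[[g]]
    } else {
      v <- evalBoolExpr(model@functions[[g]]@expr, env)
      nxt[[g]] <- if (length(v) == 1L) rep(v, m) else v
    }
  }
  nxt
}

.stateKey <- function(bits) paste(as.integer(bits), collapse = "")

.keyToState <- function(key, genes) {
  structure(as.integer(strsplit(key, "")[[1L]]), names = genes)
}

#' One synchronous update of a Boolean model
#'
#' Every non-clamped, non-input gene takes the value of its rule evaluated on
#' the current state; input genes hold their state; clamped genes take the
#' clamp value regardless of their rule.
#'
#' @param model a \linkS4class{BooleanNetwork}
#' @param state named 0/1 integer vector over the model genes
#' @param clamps optional named 0/1 vector of genes held fixed
#' @return the successor state (named integer vector)
#' @export
synchronousStep <- function(model, state, clamps = NULL) {
  clamps <- .checkClamps(model, clamps)
  if (!all(model@genes %in% names(state)))
    stop("state must cover every model gene")
  env <- lapply(model@genes, function(g) state[[g]] == 1L)
  names(env) <- model@genes
  nxt <- .stepEnv(model, env, clamps)
  structure(vapply(nxt, function(v) as.integer(v[1L]), integer(1)),
            names = model@genes)
}

.canonicalCycle <- function(keys) {
  # rotate the cycle so its lexicographically smallest state comes first
  i <- which.min(keys)
  if (i > 1L) keys <- c(keys[i:length(keys)], keys[seq_len(i - 1L)])
  keys
}

.attractorFromKeys <- function(keys, genes, basin = 1L) {
  keys <- .canonicalCycle(keys)
  mat <- vapply(keys, .keyToState, integer(length(genes)), genes = genes)
  mat <- base::matrix(mat, nrow = length(genes),
                      dimnames = list(genes, NULL))
  means <- rowMeans(mat)
  collapsed <- ifelse(means > 0.5, 1L, ifelse(means < 0.5, 0L, NA_integer_))
  # a cycle of length 1 can never tie
  collapsed <- structure(as.integer(collapsed), names = genes)
  new("Attractor", states = mat, basin = as.integer(basin),
      collapsed = collapsed)
}

# Walk one trajectory; `cache` (an environment) maps state keys to attractor
# ids across calls, `registry` collects attractors keyed by canonical id.
.walk <- function(model, startBits, clamps, cache, registry) {
  env <- lapply(startBits, function(b) b)
  names(env) <- model@genes
  path <- character(0)
  repeat {
    key <- .stateKey(unlist(env, use.names = FALSE))
    hit <- cache[[key]]
    if (!is.null(hit)) {
      for (k in path) cache[[k]] <- hit
      return(hit)
    }
    pos <- match(key, path)
    if (!is.na(pos)) {
      cyc <- path[pos:length(path)]
      canon <- .canonicalCycle(cyc)[1L]
      registry[[canon]] <- cyc
      for (k in path) cache[[k]] <- canon
      return(canon)
    }
    path <- c(path, key)
    env <- .stepEnv(model, env, clamps)
  }
}

#' Attractor reached from one initial state
#'
#' Iterates the synchronous update with cycle detection until a previously
#' visited state recurs; terminates after at most 2^n steps.
#'
#' @inheritParams synchronousStep
#' @param start named 0/1 integer vector (clamped genes are forced to their
#'   clamp value before the walk)
#' @return an \linkS4class{Attractor} with basin weight 1
#' @export
findAttractor <- function(model, start, clamps = NULL) {
  clamps <- .checkClamps(model, clamps)
  if (!all(model@genes %in% names(start)))
    stop("start state must cover every model gene")
  bits <- vapply(model@genes, function(g) start[[g]] == 1L, logical(1))
  names(bits) <- model@genes
  if (!is.null(clamps)) bits[names(clamps)] <- clamps == 1L
  cache <- new.env(parent = emptyenv())
  registry <- new.env(parent = emptyenv())
  id <- .walk(model, as.list(bits), clamps, cache, registry)
  .attractorFromKeys(registry[[id]], model@genes)
}

.sortAttractorSet <- function(atts, nStarts, method, seed) {
  b <- vapply(atts, function(a) a@basin, integer(1))
  keys <- vapply(atts, function(a) .stateKey(a@states[, 1L]), character(1))
  atts <- atts[order(-b, keys)]
  new("AttractorSet", attractors = atts, nStarts = as.integer(nStarts),
      method = method, seed = as.integer(seed))
}

#' Attractors from random initial states
#'
#' Draws \code{nStarts} random initial states (distinct states, sampled
#' without replacement whenever the state space allows it, so
#' \code{nStarts = 2^n} enumerates the space exactly), maps each to its
#' attractor and accumulates basin weights. The attractor with maximum basin
#' weight is the final stable state (\code{\link{maxBasinAttractor}}).
#'
#' @inheritParams synchronousStep
#' @param nStarts number of initial states (default 100, as in a standard
#'   synchronous simulation protocol)
#' @param seed integer seed for drawing the initial states
#' @param pinInitial optional named 0/1 vector forced into every initial
#'   state only (overexpression-style pinning; unlike \code{clamps} the genes
#'   evolve freely afterwards)
#' @return an \linkS4class{AttractorSet}
#' @export
sampleAttractors <- function(model, nStarts = 100L, seed = 1L, clamps = NULL,
                             pinInitial = NULL) {
  if (nStarts < 1L) stop("nStarts must be at least 1")
  clamps <- .checkClamps(model, clamps)
  pinInitial <- .checkClamps(model, pinInitial)
  n <- length(model@genes)
  set.seed(seed)
  if (n <= 25L && nStarts <= 2^n) {
    codes <- sample.int(2^n, nStarts) - 1L
    starts <- vapply(codes, function(code)
      bitwAnd(code, 2L^(seq_len(n) - 1L)) != 0L, logical(n))
  } else {
    starts <- base::matrix(stats::runif(n * nStarts) > 0.5, nrow = n)
  }
  starts <- base::matrix(starts, nrow = n, dimnames = list(model@genes, NULL))
  if (!is.null(pinInitial)) starts[names(pinInitial), ] <- pinInitial == 1L
  if (!is.null(clamps)) starts[names(clamps), ] <- clamps == 1L
  cache <- new.env(parent = emptyenv())
  registry <- new.env(parent = emptyenv())
  counts <- list()
  for (j in seq_len(nStarts)) {
    bits <- as.list(starts[, j])
    id <- .walk(model, bits, clamps, cache, registry)
    counts[[id]] <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
  }
  atts <- lapply(names(counts), function(id)
    .attractorFromKeys(registry[[id]], model@genes, basin = counts[[id]]))
  .sortAttractorSet(atts, nStarts, "sampled", seed)
}

#' Exact attractors and basins by exhaustive enumeration
#'
#' Enumerates all 2^n states of the (clamped) model and computes every
#' attractor with its exact basin size. Refuses models with more than 20
#' genes; sample instead.
#'
#' @inheritParams synchronousStep
#' @return an \linkS4class{AttractorSet} with basin weights summing to 2^n
#' @export
exhaustiveAttractors <- function(model, clamps = NULL) {
  clamps <- .checkClamps(model, clamps)
  n <- length(model@genes)
  if (n > 20L)
    stop("exhaustive enumeration is limited to 20 genes; use sampleAttractors()")
  free <- if (is.null(clamps)) model@genes else setdiff(model@genes, names(clamps))
  nf <- length(free)
  N <- 2L^nf
  env <- vector("list", n); names(env) <- model@genes
  for (i in seq_len(nf))
    env[[free[i]]] <- as.logical(bitwAnd(seq_len(N) - 1L, 2L^(i - 1L)))
  if (!is.null(clamps))
    for (g in names(clamps)) env[[g]] <- rep(clamps[[g]] == 1L, N)
  nxt <- .stepEnv(model, env, clamps)
  weights <- 2^(seq_len(nf) - 1L)
  codeOf <- function(e) {
    code <- numeric(N)
    for (i in seq_len(nf)) code <- code + weights[i] * e[[free[i]]]
    as.integer(code) + 1L
  }
  succ <- codeOf(nxt)
  att <- integer(N)
  onpath <- integer(N)
  cycles <- list()
  for (s in seq_len(N)) {
    if (att[s] > 0L) next
    path <- integer(0)
    cur <- s
    repeat {
      if (att[cur] > 0L) { id <- att[cur]; break }
      if (onpath[cur] > 0L) {
        cyc <- path[onpath[cur]:length(path)]
        cycles[[length(cycles) + 1L]] <- cyc
        id <- length(cycles)
        break
      }
      path <- c(path, cur)
      onpath[cur] <- length(path)
      cur <- succ[cur]
    }
    att[path] <- id
    onpath[path] <- 0L
  }
  basins <- tabulate(att, nbins = length(cycles))
  decode <- function(code) {
    bits <- structure(integer(n), names = model@genes)
    bits[free] <- as.integer(bitwAnd(code - 1L, 2L^(seq_len(nf) - 1L)) != 0L)
    if (!is.null(clamps)) bits[names(clamps)] <- clamps
    bits
  }
  atts <- lapply(seq_along(cycles), function(i) {
    keys <- vapply(cycles[[i]], function(code) .stateKey(decode(code)),
                   character(1))
    .attractorFromKeys(keys, model@genes, basin = basins[i])
  })
  .sortAttractorSet(atts, N, "exhaustive", NA_integer_)
}

#' In silico knockdown experiment
#'
#' Simulates the model unperturbed and with the knocked genes clamped to 0
#' throughout (same seed, hence identical initial draws), takes the max-basin
#' attractor of each run as the final stable state, collapses cycles to
#' per-gene states (majority over the cycle; exact ties are flagged
#' oscillating and excluded), and classifies every gene: (0,1) up-regulated,
#' (1,0) down-regulated, equal unchanged.
#'
#' @inheritParams sampleAttractors
#' @param knocked non-empty character vector of genes to clamp to 0
#' @return a \linkS4class{PerturbationResult}
#' @export
perturbationExperiment <- function(model, knocked, nStarts = 100L, seed = 1L) {
  if (!length(knocked))
    stop("knocked gene set is empty; use sampleAttractors() for an ",
         "unperturbed simulation")
  bad <- setdiff(knocked, model@genes)
  if (length(bad))
    stop(sprintf("knocked gene(s) not in model: %s", paste(bad, collapse = ", ")))
  clamps <- structure(rep(0L, length(knocked)), names = knocked)
  un <- sampleAttractors(model, nStarts = nStarts, seed = seed)
  pe <- sampleAttractors(model, nStarts = nStarts, seed = seed, clamps = clamps)
  gu <- maxBasinAttractor(un)@collapsed
  gp <- maxBasinAttractor(pe)@collapsed
  change <- classifyPerturbation(gu, gp)
  new("PerturbationResult", knocked = knocked, unperturbed = gu,
      perturbed = gp, change = change, unperturbedSet = un, perturbedSet = pe)
}

#' Classify per-gene perturbation changes
#'
#' @param unperturbed,perturbed named 0/1 (NA = oscillating) state vectors
#' @return named character: up-regulated / down-regulated / unchanged /
#'   oscillating
#' @export
classifyPerturbation <- function(unperturbed, perturbed) {
  stopifnot(identical(names(unperturbed), names(perturbed)))
  change <- ifelse(is.na(unperturbed) | is.na(perturbed), "oscillating",
            ifelse(unperturbed == 0L & perturbed == 1L, "up-regulated",
            ifelse(unperturbed == 1L & perturbed == 0L, "down-regulated",
                   "unchanged")))
  structure(change, names = names(unperturbed))
}

#' Write a perturbation report
#'
#' TSV with one row per gene (gene, unperturbed, perturbed, change) plus a
#' JSON bundle of the same content with the knockdown set and basin weights.
#'
#' @param result a \linkS4class{PerturbationResult}
#' @param prefix output path prefix (writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json})
#' @return invisibly, the two paths
#' @export
writePerturbationReport <- function(result, prefix) {
  df <- data.frame(gene = names(result@change),
                   unperturbed = unname(result@unperturbed),
                   perturbed = unname(result@perturbed),
                   change = unname(result@change))
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(knocked = result@knocked,
                            changes = df,
                            basin_unperturbed = basinWeights(result@unperturbedSet),
                            basin_perturbed = basinWeights(result@perturbedSet)),
                       js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv = tsv, json = js))
}
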