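#' @include simulation.R
NULL

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the pluripotency study conditions: a 45-gene sparse
#' signed network with 4 positive auto-regulatory loops and a mean in-degree
#' of about 1.5 (65 non-self edges over 45 genes), noise-free binary
#' trajectories, and per-gene bimodal expression drawn from a two-component
#' Gaussian location mixture on the log scale (low mean 2, high mean 8,
#' sd 0.8) so that high/low components correspond to the binary states.
#'
#' @param nGenes number of genes
#' @param meanInDegree mean number of non-self regulators per gene
#' @param pInhibition probability that a generated edge is an inhibition
#' @param nSelfActivation number of positive auto-regulatory loops
#' @param nTimepoints length of generated trajectories
#' @param noiseRate per-bit flip probability when emitting trajectories
#' @param meanLow,meanHigh,sdLow,sdHigh mixture parameters for expression
#' @param seed mandatory integer seed
#' @return a list of class \code{SynthConfig}
#' @export
synthConfig <- function(nGenes = 45L, meanInDegree = 1.5, pInhibition = 0.25,
                        nSelfActivation = 4L, nTimepoints = 50L,
                        noiseRate = 0, meanLow = 2, meanHigh = 8,
                        sdLow = 0.8, sdHigh = 0.8, seed) {
  if (missing(seed)) stop("a seed is mandatory for the synthetic generators")
  stopifnot(nGenes >= 1L, meanInDegree >= 0, pInhibition >= 0,
            pInhibition <= 1, nSelfActivation >= 0L, nTimepoints >= 2L,
            noiseRate >= 0, noiseRate <= 1, meanLow < meanHigh,
            sdLow >= 0, sdHigh >= 0)
  structure(list(nGenes = as.integer(nGenes), meanInDegree = meanInDegree,
                 pInhibition = pInhibition,
                 nSelfActivation = as.integer(nSelfActivation),
                 nTimepoints = as.integer(nTimepoints),
                 noiseRate = noiseRate, meanLow = meanLow,
                 meanHigh = meanHigh, sdLow = sdLow, sdHigh = sdHigh,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate a random signed topology with known structure
#'
#' Genes are ordered G01..Gnn and each gene draws Poisson-many regulators
#' from its predecessors (a DAG backbone, so the base graph is acyclic),
#' plus the requested number of positive self-activation loops. Edge signs
#' are inhibitions with probability \code{pInhibition}; categories are
#' assigned round-robin. Genes left without regulators are the model inputs.
#'
#' @param config a \code{\link{synthConfig}}
#' @return a \linkS4class{SignedNetwork}
#' @export
generateTopology <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  n <- config$nGenes
  if (config$nSelfActivation > n)
    stop("cannot place more self-activation loops than genes")
  set.seed(config$seed)
  gs <- sprintf("G%02d", seq_len(n))
  edges <- list()
  for (i in seq_len(n)[-1L]) {
    k <- min(stats::rpois(1L, config$meanInDegree), i - 1L)
    if (k == 0L) next
    regs <- sort(sample(gs[seq_len(i - 1L)], k))
    sign <- ifelse(stats::runif(k) < config$pInhibition,
                   "inhibition", "activation")
    edges[[length(edges) + 1L]] <-
      data.frame(source = regs, sign = sign, target = gs[i])
  }
  selfGenes <- sort(sample(gs, config$nSelfActivation))
  if (length(selfGenes))
    edges[[length(edges) + 1L]] <-
      data.frame(source = selfGenes, sign = "activation", target = selfGenes)
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  nodes <- data.frame(gene = gs,
                      category = rep(.CATEGORIES, length.out = n))
  signedNetwork(nodes, edges)
}

#' Generate a synchronous binary trajectory with optional bit-flip noise
#'
#' Starts from a seeded random state, iterates the synchronous update for
#' \code{nSteps - 1} steps and emits the gene x time 0/1 matrix; each
#' emitted bit is then flipped independently with probability
#' \code{noiseRate}.
#'
#' @param model a \linkS4class{BooleanNetwork}
#' @param nSteps number of time points (at least 2)
#' @param noiseRate per-bit flip probability
#' @param seed integer seed
#' @return 0/1 integer matrix, genes x time
#' @export
generateTimeseries <- function(model, nSteps = 50L, noiseRate = 0,
                               seed = 1L) {
  if (nSteps < 2L) stop("need at least 2 time points")
  set.seed(seed)
  n <- length(model@genes)
  out <- base::matrix(0L, n, nSteps,
                      dimnames = list(model@genes,
                                      paste0("t", seq_len(nSteps))))
  state <- structure(as.integer(stats::runif(n) > 0.5), names = model@genes)
  out[, 1L] <- state
  for (t in 2:nSteps) {
    state <- synchronousStep(model, state)
    out[, t] <- state
  }
  if (noiseRate > 0) {
    flip <- base::matrix(stats::runif(n * nSteps) < noiseRate, n, nSteps)
    out[flip] <- 1L - out[flip]
  }
  out
}

#' Generate bimodal expression from a binary state matrix
#'
#' Each entry is drawn from the mixture component matching its binary state:
#' Normal(meanLow, sdLow) for state 0 and Normal(meanHigh, sdHigh) for
#' state 1, emulating per-gene bimodal log-scale expression.
#'
#' @param binary 0/1 integer matrix, genes x samples
#' @param config a \code{\link{synthConfig}} (mixture parameters and seed)
#' @return numeric matrix with the same dimnames
#' @export
generateExpression <- function(binary, config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  mu <- ifelse(binary == 1L, config$meanHigh, config$meanLow)
  sd <- ifelse(binary == 1L, config$sdHigh, config$sdLow)
  vals <- stats::rnorm(length(binary), mean = as.vector(mu),
                       sd = as.vector(sd))
  base::matrix(vals, nrow(binary), ncol(binary), dimnames = dimnames(binary))
}
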