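#' @import methods
NULL

.CATEGORIES <- c("pluripotency_tf", "differentiation", "epigenetic", "other")
.SIGNS <- c("activation", "inhibition", "undefined")
.PROVENANCE <- c("curated", "inferred", "integrated")

#' SignedNetwork: a signed directed gene regulatory network
#'
#' Genes carry a category annotation (pluripotency transcription factor,
#' differentiation gene, epigenetic factor, or other) and interactions carry a
#' sign (activation, inhibition, or undefined) plus a provenance tag saying
#' whether the edge was curated from literature, inferred from time-series
#' data, or produced by integrating the two.
#'
#' @slot nodes data.frame with columns \code{gene} and \code{category}.
#' @slot interactions data.frame with columns \code{source}, \code{sign},
#'   \code{target}, \code{provenance}. At most one row per ordered
#'   (source, target) pair; self-interactions are allowed (auto-regulation).
#' @exportClass SignedNetwork
setClass("SignedNetwork",
  representation(nodes = "data.frame", interactions = "data.frame"))

setValidity("SignedNetwork", function(object) {
  nd <- object@nodes
  it <- object@interactions
  msgs <- character(0)
  if (!all(c("gene", "category") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns 'gene' and 'category'")
  else {
    if (anyDuplicated(nd$gene))
      msgs <- c(msgs, "duplicate gene names in nodes")
    if (any(!nzchar(nd$gene)))
      msgs <- c(msgs, "empty gene name")
    if (!all(nd$category %in% .CATEGORIES))
      msgs <- c(msgs, sprintf("unknown category: %s",
        paste(setdiff(nd$category, .CATEGORIES), collapse = ", ")))
  }
  if (!all(c("source", "sign", "target", "provenance") %in% names(it)))
    msgs <- c(msgs, "interactions must have columns source, sign, target, provenance")
  else if (nrow(it)) {
    if (!all(it$sign %in% .SIGNS))
      msgs <- c(msgs, "interaction sign must be activation/inhibition/undefined")
    if (!all(it$provenance %in% .PROVENANCE))
      msgs <- c(msgs, "interaction provenance must be curated/inferred/integrated")
    bad <- setdiff(unique(c(it$source, it$target)), nd$gene)
    if (length(bad))
      msgs <- c(msgs, sprintf("interaction endpoint(s) not in node set: %s",
        paste(bad, collapse = ", ")))
    if (anyDuplicated(paste(it$source, it$target)))
      msgs <- c(msgs, "more than one interaction for an ordered (source, target) pair")
  }
  if (length(msgs)) msgs else TRUE
})

#' BooleanFunction: one update rule
#'
#' A rooted expression tree over AND (\code{&}), OR (\code{|}) and NOT
#' (\code{!}) gates whose leaves are gene symbols (or the constants
#' TRUE/FALSE), stored as an R language object.
#'
#' @slot target gene symbol the rule updates.
#' @slot expr R language object restricted to \code{&}, \code{|}, \code{!},
#'   parentheses, gene symbols and logical constants.
#' @exportClass BooleanFunction
setClass("BooleanFunction",
  representation(target = "character", expr = "ANY"))

setValidity("BooleanFunction", function(object) {
  if (length(object@target) != 1L || !nzchar(object@target))
    return("target must be a single non-empty gene symbol")
  chk <- tryCatch({ checkBoolExpr(object@expr); TRUE },
                  error = function(e) conditionMessage(e))
  if (isTRUE(chk)) TRUE else chk
})

#' BooleanNetwork: an executable synchronous Boolean model
#'
#' @slot genes ordered character vector of gene symbols.
#' @slot functions named list of \linkS4class{BooleanFunction}, one per
#'   non-input gene.
#' @slot inputs genes with no regulators; they hold their state under
#'   synchronous update.
#' @exportClass BooleanNetwork
setClass("BooleanNetwork",
  representation(genes = "character", functions = "list", inputs = "character"))

setValidity("BooleanNetwork", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "duplicate gene names")
  fn <- names(object@functions)
  if (!setequal(fn, setdiff(object@genes, object@inputs)))
    msgs <- c(msgs, "every non-input gene must have exactly one function")
  if (length(intersect(object@inputs, fn)))
    msgs <- c(msgs, "input genes must not carry a function")
  for (f in object@functions) {
    if (!is(f, "BooleanFunction")) { msgs <- c(msgs, "functions must be BooleanFunction objects"); break }
    leaves <- setdiff(all.vars(f@expr), object@genes)
    if (length(leaves)) {
      msgs <- c(msgs, sprintf("function for %s references unknown gene(s): %s",
        f@target, paste(leaves, collapse = ", ")))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' BinarizedMatrix: per-gene 0/1 state assignments with thresholds
#'
#' @slot states integer 0/1 matrix, genes in rows, samples in columns.
#' @slot thresholds named numeric, per-gene threshold rho; expression above
#'   rho maps to state 1 for genes binarized by per-gene 2-means
#'   (\code{NA} for fallback genes, whose threshold lives on the pooled
#'   gene-mean scale in \code{fallbackThreshold}).
#' @slot method named character, per gene: \code{"timecourse_kmeans"} or
#'   \code{"unimodal_fallback"}.
#' @slot fallbackThreshold threshold separating the two groups of pooled
#'   per-gene mean expression used for unimodal genes (NA when unused).
#' @exportClass BinarizedMatrix
setClass("BinarizedMatrix",
  representation(states = "matrix", thresholds = "numeric",
                 method = "character", fallbackThreshold = "numeric"))

setValidity("BinarizedMatrix", function(object) {
  msgs <- character(0)
  g <- rownames(object@states)
  if (is.null(g)) msgs <- c(msgs, "states must have gene rownames")
  if (!all(object@states %in% c(0L, 1L)))
    msgs <- c(msgs, "states must be 0/1")
  if (!setequal(names(object@thresholds), g) || !setequal(names(object@method), g))
    msgs <- c(msgs, "thresholds and method must be named per gene")
  if (!all(object@method %in% c("timecourse_kmeans", "unimodal_fallback")))
    msgs <- c(msgs, "method must be timecourse_kmeans or unimodal_fallback")
  if (length(msgs)) msgs else TRUE
})

#' Attractor: a terminal cycle of the synchronous dynamics
#'
#' @slot states 0/1 matrix, genes in rows, one column per cycle state, in
#'   update order, rotated so the first column is the lexicographically
#'   smallest state (canonical form).
#' @slot basin integer basin weight: number of initial states whose
#'   trajectory ends in this cycle.
#' @slot collapsed named integer per-gene summary over the cycle: 0 or 1 if
#'   constant (or majority), NA if the gene oscillates with a tie.
#' @exportClass Attractor
setClass("Attractor",
  representation(states = "matrix", basin = "integer", collapsed = "integer"))

#' AttractorSet: attractors with basin weights from sampled or exhaustive starts
#'
#' @slot attractors list of \linkS4class{Attractor}, sorted by decreasing
#'   basin weight (ties broken by canonical state order).
#' @slot nStarts total number of initial states examined.
#' @slot method "sampled" or "exhaustive".
#' @slot seed seed used to draw initial states (NA for exhaustive).
#' @exportClass AttractorSet
setClass("AttractorSet",
  representation(attractors = "list", nStarts = "integer",
                 method = "character", seed = "integer"))

setValidity("AttractorSet", function(object) {
  if (sum(vapply(object@attractors, function(a) a@basin, integer(1))) !=
      object@nStarts)
    return("basin weights must sum to the number of starts")
  TRUE
})

#' PerturbationResult: per-gene knockdown outcome classification
#'
#' For each gene the unperturbed and perturbed max-basin attractor states are
#' compared: (0,1) is up-regulated, (1,0) down-regulated, equal states
#' unchanged. Genes oscillating with a tie in either attractor are flagged
#' \code{"oscillating"} and excluded from the classification.
#'
#' @slot knocked genes clamped to 0 throughout the perturbed simulation.
#' @slot unperturbed,perturbed named per-gene collapsed states (NA =
#'   oscillating).
#' @slot change named character: up-regulated / down-regulated / unchanged /
#'   oscillating.
#' @slot unperturbedSet,perturbedSet the underlying \linkS4class{AttractorSet}s.
#' @exportClass PerturbationResult
setClass("PerturbationResult",
  representation(knocked = "character", unperturbed = "integer",
                 perturbed = "integer", change = "character",
                 unperturbedSet = "AttractorSet", perturbedSet = "AttractorSet"))

setValidity("PerturbationResult", function(object) {
  k <- object@knocked
  p <- object@perturbed[k]
  if (any(!is.na(p) & p != 0L))
    return("knocked genes must have perturbed state 0")
  TRUE
})
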