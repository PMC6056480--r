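#' @include AllClasses.R
NULL

#' Gene symbols of a network or model
#' @param x a SignedNetwork, BooleanNetwork, or BinarizedMatrix
#' @return character vector of gene symbols
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Interaction table of a signed network
#' @param x a SignedNetwork
#' @return data.frame with columns source, sign, target, provenance
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' Gene category annotations
#' @param x a SignedNetwork
#' @return named character vector gene -> category
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' Input genes (no regulators; hold state under synchronous update)
#' @param x a BooleanNetwork
#' @return character vector
#' @export
setGeneric("inputGenes", function(x) standardGeneric("inputGenes"))

#' Update rules of a Boolean model
#' @param x a BooleanNetwork
#' @return named list of BooleanFunction
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' Binary state matrix
#' @param x a BinarizedMatrix
#' @return integer 0/1 matrix (genes x samples)
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Per-gene binarization thresholds (rho)
#' @param x a BinarizedMatrix
#' @return named numeric vector
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' Attractors of an AttractorSet
#' @param x an AttractorSet
#' @return list of Attractor, sorted by decreasing basin weight
#' @export
setGeneric("attractors", function(x) standardGeneric("attractors"))

#' Basin weights
#' @param x an AttractorSet
#' @return integer vector of basin weights, one per attractor
#' @export
setGeneric("basinWeights", function(x) standardGeneric("basinWeights"))

#' Max-basin attractor (the final stable state of a simulation)
#' @param x an AttractorSet
#' @return an Attractor
#' @export
setGeneric("maxBasinAttractor", function(x) standardGeneric("maxBasinAttractor"))

setMethod("genes", "SignedNetwork", function(x) x@nodes$gene)
setMethod("genes", "BooleanNetwork", function(x) x@genes)
setMethod("genes", "BinarizedMatrix", function(x) rownames(x@states))

setMethod("interactions", "SignedNetwork", function(x) x@interactions)

setMethod("categories", "SignedNetwork",
  function(x) structure(x@nodes$category, names = x@nodes$gene))

setMethod("inputGenes", "BooleanNetwork", function(x) x@inputs)
setMethod("rules", "BooleanNetwork", function(x) x@functions)

setMethod("states", "BinarizedMatrix", function(x) x@states)
setMethod("thresholds", "BinarizedMatrix", function(x) x@thresholds)

setMethod("attractors", "AttractorSet", function(x) x@attractors)
setMethod("basinWeights", "AttractorSet",
  function(x) vapply(x@attractors, function(a) a@basin, integer(1)))
setMethod("maxBasinAttractor", "AttractorSet", function(x) x@attractors[[1L]])

#' @export
setMethod("show", "SignedNetwork", function(object) {
  it <- object@interactions
  self <- it$source == it$target
  cat(sprintf("SignedNetwork: %d genes, %d interactions (%d edges, %d self-loops)\n",
              nrow(object@nodes), nrow(it), sum(!self), sum(self)))
  tab <- table(factor(object@nodes$category, levels = .CATEGORIES))
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @export
setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork: %d genes (%d with rules, %d inputs)\n",
              length(object@genes), length(object@functions),
              length(object@inputs)))
  n <- min(5L, length(object@functions))
  for (f in object@functions[seq_len(n)])
    cat(" ", formatRule(f), "\n")
  if (length(object@functions) > n) cat("  ...\n")
})

#' @export
setMethod("show", "BinarizedMatrix", function(object) {
  cat(sprintf("BinarizedMatrix: %d genes x %d samples (%d k-means, %d fallback)\n",
              nrow(object@states), ncol(object@states),
              sum(object@method == "timecourse_kmeans"),
              sum(object@method == "unimodal_fallback")))
})

#' @export
setMethod("show", "Attractor", function(object) {
  cat(sprintf("Attractor: cycle length %d, basin %d\n",
              ncol(object@states), object@basin))
})

#' @export
setMethod("show", "AttractorSet", function(object) {
  cat(sprintf("AttractorSet (%s): %d attractor(s) from %d starts\n",
              object@method, length(object@attractors), object@nStarts))
  b <- basinWeights(object)
  l <- vapply(object@attractors, function(a) ncol(a@states), integer(1))
  for (i in seq_len(min(5L, length(b))))
    cat(sprintf("  #%d: cycle length %d, basin %d\n", i, l[i], b[i]))
  if (length(b) > 5L) cat("  ...\n")
})

#' @export
setMethod("show", "PerturbationResult", function(object) {
  tab <- table(object@change)
  cat(sprintf("PerturbationResult: knockdown of {%s}\n",
              paste(object@knocked, collapse = ", ")))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})
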