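#' @include io.R
NULL

#' Synthesize Boolean logic from signed topology
#'
#' For each gene with at least one regulator, emits the rule
#' \code{OR(activators) & !(OR(inhibitors))}: any single active inhibitor
#' vetoes the gene regardless of how many activators are active. The
#' activator clause is omitted when a gene has only inhibitors (the gene is
#' then on exactly when no inhibitor is active) and vice versa. Members of
#' the dimer list that co-regulate the same target are AND-joined into one
#' composite activator (default: the POU5F1-SOX2 dimer). Regulators are
#' ordered lexicographically within a clause, so output is deterministic.
#'
#' @param network a \linkS4class{SignedNetwork}; every interaction must carry
#'   a defined sign (resolve undefined signs first, e.g. via
#'   \code{\link{integrateNetworks}}).
#' @param dimers list of character vectors; each set is AND-joined wherever
#'   all of its members activate a common target.
#' @return a \linkS4class{BooleanNetwork} over the network's genes; genes
#'   with no regulators become inputs.
#' @export
synthesizeLogic <- function(network,
                            dimers = list(c("POU5F1", "SOX2"))) {
  it <- network@interactions
  if (any(it$sign == "undefined"))
    stop("network contains undefined-sign interaction(s); ",
         "resolve signs (e.g. integrate with an inferred network) before ",
         "synthesizing logic")
  fns <- list()
  for (g in sort(genes(network))) {
    rows <- it[it$target == g, , drop = FALSE]
    if (!nrow(rows)) next
    act <- sort(rows$source[rows$sign == "activation"])
    inh <- sort(rows$source[rows$sign == "inhibition"])
    actTerms <- list()
    for (d in dimers) {
      if (length(d) >= 2L && all(d %in% act)) {
        lits <- lapply(sort(d), as.symbol)
        actTerms[[length(actTerms) + 1L]] <-
          Reduce(function(a, b) call("&", a, b), lits)
        act <- setdiff(act, d)
      }
    }
    actTerms <- c(actTerms, lapply(act, as.symbol))
    actClause <- if (length(actTerms))
      Reduce(function(a, b) call("|", a, b), actTerms) else NULL
    inhClause <- if (length(inh))
      Reduce(function(a, b) call("|", a, b), lapply(inh, as.symbol)) else NULL
    expr <- if (is.null(inhClause)) actClause
      else if (is.null(actClause)) call("!", .paren(inhClause))
      else call("&", .paren(actClause), call("!", .paren(inhClause)))
    fns[[length(fns) + 1L]] <- booleanFunction(g, expr)
  }
  booleanNetwork(fns, genes = genes(network))
}

.paren <- function(e) if (is.call(e) && length(e) > 2L) call("(", e) else e

#' Summary statistics of a signed network
#'
#' @param network a \linkS4class{SignedNetwork}
#' @return list with \code{nodes}, \code{edges} (non-self), \code{selfLoops},
#'   \code{positiveSelfLoops}, \code{negativeSelfLoops}, \code{interactions}
#'   (= edges + selfLoops) and \code{categoryCounts}.
#' @export
networkStats <- function(network) {
  it <- network@interactions
  self <- it$source == it$target
  list(
    nodes = nrow(network@nodes),
    edges = sum(!self),
    selfLoops = sum(self),
    positiveSelfLoops = sum(self & it$sign == "activation"),
    negativeSelfLoops = sum(self & it$sign == "inhibition"),
    interactions = nrow(it),
    categoryCounts = table(factor(network@nodes$category, levels = .CATEGORIES))
  )
}

#' Induced subnetwork on a gene set
#'
#' Keeps the given genes plus every interaction with both endpoints kept;
#' signs and provenance are preserved.
#'
#' @param network a \linkS4class{SignedNetwork}
#' @param keep character vector of genes to keep (must all exist)
#' @return a \linkS4class{SignedNetwork}
#' @export
pruneToGenes <- function(network, keep) {
  unknown <- setdiff(keep, genes(network))
  if (length(unknown))
    stop(sprintf("gene(s) not in network: %s", paste(unknown, collapse = ", ")))
  nd <- network@nodes[network@nodes$gene %in% keep, , drop = FALSE]
  it <- network@interactions
  it <- it[it$source %in% keep & it$target %in% keep, , drop = FALSE]
  signedNetwork(nd, it)
}

#' Integrate a curated network with an inferred network
#'
#' Returns the union of interactions. Edges present only in the inferred
#' network are added with provenance \code{inferred}. Curated edges whose
#' sign is undefined adopt the inferred sign for the same (source, target)
#' pair. When both networks define conflicting signs for a shared edge, the
#' original sign is kept and the conflict is reported (attribute
#' \code{conflicts}, also emitted as a message).
#'
#' @param original the curated \linkS4class{SignedNetwork}
#' @param inferred the inferred \linkS4class{SignedNetwork} (same gene
#'   universe)
#' @return the integrated \linkS4class{SignedNetwork} with a
#'   \code{conflicts} attribute (data.frame, possibly empty)
#' @export
integrateNetworks <- function(original, inferred) {
  if (!setequal(genes(original), genes(inferred)))
    stop("original and inferred networks must share one gene universe")
  orig <- original@interactions
  inf <- inferred@interactions
  key <- function(df) paste(df$source, df$target, sep = "\r")
  ko <- key(orig); ki <- key(inf)
  out <- orig
  conflicts <- data.frame(source = character(0), target = character(0),
                          original = character(0), inferred = character(0))
  shared <- match(ko, ki)
  for (i in which(!is.na(shared))) {
    so <- orig$sign[i]; si <- inf$sign[shared[i]]
    if (so == "undefined" && si != "undefined") {
      out$sign[i] <- si               # sign resolved from the inferred network
    } else if (so != "undefined" && si != "undefined" && so != si) {
      conflicts <- rbind(conflicts, data.frame(
        source = orig$source[i], target = orig$target[i],
        original = so, inferred = si))
    }
  }
  novel <- inf[is.na(match(ki, ko)), , drop = FALSE]
  if (nrow(novel)) novel$provenance <- "inferred"
  res <- signedNetwork(original@nodes, rbind(out, novel))
  if (nrow(conflicts))
    message(sprintf("sign conflict on %d edge(s); original sign kept", nrow(conflicts)))
  attr(res, "conflicts") <- conflicts
  res
}

#' Signed network implied by a Boolean model
#'
#' Derives one interaction per (regulator, target) pair from the monotone
#' direction of each rule in each of its regulators (non-monotone regulators
#' get an undefined sign).
#'
#' @param model a \linkS4class{BooleanNetwork}
#' @param categories optional named character vector gene -> category
#' @param provenance provenance tag for the derived edges
#' @return a \linkS4class{SignedNetwork}
#' @export
asSignedNetwork <- function(model, categories = NULL, provenance = "inferred") {
  edges <- list()
  for (fn in model@functions) {
    sg <- regulatorSigns(fn)
    if (!length(sg)) next
    edges[[length(edges) + 1L]] <- data.frame(
      source = names(sg), sign = unname(sg), target = fn@target,
      provenance = provenance)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  cats <- if (is.null(categories)) rep("other", length(model@genes))
          else unname(categories[model@genes])
  cats[is.na(cats)] <- "other"
  signedNetwork(data.frame(gene = model@genes, category = cats), edges)
}
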