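#' @include binarization.R
NULL

#' CandidateSet: best-fit Boolean function candidates per gene
#'
#' All candidates stored for a gene achieve that gene's minimal error count
#' over the observed transitions, and carry a uniform probability.
#'
#' @slot candidates named list (per gene) of lists of
#'   \linkS4class{BooleanFunction}.
#' @slot error named integer: the minimal error count per gene.
#' @exportClass CandidateSet
setClass("CandidateSet",
  representation(candidates = "list", error = "integer"))

#' @export
setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d gene(s)\n", length(object@candidates)))
  for (g in utils::head(names(object@candidates), 5L))
    cat(sprintf("  %s: %d candidate(s), error %d\n", g,
                length(object@candidates[[g]]), object@error[[g]]))
  if (length(object@candidates) > 5L) cat("  ...\n")
})

# pool transitions from a matrix or a list of matrices (genes x time)
.transitions <- function(series) {
  if (is.matrix(series)) series <- list(series)
  src <- NULL; dst <- NULL
  for (m in series) {
    if (ncol(m) < 2L) next
    src <- cbind(src, m[, -ncol(m), drop = FALSE])
    dst <- cbind(dst, m[, -1L, drop = FALSE])
  }
  if (is.null(src) || !ncol(src))
    stop("no state transitions in the series (need at least 2 time points)")
  list(src = src == 1L, dst = dst == 1L)
}

#' Mismatch count of a rule against observed transitions
#'
#' Counts the consecutive state pairs (t-1, t) for which the rule, evaluated
#' on the state at t-1, disagrees with the target gene's observed state at t.
#'
#' @param fn a \linkS4class{BooleanFunction}
#' @param series 0/1 gene x time matrix, or a list of such matrices whose
#'   transitions are pooled
#' @return integer mismatch count
#' @export
functionError <- function(fn, series) {
  tr <- .transitions(series)
  env <- lapply(rownames(tr$src), function(g) tr$src[g, ])
  names(env) <- rownames(tr$src)
  pred <- evalBoolExpr(fn@expr, env)
  if (length(pred) == 1L) pred <- rep(pred, ncol(tr$src))
  sum(pred != tr$dst[fn@target, ])
}

#' Best-fit Boolean function inference from binary time series
#'
#' For each gene, enumerates regulator subsets of size at most \code{maxK},
#' fills the subset's truth table by majority vote over the observed
#' transitions (rows tied or unseen are enumerated in both completions, up
#' to \code{maxCompletions} per subset), and scores each table by its
#' mismatch count. All minimum-error candidates whose truth table depends
#' essentially on every regulator in the subset are returned as function
#' trees with uniform probabilities; dropping inessential regulators loses
#' nothing because the projected table is found at smaller subset size with
#' the same error.
#'
#' @param series 0/1 gene x time matrix (rownames = genes), or a list of
#'   such matrices whose transitions are pooled
#' @param maxK maximal in-degree searched (at most 5; default 3)
#' @param allowedRegulators optional named list gene -> character vector
#'   restricting the regulator pool per gene
#' @param genes genes to infer rules for (default: all rows)
#' @param maxCompletions cap on tie completions enumerated per subset
#' @return a \linkS4class{CandidateSet}
#' @export
inferCandidateFunctions <- function(series, maxK = 3L,
                                    allowedRegulators = NULL,
                                    genes = NULL, maxCompletions = 64L) {
  if (maxK > 5L) stop("maxK must be at most 5")
  tr <- .transitions(series)
  allGenes <- rownames(tr$src)
  if (is.null(genes)) genes <- allGenes
  M <- ncol(tr$src)
  cands <- list(); errs <- integer(0)
  for (g in genes) {
    pool <- if (!is.null(allowedRegulators) && !is.null(allowedRegulators[[g]]))
      sort(intersect(allowedRegulators[[g]], allGenes)) else allGenes
    d <- tr$dst[g, ]
    subsets <- list()
    bestErr <- Inf
    for (k in 0:min(maxK, length(pool))) {
      combos <- if (k == 0L) list(character(0)) else
        apply(utils::combn(pool, k), 2L, identity, simplify = FALSE)
      for (S in combos) {
        if (k == 0L) idx <- rep(1L, M)
        else {
          sub <- tr$src[S, , drop = FALSE]
          idx <- 1L + as.integer(2L^(seq_len(k) - 1L) %*% sub)
        }
        nb <- 2L^k
        cnt1 <- tabulate(idx[d], nbins = nb)
        cntA <- tabulate(idx, nbins = nb)
        cnt0 <- cntA - cnt1
        err <- sum(pmin(cnt0, cnt1))
        if (err <= bestErr) {
          if (err < bestErr) { bestErr <- err; subsets <- list() }
          subsets[[length(subsets) + 1L]] <-
            list(S = S, cnt0 = cnt0, cnt1 = cnt1)
        }
      }
    }
    fns <- list()
    seen <- character(0)
    capped <- 0L
    for (sub in subsets) {
      k <- length(sub$S)
      base <- ifelse(sub$cnt1 > sub$cnt0, 1L,
              ifelse(sub$cnt1 < sub$cnt0, 0L, NA_integer_))
      ties <- which(is.na(base))
      nComp <- 2L^length(ties)
      if (nComp > maxCompletions) {
        capped <- capped + 1L
        nComp <- maxCompletions
      }
      for (ci in seq_len(nComp)) {
        tab <- base
        if (length(ties))
          tab[ties] <- as.integer(bitwAnd(ci - 1L,
                                          2L^(seq_along(ties) - 1L)) != 0L)
        if (!.allEssential(tab, k)) next
        expr <- tableToExpr(tab, sub$S)
        fn <- booleanFunction(g, expr)
        key <- formatRule(fn)
        if (key %in% seen) next
        seen <- c(seen, key)
        fns[[length(fns) + 1L]] <- fn
      }
    }
    if (capped)
      warning(sprintf(
        "gene %s: tie/unseen completions capped at %d for %d subset(s)",
        g, maxCompletions, capped))
    ord <- order(vapply(fns, function(f) length(regulatorsOf(f)), integer(1)),
                 vapply(fns, formatRule, character(1)))
    cands[[g]] <- fns[ord]
    errs[g] <- as.integer(bestErr)
  }
  new("CandidateSet", candidates = cands, error = errs)
}

#' Serialize a candidate set to JSON
#'
#' One entry per gene: a list of \code{{rule, error, probability}} records
#' with uniform probabilities.
#'
#' @param candidates a \linkS4class{CandidateSet}
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeCandidates <- function(candidates, path) {
  out <- lapply(names(candidates@candidates), function(g) {
    fns <- candidates@candidates[[g]]
    lapply(fns, function(f) list(rule = formatRule(f),
                                 error = candidates@error[[g]],
                                 probability = 1 / length(fns)))
  })
  names(out) <- names(candidates@candidates)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# similarity of a candidate to the topology-derived rule for the same gene:
# Jaccard index of the regulator sets plus 0.5 * fraction of shared
# regulators whose monotone sign agrees
.candidateScore <- function(fn, topoRegs, topoSigns) {
  regs <- regulatorsOf(fn)
  uni <- union(regs, topoRegs)
  jac <- if (!length(uni)) 1 else length(intersect(regs, topoRegs)) / length(uni)
  shared <- intersect(regs, topoRegs)
  bonus <- 0
  if (length(shared)) {
    sg <- regulatorSigns(fn)
    bonus <- 0.5 * mean(sg[shared] == topoSigns[shared])
  }
  jac + bonus
}

#' Select candidates maximally similar to topology-derived logic
#'
#' Per gene, each candidate is scored by the Jaccard similarity of its
#' regulator set to the topology rule's regulator set plus a 0.5-weighted
#' sign-agreement bonus over shared regulators; the maximum wins, with ties
#' broken by fewer regulators and then by lexicographic rule text. Genes
#' without candidates keep their topology rule.
#'
#' @param candidates a \linkS4class{CandidateSet}
#' @param topologyModel the topology-derived \linkS4class{BooleanNetwork}
#' @return the reconstructed \linkS4class{BooleanNetwork}
#' @export
selectFunctions <- function(candidates, topologyModel) {
  extra <- setdiff(names(candidates@candidates), topologyModel@genes)
  if (length(extra))
    stop(sprintf("candidate gene(s) not in topology model: %s",
                 paste(extra, collapse = ", ")))
  fns <- topologyModel@functions
  for (g in names(candidates@candidates)) {
    cl <- candidates@candidates[[g]]
    if (!length(cl)) next
    topoFn <- fns[[g]]
    topoRegs <- if (is.null(topoFn)) character(0) else regulatorsOf(topoFn)
    topoSigns <- if (is.null(topoFn))
      structure(character(0), names = character(0)) else regulatorSigns(topoFn)
    scores <- vapply(cl, .candidateScore, numeric(1),
                     topoRegs = topoRegs, topoSigns = topoSigns)
    nreg <- vapply(cl, function(f) length(regulatorsOf(f)), integer(1))
    key <- vapply(cl, formatRule, character(1))
    best <- order(-scores, nreg, key)[1L]
    fns[[g]] <- cl[[best]]
  }
  booleanNetwork(unname(fns), genes = topologyModel@genes)
}

#' Validate Boolean rules against binarized observations
#'
#' In \code{fixed_point} mode each rule is evaluated on the gene-level
#' binary state vector and is validated when its output equals the target's
#' assigned state. In \code{transition} mode the rule is evaluated on each
#' state at t-1 and compared with the target's observed state at t; the rule
#' is validated when it agrees on at least \code{minAgreement} of the
#' consecutive pairs. Rules referencing genes without states are skipped
#' with a warning.
#'
#' @param model a \linkS4class{BooleanNetwork}
#' @param binarized a \linkS4class{BinarizedMatrix} (or bare 0/1 matrix)
#' @param mode "fixed_point" (default) or "transition"
#' @param minAgreement agreement fraction required in transition mode
#'   (default 1.0)
#' @return list with per-gene \code{verdicts} (validated / violated /
#'   skipped), \code{fraction_validated} = validated / (validated +
#'   violated), counts, and the \code{mode}
#' @export
validateFunctions <- function(model, binarized,
                              mode = c("fixed_point", "transition"),
                              minAgreement = 1.0) {
  mode <- match.arg(mode)
  st <- if (is(binarized, "BinarizedMatrix")) states(binarized) else binarized
  verdicts <- character(0)
  if (mode == "fixed_point") {
    s <- if (is(binarized, "BinarizedMatrix")) geneLevelStates(binarized)
         else structure(as.integer(rowMeans(st) >= 0.5), names = rownames(st))
    env <- lapply(names(s), function(g) s[[g]] == 1L)
    names(env) <- names(s)
    for (g in names(model@functions)) {
      fn <- model@functions[[g]]
      need <- c(g, regulatorsOf(fn))
      if (!all(need %in% names(s))) {
        warning(sprintf("no state for gene(s) of rule %s; skipped", g))
        verdicts[g] <- "skipped"
        next
      }
      pred <- as.integer(evalBoolExpr(fn@expr, env))
      verdicts[g] <- if (pred == s[[g]]) "validated" else "violated"
    }
  } else {
    tr <- .transitions(st)
    env <- lapply(rownames(tr$src), function(g) tr$src[g, ])
    names(env) <- rownames(tr$src)
    for (g in names(model@functions)) {
      fn <- model@functions[[g]]
      need <- c(g, regulatorsOf(fn))
      if (!all(need %in% rownames(st))) {
        warning(sprintf("no state for gene(s) of rule %s; skipped", g))
        verdicts[g] <- "skipped"
        next
      }
      pred <- evalBoolExpr(fn@expr, env)
      if (length(pred) == 1L) pred <- rep(pred, ncol(tr$src))
      agree <- mean(pred == tr$dst[g, ])
      verdicts[g] <- if (agree >= minAgreement) "validated" else "violated"
    }
  }
  nv <- sum(verdicts == "validated")
  nx <- sum(verdicts == "violated")
  list(verdicts = verdicts,
       fraction_validated = if (nv + nx) nv / (nv + nx) else NA_real_,
       n_validated = nv, n_violated = nx,
       n_skipped = sum(verdicts == "skipped"),
       mode = mode)
}
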