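#' @include AllClasses.R
NULL

#' log-CPM normalization of a count matrix
#'
#' \code{log2((count + prior) / (libsize + 2 * prior) * 1e6)} per entry,
#' where libsize is the column sum. The pseudo-count keeps all-zero genes
#' finite.
#'
#' @param counts non-negative integer matrix, genes x samples
#' @param prior pseudo-count added to each entry (default 0.5)
#' @return numeric matrix of log2 counts-per-million
#' @export
logcpmNormalize <- function(counts, prior = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop(sprintf("zero library size for sample(s): %s",
                 paste(bad, collapse = ", ")))
  }
  log2(sweep(counts + prior, 2L, lib + 2 * prior, "/") * 1e6)
}

#' Bimodality amplitude of a sample
#'
#' A [0, 1] statistic of the proportion of bimodality: 0 for a unimodal
#' sample, 1 for two point masses. The density is estimated by a histogram
#' with \code{ceiling(sqrt(n))} bins smoothed by a 3-bin moving average
#' (or by a Gaussian kernel density when \code{estimator = "kernel"}). With
#' fewer than two local maxima the amplitude is 0; otherwise it is
#' \code{(A_low - A_antimode) / A_low}, where \code{A_low} is the smaller of
#' the two highest peaks and \code{A_antimode} the minimum density between
#' them, clipped to [0, 1].
#'
#' Local maxima below \code{minPeakFrac} of the highest density are ignored:
#' without this floor a spurious sample bump far out in the tail of a
#' unimodal distribution would count as a second mode and, because the dip
#' between it and the main peak reaches near zero, inflate the amplitude to
#' nearly 1.
#'
#' @param values numeric vector (at least 3 values)
#' @param estimator "histogram" (default) or "kernel"
#' @param bins number of histogram bins (default \code{ceiling(sqrt(n))})
#' @param minPeakFrac minimum height of a countable peak, as a fraction of
#'   the highest density (default 0.1)
#' @return amplitude in [0, 1]
#' @export
bimodalityAmplitude <- function(values, estimator = c("histogram", "kernel"),
                                bins = NULL, minPeakFrac = 0.1) {
  estimator <- match.arg(estimator)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L) stop("need at least 3 values to assess bimodality")
  if (diff(range(values)) == 0) return(0)
  if (estimator == "histogram") {
    if (is.null(bins)) bins <- ceiling(sqrt(n))
    h <- graphics::hist(values, breaks = seq(min(values), max(values),
                                             length.out = bins + 1L),
                        plot = FALSE)
    dens <- h$density
    if (length(dens) >= 6L)                      # 3-bin moving average
      dens <- stats::filter(c(dens[1L], dens, dens[length(dens)]),
                            rep(1 / 3, 3L))[2L:(length(dens) + 1L)]
    dens <- as.numeric(dens)
  } else {
    dens <- stats::density(values, n = 512L)$y
  }
  # peak scan on runs of equal density, so flat-topped peaks count once
  r <- rle(dens)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isMax <- logical(length(dens))
  for (j in seq_along(r$values)) {
    left <- if (j > 1L) r$values[j - 1L] else -Inf
    right <- if (j < length(r$values)) r$values[j + 1L] else -Inf
    if (r$values[j] > left && r$values[j] > right) isMax[starts[j]] <- TRUE
  }
  peaks <- which(isMax & dens >= minPeakFrac * max(dens))
  if (length(peaks) < 2L) return(0)
  top2 <- peaks[order(dens[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  aLow <- min(dens[lo], dens[hi])
  aAnti <- min(dens[lo:hi])
  if (aLow <= 0) return(0)
  amp <- max(0, min(1, (aLow - aAnti) / aLow))
  if (amp < 1e-8) 0 else amp     # guard against floating-point dust
}

#' Binarize an expression matrix by per-gene 2-means clustering
#'
#' Genes with non-zero bimodality amplitude are binarized individually:
#' 2-means over that gene's values, the higher-mean cluster mapped to 1, and
#' the threshold rho placed midway between the maximum of the low cluster
#' and the minimum of the high cluster (so state 1 iff expression > rho).
#' Unimodal genes (amplitude 0, including constant genes) are pooled: 2-means
#' is run on their per-gene mean expression and each such gene receives one
#' gene-level state (higher group = 1) replicated across samples.
#'
#' @param matrix numeric expression matrix, genes x samples (no NAs)
#' @param seed integer seed for the k-means restarts
#' @param nstart number of k-means restarts (default 10)
#' @param estimator density estimator for the bimodality gate
#' @return a \linkS4class{BinarizedMatrix}
#' @export
binarizeExpression <- function(matrix, seed = 1L, nstart = 10L,
                               estimator = "histogram") {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (is.null(rownames(matrix))) stop("expression matrix needs gene rownames")
  if (length(unique(as.vector(matrix))) < 2L)
    stop("need at least 2 distinct expression values")
  gs <- rownames(matrix)
  set.seed(seed)
  amp <- vapply(gs, function(g) {
    v <- matrix[g, ]
    if (length(v) < 3L || diff(range(v)) == 0) 0
    else bimodalityAmplitude(v, estimator = estimator)
  }, numeric(1))
  bimodal <- names(amp)[amp > 0]
  unimodal <- setdiff(gs, bimodal)
  states <- base::matrix(0L, nrow(matrix), ncol(matrix),
                         dimnames = dimnames(matrix))
  rho <- structure(rep(NA_real_, length(gs)), names = gs)
  method <- structure(rep("timecourse_kmeans", length(gs)), names = gs)
  for (g in bimodal) {
    v <- matrix[g, ]
    km <- stats::kmeans(v, centers = 2L, nstart = nstart)
    hiClust <- which.max(km$centers)
    hi <- v[km$cluster == hiClust]
    lo <- v[km$cluster != hiClust]
    rho[g] <- (max(lo) + min(hi)) / 2
    states[g, ] <- as.integer(v > rho[g])
  }
  fallbackRho <- NA_real_
  if (length(unimodal)) {
    method[unimodal] <- "unimodal_fallback"
    mu <- rowMeans(matrix[unimodal, , drop = FALSE])
    if (length(unique(mu)) < 2L) {
      warning("fewer than 2 distinct gene-level summaries in fallback pool; ",
              "all fallback genes assigned state 0")
      states[unimodal, ] <- 0L
    } else {
      km <- stats::kmeans(mu, centers = 2L, nstart = nstart)
      hiClust <- which.max(km$centers)
      hiGenes <- unimodal[km$cluster == hiClust]
      loGenes <- unimodal[km$cluster != hiClust]
      fallbackRho <- (max(mu[loGenes]) + min(mu[hiGenes])) / 2
      states[hiGenes, ] <- 1L
      states[loGenes, ] <- 0L
    }
  }
  new("BinarizedMatrix", states = states, thresholds = rho, method = method,
      fallbackThreshold = fallbackRho)
}

#' Collapse a binarized matrix to one state per gene
#'
#' Majority state across samples (ties resolved to 1, matching "expression
#' above threshold in at least half the samples"); fallback genes are
#' constant by construction.
#'
#' @param binarized a \linkS4class{BinarizedMatrix}
#' @return named integer 0/1 vector
#' @export
geneLevelStates <- function(binarized) {
  s <- states(binarized)
  structure(as.integer(rowMeans(s) >= 0.5), names = rownames(s))
}

#' Chi-square test of independence between binary state and gene category
#'
#' Builds the 2 x 2 contingency table of gene-level binary state against two
#' gene categories and applies Pearson's chi-square test (no continuity
#' correction by default).
#'
#' @param states named 0/1 vector of gene-level states (see
#'   \code{\link{geneLevelStates}})
#' @param annotations named character vector gene -> category
#' @param compare the two categories to contrast
#' @param correct apply Yates continuity correction (default FALSE)
#' @return list with \code{contingency}, \code{statistic}, \code{df},
#'   \code{p_value}
#' @export
categoryIndependenceTest <- function(states, annotations,
                                     compare = c("pluripotency_tf",
                                                 "differentiation"),
                                     correct = FALSE) {
  if (length(compare) != 2L) stop("exactly two categories must be compared")
  gs <- intersect(names(states), names(annotations))
  cat <- annotations[gs]
  keep <- cat %in% compare
  if (!all(compare %in% cat))
    stop(sprintf("no genes in category: %s",
                 paste(setdiff(compare, cat), collapse = ", ")))
  tab <- table(state = factor(states[gs][keep], levels = c(0L, 1L)),
               category = factor(cat[keep], levels = compare))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(contingency = tab,
       statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
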