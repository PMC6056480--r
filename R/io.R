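#' @include boolexpr.R
NULL

.SIGN_CODE <- c(activation = "+", inhibition = "-", undefined = "?")
.CODE_SIGN <- structure(names(.SIGN_CODE), names = .SIGN_CODE)

#' Construct a SignedNetwork from tables
#'
#' @param nodes data.frame with columns \code{gene}, \code{category}, or a
#'   character vector of gene names (categories default to "other").
#' @param interactions data.frame with columns \code{source}, \code{sign}
#'   (activation/inhibition/undefined or +/-/?), \code{target} and optionally
#'   \code{provenance} (default "curated").
#' @return a \linkS4class{SignedNetwork}; rows are sorted by source then
#'   target so equal networks serialize identically.
#' @export
signedNetwork <- function(nodes, interactions = NULL) {
  if (is.character(nodes))
    nodes <- data.frame(gene = nodes, category = "other")
  nodes <- data.frame(gene = as.character(nodes$gene),
                      category = as.character(nodes$category))
  if (is.null(interactions) || !nrow(interactions)) {
    interactions <- data.frame(source = character(0), sign = character(0),
                               target = character(0), provenance = character(0))
  } else {
    sg <- as.character(interactions$sign)
    sg[sg %in% names(.CODE_SIGN)] <- .CODE_SIGN[sg[sg %in% names(.CODE_SIGN)]]
    prov <- if ("provenance" %in% names(interactions))
      as.character(interactions$provenance) else rep("curated", nrow(interactions))
    interactions <- data.frame(source = as.character(interactions$source),
                               sign = sg,
                               target = as.character(interactions$target),
                               provenance = prov)
  }
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  interactions <- interactions[order(interactions$source, interactions$target), ,
                               drop = FALSE]
  rownames(nodes) <- NULL
  rownames(interactions) <- NULL
  new("SignedNetwork", nodes = nodes, interactions = interactions)
}

#' Read a signed network from an edge list and annotation file
#'
#' The edge list is a TSV with columns \code{source}, \code{sign}
#' (\code{+}/\code{-}/\code{?}), \code{target}; the annotation file a TSV
#' with columns \code{gene}, \code{category}. Comment lines start with
#' \code{#}. Genes present only in the edge list are kept with category
#' \code{other} (with a warning), as are genes with unrecognized categories.
#'
#' @param edge_file path to the edge TSV
#' @param annotation_file path to the annotation TSV
#' @return a \linkS4class{SignedNetwork}
#' @export
readNetwork <- function(edge_file, annotation_file) {
  ann <- utils::read.table(annotation_file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("gene", "category") %in% names(ann)))
    stop("annotation file must have columns 'gene' and 'category'")
  bad <- !ann$category %in% .CATEGORIES
  if (any(bad)) {
    warning(sprintf("unknown categories mapped to 'other': %s",
                    paste(unique(ann$category[bad]), collapse = ", ")))
    ann$category[bad] <- "other"
  }
  edges <- utils::read.table(edge_file, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE,
                             colClasses = "character")
  if (nrow(edges)) {
    if (!all(c("source", "sign", "target") %in% names(edges)))
      stop("edge file must have columns 'source', 'sign', 'target'")
    key <- paste(edges$source, edges$target)
    if (anyDuplicated(key))
      stop(sprintf("duplicate interaction row(s) for pair(s): %s",
                   paste(unique(key[duplicated(key)]), collapse = "; ")))
    missing <- setdiff(unique(c(edges$source, edges$target)), ann$gene)
    if (length(missing)) {
      warning(sprintf("edge endpoint(s) missing from annotations, added as 'other': %s",
                      paste(missing, collapse = ", ")))
      ann <- rbind(ann, data.frame(gene = missing, category = "other"))
    }
    if (!"provenance" %in% names(edges)) edges$provenance <- "curated"
  }
  signedNetwork(ann, edges)
}

#' Construct a BooleanNetwork from rules
#'
#' Genes appearing only as rule leaves become inputs (no regulators; they
#' hold their state under synchronous update).
#'
#' @param functions list of \linkS4class{BooleanFunction}
#' @param genes optional full gene universe (adds rule-less genes as inputs)
#' @return a \linkS4class{BooleanNetwork}
#' @export
booleanNetwork <- function(functions, genes = NULL) {
  targets <- vapply(functions, function(f) f@target, character(1))
  if (anyDuplicated(targets))
    stop(sprintf("two rules for target(s): %s",
                 paste(unique(targets[duplicated(targets)]), collapse = ", ")))
  names(functions) <- targets
  leaves <- unique(unlist(lapply(functions, regulatorsOf)))
  allGenes <- sort(unique(c(targets, leaves, genes)))
  new("BooleanNetwork", genes = allGenes, functions = functions,
      inputs = setdiff(allGenes, targets))
}

#' Read a Boolean rule file
#'
#' BoolNet-compatible text dialect: optional header \code{targets, factors},
#' then one rule per line in the form \code{target, expr} (or
#' \code{target <- expr}), with operators \code{!}, \code{&}, \code{|} and
#' parentheses. Identity rules (\code{g, g}) are treated as input genes.
#'
#' @param function_file path to the rule file
#' @return a \linkS4class{BooleanNetwork}
#' @export
readFunctions <- function(function_file) {
  lines <- readLines(function_file)
  fns <- list()
  inputs <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(line)) next
    if (i == 1L && grepl("^targets\\s*,\\s*factors\\s*$", line, ignore.case = TRUE))
      next
    m <- regmatches(line, regexec("^([^,<]+?)\\s*(?:,|<-)\\s*(.+)$", line))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("line %d: cannot parse rule '%s'", i, line))
    target <- trimws(m[2L])
    body <- trimws(m[3L])
    fn <- tryCatch(booleanFunction(target, body),
                   error = function(e)
                     stop(sprintf("line %d: %s", i, conditionMessage(e)),
                          call. = FALSE))
    if (is.symbol(fn@expr) && identical(as.character(fn@expr), target)) {
      inputs <- c(inputs, target)              # identity rule = input gene
      next
    }
    if (target %in% vapply(fns, function(f) f@target, character(1)))
      stop(sprintf("line %d: second rule for target %s", i, target))
    fns[[length(fns) + 1L]] <- fn
  }
  booleanNetwork(fns, genes = inputs)
}

#' Write a network, Boolean model and annotations to a directory
#'
#' Writes \code{edges.tsv}, \code{rules.txt} (BoolNet dialect, inputs as
#' identity rules) and \code{annotations.tsv}. Output is byte-stable: rows
#' are sorted by gene then target.
#'
#' @param network a \linkS4class{SignedNetwork}
#' @param model a \linkS4class{BooleanNetwork} (or NULL to skip the rule file)
#' @param out_dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeModel <- function(network, model = NULL, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  edgePath <- file.path(out_dir, "edges.tsv")
  annPath <- file.path(out_dir, "annotations.tsv")
  it <- network@interactions
  out <- data.frame(source = it$source, sign = .SIGN_CODE[it$sign],
                    target = it$target, provenance = it$provenance)
  out <- out[order(out$source, out$target), , drop = FALSE]
  utils::write.table(out, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nd <- network@nodes[order(network@nodes$gene), , drop = FALSE]
  utils::write.table(nd, annPath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(edges = edgePath, annotations = annPath)
  if (!is.null(model)) {
    rulePath <- file.path(out_dir, "rules.txt")
    gs <- sort(model@genes)
    lines <- c("targets, factors", vapply(gs, function(g) {
      if (g %in% model@inputs) sprintf("%s, %s", g, g)
      else formatRule(model@functions[[g]])
    }, character(1)))
    writeLines(lines, rulePath)
    paths <- c(paths, rules = rulePath)
  }
  invisible(paths)
}
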