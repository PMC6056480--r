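#' @include logic.R
NULL

.fixtureFile <- function(name)
  system.file("extdata", name, package = "BoolGRN", mustWork = TRUE)

#' The packaged 45-gene pluripotency network fixture
#'
#' Returns the curated signed network of the human pluripotency circuit
#' (45 genes; 65 non-self edges of which 4 carry an undefined sign; 4
#' positive auto-regulatory loops), the inferred novel-interaction network,
#' the integrated network (curated topology plus novel edges, undefined
#' signs resolved), and the Boolean model synthesized from the integrated
#' topology with the POU5F1-SOX2 dimer AND-joined.
#'
#' The exact published edge list is only available as a figure; this fixture
#' is a synthetic transcription that preserves every interaction named in
#' the primary text and the published node/edge/loop counts, with
#' literature-plausible infill for the rest (documented edge by edge in
#' \code{inst/extdata/pluripotency_edges_provenance.tsv}).
#'
#' @return list with elements \code{curated}, \code{inferred},
#'   \code{integrated} (\linkS4class{SignedNetwork}s) and \code{model}
#'   (\linkS4class{BooleanNetwork} of the integrated network)
#' @examples
#' fx <- pluripotencyFixture()
#' networkStats(fx$curated)$nodes
#' @export
pluripotencyFixture <- function() {
  ann <- .fixtureFile("pluripotency_annotations.tsv")
  curated <- readNetwork(.fixtureFile("pluripotency_curated_edges.tsv"), ann)
  inferred <- readNetwork(.fixtureFile("pluripotency_inferred_edges.tsv"), ann)
  ii <- inferred@interactions
  ii$provenance <- "inferred"
  inferred@interactions <- ii
  integrated <- integrateNetworks(curated, inferred)
  list(curated = curated, inferred = inferred, integrated = integrated,
       model = synthesizeLogic(integrated))
}
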