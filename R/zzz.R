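#' BoolGRN: Boolean modelling and in silico perturbation of signed gene
#' regulatory networks
#'
#' Build a signed gene regulatory network, derive Boolean logic from its
#' topology, binarize expression to validate the logic, infer and integrate
#' novel interactions from binary time series, and predict single and
#' combinatorial knockdown outcomes through synchronous attractor analysis.
#'
#' @keywords internal
"_PACKAGE"
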