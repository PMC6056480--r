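---
title: "Discrete modelling of the human pluripotency network with BoolGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete modelling of the human pluripotency network with BoolGRN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolGRN)
```

## The model

BoolGRN treats a gene regulatory network (GRN) as a synchronous Boolean
network: each gene $G_i$ holds a state $s_i \in \{0, 1\}$, and all genes
update simultaneously,

$$ s_i(t+1) = \Psi_i\big(s(t)\big), $$

where $\Psi_i$ is a logic function over the gene's regulators built from
AND, OR and NOT gates. Genes with no regulators are *inputs* and hold their
state. Trajectories are deterministic and the state space is finite, so
every trajectory ends in an *attractor* — a fixed point or a cycle —
interpreted as a stable cellular phenotype. The package is built around the
core circuit of human pluripotency (POU5F1/OCT4, SOX2, NANOG), but all
machinery is generic over any signed GRN.

### Topology-to-logic synthesis

Given a signed topology, `synthesizeLogic()` derives one rule per regulated
gene:

$$ \Psi_i = \big(A_1 \lor A_2 \lor \dots\big) \land
            \lnot\big(I_1 \lor I_2 \lor \dots\big), $$

activators OR-joined, inhibitors OR-joined under a single negation. The
semantics are deliberately asymmetric: one active inhibitor silences the
gene no matter how many activators are on (a "veto" rule, standard for
literature-curated GRNs where inhibition is usually dominant). A gene with
only inhibitors is on exactly when all of them are off; a gene with only
activators needs at least one active. Heterodimers that act as a unit are
AND-joined: by default the POU5F1–SOX2 dimer, so a target activated by both
receives `POU5F1 & SOX2` as one composite activator. The dimer list is an
argument, not a constant.

A rule set is an executable `BooleanNetwork`; rules are stored as R language
objects restricted to `&`, `|`, `!` and parentheses, which gives exact,
inspectable expression trees and vectorized evaluation for free.

### Simulation, attractors and knockdowns

`sampleAttractors()` draws random initial states (100 by default, the
standard protocol for networks too large to enumerate), iterates the
synchronous update with cycle detection, and accumulates a basin weight
$B_i$ per attractor — the number of initial states ending in it. The
attractor with maximal $B_i$ is the *final stable state*. Initial states
are drawn **without replacement** whenever the state space allows it: random
distinct initial conditions are the natural reading of the protocol, and it
makes `nStarts = 2^n` an exact enumeration, directly comparable with
`exhaustiveAttractors()` (which is also the test oracle below 21 genes).

A knockdown clamps the targeted genes to 0 at every step, including the
initial state; the clamp is permanent, which matches "coerced to the OFF
state during the simulation" rather than a transient initial condition. The
complementary probe — overexpression — is provided as *initial-state
pinning* (`pinInitial`): the gene starts at 1 but then evolves freely,
which is the right abstraction for a transient activation stimulus.
`perturbationExperiment()` runs the unperturbed and clamped simulations
with the same seed (hence identical initial draws), collapses each
max-basin attractor to per-gene states, and classifies every gene:

$$ S_i = \begin{cases}
  \text{up-regulated} & G_{iu} = 0,\ G_{ip} = 1 \\
  \text{down-regulated} & G_{iu} = 1,\ G_{ip} = 0 \\
  \text{unchanged} & G_{iu} = G_{ip}.
\end{cases} $$

Cyclic attractors are collapsed by per-gene majority over the cycle; an
exact tie is flagged `oscillating` and excluded from the classification —
the classification above implicitly assumes fixed points, and majority with
an explicit tie flag is the least-surprising extension. Ties between
equal-weight attractors are broken toward the lexicographically smallest
canonical state, so results are deterministic for a fixed seed.

### Binarization and bimodality

Boolean validation needs 0/1 data. Expression of most GRN genes is
empirically bimodal on the log scale, so `binarizeExpression()` uses
per-gene 2-means clustering: the higher-mean cluster maps to 1 and the
threshold $\rho$ sits midway between the maximum of the low cluster and the
minimum of the high cluster, giving the exact invariant
$s = 1 \iff \varepsilon > \rho$. Whether a gene is bimodal at all is decided
by `bimodalityAmplitude()`: a histogram of $\lceil\sqrt{n}\rceil$ bins
(3-bin moving-average smoothed; a kernel estimator is available), with
amplitude

$$ \frac{A_\text{low} - A_\text{antimode}}{A_\text{low}} \in [0, 1], $$

where $A_\text{low}$ is the smaller of the two highest peaks and
$A_\text{antimode}$ the minimum density between them. Zero means unimodal,
one means two point masses. Peaks below 10% of the density maximum are not
counted: a spurious tail bump would otherwise register as a second mode
whose near-zero antimode drives the amplitude to 1 on plainly unimodal
data. Unimodal genes cannot be thresholded individually; they are pooled
and 2-means is run on their per-gene mean, assigning one gene-level state
(the natural fallback for snapshot rather than time-course behaviour).

"Component separation" in the recovery guarantees is measured from each
component mean to the inter-cluster threshold: with each component 4 sd
from the cut, state recovery is ≥ 99%; for means only 4 sd *apart* the
irreducible mixture overlap already exceeds 2%, so no binarization could
promise 99% there.

The binary-state/category association is tested with Pearson's chi-square
(`categoryIndependenceTest()`), without continuity correction by default —
the correction is a flag, because published 2×2 p-values can be computed
either way, and R's own default (correction on) would silently change the
statistic. Gene-level states for the table are the per-gene majority across
samples (ties toward 1).

### Rule validation and best-fit inference

`validateFunctions()` checks rules two ways. *Fixed-point* mode (default)
plugs the gene-level states into each rule and requires the output to equal
the target's assigned state.
*Transition* mode evaluates the rule on the state at $t-1$ and compares
with the target at $t$ for every consecutive pair, validating at a
configurable agreement fraction (default 1.0).

`inferCandidateFunctions()` implements best-fit truth-table search: for
each gene, all regulator subsets up to `maxK` (default 3; the subset count
is combinatorial in `maxK`, and 3 keeps 45-gene problems tractable), the
subset's truth table filled by majority over observed transitions, scored
by mismatch count. All minimum-error candidates are kept with uniform
probabilities. Two pragmatic policies shape the candidate set:

* tied or unseen truth-table rows are expanded in both completions, capped
  at 64 per subset (with a warning) to bound the combinatorics;
* candidates must depend *essentially* on every regulator in their subset —
  a table that ignores a regulator is exactly the projection found at the
  smaller subset with the same error, so keeping it would only duplicate.

`selectFunctions()` mirrors the manual "maximum similarity" selection with
a fixed, reproducible score: Jaccard similarity of the candidate's
regulator set to the topology rule's regulator set, plus 0.5 times the
fraction of shared regulators whose monotone sign agrees. Ties prefer fewer
regulators, then lexicographic rule text. Genes without candidates keep the
topology rule. `integrateNetworks()` then merges inferred interactions into
the curated topology: novel edges enter with provenance `inferred`,
curated edges with undefined signs adopt the inferred sign, and genuine
sign conflicts keep the curated sign and are reported rather than silently
resolved.

## The packaged pluripotency fixture

`pluripotencyFixture()` returns the curated 45-gene network (65 non-self
edges, 4 of them with undefined sign, plus 4 positive auto-regulatory
loops), the inferred novel-interaction network (NANOG ⊣ KLF4; NANOG,
POU5F1, SOX2 → TBX3; FGF2 → FGFR2; FGFR2 ⊣ TCF3, NOG, BMP4; the MYC
negative auto-loop), the integrated network, and its synthesized Boolean
model. The full published edge list exists only as a figure, so the fixture
is a *synthetic transcription*: every interaction named in the primary text
is present verbatim, the node/edge/loop counts match, and the remaining
edges are literature-plausible infill chosen so the dynamics reproduce the
documented behaviour of the core circuit — the max-basin attractor
expresses POU5F1/SOX2/NANOG, POU5F1 knockdown collapses the core while
NANOG knockdown spares POU5F1, and the POU5F1+NANOG double knockdown equals
the POU5F1 single knockdown. Every edge's provenance (named vs constraint
vs infill) is tabulated in
`inst/extdata/pluripotency_edges_provenance.tsv`. Quantities that depend on
the exact published rule set — such as the number of genes changed by a
POU5F1 knockdown — are reported as computed from this fixture, not forced
toward published values.

```{r fixture}
fx <- pluripotencyFixture()
networkStats(fx$curated)[c("nodes", "edges", "selfLoops", "interactions")]
as <- sampleAttractors(fx$model, nStarts = 100, seed = 1)
maxBasinAttractor(as)@collapsed[c("POU5F1", "SOX2", "NANOG", "GATA6")]
```

## What the synthetic generators emulate — and what they do not

`generateTopology()` draws a sparse signed DAG backbone (Poisson in-degrees
from lexicographic predecessors, so the base graph is acyclic) plus a
requested number of positive self-activation loops; defaults mirror the
pluripotency study scale (45 genes, mean in-degree ≈ 1.5, 4 self-loops,
25% inhibition). `generateTimeseries()` emits a synchronous trajectory with
independent per-bit flip noise (default 0). `generateExpression()` draws
each observation from the Gaussian component matching its binary state —
low mean 2, high mean 8, sd 0.8 on a log-like scale, chosen so default
binarization is near-perfect while the threshold code is still exercised.

These generators validate *inference under the model's own assumptions*:
exact synchrony, independent noise, clean two-component expression. Real
single-cell data violate all three (asynchronous dynamics, dropout,
library-size variation, unordered cells — pseudotime inference is out of
scope, and column order is taken as temporal order). A passing test suite
therefore demonstrates correctness of the algorithms, not biological
validity of conclusions drawn from any particular dataset.

## Numerical and design choices

* **Determinism.** Every stochastic entry point takes a seed; ordering and
  tie-breaks are lexicographic throughout (gene order in clauses, canonical
  attractor rotation, candidate ordering), so equal inputs give
  byte-identical outputs.
* **Degenerate inputs.** Constant genes route to the unimodal fallback; a
  fallback pool without two distinct summaries assigns 0 with a warning;
  empty knockdown sets, undefined-sign rules at synthesis time, duplicate
  edges and duplicate rule targets are hard errors.
* **Scale limits.** `exhaustiveAttractors()` refuses beyond 20 genes;
  `truthTable()` beyond 16 variables; `inferCandidateFunctions()` beyond
  `maxK = 5`. The test suite exercises 8–10-gene networks exhaustively
  (50-model attractor cross-checks, 20-seed inference recovery) and the
  45-gene fixture through sampling — sizes at which the full suite runs in
  a few minutes.
* **Validation denominator.** The validated fraction is
  validated / (validated + violated); skipped rules (missing states) are
  excluded from the denominator and reported separately, since the
  published ~93% figure does not state its denominator.
* **Pipeline.** `runPipeline()` composes normalize → binarize → logic →
  validate → infer → select → integrate → simulate → perturb from a YAML or
  list config, writing every intermediate artifact, a MANIFEST in
  execution order, a seed-echoing log, and a versioned summary JSON.
  Undefined-sign edges are set aside at the logic stage and resolved (or
  dropped, if still non-monotone) at integration.

## Known limitations

* Synchronous updating only; asynchronous and probabilistic schemes are
  out of scope.
* The curated fixture is a documented synthetic transcription, not the
  published figure edge list; quantities tied to the exact published rules
  are reproducible only with the original supplementary data supplied by
  the user (see `tests/testthat/test-acceptance.R` for the expected file
  layout).
* Best-fit inference assumes the observation order is the temporal order
  and treats each consecutive pair as one synchronous step.
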