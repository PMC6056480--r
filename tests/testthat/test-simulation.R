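test_that("the synchronous step obeys rules, inputs and clamps", {
  # constant rules map every state to the constant vector
  cm <- booleanNetwork(list(booleanFunction("A", quote(TRUE)),
                            booleanFunction("B", quote(FALSE))))
  expect_equal(synchronousStep(cm, c(A = 0L, B = 1L)), c(A = 1L, B = 0L))

  # a clamp overrides the rule
  expect_equal(synchronousStep(cm, c(A = 0L, B = 1L),
                               clamps = c(A = 0L))[["A"]], 0L)

  # inputs hold their state
  bn <- booleanNetwork(list(booleanFunction("B", "A")))
  expect_equal(synchronousStep(bn, c(A = 1L, B = 0L)),
               c(A = 1L, B = 1L))

  expect_error(synchronousStep(cm, c(A = 1L, B = 0L), clamps = c(Z = 1L)),
               "Z")

  # agreement with an independent recursive evaluator on random pairs
  for (seed in 1:25) {
    rm <- randomModel(seed, nGenes = 8L, nSelf = seed %% 3L)
    set.seed(seed + 500)
    for (i in 1:8) {
      st <- randomState(rm$model)
      expect_identical(synchronousStep(rm$model, st),
                       refStep(rm$model, st))
      cl <- structure(1L, names = genes(rm$model)[1L])
      expect_identical(synchronousStep(rm$model, st, clamps = cl),
                       refStep(rm$model, st, clamps = cl))
    }
  }
})

test_that("attractors are found, canonicalized and verify their cycle property", {
  # fixed point
  cm <- booleanNetwork(list(booleanFunction("A", quote(TRUE)),
                            booleanFunction("B", quote(FALSE))))
  a <- findAttractor(cm, c(A = 1L, B = 0L))
  expect_equal(ncol(a@states), 1L)
  expect_equal(unname(a@states[, 1L]), c(1L, 0L))

  # forced 2-cycle: A' = B, B' = A from (0, 1)
  sw <- booleanNetwork(list(booleanFunction("A", "B"),
                            booleanFunction("B", "A")))
  a2 <- findAttractor(sw, c(A = 0L, B = 1L))
  expect_equal(ncol(a2@states), 2L)
  expect_setequal(apply(a2@states, 2L, paste, collapse = ""),
                  c("01", "10"))
  # canonical rotation starts at the lexicographically smallest state
  expect_equal(paste(a2@states[, 1L], collapse = ""), "01")
  expect_true(is.na(a2@collapsed[["A"]]))

  # every reached attractor satisfies the cycle property under the step
  for (seed in 1:10) {
    rm <- randomModel(seed + 60L, nGenes = 9L, nSelf = 2L)
    set.seed(seed)
    a <- findAttractor(rm$model, randomState(rm$model))
    L <- ncol(a@states)
    for (j in seq_len(L)) {
      nxt <- synchronousStep(rm$model, a@states[, j])
      expect_equal(unname(nxt), unname(a@states[, (j %% L) + 1L]))
    }
  }
})

test_that("exhaustive enumeration matches the pointer-doubling oracle", {
  # one gene, identity rule: two fixed points with basins 1 and 1
  idm <- booleanNetwork(list(booleanFunction("A", "A")))
  as1 <- exhaustiveAttractors(idm)
  expect_equal(sort(basinWeights(as1)), c(1L, 1L))
  expect_equal(length(attractors(as1)), 2L)

  # one gene, negation: a single 2-cycle with basin 2
  ng <- booleanNetwork(list(booleanFunction("A", "!A")))
  as2 <- exhaustiveAttractors(ng)
  expect_equal(basinWeights(as2), 2L)
  expect_equal(ncol(maxBasinAttractor(as2)@states), 2L)

  expect_error(exhaustiveAttractors(randomModel(1L, nGenes = 21L)$model),
               "20 genes")

  for (seed in 1:50) {
    rm <- randomModel(seed + 300L, nGenes = 8L, nSelf = seed %% 3L)
    got <- exhaustiveAttractors(rm$model)
    expect_equal(sum(basinWeights(got)), 2L^8)
    oracle <- doublingAttractors(rm$model)
    gotSets <- lapply(attractors(got), attractorKeySet)
    ord <- order(vapply(gotSets, `[`, character(1), 1L))
    oord <- order(vapply(oracle$stateSets, `[`, character(1), 1L))
    expect_identical(gotSets[ord], oracle$stateSets[oord])
    expect_identical(basinWeights(got)[ord], oracle$basins[oord])
  }
})

test_that("sampled attractor sets are deterministic, complete and consistent", {
  # constant model: every start converges to the single attractor
  cm <- booleanNetwork(list(booleanFunction("A", quote(TRUE)),
                            booleanFunction("B", "A")))
  as <- sampleAttractors(cm, nStarts = 100L, seed = 3L)
  expect_length(attractors(as), 1L)
  expect_equal(basinWeights(as), 100L)

  for (seed in 1:10) {
    rm <- randomModel(seed + 80L, nGenes = 9L, nSelf = 2L)
    s1 <- sampleAttractors(rm$model, nStarts = 64L, seed = seed)
    s2 <- sampleAttractors(rm$model, nStarts = 64L, seed = seed)
    # determinism under a fixed seed
    expect_identical(lapply(attractors(s1), attractorKeySet),
                     lapply(attractors(s2), attractorKeySet))
    expect_identical(basinWeights(s1), basinWeights(s2))
    expect_equal(sum(basinWeights(s1)), 64L)
    # sampled attractors are a subset of the exhaustive ones
    ex <- exhaustiveAttractors(rm$model)
    exSets <- lapply(attractors(ex), attractorKeySet)
    for (ks in lapply(attractors(s1), attractorKeySet))
      expect_true(any(vapply(exSets, identical, logical(1), ks)))
  }
})

test_that("overexpression pinning fixes the initial state only", {
  # A holds its initial value; pinning A = 1 selects the on-branch basin
  bn <- booleanNetwork(list(booleanFunction("A", "A"),
                            booleanFunction("B", "A")))
  pin <- sampleAttractors(bn, nStarts = 4L, seed = 1L,
                          pinInitial = c(A = 1L))
  expect_length(attractors(pin), 1L)
  expect_equal(unname(maxBasinAttractor(pin)@collapsed), c(1L, 1L))
  # unlike a clamp, a pinned negated gene still evolves
  ng <- booleanNetwork(list(booleanFunction("A", "!A")))
  p2 <- sampleAttractors(ng, nStarts = 2L, seed = 1L, pinInitial = c(A = 1L))
  expect_equal(ncol(maxBasinAttractor(p2)@states), 2L)
})

test_that("knockdowns classify genes by comparing max-basin attractor states", {
  # knocking a self-sustaining gene with no outgoing edges only downs itself
  pr <- perturbationExperiment(toyModel(), "A", nStarts = 8L, seed = 2L)
  expect_equal(unname(pr@change["A"]), "down-regulated")
  expect_true(all(pr@change[c("B", "C")] == "unchanged"))
  expect_equal(unname(pr@perturbed["A"]), 0L)

  expect_error(perturbationExperiment(toyModel(), character(0)), "empty")
  expect_error(perturbationExperiment(toyModel(), "NOPE"), "NOPE")

  # classification equals the direct vector comparison, and knocked genes
  # never classify as up-regulated
  for (seed in 1:10) {
    rm <- randomModel(seed + 120L, nGenes = 8L, nSelf = 2L)
    kg <- genes(rm$model)[(seed %% 8L) + 1L]
    pr <- perturbationExperiment(rm$model, kg, nStarts = 64L, seed = seed)
    ref <- ifelse(is.na(pr@unperturbed) | is.na(pr@perturbed), "oscillating",
           ifelse(pr@unperturbed == 0L & pr@perturbed == 1L, "up-regulated",
           ifelse(pr@unperturbed == 1L & pr@perturbed == 0L, "down-regulated",
                  "unchanged")))
    expect_identical(unname(pr@change), unname(ref))
    expect_false(pr@change[[kg]] == "up-regulated")
    # determinism: same seed, same result
    pr2 <- perturbationExperiment(rm$model, kg, nStarts = 64L, seed = seed)
    expect_identical(pr@change, pr2@change)
  }
})

test_that("perturbation reports serialize to TSV and JSON", {
  pr <- perturbationExperiment(toyModel(), "A", nStarts = 8L, seed = 2L)
  dir <- withr::local_tempdir()
  paths <- writePerturbationReport(pr, file.path(dir, "kd_A"))
  tab <- read.delim(paths[["tsv"]])
  expect_setequal(tab$gene, genes(toyModel()))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(unlist(js$knocked), "A")
})
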