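test_that("edge lists and annotations survive a write/read round trip", {
  for (seed in 1:200) {
    rm <- randomModel(seed, nGenes = 6L, nSelf = seed %% 3L)
    dir <- withr::local_tempdir()
    writeModel(rm$network, NULL, dir)
    back <- readNetwork(file.path(dir, "edges.tsv"),
                        file.path(dir, "annotations.tsv"))
    expect_identical(back@nodes, rm$network@nodes)
    expect_identical(back@interactions[, c("source", "sign", "target")],
                     rm$network@interactions[, c("source", "sign", "target")])
  }
})

test_that("network reading enforces its contracts", {
  dir <- withr::local_tempdir()
  ann <- file.path(dir, "ann.tsv")
  writeLines(c("gene\tcategory", "A\tpluripotency_tf", "B\tweird"), ann)
  edges <- file.path(dir, "edges.tsv")

  # empty edge list: genes come from the annotations alone
  writeLines("source\tsign\ttarget", edges)
  expect_warning(net <- readNetwork(edges, ann), "weird")
  expect_equal(networkStats(net)$nodes, 2L)
  expect_equal(networkStats(net)$interactions, 0L)
  expect_equal(unname(categories(net)["B"]), "other")

  # duplicate (source, target) rows are a hard error naming the pair
  writeLines(c("source\tsign\ttarget", "A\t+\tB", "A\t-\tB"), edges)
  suppressWarnings(expect_error(readNetwork(edges, ann), "A B"))

  # endpoints absent from the annotations are added as 'other'
  writeLines(c("source\tsign\ttarget", "A\t+\tC"), edges)
  ann2 <- file.path(dir, "ann2.tsv")
  writeLines(c("gene\tcategory", "A\tpluripotency_tf"), ann2)
  expect_warning(net <- readNetwork(edges, ann2), "C")
  expect_equal(unname(categories(net)["C"]), "other")
})

test_that("rule files parse to the expected trees and round-trip as truth tables", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rules.txt")
  writeLines(c("targets, factors", "B, A & !C"), f)
  bn <- readFunctions(f)
  fn <- rules(bn)[["B"]]
  expect_identical(fn@expr, quote(A & !C))
  expect_setequal(inputGenes(bn), c("A", "C"))

  # dimer-style AND rule
  writeLines(c("targets, factors", "NANOG, POU5F1 & SOX2"), f)
  nf <- rules(readFunctions(f))[["NANOG"]]
  expect_identical(truthTable(nf)$output, c(0L, 0L, 0L, 1L))

  # arrow dialect
  writeLines("B <- A | !C", f)
  expect_identical(rules(readFunctions(f))[["B"]]@expr, quote(A | !C))

  # syntax errors carry the line number; duplicate targets are fatal
  writeLines(c("targets, factors", "B, A &"), f)
  expect_error(readFunctions(f), "line 2")
  writeLines(c("B, A", "B, !A"), f)
  expect_error(readFunctions(f), "second rule")

  # parse(write(parse(f))) is truth-table identical to parse(f)
  for (seed in 1:20) {
    rm <- randomModel(seed, nGenes = 6L)
    writeModel(rm$network, rm$model, dir)
    back <- readFunctions(file.path(dir, "rules.txt"))
    expect_setequal(genes(back), genes(rm$model))
    for (g in names(rules(rm$model))) {
      fb <- rules(back)[[g]]
      # a pure self-activation rule reads back as an input gene, whose
      # hold-state dynamics equal the identity rule
      if (is.null(fb)) fb <- booleanFunction(g, as.symbol(g))
      expect_true(BoolGRN:::sameBoolFunction(rules(rm$model)[[g]], fb))
    }
  }
})

test_that("written model files are byte-stable", {
  rm <- randomModel(5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeModel(rm$network, rm$model, d1)
  writeModel(rm$network, rm$model, d2)
  for (f in c("edges.tsv", "annotations.tsv", "rules.txt"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # empty model: files still valid and re-readable
  empty <- signedNetwork(c("A", "B"))
  writeModel(empty, booleanNetwork(list(), genes = c("A", "B")), d1)
  expect_equal(networkStats(readNetwork(file.path(d1, "edges.tsv"),
                                        file.path(d1, "annotations.tsv")))$nodes, 2L)
})

test_that("logic synthesis implements OR-activators vetoed by any inhibitor", {
  net <- signedNetwork(c("A1", "A2", "I1", "B"), data.frame(
    source = c("A1", "A2", "I1"), sign = c("+", "+", "-"), target = "B"))
  fn <- rules(synthesizeLogic(net))[["B"]]
  for (s in 0:7) {
    st <- structure(c(bitwAnd(s, 1L) != 0, bitwAnd(s, 2L) != 0,
                      bitwAnd(s, 4L) != 0), names = c("A1", "A2", "I1"))
    st <- structure(as.integer(st), names = names(st))
    expect_equal(refEval(fn@expr, st), vetoEval(c("A1", "A2"), "I1", st))
  }

  # single activator degenerates to the bare symbol
  net1 <- signedNetwork(c("A", "B"), data.frame(source = "A", sign = "+",
                                                target = "B"))
  expect_identical(rules(synthesizeLogic(net1))[["B"]]@expr, quote(A))

  # dimer members co-regulating a target are AND-joined; hand enumeration
  net2 <- signedNetwork(c("POU5F1", "SOX2", "X", "NANOG"), data.frame(
    source = c("POU5F1", "SOX2", "X"), sign = "+", target = "NANOG"))
  fn2 <- rules(synthesizeLogic(net2))[["NANOG"]]
  tt <- truthTable(fn2, c("POU5F1", "SOX2", "X"))
  expected <- as.integer((tt$POU5F1 & tt$SOX2) | tt$X)
  expect_identical(tt$output, expected)

  # undefined signs must be resolved before synthesis
  net3 <- signedNetwork(c("A", "B"), data.frame(source = "A", sign = "?",
                                                target = "B"))
  expect_error(synthesizeLogic(net3), "undefined")

  # property: random topologies, every regulator combination, k <= 10
  for (seed in 1:10) {
    rm <- randomModel(seed, nGenes = 7L, meanInDegree = 2)
    it <- interactions(rm$network)
    for (g in names(rules(rm$model))) {
      rows <- it[it$target == g, ]
      act <- rows$source[rows$sign == "activation"]
      inh <- rows$source[rows$sign == "inhibition"]
      regs <- sort(unique(c(act, inh)))
      tt <- truthTable(rules(rm$model)[[g]], regs)
      for (r in seq_len(nrow(tt))) {
        st <- structure(as.integer(tt[r, regs]), names = regs)
        expect_equal(tt$output[r], vetoEval(act, inh, st))
      }
    }
  }
})

test_that("network statistics decompose into edges plus self-loops", {
  one <- signedNetwork("A", data.frame(source = "A", sign = "+", target = "A"))
  st <- networkStats(one)
  expect_equal(st$nodes, 1L)
  expect_equal(st$edges, 0L)
  expect_equal(st$selfLoops, 1L)
  expect_equal(st$positiveSelfLoops, 1L)
  expect_equal(st$interactions, 1L)
  for (seed in 1:20) {
    st <- networkStats(randomModel(seed, nSelf = seed %% 4L)$network)
    expect_equal(st$interactions, st$edges + st$selfLoops)
  }
})

test_that("pruning returns the induced subnetwork", {
  big <- generateTopology(synthConfig(nGenes = 122L, meanInDegree = 1.3,
                                      nSelfActivation = 4L, seed = 11L))
  set.seed(12L)
  keep <- sort(sample(genes(big), 45L))
  sub <- pruneToGenes(big, keep)
  expect_equal(networkStats(sub)$nodes, 45L)
  it <- interactions(big)
  manual <- it[it$source %in% keep & it$target %in% keep, ]
  expect_equal(nrow(interactions(sub)), nrow(manual))
  expect_setequal(paste(interactions(sub)$source, interactions(sub)$target),
                  paste(manual$source, manual$target))
  # identity and error cases
  expect_identical(interactions(pruneToGenes(big, genes(big))),
                   interactions(big))
  expect_error(pruneToGenes(big, c(keep, "NOPE")), "NOPE")
})

test_that("network integration adds novel edges, resolves signs, keeps originals on conflict", {
  gs <- c("A", "B", "C", "D")
  orig <- signedNetwork(gs, data.frame(
    source = c("A", "A", "B"), sign = c("+", "?", "-"),
    target = c("B", "C", "C")))
  inf <- signedNetwork(gs, data.frame(
    source = c("A", "A", "B", "C"), sign = c("-", "-", "-", "+"),
    target = c("B", "C", "C", "D"), provenance = "inferred"))
  expect_message(merged <- integrateNetworks(orig, inf), "conflict")
  it <- interactions(merged)
  row <- function(s, t) it[it$source == s & it$target == t, ]
  expect_equal(row("A", "B")$sign, "activation")      # conflict: original kept
  expect_equal(row("A", "C")$sign, "inhibition")      # undefined resolved
  expect_equal(row("C", "D")$provenance, "inferred")  # novel edge
  expect_equal(nrow(attr(merged, "conflicts")), 1L)
  # brute-force union over enumerated pairs
  expect_setequal(paste(it$source, it$target),
                  union(paste(orig@interactions$source, orig@interactions$target),
                        paste(inf@interactions$source, inf@interactions$target)))
  # idempotence and monotonicity
  again <- integrateNetworks(merged, merged)
  expect_identical(interactions(again), interactions(merged))
  expect_true(all(paste(orig@interactions$source, orig@interactions$target)
                  %in% paste(it$source, it$target)))
})
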