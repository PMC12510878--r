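# Grammar construction, parameter handling, the motif probability split,
# training by counting, and sampling.

test_that("loop probability split conserves mass and matches worked examples", {
  s <- splitLoopProbability(0.3475, 0.4, 15)
  expect_equal(round(s$generic, 4), 0.2085)
  expect_equal(round(s$perMotif, 4), 0.0093)
  expect_equal(s$generic + 15 * s$perMotif, 0.3475, tolerance = 1e-12)
  expect_equal(splitLoopProbability(0.7, 0, 5), list(generic = 0.7, perMotif = 0))
  expect_equal(splitLoopProbability(0.7, 0.4, 0), list(generic = 0.7, perMotif = 0))
  s2 <- splitLoopProbability(0.5, 0.5, 2)
  expect_equal(s2$generic, 0.25)
  expect_equal(s2$perMotif, 0.125)
})

test_that("built grammars have normalized rules and the documented sizes", {
  p <- defaultFoldParams()
  for (tr in p@transitions) expect_equal(sum(tr), 1, tolerance = 1e-9)
  g0 <- buildRbgj3j4(p)
  expect_equal(nonterminalCount(g0), 11L)
  vs <- smallMotifVariants()
  g1 <- buildR3dGrammar(vs, p)
  expect_equal(nonterminalCount(g1), 11L + length(vs))
  # the split leaves the total mass out of each loop rule unchanged
  rp <- RNAMotifFold:::.effectiveRuleProbs(g1)
  for (slot in c("hairpin", "bulgeL", "bulgeR", "internal")) {
    tot <- exp(rp[[slot]]$gen) + sum(exp(rp[[slot]]$motif))
    expect_equal(tot, unname(p@transitions$P[[sub("bulgeL", "bulgeL",
      slot)]]), tolerance = 1e-12)
  }
  expect_equal(exp(rp$J3$gen) + sum(exp(rp$J3$motif)), 1, tolerance = 1e-12)
})

test_that("default multiloop split follows the trained junction frequencies", {
  p <- defaultFoldParams()
  ml <- p@transitions$P[c("J3", "J4", "JN")]
  expect_equal(unname(ml / sum(ml)), c(0.51, 0.32, 0.17), tolerance = 1e-9)
  expect_equal(unname(p@transitions$P[["hairpin"]]), 0.3475)
})

test_that("a grammar with zero four-way junction mass never emits one", {
  p <- foldParams(transitions = list(
    S = c(aS = 0.4, F0S = 0.2, end = 0.4),
    F0 = c(pairF5 = 0.6, pairP = 0.4),
    F5 = c(pairF5 = 0.6, pairP = 0.4),
    P = c(hairpin = 0.55, bulgeL = 0.1, bulgeR = 0.1, internal = 0.15,
          J3 = 0.06, J4 = 0, J5plus = 0.04),
    M1 = c(more = 0.3, last = 0.7)))
  nJ4 <- 0L; nJ3 <- 0L
  for (k in seq_len(1e4)) {
    cnt <- countJunctions(sampleDerivation(p, seed = k)$tree)
    nJ4 <- nJ4 + cnt[["J4"]]; nJ3 <- nJ3 + cnt[["J3"]]
  }
  expect_equal(nJ4, 0L)
  expect_gt(nJ3, 0L)  # the sampler does reach junctions
})

test_that("training by counting matches the pseudocount arithmetic", {
  # two helices of exactly two stacked pairs: F0 -> aF5a' used twice,
  # F0 -> aPa' never; with +1 pseudocounts p(pairF5) = (2+1)/(2+1+0+1)
  ex <- list(seq = "GGAAACCGGUUUCC", db = "((...))((...))")
  tree <- structureToParse(ex$seq, ex$db)
  p <- trainByCounting(list(list(seq = ex$seq, tree = tree)))
  expect_equal(unname(p@transitions$F0[["pairF5"]]), 0.75)
  # structures without multiloops leave junction rules at the floor
  expect_equal(unname(p@transitions$P[["J3"]]),
               unname(p@transitions$P[["J4"]]))
  expect_equal(unname(p@transitions$P[["J3"]]), 1 / (2 + 7), tolerance = 1e-12)
  # empty training set: uniform with a warning
  expect_warning(p0 <- trainByCounting(list()), "empty training set")
  expect_equal(unname(p0@transitions$F0), c(0.5, 0.5))
})

test_that("parameters recover from sampled derivations", {
  p <- defaultFoldParams()
  n <- 2000L
  ex <- vector("list", n)
  for (k in seq_len(n)) {
    s <- sampleSafe(p, 5000 + k)
    ex[[k]] <- list(seq = s$seq, tree = s$tree)
  }
  ph <- trainByCounting(ex)
  for (nt in names(p@transitions)) {
    expect_lt(max(abs(ph@transitions[[nt]] - p@transitions[[nt]])), 0.03,
              label = paste("transition recovery for", nt))
  }
})

test_that("parameter JSON round trip is bit-exact", {
  p <- defaultFoldParams()
  f <- tempfile(fileext = ".json")
  writeParamsJSON(p, f)
  p2 <- readParamsJSON(f)
  expect_identical(p@transitions, p2@transitions)
  expect_identical(p@eSingle, p2@eSingle)
  expect_identical(unname(p@ePair), unname(p2@ePair))
  expect_identical(unname(p@eStack), unname(p2@eStack))
  expect_identical(p@runGeom, p2@runGeom)
  expect_identical(p@classFractions, p2@classFractions)
})

test_that("inside probability is continuous as motif mass vanishes", {
  cf <- c(HL = 1e-6, BL = 1e-6, IL = 1e-6, J3 = 1e-6, J4 = 1e-6, BS = 1e-6)
  base <- defaultFoldParams()
  pEps <- foldParams(transitions = base@transitions, eSingle = base@eSingle,
                     ePair = base@ePair, eStack = base@eStack,
                     runGeom = base@runGeom, classFractions = cf)
  g0 <- buildRbgj3j4(base)
  g1 <- buildR3dGrammar(smallMotifVariants(), pEps)
  set.seed(12)
  for (k in 1:5) {
    pa <- probAlignmentFromSequence(randRNA(sample(6:10, 1)))
    expect_equal(insideLogProb(pa, g1), insideLogProb(pa, g0),
                 tolerance = 1e-4)
  }
})
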