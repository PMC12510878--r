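# Constrained CYK / inside engine: oracle agreement on small cases,
# constraint handling, traceback round trips, and scaling.

test_that("CYK and inside agree with exhaustive enumeration (spot checks)", {
  p <- defaultFoldParams()
  g0 <- buildRbgj3j4(p)
  g1 <- buildR3dGrammar(smallMotifVariants(), p)
  set.seed(31)
  seqs <- c("GCGAAAGC", "GGCGAAAGCC", replicate(6, randRNA(sample(4:8, 1))))
  for (seq in seqs) for (g in list(g0, g1)) {
    pa <- probAlignmentFromSequence(seq)
    en <- enumerateDerivations(pa, g)
    expect_equal(parseLogProb(foldCYK(pa, g)), max(en$lpMax),
                 tolerance = 1e-9, label = paste("CYK", seq))
    expect_equal(insideLogProb(pa, g), logSumExp(en$lpSum),
                 tolerance = 1e-9, label = paste("inside", seq))
  }
})

test_that("inside is never below the CYK optimum", {
  p <- defaultFoldParams()
  g <- buildR3dGrammar(smallMotifVariants(), p)
  set.seed(32)
  for (k in 1:15) {
    pa <- probAlignmentFromSequence(randRNA(sample(5:14, 1)))
    expect_gte(insideLogProb(pa, g) + 1e-12, parseLogProb(foldCYK(pa, g)))
  }
})

test_that("forced pairs appear and forbidden pairs never do", {
  p <- defaultFoldParams()
  g <- buildRbgj3j4(p)
  pa <- probAlignmentFromSequence("GGGAAACCC")
  forced <- rbind(c(1, 9), c(2, 8), c(3, 7))
  res <- foldCYK(pa, g, foldConstraints(forced = forced))
  got <- pairLayers(res)[[1]]
  expect_true(all(paste(forced[, 1], forced[, 2]) %in%
                  paste(got[, 1], got[, 2])))
  res2 <- foldCYK(pa, g, foldConstraints(forbidden = rbind(c(1, 9))))
  got2 <- pairLayers(res2)[[1]]
  expect_false("1 9" %in% paste(got2[, 1], got2[, 2]))
  # constrained optimum still matches the constrained enumeration
  cs <- foldConstraints(forced = rbind(c(1, 9)))
  en <- enumerateDerivations(pa, g, cs)
  expect_equal(parseLogProb(foldCYK(pa, g, cs)), max(en$lpMax),
               tolerance = 1e-9)
})

test_that("infeasible constraints raise explicit errors", {
  p <- defaultFoldParams()
  g <- buildRbgj3j4(p)
  pa <- probAlignmentFromSequence("GGGAAACCC")
  expect_error(foldCYK(pa, g, foldConstraints(forced = rbind(c(3, 3)))),
               "single column")
  expect_error(foldCYK(pa, g, foldConstraints(forced = rbind(c(1, 9), c(1, 8)))),
               "two forced pairs")
  expect_error(foldCYK(pa, g, foldConstraints(forced = rbind(c(1, 5), c(3, 8)))),
               "cross")
  expect_error(foldCYK(pa, g, foldConstraints(forced = rbind(c(1, 9)),
                                              forbidden = rbind(c(1, 9)))),
               "forbidden")
  # a forced pair too tight to close any loop is unsatisfiable
  expect_error(foldCYK(pa, g, foldConstraints(forced = rbind(c(4, 5)))),
               "unsatisfiable")
})

test_that("a planted tetraloop is called with exact loop ends", {
  p <- defaultFoldParams()
  g <- buildR3dGrammar(smallMotifVariants(), p)
  pa <- probAlignmentFromSequence("GGGGAAACCC")
  cs <- foldConstraints(forced = rbind(c(1, 10), c(2, 9), c(3, 8)))
  res <- foldCYK(pa, g, cs)
  calls <- motifCalls(res)
  expect_true("GNRA" %in% calls$name)
  expect_equal(calls$start[calls$name == "GNRA"], 4L)
  expect_equal(calls$end[calls$name == "GNRA"], 7L)
  # verified against the enumeration oracle
  en <- enumerateDerivations(pa, g, cs)
  top <- en[which.max(en$lpMax), ]
  expect_match(top$motifs, "GNRA")
  expect_equal(parseLogProb(res), max(en$lpMax), tolerance = 1e-9)
})

test_that("adding a motif does not hurt instances carrying its consensus", {
  p <- defaultFoldParams()
  g0 <- buildR3dGrammar(list(), p)
  g1 <- buildR3dGrammar(smallMotifVariants(), p)
  pa <- probAlignmentFromSequence("GGGGAAACCC")
  cs <- foldConstraints(forced = rbind(c(1, 10), c(2, 9), c(3, 8)))
  expect_gte(parseLogProb(foldCYK(pa, g1, cs)),
             parseLogProb(foldCYK(pa, g0, cs)))
})

test_that("traceback rescoring reproduces the CYK optimum", {
  p <- defaultFoldParams()
  g <- buildR3dGrammar(smallMotifVariants(), p)
  set.seed(33)
  for (k in 1:10) {
    pa <- probAlignmentFromSequence(randRNA(sample(8:20, 1)))
    res <- foldCYK(pa, g)
    expect_equal(rescoreParse(attr(res, "tree"), pa, g), parseLogProb(res),
                 tolerance = 1e-9)
    # layer-1 pairs are well-formed: nested, no shared positions
    pr <- pairLayers(res)[[1]]
    if (nrow(pr) > 1) {
      expect_false(any(duplicated(as.vector(pr))))
      for (a in 1:(nrow(pr) - 1)) for (b in (a + 1):nrow(pr)) {
        i1 <- pr[a, 1]; j1 <- pr[a, 2]; i2 <- pr[b, 1]; j2 <- pr[b, 2]
        crossing <- (i1 < i2 && i2 < j1 && j1 < j2) ||
                    (i2 < i1 && i1 < j2 && j2 < j1)
        expect_false(crossing)
      }
    }
  }
})

test_that("folding an S = 1 alignment equals folding the literal sequence", {
  p <- defaultFoldParams()
  g <- buildR3dGrammar(smallMotifVariants(), p)
  seq <- "GGGGAAACCCAUGGCGAAAGCC"
  paSeq <- probAlignmentFromSequence(seq)
  paAln <- buildProbAlignment(rnaMSA("only", seq))
  expect_equal(parseLogProb(foldCYK(paSeq, g)), parseLogProb(foldCYK(paAln, g)),
               tolerance = 1e-12)
  expect_equal(insideLogProb(paSeq, g), insideLogProb(paAln, g),
               tolerance = 1e-12)
})

test_that("layer grammar extends a forced lone pair into its helix", {
  p <- defaultFoldParams()
  gl <- buildLayerGrammar(p)
  pa <- probAlignmentFromSequence("GGGAAACCC")
  lr <- foldLayer(pa, gl, foldConstraints(forced = rbind(c(2, 8))))
  got <- paste(lr$pairs[, 1], lr$pairs[, 2])
  expect_true("2 8" %in% got)
  # stacking-aware extension of the same helix
  expect_true(all(got %in% c("1 9", "2 8", "3 7")))
})

test_that("runtime grows at most cubically with length (trend)", {
  p <- defaultFoldParams()
  g <- buildR3dGrammar(suppressMessages(expandVariants(builtinMotifLibrary())), p)
  set.seed(34)
  times <- vapply(c(40, 80, 160), function(L) {
    pa <- probAlignmentFromSequence(randRNA(L))
    t0 <- proc.time()[3]
    foldCYK(pa, g)
    proc.time()[3] - t0
  }, numeric(1))
  # doubling the length may grow cost ~8x; allow generous slack for noise
  expect_lt(times[2] / max(times[1], 0.05), 16)
  expect_lt(times[3] / max(times[2], 0.05), 16)
})
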