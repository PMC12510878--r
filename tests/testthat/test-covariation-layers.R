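# Covariation evidence, layer decomposition, multilayer folding, motif
# support flags and FDR arithmetic.

test_that("pair TSV reading validates and filters", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("i\tj\tE\tclass", "3\t20\t0.001\tpositive",
               "5\t18\t0.02\tpositive", "4\t9\t1\tnegative"), f)
  ps <- readPairsTSV(f)
  expect_equal(nrow(positivePairs(ps)), 2)
  expect_equal(nrow(negativePairs(ps)), 1)
  # pair on a gap-filtered column is dropped with a warning
  msa <- rnaMSA(paste0("s", 1:4), c("GGGA-AACCCAAAAAAAAAA",
                                    "GGGA-AACCCAAAAAAAAAA",
                                    "GGGA-AACCCAAAAAAAAAA",
                                    "GGGA-AACCCAAAAAAAAAA"))
  pa <- buildProbAlignment(msa)
  f2 <- tempfile()
  writeLines(c("3\t20\t0.001\tpositive", "5\t18\t0.02\tpositive"), f2)
  expect_warning(ps2 <- readPairsTSV(f2, pa), "dropped")
  expect_equal(nrow(positivePairs(ps2)), 1)
  # duplicates and malformed rows fail
  f3 <- tempfile()
  writeLines(c("3\t20\t0.001\tpositive", "3\t20\t0.01\tpositive"), f3)
  expect_error(readPairsTSV(f3), "duplicate")
  f4 <- tempfile(); writeLines("3\t20\txx\tpositive", f4)
  expect_error(readPairsTSV(f4), "line 1")
})

test_that("layer decomposition matches the worked examples", {
  l1 <- decomposeLayers(rbind(c(1, 10), c(2, 9), c(3, 8)))
  expect_length(l1, 1)
  l2 <- decomposeLayers(rbind(c(1, 5), c(3, 8)))
  expect_length(l2, 2)
  expect_equal(unname(l2[[1]]), rbind(c(1L, 5L)))   # lexicographic tie-break
  # union equals input, layers are disjoint and nested within themselves
  pairs <- rbind(c(1, 20), c(2, 19), c(5, 25), c(6, 24), c(3, 18))
  ls <- decomposeLayers(pairs)
  all <- do.call(rbind, ls)
  expect_setequal(paste(all[, 1], all[, 2]), paste(pairs[, 1], pairs[, 2]))
  for (m in ls) if (nrow(m) > 1)
    for (a in 1:(nrow(m) - 1)) for (b in (a + 1):nrow(m)) {
      i1 <- m[a, 1]; j1 <- m[a, 2]; i2 <- m[b, 1]; j2 <- m[b, 2]
      expect_false((i1 < i2 && i2 < j1 && j1 < j2) ||
                   (i2 < i1 && i1 < j2 && j2 < j1))
    }
})

test_that("layer-1 cardinality equals the exhaustive maximum (random sets)", {
  set.seed(41)
  for (trial in 1:60) {
    n <- sample(2:12, 1)
    pairs <- unique(t(replicate(n, sort(sample.int(16, 2)))))
    ls <- decomposeLayers(pairs)
    expect_equal(nrow(ls[[1]]), maxNestedBrute(pairs),
                 label = paste("trial", trial))
  }
})

test_that("the stand-in statistic recovers planted covariation and stays calibrated", {
  spec <- plantSpec(nSeq = 50, length = 46,
    helices = data.frame(i5 = c(3, 14), j3 = c(44, 33), len = c(10, 5),
                         rate = 1),
    seed = 42)
  ga <- generateAlignment(spec)
  ps <- suppressMessages(covariationStandin(ga$msa, nShuffles = 100,
                                            seed = 43))
  tk <- paste(ga$truth$pairs[, 1], ga$truth$pairs[, 2])
  ck <- paste(positivePairs(ps)[, 1], positivePairs(ps)[, 2])
  expect_true(all(tk %in% ck))
  # fully conserved alignment: no variation, no positives
  cons <- rnaMSA(paste0("s", 1:10), rep("GGGAAACCCUUUAUGC", 10))
  ps0 <- suppressMessages(covariationStandin(cons, nShuffles = 30, seed = 44))
  expect_equal(nrow(positivePairs(ps0)), 0)
  # a shuffled (null) query yields about the expected false positive count
  sh <- shuffleColumns(ga$msa, 45)
  psN <- suppressMessages(covariationStandin(sh, nShuffles = 60, seed = 46))
  expect_lte(nrow(positivePairs(psN)), 3)
})

test_that("multilayer folding places all positives and respects negatives", {
  p <- defaultFoldParams()
  g <- buildR3dGrammar(smallMotifVariants(), p)
  seq <- "GGGAAGCGAAAGCUAAACCCAAAUUGAAU"
  pa <- probAlignmentFromSequence(seq)
  pos <- rbind(c(1, 20), c(2, 19), c(3, 18), c(10, 25))
  neg <- rbind(c(5, 15))
  lay <- decomposeLayers(pos)
  expect_length(lay, 2)
  res <- suppressMessages(foldMultilayer(pa, g, layers = lay,
                                         negatives = neg))
  expect_length(pairLayers(res), 2)
  got <- unlist(lapply(pairLayers(res), function(m) paste(m[, 1], m[, 2])))
  expect_true(all(paste(pos[, 1], pos[, 2]) %in% got))
  expect_false("5 15" %in% got)
  # a positive that is also negative is infeasible
  expect_error(
    foldMultilayer(pa, g, layers = lay, negatives = rbind(c(1, 20))),
    "infeasible")
  # without positives: a single unconstrained layer
  res0 <- foldCYK(pa, g)
  expect_length(pairLayers(res0), 1)
})

test_that("motif support follows the bounding-helix rule", {
  p <- defaultFoldParams()
  g <- buildR3dGrammar(smallMotifVariants(), p)
  pa <- probAlignmentFromSequence("GGGGAAACCC")
  pos <- rbind(c(1, 10), c(2, 9), c(3, 8))
  res <- foldMultilayer(pa, g, layers = decomposeLayers(pos))
  res <- annotateSupport(res, pairSet(cbind(pos, 0.001)))
  calls <- motifCalls(res)
  expect_true(all(calls$supported[calls$name == "GNRA"]))
  # empty positive set: nothing is supported
  res2 <- annotateSupport(res, pairSet(NULL, NULL))
  expect_false(any(motifCalls(res2)$supported))
  # a junction motif supported only through its third enclosed helix:
  # constructed parse with explicit bounding pairs
  calls3 <- data.frame(name = "j3x", class = "J3", variant = 1L,
                       start = 10L, end = 40L, logScore = -1,
                       supported = NA, segments = "")
  calls3$bounding <- I(list(list(c(9, 41), c(12, 20), c(22, 30), c(32, 38))))
  pr <- new("ParseResult",
            layers = list(rbind(c(9L, 41L), c(32L, 38L), c(33L, 37L))),
            motifCalls = calls3, logProb = 0, L = 50L,
            keptColumns = 1:50)
  sup <- annotateSupport(pr, pairSet(rbind(c(33, 37, 0.01))))
  expect_true(motifCalls(sup)$supported[1])
  sup2 <- annotateSupport(pr, pairSet(rbind(c(2, 5, 0.01))))
  expect_false(motifCalls(sup2)$supported[1])
})

test_that("FDR arithmetic matches the control-count definitions", {
  r <- fdrReport(1460, 2124, 121, 290, threshold = 0.05,
                 nCtrlHelices = 14146)
  expect_equal(round(r$fdrSupported, 1), 8.3)
  expect_equal(r$fdrUnsupported, 100 * 169 / 664, tolerance = 1e-12)
  expect_equal(r$nullHelixExpect, 707.3)
  r0 <- fdrReport(10, 20, 0, 0)
  expect_equal(r0$fdrSupported, 0)
  r1 <- fdrReport(0, 0, 0, 0)
  expect_true(is.na(r1$fdrSupported))
  expect_true(is.na(r1$fdrUnsupported))
})
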