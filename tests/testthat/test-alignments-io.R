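# Alignment I/O, the probabilistic-sequence representation, and column
# shuffling.

toyStockholm <- function(rows, ids = paste0("s", seq_along(rows)),
                         ss = NULL) {
  f <- tempfile(fileext = ".sto")
  lines <- c("# STOCKHOLM 1.0", paste(ids, rows))
  if (!is.null(ss)) lines <- c(lines, paste("#=GC SS_cons", ss))
  writeLines(c(lines, "//"), f)
  f
}

test_that("Stockholm reading, writing and error handling work", {
  f <- toyStockholm(c("GGGAAACCCU", "GGGAAACCCU"), ss = "<<<....>>>")
  msa <- readStockholm(f)
  expect_s4_class(msa, "RnaMSA")
  expect_equal(nSeq(msa), 2L)
  expect_equal(alnLength(msa), 10L)
  expect_equal(ssCons(msa), "<<<....>>>")

  out <- tempfile(fileext = ".sto")
  writeStockholm(msa, out)
  msa2 <- readStockholm(out)
  expect_equal(seqIds(msa2), seqIds(msa))
  expect_equal(alnRows(msa2), alnRows(msa))
  expect_equal(ssCons(msa2), ssCons(msa))

  ragged <- toyStockholm(c("GGGAAACCCU", "GGGAAA"))
  expect_error(readStockholm(ragged), "ragged")
  empty <- tempfile(); writeLines("# STOCKHOLM 1.0", empty)
  expect_error(readStockholm(empty), "no sequences")
  notsto <- tempfile(); writeLines("GGGAAACCC", notsto)
  expect_error(readStockholm(notsto), "STOCKHOLM")
})

test_that("residues are normalized on ingest (T -> U, gap characters, case)", {
  msa <- rnaMSA(c("a", "b"), c("ggt.a", "GGU_~"))
  expect_equal(alnRows(msa), c("GGU-A", "GGU--"))
})

test_that("FASTA input becomes an S = 1 alignment", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">seq1 some description", "GGGAAA", "CCC"), f)
  msa <- readFastaMSA(f)
  expect_equal(nSeq(msa), 1L)
  expect_equal(alnRows(msa), "GGGAAACCC")
})

test_that("probabilistic alignment frequencies follow direct counts", {
  msa <- rnaMSA(paste0("s", 1:4), c("AAGA", "AAG-", "GAGC", "GAGU"))
  pa <- buildProbAlignment(msa)
  sf <- singleFreq(pa)
  expect_equal(unname(sf[, 2]), c(1, 0, 0, 0))             # column "AAAA"
  expect_equal(unname(sf[, 1]), c(0.5, 0, 0.5, 0))         # column "AAGG"
  expect_true(all(abs(colSums(sf) - 1) < 1e-9))
  # pair frequencies from sequences ungapped at both columns
  msa2 <- rnaMSA(paste0("s", 1:3), c("AU", "AU", "GC"))
  pa2 <- buildProbAlignment(msa2)
  pf <- pairFreq(pa2, 1, 2)
  expect_equal(pf["A", "U"], 2 / 3)
  expect_equal(pf["G", "C"], 1 / 3)
  expect_equal(sum(pf), 1)
  # marginals of the joint equal the single frequencies on ungapped data
  expect_equal(unname(rowSums(pf)), unname(singleFreq(pa2)[, 1]))
  expect_equal(unname(colSums(pf)), unname(singleFreq(pa2)[, 2]))
})

test_that("columns beyond the gap threshold are removed", {
  rows <- c(rep("A-", 2), rep("--", 8))  # col 1: 80% gaps; col 2: 100%
  msa <- rnaMSA(paste0("s", 1:10), rows)
  pa <- buildProbAlignment(msa, gapMax = 0.75)
  expect_equal(length(keptColumns(pa)), 0L)
  rows2 <- c(rep("AA", 3), rep("-A", 7))  # col 1: 70% gaps
  pa2 <- buildProbAlignment(rnaMSA(paste0("s", 1:10), rows2))
  expect_equal(keptColumns(pa2), c(1L, 2L))
  # a retained all-gap column (gapMax = 1) becomes uniform, with a message
  expect_message(
    pa3 <- buildProbAlignment(rnaMSA(c("a", "b"), c("A-", "A-")), gapMax = 1),
    "all gaps")
  expect_equal(unname(singleFreq(pa3)[, 2]), rep(0.25, 4))
})

test_that("ambiguity codes spread mass uniformly over their residue sets", {
  pa <- buildProbAlignment(rnaMSA("a", "RNY"))
  expect_equal(unname(singleFreq(pa)[, 1]), c(0.5, 0, 0.5, 0))
  expect_equal(unname(singleFreq(pa)[, 2]), rep(0.25, 4))
  expect_equal(unname(singleFreq(pa)[, 3]), c(0, 0.5, 0, 0.5))
})

test_that("a single sequence yields point-mass distributions", {
  pa <- probAlignmentFromSequence("GAUC")
  expect_equal(unname(apply(singleFreq(pa), 2, max)), rep(1, 4))
})

test_that("column shuffling preserves per-column composition, deterministically", {
  msa <- rnaMSA(paste0("s", 1:6),
                c("GGGAAACCC", "GGGUUUCCC", "CCCAAAGGG",
                  "AUGCAUGCA", "GGGGGGGGG", "UUUCCCAAA"))
  sh <- shuffleColumns(msa, 7)
  m0 <- do.call(rbind, strsplit(alnRows(msa), ""))
  m1 <- do.call(rbind, strsplit(alnRows(sh), ""))
  for (j in 1:9) expect_equal(sort(m0[, j]), sort(m1[, j]))
  expect_identical(alnRows(shuffleColumns(msa, 7)), alnRows(sh))
})

test_that("shuffling destroys covariation: joint approaches marginal product", {
  spec <- plantSpec(nSeq = 200, length = 10,
                    helices = data.frame(i5 = 2, j3 = 9, len = 1, rate = 1),
                    seed = 21)
  ga <- generateAlignment(spec)
  pa0 <- buildProbAlignment(ga$msa)
  pf0 <- pairFreq(pa0, 2, 9)
  # planted column pair is strongly dependent ...
  dep0 <- max(abs(pf0 - outer(singleFreq(pa0)[, 2], singleFreq(pa0)[, 9])))
  expect_gt(dep0, 0.1)
  # ... and near-independent after shuffling
  pa1 <- buildProbAlignment(shuffleColumns(ga$msa, 5))
  pf1 <- pairFreq(pa1, 2, 9)
  dep1 <- max(abs(pf1 - outer(singleFreq(pa1)[, 2], singleFreq(pa1)[, 9])))
  expect_lt(dep1, 0.1)
})
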