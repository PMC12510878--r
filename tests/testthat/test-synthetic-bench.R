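# Planted-alignment generation and prediction scoring.

test_that("zero compensatory rate gives perfectly conserved paired columns", {
  spec <- plantSpec(nSeq = 30, length = 20,
                    helices = data.frame(i5 = 3, j3 = 18, len = 4, rate = 0),
                    seed = 51)
  ga <- generateAlignment(spec)
  m <- do.call(rbind, strsplit(alnRows(ga$msa), ""))
  for (cl in c(3:6, 15:18)) expect_length(unique(m[, cl]), 1)
  # and the planted pairs are canonical
  for (r in seq_len(nrow(ga$truth$pairs))) {
    a <- m[1, ga$truth$pairs[r, 1]]; b <- m[1, ga$truth$pairs[r, 2]]
    expect_true(paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG"))
  }
})

test_that("generation is byte-identical for a fixed seed", {
  spec <- plantSpec(nSeq = 10, length = 30,
                    helices = data.frame(i5 = 2, j3 = 28, len = 5, rate = 0.5),
                    seed = 52)
  expect_identical(alnRows(generateAlignment(spec)$msa),
                   alnRows(generateAlignment(spec)$msa))
})

test_that("planted pairs outrank background pairs under the covariation statistic", {
  # perfectly covarying planted pairs (every sequence draws its own
  # canonical pair) separate cleanly from background at S = 50
  spec <- plantSpec(nSeq = 50, length = 24,
                    helices = data.frame(i5 = 4, j3 = 21, len = 4, rate = 1),
                    seed = 53)
  ga <- generateAlignment(spec)
  mi <- RNAMotifFold:::.apcMI(ga$msa, 1:24)
  tk <- ga$truth$pairs
  planted <- mi[tk]
  mask <- upper.tri(mi)
  mask[tk] <- FALSE
  expect_gt(min(planted), max(mi[mask]))
})

test_that("overlapping plants are rejected", {
  expect_error(plantSpec(length = 20,
    helices = data.frame(i5 = c(2, 4), j3 = c(18, 16), len = c(4, 4),
                         rate = 0.5)), "overlapping")
})

test_that("prediction scoring demands exact name and end matches", {
  truth <- data.frame(name = c("GNRA", "K-turn", "GNRA"),
                      start = c(5, 20, 40), end = c(8, 34, 43))
  callsAll <- truth
  s <- scorePredictions(callsAll, truth)
  expect_equal(s$sensitivity, 100)
  expect_equal(s$fpPerSequence, 0)
  # 2 of 3 found, one spurious call, spread over 10 inputs
  calls <- list(truth[1:2, ],
                data.frame(name = "GNRA", start = 11, end = 14))
  calls <- c(calls, replicate(8, NULL))
  truths <- c(list(truth), replicate(9, NULL))
  s2 <- scorePredictions(calls, truths)
  expect_equal(s2$sensitivity, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(s2$fpPerSequence, 0.1)
  # off-by-one end is not a find (and counts as a false positive)
  off <- data.frame(name = "GNRA", start = 5, end = 9)
  s3 <- scorePredictions(off, truth[1, ])
  expect_equal(s3$sensitivity, 0)
  expect_equal(s3$fpPerSequence, 1)
})

test_that("truth sets write to a readable TSV", {
  spec <- plantSpec(nSeq = 5, length = 20,
                    helices = data.frame(i5 = 2, j3 = 18, len = 3, rate = 0.5),
                    motifs = list(list(name = "GNRA", consensus = "GAAA",
                                       start = 8, end = 11, mutRate = 0)),
                    seed = 54)
  ga <- generateAlignment(spec)
  f <- tempfile(fileext = ".tsv")
  writeTruthTSV(ga$truth, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^pair", lines)), 3)
  expect_equal(sum(grepl("^motif", lines)), 1)
})
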