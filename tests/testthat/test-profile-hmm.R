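# Profile HMM construction, expected length, and forward scoring.

test_that("match emissions follow the mismatch rule for all class sizes", {
  h <- buildPHMM("URA")
  expect_equal(unname(h@matchEmissions["U", 1]), 0.9997)
  expect_equal(unname(h@matchEmissions["A", 1]), 0.0001)
  expect_equal(unname(h@matchEmissions["A", 2]), 0.4999)
  expect_equal(unname(h@matchEmissions["G", 2]), 0.4999)
  expect_equal(unname(h@matchEmissions["C", 2]), 0.0001)
  # class sizes 3 and 4
  h2 <- buildPHMM("VN")
  expect_equal(unname((h2@matchEmissions[c("A", "C", "G"), 1])),
               rep((1 - 1e-4) / 3, 3))
  expect_equal(unname(h2@matchEmissions[, 2]), rep(0.25, 4))
  expect_true(all(abs(colSums(h2@matchEmissions) - 1) < 1e-9))
  expect_error(buildPHMM("AXZ"), "invalid consensus")
})

test_that("analytic expected length equals the target rule", {
  for (Lc in c(1, 2, 3, 5, 10, 14, 15, 16, 20, 40)) {
    h <- buildPHMM(strrep("A", Lc))
    expect_equal(expectedLength(h), Lc + min(0.1 * Lc, 1.5), tolerance = 1e-6)
  }
  expect_equal(expectedLength(buildPHMM("URA")), 3.3, tolerance = 1e-6)
  expect_equal(expectedLength(buildPHMM(strrep("N", 20))), 21.5,
               tolerance = 1e-6)
  expect_equal(expectedLength(buildPHMM("A")), 1.1, tolerance = 1e-6)
  # empty consensus keeps a reachable insert path
  expect_equal(expectedLength(buildPHMM("")), 0.5, tolerance = 1e-6)
})

test_that("column-mixture emission reduces correctly on mixed and point columns", {
  h <- buildPHMM("R")
  colAG <- matrix(c(0.5, 0, 0.5, 0), 4, 1)
  # single match emission factor 0.5*0.4999 + 0.5*0.4999
  direct <- exp(phmmForward(h, colAG))
  # compare against replacing the emission by the literal mixture value:
  # same path structure as scoring "A", with emission 0.4999 in both cases
  expect_equal(direct, exp(phmmForward(h, "A")), tolerance = 1e-12)
  # point-mass equivalence on a longer model
  h3 <- buildPHMM("URA")
  cols <- vapply(c("U", "G", "A"), function(ch) {
    v <- numeric(4); names(v) <- c("A", "C", "G", "U"); v[ch] <- 1; v
  }, numeric(4))
  expect_equal(phmmForward(h3, cols), phmmForward(h3, "UGA"),
               tolerance = 1e-12)
})

test_that("forward equals brute-force path enumeration on small models", {
  models <- lapply(c("", "A", "R", "URA"), buildPHMM)
  alph <- c("A", "C", "G", "U")
  segs <- c("", alph,
            apply(expand.grid(alph, alph), 1, paste, collapse = ""),
            apply(expand.grid(alph, alph, alph), 1,
                  paste, collapse = ""))
  for (h in models) for (s in segs) {
    expect_equal(phmmForward(h, s), phmmPathSum(h, s), tolerance = 1e-9)
  }
  # a few length-4 segments against every model
  set.seed(4)
  for (h in models) for (k in 1:5) {
    s <- randRNA(4)
    expect_equal(phmmForward(h, s), phmmPathSum(h, s), tolerance = 1e-9)
  }
})

test_that("the emitted-length distribution is a proper distribution", {
  # scoring all-ones pseudo-columns sums the forward over all strings of a
  # given length, i.e. P(length = l); these must sum to 1 over l
  h <- buildPHMM("RA")
  tot <- sum(vapply(0:30, function(l) {
    cols <- matrix(1, 4, l)
    exp(phmmForward(h, cols))
  }, numeric(1)))
  expect_lt(tot, 1 + 1e-9)
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("sampled lengths reproduce the analytic expectation", {
  h <- buildPHMM("GNRA")
  n <- 1e5
  lens <- phmmSampleLengths(h, n, seed = 8)
  se <- sd(lens) / sqrt(n)
  expect_lt(abs(mean(lens) - expectedLength(h)), 3 * se)
})

test_that("empty slices score the all-delete path", {
  h0 <- buildPHMM("")
  # single no-emission path: terminate immediately with probability 1 - q
  expect_equal(phmmForward(h0, ""), log(1 - h0@q), tolerance = 1e-12)
  h2 <- buildPHMM("AG")
  expect_equal(phmmForward(h2, ""),
               (nchar("AG") + 1) * log(1 - h2@q) + 2 * log(h2@d),
               tolerance = 1e-12)
})
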