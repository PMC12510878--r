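# Descriptor parsing, bundled library, and variant expansion.

parseLines <- function(lines) {
  f <- tempfile(fileext = ".r3d")
  writeLines(lines, f)
  parseDescriptor(f)
}

test_that("descriptor records parse into the documented segment layouts", {
  ds <- parseLines(c("HL GNRA L1=G Loop=N R1=RA",
                     "HL U-turn L1= Loop=URA R1=",
                     "J3 groupII S1=A S2=RAA S3="))
  expect_length(ds, 3)
  expect_equal(ds[[1]]@segments[["L1"]], "G")
  expect_equal(ds[[1]]@segments[["Loop"]], "N")
  expect_equal(ds[[1]]@segments[["R1"]], "RA")
  expect_equal(ds[[2]]@segments[["Loop"]], "URA")
  expect_equal(unname(ds[[2]]@segments[c("L1", "R1")]), c("", ""))
  expect_equal(unname(ds[[3]]@segments[c("S1", "S2", "S3")]),
               c("A", "RAA", ""))
})

test_that("malformed descriptors fail with the offending line", {
  expect_error(parseLines("XX foo S1=A"), "line 1.*unknown motif class")
  expect_error(parseLines("HL gnra L1=G Loop=Z R1=RA"), "invalid IUPAC")
  expect_error(parseLines("IL kt Lo= Loop1= Li=GA Ri=AG Loop2=RNN"),
               "missing segment")
  expect_error(parseLines(c("HL a L1=G Loop=N R1=RA",
                            "HL a L1=G Loop=N R1=RA")), "duplicate motif name")
  expect_error(parseLines("HL a L1=G Loop=N R1=RA X9=AA"), "unknown key")
})

test_that("variant counts per class match the motif topology", {
  count <- function(lines) length(suppressMessages(
    expandVariants(parseLines(lines))))
  expect_equal(count("HL h L1=G Loop=N R1=RA"), 1)
  expect_equal(count("BL b L1= Loop=UR R1="), 2)
  expect_equal(count("IL i Lo=A Loop1=C Li=G Ri=U Loop2=AA Ro=G"), 2)
  expect_equal(count("J3 j S1=A S2=C S3=G"), 3)
  expect_equal(count("J4 j S1=A S2=C S3=G S4=U"), 4)
  expect_equal(count("BS b S1=GGA"), 1)
})

test_that("redundant variants are merged, distinct ones never are", {
  # fully symmetric internal loop: both attachments read identically
  expect_equal(length(suppressMessages(expandVariants(
    parseLines("IL sym Lo=A Loop1=C Li=A Ri=A Loop2=C Ro=A")))), 1)
  # all-empty four-way junction: all four rotations coincide
  expect_equal(length(suppressMessages(expandVariants(
    parseLines("J4 coax S1= S2= S3= S4=")))), 1)
  # brute-force pairwise check on the bundled library: retained variants
  # all differ; every variant of the full expansion equals some retained one
  lib <- builtinMotifLibrary()
  uniq <- suppressMessages(expandVariants(lib))
  keys <- vapply(uniq, function(v)
    paste(v@descriptor@motifClass, paste(v@elements, collapse = "|")),
    character(1))
  expect_false(any(duplicated(keys)))
})

test_that("variant expansion is deterministic and order-independent", {
  lib <- builtinMotifLibrary()
  k1 <- sort(vapply(suppressMessages(expandVariants(lib)),
                    function(v) v@uniqueId, character(1)))
  k2 <- sort(vapply(suppressMessages(expandVariants(rev(lib))),
                    function(v) v@uniqueId, character(1)))
  expect_identical(k1, k2)
})

test_that("the bundled library loads and reports its variant count", {
  lib <- builtinMotifLibrary()
  expect_gte(length(lib), 8)
  expect_message(expandVariants(lib), "nonredundant motif variants")
})
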