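# Shared fixtures: small motif libraries, sequence generators, and
# independent brute-force oracles used across test files.

# three-motif test library: two hairpin motifs and one bulge motif, all
# exercisable by enumeration at small lengths
smallMotifVariants <- function() {
  tmp <- tempfile(fileext = ".r3d")
  writeLines(c("HL GNRA L1=G Loop=N R1=RA",
               "HL U-turn L1= Loop=URA R1=",
               "BL bmot L1= Loop=UR R1="), tmp)
  suppressMessages(expandVariants(parseDescriptor(tmp)))
}

randRNA <- function(L, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# independent profile-HMM oracle: explicit recursion over every state path
# (insert / match / delete decisions), no shared dynamic programming
phmmPathSum <- function(phmm, seq) {
  chars <- if (nzchar(seq)) strsplit(seq, "")[[1]] else character(0)
  n <- length(chars)
  Lc <- nchar(phmm@consensus)
  q <- phmm@q; d <- phmm@d
  pm <- function(pos, ch) phmm@matchEmissions[ch, pos]
  pi <- function(ch) phmm@insertEmission[match(ch, c("A", "C", "G", "U"))]
  rec <- function(slot, k) {
    tot <- 0
    if (k < n) tot <- tot + q * pi(chars[k + 1]) * rec(slot, k + 1)
    if (slot < Lc) {
      if (k < n) tot <- tot + (1 - q) * (1 - d) * pm(slot + 1, chars[k + 1]) *
        rec(slot + 1, k + 1)
      tot <- tot + (1 - q) * d * rec(slot + 1, k)
    } else if (k == n) tot <- tot + (1 - q)
    tot
  }
  unname(log(rec(0, 0)))
}

# exhaustive maximum mutually-nested subset of a pair list (for the layer
# decomposition oracle); branch-and-bound over the conflict graph
maxNestedBrute <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0) return(0L)
  conflict <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    i1 <- pairs[a, 1]; j1 <- pairs[a, 2]; i2 <- pairs[b, 1]; j2 <- pairs[b, 2]
    shared <- length(intersect(c(i1, j1), c(i2, j2))) > 0
    crossing <- (i1 < i2 && i2 < j1 && j1 < j2) ||
                (i2 < i1 && i1 < j2 && j2 < j1)
    conflict[a, b] <- shared || crossing
  }
  best <- 0L
  rec <- function(idx, chosen) {
    if (length(chosen) + (n - idx + 1L) <= best) return(invisible(NULL))
    if (idx > n) { best <<- max(best, length(chosen)); return(invisible(NULL)) }
    if (!length(chosen) || !any(conflict[idx, chosen]))
      rec(idx + 1L, c(chosen, idx))
    rec(idx + 1L, chosen)
  }
  rec(1L, integer(0))
  best
}

# enumeration cache shared between the oracle-equivalence and unambiguity
# acceptance tests (the enumeration is the expensive part)
.enumCache <- new.env(parent = emptyenv())

enumCase <- function(seq, grammar, tag) {
  key <- paste0(tag, ":", seq)
  hit <- .enumCache[[key]]
  if (!is.null(hit)) return(hit)
  pa <- probAlignmentFromSequence(seq)
  val <- list(pa = pa, en = enumerateDerivations(pa, grammar))
  assign(key, val, envir = .enumCache)
  val
}

# sample a derivation, retrying with an offset seed on the (rare) runaway
# guard
sampleSafe <- function(p, seed) {
  repeat {
    s <- tryCatch(sampleDerivation(p, seed = seed), error = function(e) NULL)
    if (!is.null(s)) return(s)
    seed <- seed + 1000003L
  }
}
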