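# Probabilistic-sequence construction: per-column nucleotide frequency
# vectors after gap filtering, with on-demand joint pair frequencies.

#' Build the probabilistic representation of an alignment
#'
#' Columns whose gap fraction exceeds \code{gapMax} are removed (the default
#' mirrors the covariation analyzer's 75\% rule). Within a kept column, gaps
#' are excluded and frequencies renormalized over observed residues; IUPAC
#' ambiguity codes spread their mass uniformly over their residue sets. A
#' kept column consisting entirely of gaps is represented as the uniform
#' distribution (with a message). Pair frequencies are computed lazily from
#' the sequences ungapped at both columns and memoized.
#'
#' @param msa an \linkS4class{RnaMSA}
#' @param gapMax maximum tolerated gap fraction per column, in (0, 1]
#' @param weights optional per-sequence weights (default uniform)
#' @return a \linkS4class{ProbAlignment}; the kept-to-original column map is
#'   in \code{keptColumns()}
#' @export
buildProbAlignment <- function(msa, gapMax = 0.75, weights = NULL) {
  stopifnot(is(msa, "RnaMSA"))
  if (!(gapMax > 0 && gapMax <= 1)) .stopf("gapMax must be in (0, 1]")
  m <- .charMatrix(msa)
  S <- nrow(m); L <- ncol(m)
  if (is.null(weights)) weights <- rep(1, S)
  if (length(weights) != S || any(weights < 0) || sum(weights) == 0)
    .stopf("weights must be %d nonnegative values with positive sum", S)
  gapm <- matrix(m %in% GAP_CHARS, nrow = S)
  gapFrac <- colSums(gapm * weights) / sum(weights)
  kept <- which(gapFrac <= gapMax)
  # per-residue mass lookup for every distinct character in the alignment
  lut <- lapply(setNames(nm = unique(as.vector(m))), .residueMass)
  sf <- matrix(0, nrow = 4, ncol = length(kept),
               dimnames = list(NUCS, NULL))
  for (k in seq_along(kept)) {
    col <- m[, kept[k]]
    tot <- numeric(4)
    for (s in seq_len(S)) {
      mass <- lut[[col[s]]]
      if (!is.null(mass)) tot <- tot + weights[s] * mass
    }
    if (sum(tot) == 0) {
      message("column ", kept[k], " is all gaps; using uniform distribution")
      tot <- rep(0.25, 4)
    }
    sf[, k] <- tot / sum(tot)
  }
  new("ProbAlignment", keptColumns = as.integer(kept), singleFreq = sf,
      gapFraction = gapFrac, weights = weights, chars = m,
      cache = new.env(parent = emptyenv()))
}

#' Joint 4x4 pair frequency of two kept columns
#'
#' Computed over the sequences ungapped at both columns (sequences gapped at
#' exactly one of the two are excluded); ambiguity codes contribute the outer
#' product of their uniform masses. Falls back to the product of the two
#' single-column distributions when no sequence covers both columns.
#'
#' @param pa a \linkS4class{ProbAlignment}
#' @param i,j kept-column indices (1-based, i != j)
#' @return 4x4 matrix over (A,C,G,U) x (A,C,G,U) summing to 1
#' @export
pairFreq <- function(pa, i, j) {
  if (i == j) .stopf("pairFreq needs two distinct columns")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  key <- paste0(i, "_", j)
  hit <- pa@cache[[key]]
  if (!is.null(hit)) return(hit)
  ci <- pa@chars[, pa@keptColumns[i]]
  cj <- pa@chars[, pa@keptColumns[j]]
  w <- pa@weights
  ok <- !(ci %in% GAP_CHARS) & !(cj %in% GAP_CHARS)
  tot <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  if (any(ok)) {
    # aggregate sequence weights per distinct residue-character pair
    pairChars <- paste0(ci[ok], cj[ok])
    wsum <- tapply(w[ok], pairChars, sum)
    for (k in seq_along(wsum)) {
      chs <- strsplit(names(wsum)[k], "")[[1]]
      tot <- tot + wsum[k] * outer(.residueMass(chs[1]), .residueMass(chs[2]))
    }
  }
  if (sum(tot) == 0) tot <- outer(pa@singleFreq[, i], pa@singleFreq[, j])
  tot <- tot / sum(tot)
  assign(key, tot, envir = pa@cache)
  tot
}

# number of kept columns
.nKept <- function(pa) length(pa@keptColumns)

#' Build a ProbAlignment directly from literal sequences
#'
#' Convenience wrapper for folding a single sequence (point-mass columns).
#'
#' @param seq a character string over ACGU (T accepted)
#' @param ... passed to \code{buildProbAlignment}
#' @export
probAlignmentFromSequence <- function(seq, ...) {
  buildProbAlignment(rnaMSA("seq1", seq), ...)
}
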