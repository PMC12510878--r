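# Profile HMMs over motif consensus segments.
#
# Layout: a begin state, one match state per consensus position, one insert
# slot per position plus flanks, and deletion bypasses. Emission happens on
# transition. After arriving at slot i (0 <= i <= Lc) the model emits a
# geometric run of inserts (self-extension probability q), then advances:
# match position i+1 with probability (1-q)(1-d) emitting one residue, or
# delete it with probability (1-q)d emitting nothing; from the last slot it
# terminates with probability (1-q).
#
# The expected emitted length is Lc(1-d) + (Lc+1) q/(1-q). d is fixed at a
# small value and q solved in closed form so that the expectation equals the
# target Lc + min(0.1 Lc, 1.5).

.PHMM_DELETE <- 0.01

# target mean length excess; an empty consensus keeps 0.5 so inserts stay
# reachable (the only way an empty segment can match residues)
.expectedExtra <- function(Lc) if (Lc == 0L) 0.5 else min(0.1 * Lc, 1.5)

#' Build a profile HMM from a consensus string
#'
#' Match emissions follow the mismatch rule: for a consensus class of size c,
#' each in-class residue gets (1 - (4-c) * epsilon) / c and each out-of-class
#' residue epsilon. A single-residue position 'U' therefore emits U with
#' probability 1 - 3 epsilon = 0.9997 at the default epsilon, and a
#' two-residue class 'R' emits A and G with (1 - 2 epsilon)/2 = 0.4999 each.
#'
#' @param consensus IUPAC string; the empty string builds an insert-only model
#' @param epsilon mismatch probability (default 1e-4)
#' @param insertEmission shared insert emission distribution (default uniform;
#'   the training-set residue frequencies may be supplied instead)
#' @return a \linkS4class{ProfileHMM}
#' @export
buildPHMM <- function(consensus, epsilon = 1e-4,
                      insertEmission = rep(0.25, 4)) {
  consensus <- toupper(consensus)
  chars <- if (nzchar(consensus)) strsplit(consensus, "")[[1]] else character(0)
  if (length(chars) && !all(chars %in% names(IUPAC)))
    .stopf("invalid consensus character in '%s'", consensus)
  Lc <- length(chars)
  me <- matrix(0, nrow = 4, ncol = Lc, dimnames = list(NUCS, NULL))
  for (i in seq_len(Lc)) {
    set <- IUPAC[[chars[i]]]
    cs <- length(set)
    v <- rep(epsilon, 4); names(v) <- NUCS
    v[set] <- (1 - (4 - cs) * epsilon) / cs
    me[, i] <- v
  }
  d <- if (Lc == 0L) 0 else .PHMM_DELETE
  extra <- .expectedExtra(Lc)
  r <- (extra + Lc * d) / (Lc + 1)   # target q/(1-q) per insert slot
  q <- r / (1 + r)
  obj <- new("ProfileHMM", consensus = consensus, matchEmissions = me,
             insertEmission = insertEmission / sum(insertEmission),
             q = q, d = d, epsilon = epsilon)
  validObject(obj)
  obj
}

#' Analytic expected emitted length of a profile HMM
#'
#' @param phmm a \linkS4class{ProfileHMM}
#' @return Lc(1-d) + (Lc+1) q/(1-q), which by construction equals
#'   Lc + min(0.1 Lc, 1.5) (0.5 for an empty consensus)
#' @export
expectedLength <- function(phmm) {
  Lc <- nchar(phmm@consensus)
  Lc * (1 - phmm@d) + (Lc + 1) * phmm@q / (1 - phmm@q)
}

#' Forward log probability of a segment under a profile HMM
#'
#' Sums over all state paths that emit exactly the given columns. Each column
#' is a nucleotide distribution; emissions use the column-mixture rule
#' P(o) = sum_a p_o(a) P(a), which reduces to the literal-sequence emission on
#' point-mass columns. An empty segment is scored as the all-delete,
#' no-insert path set.
#'
#' @param phmm a \linkS4class{ProfileHMM}
#' @param cols 4 x n matrix of column distributions (n may be 0); a character
#'   string is accepted and converted to point-mass columns
#' @return log probability
#' @export
phmmForward <- function(phmm, cols) {
  if (is.character(cols)) cols <- .seqToCols(cols)
  n <- if (is.null(dim(cols))) 0L else ncol(cols)
  Lc <- nchar(phmm@consensus)
  lq <- log(phmm@q); l1q <- log1p(-phmm@q)
  ld <- if (phmm@d > 0) log(phmm@d) else -Inf
  l1d <- log1p(-phmm@d)
  # mixture emission logs
  insE <- if (n) log(as.vector(crossprod(cols, phmm@insertEmission))) else numeric(0)
  matE <- if (n && Lc) log(crossprod(cols, phmm@matchEmissions)) else
    matrix(numeric(0), nrow = n, ncol = Lc)   # [k, i]
  # A[i+1, k+1] = log P(at slot i, k columns consumed)
  A <- matrix(-Inf, nrow = Lc + 1L, ncol = n + 1L)
  A[1L, 1L] <- 0
  for (k in seq_len(n)) A[1L, k + 1L] <- A[1L, k] + lq + insE[k]
  for (i in seq_len(Lc)) {
    A[i + 1L, 1L] <- A[i, 1L] + l1q + ld
    for (k in seq_len(n)) {
      A[i + 1L, k + 1L] <- logSumExp(c(
        A[i + 1L, k] + lq + insE[k],                 # insert at slot i
        A[i, k] + l1q + l1d + matE[k, i],            # match position i
        A[i, k + 1L] + l1q + ld))                    # delete position i
    }
  }
  A[Lc + 1L, n + 1L] + l1q                            # terminate
}

# literal sequence -> point-mass column matrix
.seqToCols <- function(seq) {
  chars <- if (nzchar(seq)) strsplit(toupper(gsub("T", "U", seq)), "")[[1]]
           else character(0)
  if (!length(chars)) return(matrix(numeric(0), nrow = 4, ncol = 0))
  vapply(chars, function(ch) {
    m <- .residueMass(ch)
    if (is.null(m)) .stopf("gap character in literal segment")
    m
  }, numeric(4))
}

#' Sample an emitted sequence from a profile HMM
#'
#' Used to check the length parameterization by simulation.
#'
#' @param phmm a \linkS4class{ProfileHMM}
#' @param n number of samples
#' @param seed RNG seed
#' @return integer vector of emitted lengths
#' @export
phmmSampleLengths <- function(phmm, n, seed = 1L) {
  Lc <- nchar(phmm@consensus)
  .withSeed(seed, {
    vapply(seq_len(n), function(dummy) {
      len <- 0L
      for (slot in 0:Lc) {
        while (runif(1) < phmm@q) len <- len + 1L      # inserts
        if (slot < Lc && runif(1) >= phmm@d) len <- len + 1L  # match vs delete
      }
      len
    }, integer(1))
  })
}
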