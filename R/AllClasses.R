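#' @import methods
NULL

#' Multiple sequence alignment of RNA sequences
#'
#' Thin S4 container for an aligned set of RNA sequences. All rows have equal
#' length; residues are upper-case IUPAC codes with T normalized to U and all
#' gap characters normalized to '-'. The optional \code{ssCons} slot holds a
#' consensus-structure annotation line (WUSS/dot-bracket) and \code{gc} any
#' further per-column annotation lines from a Stockholm file.
#'
#' @slot ids character vector of sequence identifiers
#' @slot rows character vector of aligned sequence strings
#' @slot ssCons consensus structure line or NA
#' @slot gc named list of additional per-column annotation strings
#' @exportClass RnaMSA
setClass("RnaMSA",
  representation(ids = "character", rows = "character",
                 ssCons = "character", gc = "list"),
  prototype(ssCons = NA_character_, gc = list()))

setValidity("RnaMSA", function(object) {
  if (length(object@ids) != length(object@rows))
    return("ids and rows differ in length")
  if (length(object@rows) < 1L) return("alignment needs at least one sequence")
  L <- unique(nchar(object@rows))
  if (length(L) != 1L) return("rows have unequal lengths")
  if (!is.na(object@ssCons) && nchar(object@ssCons) != L)
    return("SS_cons length does not match alignment length")
  TRUE
})

#' Probabilistic representation of an alignment
#'
#' Columns passing the gap-fraction filter are represented by per-column
#' nucleotide frequency vectors; per-column-pair joint 4x4 frequencies are
#' computed on demand (and memoized) from the sequences ungapped at both
#' columns. This object is what the folding grammars operate on: the grammar
#' emits column \emph{distributions}, not individual residues.
#'
#' @slot keptColumns original 1-based column indices retained (strictly increasing)
#' @slot singleFreq 4 x K matrix, column k = nucleotide frequencies of kept column k
#' @slot gapFraction per original column gap fraction
#' @slot weights per-sequence weights (uniform by default)
#' @slot chars S x L character matrix of the normalized alignment (for pair counts)
#' @slot cache environment memoizing pair frequency queries
#' @exportClass ProbAlignment
setClass("ProbAlignment",
  representation(keptColumns = "integer", singleFreq = "matrix",
                 gapFraction = "numeric", weights = "numeric",
                 chars = "matrix", cache = "environment"))

setValidity("ProbAlignment", function(object) {
  K <- length(object@keptColumns)
  if (K > 1L && any(diff(object@keptColumns) <= 0L))
    return("keptColumns must be strictly increasing")
  if (ncol(object@singleFreq) != K) return("singleFreq has wrong column count")
  if (nrow(object@singleFreq) != 4L) return("singleFreq must have 4 rows")
  s <- colSums(object@singleFreq)
  if (K > 0L && any(abs(s - 1) > 1e-9))
    return("single-column distributions must each sum to 1")
  TRUE
})

#' Descriptor of one RNA 3D motif
#'
#' @slot name motif name (unique within a library)
#' @slot motifClass one of HL, BL, IL, J3, J4, BS
#' @slot segments named character vector of consensus segment strings (IUPAC;
#'   possibly empty strings)
#' @exportClass MotifDescriptor
setClass("MotifDescriptor",
  representation(name = "character", motifClass = "character",
                 segments = "character"))

MOTIF_CLASSES <- c("HL", "BL", "IL", "J3", "J4", "BS")

setValidity("MotifDescriptor", function(object) {
  if (!object@motifClass %in% MOTIF_CLASSES)
    return(paste("unknown motif class:", object@motifClass))
  segs <- object@segments
  bad <- unlist(strsplit(segs[nzchar(segs)], ""))
  if (length(bad) && !all(bad %in% names(IUPAC)))
    return("segments contain non-IUPAC characters")
  if (!any(nzchar(segs)) && !object@motifClass %in% c("J3", "J4"))
    return("all-empty segments only allowed for J3/J4 (coaxial stacking)")
  TRUE
})

#' One topological variant of a motif
#'
#' Motifs bounded by more than one helix can attach to the rest of the
#' structure through any of their bounding helices; each attachment is a
#' variant. \code{elements} lists segments and enclosed-helix placeholders
#' ("&") in 5'-to-3' order for this attachment; it is the key used for
#' redundancy elimination.
#'
#' @slot descriptor the parent MotifDescriptor
#' @slot topologyIndex which attachment this is (1-based)
#' @slot elements character vector: consensus strings interleaved with "&"
#'   helix placeholders, 5' to 3'
#' @slot segNames names of the consensus elements (placeholders named "&")
#' @slot uniqueId identifier, \code{name.class.index}
#' @exportClass MotifVariant
setClass("MotifVariant",
  representation(descriptor = "MotifDescriptor", topologyIndex = "integer",
                 elements = "character", segNames = "character",
                 uniqueId = "character"))

#' Profile HMM over one consensus segment
#'
#' Match/insert/delete model with emission on transition. One match state per
#' consensus position; a shared insert emission distribution; a per-slot
#' geometric insert-extension probability \code{q} and a per-position delete
#' probability \code{d} solved so the expected emitted length equals
#' Lc + min(0.1 Lc, 1.5) (0.5 for an empty consensus).
#'
#' @slot consensus the consensus string (may be empty)
#' @slot matchEmissions 4 x Lc matrix of match emission probabilities
#' @slot insertEmission shared insert emission 4-vector
#' @slot q geometric insert self-extension probability
#' @slot d per-position delete probability
#' @slot epsilon mismatch probability used to build match emissions
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(consensus = "character", matchEmissions = "matrix",
                 insertEmission = "numeric", q = "numeric", d = "numeric",
                 epsilon = "numeric"))

setValidity("ProfileHMM", function(object) {
  Lc <- nchar(object@consensus)
  if (ncol(object@matchEmissions) != Lc) return("matchEmissions wrong width")
  if (Lc > 0 && any(abs(colSums(object@matchEmissions) - 1) > 1e-9))
    return("match emissions must sum to 1")
  if (abs(sum(object@insertEmission) - 1) > 1e-9)
    return("insert emission must sum to 1")
  if (object@q <= 0 || object@q >= 1) return("q out of (0,1)")
  if (object@d < 0 || object@d >= 1) return("d out of [0,1)")
  TRUE
})

#' Grammar parameter set
#'
#' Transition probabilities for every nonterminal of the helix/loop grammar,
#' emission tables (single residue, base pair, stacked base pair), geometric
#' run-length laws per loop context, the multiloop split among three-way,
#' four-way and higher junctions, and the per-class motif mass fractions.
#'
#' @slot transitions named list of named probability vectors (S, F0, F5, P, M1)
#' @slot eSingle unpaired-residue emission 4-vector
#' @slot ePair 4x4 base-pair emission table
#' @slot eStack 16x16 stacked-pair table: row = outer pair (16 codes), col = inner
#' @slot runGeom named continuation probabilities for loop run lengths
#'   (hairpin, bulge, internal, ml)
#' @slot classFractions motif mass fraction per class (HL, BL, IL, J3, J4, BS)
#' @slot epsilon profile-HMM mismatch probability
#' @exportClass FoldParams
setClass("FoldParams",
  representation(transitions = "list", eSingle = "numeric", ePair = "matrix",
                 eStack = "matrix", runGeom = "numeric",
                 classFractions = "numeric", epsilon = "numeric"))

setValidity("FoldParams", function(object) {
  for (nt in names(object@transitions)) {
    p <- object@transitions[[nt]]
    if (any(p < 0)) return(paste("negative transition probability in", nt))
    if (abs(sum(p) - 1) > 1e-9)
      return(paste("transitions of", nt, "do not sum to 1"))
  }
  if (abs(sum(object@eSingle) - 1) > 1e-9) return("eSingle does not sum to 1")
  if (abs(sum(object@ePair) - 1) > 1e-9) return("ePair does not sum to 1")
  if (any(abs(rowSums(object@eStack) - 1) > 1e-9))
    return("eStack rows must each sum to 1")
  if (any(object@runGeom <= 0 | object@runGeom >= 1))
    return("run-length continuation probabilities must lie in (0,1)")
  cf <- object@classFractions
  if (!all(MOTIF_CLASSES %in% names(cf))) return("classFractions incomplete")
  if (any(cf < 0 | cf > 1)) return("classFractions out of [0,1]")
  TRUE
})

#' A folding grammar ready for the dynamic programming engine
#'
#' @slot type "rbgj3j4" (helix/loop grammar without motifs), "r3d" (with motif
#'   nonterminals) or "layer" (small nested grammar for pseudoknot layers)
#' @slot params FoldParams
#' @slot variants list of MotifVariant (with built profile HMMs attached)
#' @slot phmms named list: for each variant id, list of ProfileHMM per segment
#' @slot options list: minHairpin, maxBulge, maxIntLoop, maxMlRun, segSlack
#' @exportClass FoldGrammar
setClass("FoldGrammar",
  representation(type = "character", params = "FoldParams",
                 variants = "list", phmms = "list", options = "list"))

#' Result of a (multi)layer fold
#'
#' @slot layers list of two-column matrices of base pairs, 1-based original
#'   alignment columns; layer 1 is the nested consensus structure
#' @slot motifCalls data.frame: name, class, variant, start, end, logScore,
#'   supported, plus a list-column of bounding pairs
#' @slot logProb log probability of the layer-1 parse
#' @slot L alignment length (original columns)
#' @slot keptColumns the kept-column map used
#' @exportClass ParseResult
setClass("ParseResult",
  representation(layers = "list", motifCalls = "data.frame",
                 logProb = "numeric", L = "integer", keptColumns = "integer"))

#' Covariation evidence: positive and negative column pairs
#'
#' @slot positives matrix with columns i, j, E (1-based original columns)
#' @slot negatives matrix with columns i, j
#' @slot threshold E-value cutoff used
#' @exportClass PairSet
setClass("PairSet",
  representation(positives = "matrix", negatives = "matrix",
                 threshold = "numeric"))

setValidity("PairSet", function(object) {
  pos <- object@positives; neg <- object@negatives
  if (nrow(pos) && any(pos[, 1] >= pos[, 2])) return("positive pairs need i < j")
  if (nrow(neg) && any(neg[, 1] >= neg[, 2])) return("negative pairs need i < j")
  pk <- paste(pos[, 1], pos[, 2]); nk <- paste(neg[, 1], neg[, 2])
  if (nrow(pos) && anyDuplicated(pk)) return("duplicate positive pairs")
  if (nrow(neg) && anyDuplicated(nk)) return("duplicate negative pairs")
  if (nrow(pos) && nrow(neg) && length(intersect(pk, nk)))
    return("positive and negative sets overlap")
  TRUE
})

# ---- show methods -------------------------------------------------------

setMethod("show", "RnaMSA", function(object) {
  cat(sprintf("RnaMSA: %d sequences x %d columns\n",
              length(object@rows), nchar(object@rows[1])))
  if (!is.na(object@ssCons)) cat("  SS_cons present\n")
})

setMethod("show", "ProbAlignment", function(object) {
  cat(sprintf("ProbAlignment: %d kept of %d columns, %d sequences\n",
              length(object@keptColumns), length(object@gapFraction),
              nrow(object@chars)))
})

setMethod("show", "MotifDescriptor", function(object) {
  segs <- paste(names(object@segments), object@segments, sep = "=",
                collapse = " ")
  cat(sprintf("MotifDescriptor %s [%s] %s\n", object@name, object@motifClass,
              segs))
})

setMethod("show", "MotifVariant", function(object) {
  cat(sprintf("MotifVariant %s: %s\n", object@uniqueId,
              paste(object@elements, collapse = " ")))
})

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM consensus '%s' (q=%.4f, d=%.4f, E[len]=%.3f)\n",
              object@consensus, object@q, object@d, expectedLength(object)))
})

setMethod("show", "FoldGrammar", function(object) {
  cat(sprintf("FoldGrammar type=%s, %d motif variants, %d nonterminals\n",
              object@type, length(object@variants),
              nonterminalCount(object)))
})

setMethod("show", "ParseResult", function(object) {
  cat(sprintf("ParseResult: %d layer(s), %d pairs in layer 1, %d motif call(s), logP = %.4f\n",
              length(object@layers),
              if (length(object@layers)) nrow(object@layers[[1]]) else 0L,
              nrow(object@motifCalls), object@logProb))
})

setMethod("show", "PairSet", function(object) {
  cat(sprintf("PairSet: %d positive, %d negative pairs (E <= %g)\n",
              nrow(object@positives), nrow(object@negatives),
              object@threshold))
})

# ---- accessors ----------------------------------------------------------

#' Number of sequences in an alignment
#' @param x an RnaMSA
#' @export
nSeq <- function(x) length(x@rows)

#' Number of alignment columns
#' @param x an RnaMSA
#' @export
alnLength <- function(x) nchar(x@rows[1])

#' Sequence identifiers
#' @param x an RnaMSA
#' @export
seqIds <- function(x) x@ids

#' Aligned rows as character strings
#' @param x an RnaMSA
#' @export
alnRows <- function(x) x@rows

#' Consensus structure annotation (or NA)
#' @param x an RnaMSA
#' @export
ssCons <- function(x) x@ssCons

#' Kept original columns of a probabilistic alignment
#' @param x a ProbAlignment
#' @export
keptColumns <- function(x) x@keptColumns

#' Per-column nucleotide frequencies (4 x K)
#' @param x a ProbAlignment
#' @export
singleFreq <- function(x) x@singleFreq

#' Gap fraction per original column
#' @param x a ProbAlignment
#' @export
gapFraction <- function(x) x@gapFraction

#' Base-pair layers of a parse (1-based original columns)
#' @param x a ParseResult
#' @export
pairLayers <- function(x) x@layers

#' Motif calls of a parse
#' @param x a ParseResult
#' @export
motifCalls <- function(x) x@motifCalls

#' Log probability of the layer-1 parse
#' @param x a ParseResult
#' @export
parseLogProb <- function(x) x@logProb

#' Positive covarying pairs
#' @param x a PairSet
#' @export
positivePairs <- function(x) x@positives

#' Negative (excluded) pairs
#' @param x a PairSet
#' @export
negativePairs <- function(x) x@negatives
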