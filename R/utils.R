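# Shared low-level helpers: nucleotide coding, IUPAC degeneracy, log-space
# arithmetic, seeded RNG scoping.

NUCS <- c("A", "C", "G", "U")

# IUPAC degeneracy sets over the RNA alphabet (T handled by T->U on ingest)
IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

GAP_CHARS <- c("-", ".", "_", "~")

#' @keywords internal
.isGap <- function(ch) ch %in% GAP_CHARS

# residue character -> 4-vector of uniform mass over its IUPAC set; NULL for gaps
.residueMass <- function(ch) {
  if (.isGap(ch)) return(NULL)
  set <- IUPAC[[ch]]
  if (is.null(set)) stop("invalid residue character: '", ch, "'")
  v <- numeric(4)
  names(v) <- NUCS
  v[set] <- 1 / length(set)
  v
}

# numerically stable log(sum(exp(x))) over a vector; -Inf-safe
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# combine two log values under "max" or "sum" semantics
.acc <- function(x, mode) {
  if (mode == "max") max(x) else logSumExp(x)
}

# log P(len) for a geometric run-length law with support len >= min and
# continuation probability g: P(len) = (1 - g) * g^(len - min)
.geomLog <- function(len, min, g) {
  ifelse(len < min, -Inf, log1p(-g) + (len - min) * log(g))
}

# evaluate expr under a fixed RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# strictly increasing kept-column map helpers -----------------------------

# kept index -> original 1-based column
.keptToOrig <- function(kept, idx) kept[idx]

# original column -> kept index (NA if dropped)
.origToKept <- function(kept, col) {
  m <- match(col, kept)
  m
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
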