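# Covariation evidence handling: external pair lists, an approximate
# built-in covariation statistic, decomposition of positive pairs into
# nested layers, multilayer folding, covariation support flags for motif
# calls, and control-based false discovery summaries.

#' Construct a PairSet
#'
#' @param positives matrix/data.frame with columns i, j, E
#' @param negatives matrix/data.frame with columns i, j
#' @param threshold E-value cutoff
#' @export
pairSet <- function(positives = NULL, negatives = NULL, threshold = 0.05) {
  toM <- function(m, k) {
    if (is.null(m) || !NROW(m)) return(matrix(numeric(0), 0, k))
    m <- as.matrix(m)[, seq_len(k), drop = FALSE]
    m
  }
  pos <- toM(positives, 3); colnames(pos) <- c("i", "j", "E")
  neg <- toM(negatives, 2); colnames(neg) <- c("i", "j")
  obj <- new("PairSet", positives = pos, negatives = neg,
             threshold = threshold)
  validObject(obj)
  obj
}

#' Read a covarying-pair list from a TSV file
#'
#' Expected columns: i, j, E (E-value), class ("positive"/"negative"),
#' 1-based original alignment columns, as produced by an external
#' covariation analyzer. Pairs touching gap-filtered columns are dropped
#' with a warning.
#'
#' @param path TSV path (header optional; '#' comments allowed)
#' @param pa the \linkS4class{ProbAlignment} the pairs refer to (for the
#'   kept-column filter); NULL to skip filtering
#' @param threshold E-value cutoff recorded in the PairSet
#' @return a \linkS4class{PairSet}
#' @export
readPairsTSV <- function(path, pa = NULL, threshold = 0.05) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^[ij]", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  pos <- NULL; neg <- NULL
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\t|\\s+")[[1]]
    if (length(f) < 4) .stopf("line %d: expected 'i j E class'", k)
    i <- suppressWarnings(as.integer(f[1])); j <- suppressWarnings(as.integer(f[2]))
    ev <- suppressWarnings(as.numeric(f[3]))
    if (is.na(i) || is.na(j) || is.na(ev))
      .stopf("line %d: malformed numeric field", k)
    if (i >= j) .stopf("line %d: need i < j", k)
    cls <- tolower(f[4])
    if (cls == "positive") pos <- rbind(pos, c(i, j, ev))
    else if (cls == "negative") neg <- rbind(neg, c(i, j))
    else .stopf("line %d: class must be positive or negative", k)
  }
  if (!is.null(pa)) {
    keep <- function(m, k) {
      if (is.null(m)) return(NULL)
      ok <- !is.na(.origToKept(pa@keptColumns, m[, 1])) &
            !is.na(.origToKept(pa@keptColumns, m[, 2]))
      if (any(!ok))
        .warnf("%d pair(s) on gap-filtered columns dropped", sum(!ok))
      m[ok, , drop = FALSE]
    }
    pos <- keep(pos, 3); neg <- keep(neg, 2)
  }
  pairSet(pos, neg, threshold)
}

#' Approximate covariation statistic with a shuffled-column null
#'
#' Average-product-corrected mutual information per column pair, with
#' E-values estimated from column-shuffled alignments: E(s) is the mean
#' count of pairs scoring at least s in a shuffled control, i.e. the
#' expected number of false positives at that score. This is a simplified
#' stand-in for a full phylogeny-aware covariation analysis and is labelled
#' as such in logs; an externally computed pair list is the preferred input.
#'
#' @param msa an \linkS4class{RnaMSA}
#' @param pa the matching \linkS4class{ProbAlignment} (for the kept-column
#'   map)
#' @param nShuffles number of shuffled controls
#' @param seed RNG seed
#' @param threshold E-value cutoff for positive pairs
#' @return a \linkS4class{PairSet} (positives only; coordinates are original
#'   columns)
#' @export
covariationStandin <- function(msa, pa = NULL, nShuffles = 100, seed = 1L,
                               threshold = 0.05) {
  if (is.null(pa)) pa <- buildProbAlignment(msa)
  if (nSeq(msa) < 5) .warnf("fewer than 5 sequences: covariation statistic unreliable")
  message("covariation stand-in statistic (APC-corrected mutual information); ",
          "not a full phylogeny-aware analysis")
  obs <- .apcMI(msa, pa@keptColumns)
  nulls <- .withSeed(seed, {
    lapply(seq_len(nShuffles), function(r)
      .apcMI(shuffleColumns(msa, seed = sample.int(2^30, 1)), pa@keptColumns))
  })
  nullVals <- sort(unlist(lapply(nulls, function(m) m[upper.tri(m)])),
                   decreasing = TRUE)
  # E(s): mean per-shuffle count of pairs scoring >= s
  evalOf <- function(s) sum(nullVals >= s) / nShuffles
  kept <- pa@keptColumns
  K <- length(kept)
  pos <- NULL
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    s <- obs[a, b]
    if (!is.finite(s)) next
    ev <- evalOf(s)
    if (ev <= threshold) pos <- rbind(pos, c(kept[a], kept[b], ev))
  }
  pairSet(pos, NULL, threshold)
}

# APC-corrected mutual information over kept columns
.apcMI <- function(msa, kept) {
  m <- .charMatrix(msa)[, kept, drop = FALSE]
  K <- ncol(m)
  code <- matrix(match(m, NUCS), nrow = nrow(m))  # ambiguity/gaps -> NA
  MI <- matrix(0, K, K)
  for (a in seq_len(max(0L, K - 1L))) for (b in (a + 1L):K) {
    ok <- !is.na(code[, a]) & !is.na(code[, b])
    if (sum(ok) < 2) next
    ja <- code[ok, a]; jb <- code[ok, b]
    joint <- tabulate((ja - 1L) * 4L + jb, nbins = 16L) / sum(ok)
    pa <- tabulate(ja, nbins = 4L) / sum(ok)
    pb <- tabulate(jb, nbins = 4L) / sum(ok)
    ex <- as.vector(outer(pa, pb))
    jm <- matrix(joint, 4, 4, byrow = TRUE)
    nz <- joint > 0 & ex > 0
    MI[a, b] <- MI[b, a] <- sum(joint[nz] * log(joint[nz] / ex[nz]))
  }
  if (K >= 2) {
    rm <- rowSums(MI) / (K - 1)
    gm <- sum(MI[upper.tri(MI)]) * 2 / (K * (K - 1))
    if (gm > 0) {
      apc <- outer(rm, rm) / gm
      MI <- MI - apc
    }
  }
  diag(MI) <- -Inf
  MI
}

#' Decompose positive pairs into mutually nested layers
#'
#' Layer 1 is a maximum-cardinality subset of mutually nested pairs (found
#' by interval dynamic programming); remaining pairs are layered
#' recursively. Ties are broken toward the lexicographically smallest pair
#' set (prefer the pair with the smaller left endpoint, then the smaller
#' right endpoint).
#'
#' @param pairset a \linkS4class{PairSet} (or a two-column matrix)
#' @return list of two-column matrices; the union equals the positive set
#' @export
decomposeLayers <- function(pairset) {
  pairs <- if (is(pairset, "PairSet")) pairset@positives[, 1:2, drop = FALSE]
           else as.matrix(pairset)[, 1:2, drop = FALSE]
  layers <- list()
  remaining <- pairs
  while (nrow(remaining)) {
    sel <- .maxNested(remaining)
    layers[[length(layers) + 1L]] <- remaining[sel, , drop = FALSE]
    remaining <- remaining[-sel, , drop = FALSE]
  }
  layers
}

# maximum nested subset by interval DP over the coordinate range
.maxNested <- function(pairs) {
  n <- nrow(pairs)
  if (n == 1L) return(1L)
  lo <- min(pairs); hi <- max(pairs)
  coords <- lo:hi
  idx <- function(x) x - lo + 1L
  m <- length(coords)
  byStart <- split(seq_len(n), pairs[, 1])
  cnt <- matrix(NA_integer_, m + 1L, m + 1L)  # cnt[i, j+1], i > j allowed
  best <- function(i, j) {
    if (i > j) return(0L)
    if (!is.na(cnt[idx(i), idx(j) + 1L])) return(cnt[idx(i), idx(j) + 1L])
    r <- best(i + 1L, j)
    cand <- byStart[[as.character(i)]]
    if (!is.null(cand)) for (p in cand) {
      k <- pairs[p, 2]
      if (k <= j) r <- max(r, 1L + best(i + 1L, k - 1L) + best(k + 1L, j))
    }
    cnt[idx(i), idx(j) + 1L] <<- r
    r
  }
  total <- best(lo, hi)
  sel <- integer(0)
  trace <- function(i, j) {
    while (i <= j) {
      target <- best(i, j)
      if (target == 0L) return(invisible(NULL))
      cand <- byStart[[as.character(i)]]
      chosen <- FALSE
      if (!is.null(cand)) {
        ks <- sort(pairs[cand, 2])
        for (k in ks) {
          if (k <= j && 1L + best(i + 1L, k - 1L) + best(k + 1L, j) == target) {
            p <- cand[pairs[cand, 2] == k][1L]
            sel <<- c(sel, p)
            trace(i + 1L, k - 1L)
            i <- k + 1L
            chosen <- TRUE
            break
          }
        }
      }
      if (!chosen) i <- i + 1L
    }
    invisible(NULL)
  }
  trace(lo, hi)
  stopifnot(length(sel) == total)
  sort(sel)
}

#' Multilayer constrained fold
#'
#' Layer 1 folds the full alignment with the motif grammar, forcing the
#' layer-1 nested covarying pairs and forbidding the negative pairs. Each
#' further layer folds with the small layer grammar, forcing that layer's
#' pairs and forbidding negatives plus all pairs already placed. Overlaps
#' between layers (triplets, alternative helices) are reported in the
#' result, not resolved.
#'
#' @param pa a \linkS4class{ProbAlignment}
#' @param grammar the motif \linkS4class{FoldGrammar} for layer 1
#' @param layerGrammar a layer \linkS4class{FoldGrammar} (built if NULL)
#' @param layers list of pair matrices from \code{decomposeLayers} (may be
#'   empty for an unconstrained fold)
#' @param negatives two-column matrix of negative pairs
#' @return a \linkS4class{ParseResult} with one pair matrix per layer
#' @export
foldMultilayer <- function(pa, grammar, layerGrammar = NULL,
                           layers = list(), negatives = NULL) {
  if (length(layers) && nrow(layers[[1]]) && !is.null(negatives) &&
      nrow(negatives)) {
    fk <- unlist(lapply(layers, function(m) paste(m[, 1], m[, 2])))
    nk <- paste(negatives[, 1], negatives[, 2])
    if (length(intersect(fk, nk)))
      .stopf("a positive (forced) pair is also negative: infeasible")
  }
  forced1 <- if (length(layers)) layers[[1]] else NULL
  res <- tryCatch(
    foldCYK(pa, grammar,
            foldConstraints(forced = forced1, forbidden = negatives)),
    error = function(e) .stopf("layer 1 infeasible: %s", conditionMessage(e)))
  outLayers <- res@layers
  placed <- outLayers[[1]]
  if (length(layers) > 1L) {
    if (is.null(layerGrammar)) layerGrammar <- buildLayerGrammar(grammar@params)
    for (ly in 2:length(layers)) {
      forb <- rbind(negatives, placed)
      lr <- tryCatch(
        foldLayer(pa, layerGrammar,
                  foldConstraints(forced = layers[[ly]], forbidden = forb)),
        error = function(e)
          .stopf("layer %d infeasible (pairs %s): %s", ly,
                 paste(apply(layers[[ly]], 1, paste, collapse = "-"),
                       collapse = ","), conditionMessage(e)))
      keptPairs <- .keepCovariedHelices(lr$pairs, layers[[ly]])
      outLayers[[ly]] <- keptPairs
      placed <- rbind(placed, keptPairs)
    }
  }
  ov <- .layerOverlaps(outLayers)
  if (nrow(ov))
    message(nrow(ov), " position(s) engaged by more than one layer ",
            "(possible triplets or alternative helices); left unresolved")
  new("ParseResult", layers = outLayers, motifCalls = res@motifCalls,
      logProb = res@logProb, L = res@L, keptColumns = res@keptColumns) ->
    out
  attr(out, "tree") <- attr(res, "tree")
  attr(out, "overlaps") <- ov
  out
}

# layers beyond the first only exist to place covarying pairs: retain the
# forced pairs and their helix extensions, discard helices the layer
# grammar invented without covariation support
.keepCovariedHelices <- function(pairs, forced) {
  if (!nrow(pairs)) return(pairs)
  hid <- .helixIds(pairs)
  fk <- paste(forced[, 1], forced[, 2])
  keepH <- unique(hid[match(fk, paste(pairs[, 1], pairs[, 2]))])
  keepH <- keepH[!is.na(keepH)]
  pairs[hid %in% keepH, , drop = FALSE]
}

.layerOverlaps <- function(layers) {
  pos <- unlist(lapply(layers, function(m) as.vector(m[, 1:2])))
  dup <- unique(pos[duplicated(pos)])
  data.frame(position = dup)
}

#' Flag motif calls by covariation support
#'
#' A motif is supported if at least one of its bounding helices (the helix
#' closed by the loop's closing pair and, for multibranch motifs, each
#' enclosed helix) contains at least one positive covarying pair. Helices
#' are maximal stacks of pairs with adjacent indices; a lone pair counts as
#' a helix.
#'
#' @param parse a \linkS4class{ParseResult}
#' @param pairset a \linkS4class{PairSet}
#' @return the parse with \code{motifCalls$supported} filled in
#' @export
annotateSupport <- function(parse, pairset) {
  calls <- parse@motifCalls
  if (!nrow(calls)) return(parse)
  pairs <- parse@layers[[1]]
  helixId <- .helixIds(pairs)
  pk <- paste(pairs[, 1], pairs[, 2])
  pos <- pairset@positives
  posInHelix <- unique(helixId[match(paste(pos[, 1], pos[, 2]), pk)])
  posInHelix <- posInHelix[!is.na(posInHelix)]
  supported <- logical(nrow(calls))
  for (r in seq_len(nrow(calls))) {
    bnd <- calls$bounding[[r]]
    hids <- unique(unlist(lapply(bnd, function(p)
      helixId[match(paste(p[1], p[2]), pk)])))
    supported[r] <- any(hids %in% posInHelix)
  }
  calls$supported <- supported
  methods::initialize(parse, motifCalls = calls)
}

# helix membership: pairs (i,j) and (i+1,j-1) belong to the same helix
.helixIds <- function(pairs) {
  n <- nrow(pairs)
  if (!n) return(integer(0))
  ord <- order(pairs[, 1])
  id <- integer(n)
  key <- paste(pairs[, 1], pairs[, 2])
  cur <- 0L
  for (r in ord) {
    innerOf <- match(paste(pairs[r, 1] - 1L, pairs[r, 2] + 1L), key)
    if (!is.na(innerOf) && id[innerOf] > 0L) id[r] <- id[innerOf]
    else { cur <- cur + 1L; id[r] <- cur }
  }
  id
}

#' Control-based false discovery report
#'
#' Given motif counts on real alignments and on column-shuffled controls,
#' reports the estimated false discovery rate separately for
#' covariation-supported and unsupported predictions, and (optionally) the
#' expected number of helices with a covarying pair under the null.
#'
#' @param nRealSupported,nRealTotal supported / total motif counts on real
#'   alignments
#' @param nCtrlSupported,nCtrlTotal the same counts on shuffled controls
#' @param threshold E-value cutoff (for the null helix expectation)
#' @param nCtrlHelices number of helices in the control predictions
#' @return list with \code{fdrSupported} and \code{fdrUnsupported} (percent;
#'   NA when undefined) and \code{nullHelixExpect} if computable
#' @export
fdrReport <- function(nRealSupported, nRealTotal, nCtrlSupported,
                      nCtrlTotal, threshold = NULL, nCtrlHelices = NULL) {
  stopifnot(nRealSupported <= nRealTotal, nCtrlSupported <= nCtrlTotal,
            min(nRealSupported, nRealTotal, nCtrlSupported, nCtrlTotal) >= 0)
  fdrS <- if (nRealSupported > 0) 100 * nCtrlSupported / nRealSupported
          else NA_real_
  den <- nRealTotal - nRealSupported
  fdrU <- if (den > 0) 100 * (nCtrlTotal - nCtrlSupported) / den
          else NA_real_
  out <- list(fdrSupported = fdrS, fdrUnsupported = fdrU)
  if (!is.null(threshold) && !is.null(nCtrlHelices))
    out$nullHelixExpect <- threshold * nCtrlHelices
  out
}
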