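# Constrained folding engine: CYK (maximum-probability derivation) and
# inside (summed probability) dynamic programming over a probabilistic
# alignment, with traceback to base pairs and motif calls.
#
# All tables are indexed by kept-column spans [i, j] (1-based, inclusive).
# Multiway rules are binarized internally through helper tables; helper
# tables are an implementation device, not grammar nonterminals.

#' Construct a folding constraint set
#'
#' Coordinates are 1-based original alignment columns. Forced pairs must be
#' mutually nested within a layer; a position in a forced pair may only pair
#' with its partner and may not be left unpaired. Forbidden pairs score
#' -Inf; forbidden positions may not pair at all.
#'
#' @param forced,forbidden two-column matrices of pairs (or NULL)
#' @param forbiddenPos integer vector of unpairable positions
#' @return a constraint list for \code{foldCYK}/\code{insideLogProb}
#' @export
foldConstraints <- function(forced = NULL, forbidden = NULL,
                            forbiddenPos = integer(0)) {
  norm <- function(m) {
    if (is.null(m) || !length(m)) return(matrix(integer(0), 0, 2))
    m <- as.matrix(m)[, 1:2, drop = FALSE]
    storage.mode(m) <- "integer"
    t(apply(m, 1, sort))
  }
  list(forced = norm(forced), forbidden = norm(forbidden),
       forbiddenPos = as.integer(forbiddenPos))
}

# map constraints into kept coordinates and validate
.mapConstraints <- function(constraints, kept) {
  if (is.null(constraints)) constraints <- foldConstraints()
  mapPair <- function(m, what, dropMissing) {
    if (!nrow(m)) return(matrix(integer(0), 0, 2))
    a <- .origToKept(kept, m[, 1]); b <- .origToKept(kept, m[, 2])
    bad <- is.na(a) | is.na(b)
    if (any(bad) && !dropMissing)
      .stopf("%s pair (%d,%d) touches a gap-filtered column",
             what, m[which(bad)[1], 1], m[which(bad)[1], 2])
    if (any(bad)) { a <- a[!bad]; b <- b[!bad] }
    cbind(a, b)
  }
  forced <- mapPair(constraints$forced, "forced", FALSE)
  forbidden <- mapPair(constraints$forbidden, "forbidden", TRUE)
  fpos <- .origToKept(kept, constraints$forbiddenPos)
  fpos <- fpos[!is.na(fpos)]
  if (nrow(forced)) {
    if (any(forced[, 1] == forced[, 2]))
      .stopf("forced pair of a single column is infeasible")
    ends <- as.vector(forced)
    if (anyDuplicated(ends))
      .stopf("a column appears in two forced pairs of the same layer")
    ord <- order(forced[, 1])
    f <- forced[ord, , drop = FALSE]
    if (nrow(f) > 1) for (a in 1:(nrow(f) - 1)) for (b in (a + 1):nrow(f)) {
      if (f[a, 1] < f[b, 1] && f[b, 1] < f[a, 2] && f[a, 2] < f[b, 2])
        .stopf("forced pairs cross within a layer: (%d,%d) and (%d,%d)",
               f[a, 1], f[a, 2], f[b, 1], f[b, 2])
    }
    if (nrow(forbidden)) {
      fk <- paste(forced[, 1], forced[, 2])
      bk <- paste(forbidden[, 1], forbidden[, 2])
      if (length(intersect(fk, bk)))
        .stopf("a forced pair is also forbidden: infeasible constraints")
    }
  }
  list(forced = forced, forbidden = forbidden, forbiddenPos = fpos)
}

# ---- engine context -----------------------------------------------------

# Precomputed emission scores, constraint masks, rule probabilities and
# per-variant motif segment/group tables for one (pa, grammar, constraints,
# mode) combination.
.engineContext <- function(pa, grammar, constraints = NULL, mode = "max") {
  E <- new.env(parent = emptyenv())
  E$mode <- mode
  E$accv <- if (mode == "max") {
    function(v) if (length(v)) max(v) else -Inf
  } else logSumExp
  n <- .nKept(pa)
  if (n < 1L) .stopf("alignment has no kept columns")
  E$n <- n
  E$kept <- pa@keptColumns
  E$pa <- pa
  E$opts <- grammar@options
  p <- grammar@params
  E$rp <- .effectiveRuleProbs(grammar)
  cs <- .mapConstraints(constraints, E$kept)
  E$cs <- cs

  fp <- integer(n)
  if (nrow(cs$forced)) {
    fp[cs$forced[, 1]] <- cs$forced[, 2]
    fp[cs$forced[, 2]] <- cs$forced[, 1]
  }
  E$forcedPartner <- fp
  forb <- matrix(FALSE, n, n)
  if (nrow(cs$forbidden)) forb[cs$forbidden] <- TRUE
  isFpos <- rep(FALSE, n); isFpos[cs$forbiddenPos] <- TRUE
  E$allowed <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    E$allowed[i, j] <- !forb[i, j] && !isFpos[i] && !isFpos[j] &&
      (fp[i] == 0L || fp[i] == j) && (fp[j] == 0L || fp[j] == i)
  }

  # single-column emission scores and run helpers
  sf <- pa@singleFreq
  E$w1 <- log(as.vector(crossprod(sf, p@eSingle)))
  E$cumw1 <- c(0, cumsum(E$w1))
  isForced <- fp > 0L
  mf <- integer(n + 1L)                 # free run length starting at i
  for (i in n:1) mf[i] <- if (isForced[i]) 0L else mf[i + 1L] + 1L
  E$maxFreeFrom <- mf
  mb <- integer(n + 1L)                 # free run length ending at j (mb[j+1])
  for (j in 1:n) mb[j + 1L] <- if (isForced[j]) 0L else mb[j] + 1L
  E$maxFreeTo <- mb[-1L]
  E$unpairFree <- !isForced

  gv <- lapply(names(RUN_MIN), function(ctx)
    .geomLog(0:n, RUN_MIN[[ctx]], p@runGeom[[ctx]]))
  names(gv) <- names(RUN_MIN)
  E$geom <- gv
  # run starting at i, lengths 0..lmax
  E$runVec <- function(i, lmax, ctx) {
    l <- 0:lmax
    out <- gv[[ctx]][l + 1L] + (E$cumw1[i + l] - E$cumw1[i])
    out[l > mf[i]] <- -Inf
    out
  }
  # run ending at j, lengths 1..lmax
  E$runVecRight <- function(j, lmax, ctx) {
    l <- seq_len(lmax)
    out <- gv[[ctx]][l + 1L] + (E$cumw1[j + 1L] - E$cumw1[j + 1L - l])
    out[l > E$maxFreeTo[j]] <- -Inf
    out
  }
  E$runScore <- function(i, j, ctx) {   # exact span i..j (len may be 0)
    len <- j - i + 1L
    if (len == 0L) return(gv[[ctx]][1L])
    if (len > mf[i]) return(-Inf)
    gv[[ctx]][len + 1L] + (E$cumw1[j + 1L] - E$cumw1[i])
  }

  # pair emission matrices
  WP <- matrix(-Inf, n, n); WPS <- matrix(-Inf, n, n)
  ePv <- p@ePair; eSt <- p@eStack
  pfFlat <- function(i, j) as.vector(t(pairFreq(pa, i, j)))  # .pairCode layout
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!E$allowed[i, j]) next
    pf <- pairFreq(pa, i, j)
    WP[i, j] <- log(sum(pf * ePv))
    if (i > 1L && j < n && E$allowed[i - 1L, j + 1L]) {
      mixRow <- as.vector(pfFlat(i - 1L, j + 1L) %*% eSt)
      WPS[i, j] <- log(sum(pfFlat(i, j) * mixRow))
    }
  }
  E$WP <- WP; E$WPS <- WPS

  # motif variant machinery
  E$hl <- list(); E$bs <- list(); E$mv <- list()
  E$slotIdx <- list(BLleft = integer(0), BLright = integer(0),
                    IL = integer(0), J3 = integer(0), J4 = integer(0))
  grp <- E$rp$groups
  segAll <- function(ph) .segForwardAll(E, ph)
  buildGroups <- function(v) {
    lay <- .variantLayout(v, grammar@phmms[[v@uniqueId]],
                          slack = E$opts$segSlack)
    Gs <- list()
    for (g in seq_along(lay)) {
      if (lay[[g]]$kind != "seg") { Gs[[g]] <- NULL; next }
      Gs[[g]] <- .groupForwardAll(E, lay[[g]], segAll)
    }
    list(layout = lay, G = Gs)
  }
  addChain <- function(v, slot) {
    bg <- buildGroups(v)
    segIdx <- which(vapply(bg$layout, function(x) x$kind == "seg", TRUE))
    E$mv[[length(E$mv) + 1L]] <- list(
      v = v, slot = slot, layout = bg$layout,
      G = bg$G[segIdx],                       # group tables in order 1..m+1
      caps = vapply(bg$layout[segIdx], function(x) x$cap, integer(1)),
      m = sum(vapply(bg$layout, function(x) x$kind == "helix", TRUE)))
    E$slotIdx[[slot]] <- c(E$slotIdx[[slot]], length(E$mv))
  }
  for (v in grp$HL) {
    bg <- buildGroups(v)
    E$hl[[length(E$hl) + 1L]] <- list(v = v, G = bg$G[[1L]],
                                      cap = bg$layout[[1L]]$cap)
  }
  for (v in grp$BS) {
    bg <- buildGroups(v)
    E$bs[[length(E$bs) + 1L]] <- list(v = v, G = bg$G[[1L]],
                                      cap = bg$layout[[1L]]$cap,
                                      empty = bg$G[[1L]][n + 1L, 1L])
  }
  for (v in grp$BLleft) addChain(v, "BLleft")
  for (v in grp$BLright) addChain(v, "BLright")
  for (v in grp$IL) addChain(v, "IL")
  for (v in grp$J3) addChain(v, "J3")
  for (v in grp$J4) addChain(v, "J4")
  E
}

# forward scores of one profile HMM against every slice: matrix with rows
# start i (1..n+1) and columns length 0..cap; one DP per start gives all
# lengths at once.
.segForwardAll <- function(E, phmm) {
  n <- E$n
  cap <- { Lc <- nchar(phmm@consensus)
           if (Lc == 0L) max(2L, E$opts$segSlack %/% 2L)
           else Lc + E$opts$segSlack }
  Lc <- nchar(phmm@consensus)
  lq <- log(phmm@q); l1q <- log1p(-phmm@q)
  ld <- if (phmm@d > 0) log(phmm@d) else -Inf
  l1d <- log1p(-phmm@d)
  sf <- E$pa@singleFreq
  insE <- log(as.vector(crossprod(sf, phmm@insertEmission)))
  matE <- if (Lc) log(crossprod(sf, phmm@matchEmissions)) else NULL  # [col, pos]
  out <- matrix(-Inf, n + 1L, cap + 1L)
  emptyScore <- {  # all-delete, no-insert path
    v <- l1q * (Lc + 1L) + ld * Lc
    v
  }
  for (i in seq_len(n + 1L)) {
    kmax <- min(cap, n - i + 1L)
    if (i <= n && E$maxFreeFrom[i] < kmax) kmax <- E$maxFreeFrom[i]
    if (i > n) kmax <- 0L
    A <- matrix(-Inf, Lc + 1L, kmax + 1L)
    A[1L, 1L] <- 0
    if (kmax > 0L) for (k in seq_len(kmax))
      A[1L, k + 1L] <- A[1L, k] + lq + insE[i + k - 1L]
    if (Lc > 0L) for (s in seq_len(Lc)) {
      A[s + 1L, 1L] <- A[s, 1L] + l1q + ld
      if (kmax > 0L) for (k in seq_len(kmax)) {
        col <- i + k - 1L
        A[s + 1L, k + 1L] <- logSumExp(c(
          A[s + 1L, k] + lq + insE[col],
          A[s, k] + l1q + l1d + matE[col, s],
          A[s, k + 1L] + l1q + ld))
      }
    }
    out[i, 1:(kmax + 1L)] <- A[Lc + 1L, 1:(kmax + 1L)] + l1q
  }
  out[n + 1L, 1L] <- emptyScore
  out
}

# combine the segments of one group into a single start x length table;
# splits between consecutive segments are folded into the score (max or sum
# by mode), so they are not derivation choices.
.groupForwardAll <- function(E, group, segAll) {
  n <- E$n
  segs <- group$phmms
  if (!length(segs)) {   # empty group: consumes exactly zero columns
    out <- matrix(-Inf, n + 1L, 1L)
    out[, 1L] <- 0
    return(out)
  }
  tabs <- lapply(segs, segAll)
  caps <- group$segCaps
  cap <- group$cap
  out <- matrix(-Inf, n + 1L, cap + 1L)
  for (i in seq_len(n + 1L)) {
    lmax <- min(cap, n - i + 1L)
    # D[l+1] after t segments = best/sum score of first t segments covering
    # columns i .. i+l-1
    D <- rep(-Inf, lmax + 1L); D[1L] <- 0
    for (t in seq_along(tabs)) {
      Dn <- rep(-Inf, lmax + 1L)
      for (l in 0:lmax) {
        dls <- 0:min(caps[t], l)
        prev <- D[l - dls + 1L]
        starts <- i + l - dls
        segv <- tabs[[t]][cbind(starts, dls + 1L)]
        Dn[l + 1L] <- E$accv(prev + segv)
      }
      D <- Dn
    }
    out[i, 1:(lmax + 1L)] <- D
  }
  out
}

# ---- table fill ---------------------------------------------------------

.fillTables <- function(E) {
  n <- E$n; rp <- E$rp; opts <- E$opts; accv <- E$accv
  mk <- function() matrix(-Inf, n, n)
  S <- mk(); F0 <- mk(); F5 <- mk(); P <- mk()
  BB <- mk(); BT <- mk(); Rt <- mk()
  T2g <- mk(); body3 <- mk(); body4 <- mk()
  MR <- mk(); N1 <- mk(); N2 <- mk(); bodyN <- mk()
  J3t <- mk(); J4t <- mk()
  nmv <- length(E$mv)
  A <- vector("list", nmv); Tt <- vector("list", nmv)
  for (t in seq_len(nmv)) {
    A[[t]] <- replicate(E$mv[[t]]$m, mk(), simplify = FALSE)
    Tt[[t]] <- replicate(E$mv[[t]]$m, mk(), simplify = FALSE)
  }
  Sempty <- rp$S[["end"]]
  Rempty <- E$geom$ml[1L]
  BTempty <- accv(c(rp$BT$gen + E$geom$ml[1L],
                    if (length(E$bs))
                      rp$BT$motif + vapply(E$bs, `[[`, 0, "empty")))
  E$Sempty <- Sempty; E$Rempty <- Rempty; E$BTempty <- BTempty

  for (len in seq_len(n)) for (i in seq_len(n - len + 1L)) {
    j <- i + len - 1L
    # helices ------------------------------------------------------------
    if (len >= 5L && E$allowed[i, j]) {
      ii <- i + 1L; jj <- j - 1L
      F0[i, j] <- E$WP[i, j] + accv(c(rp$F0[["pairF5"]] + F5[ii, jj],
                                      rp$F0[["pairP"]] + P[ii, jj]))
      if (i > 1L && j < n && is.finite(E$WPS[i, j]))
        F5[i, j] <- E$WPS[i, j] + accv(c(rp$F5[["pairF5"]] + F5[ii, jj],
                                         rp$F5[["pairP"]] + P[ii, jj]))
    }
    # multiloop branches -------------------------------------------------
    if (len >= 5L) {
      lmax <- min(opts$maxMlRun, len - 5L)
      cands <- rp$BB$gen +
        accv(E$runVec(i, lmax, "ml") + F0[cbind(i + 0:lmax, j)])
      if (length(E$bs)) for (b in seq_along(E$bs)) {
        lb <- min(E$bs[[b]]$cap, len - 5L)
        cands <- c(cands, rp$BB$motif[b] +
          accv(E$bs[[b]]$G[i, 1:(lb + 1L)] + F0[cbind(i + 0:lb, j)]))
      }
      BB[i, j] <- accv(cands)
    }
    bt <- rp$BT$gen + E$runScore(i, j, "ml")
    if (length(E$bs)) for (b in seq_along(E$bs))
      if (len <= E$bs[[b]]$cap)
        bt <- c(bt, rp$BT$motif[b] + E$bs[[b]]$G[i, len + 1L])
    BT[i, j] <- accv(bt)
    Rt[i, j] <- E$runScore(i, j, "ml")
    # generic junction helpers -------------------------------------------
    if (len >= 5L) {
      ss <- if (j - 1L >= i + 4L) (i + 4L):(j - 1L) else integer(0)
      bbv <- BB[cbind(i, ss)]
      T2g[i, j] <- accv(c(bbv + BT[cbind(ss + 1L, j)],
                          BB[i, j] + E$BTempty))
      MR[i, j] <- accv(c(rp$M1[["more"]] + bbv + MR[cbind(ss + 1L, j)],
                         rp$M1[["last"]] + bbv + Rt[cbind(ss + 1L, j)],
                         rp$M1[["last"]] + BB[i, j] + Rempty))
      if (length(ss)) {
        body3[i, j] <- accv(bbv + T2g[cbind(ss + 1L, j)])
        body4[i, j] <- accv(bbv + body3[cbind(ss + 1L, j)])
        N1[i, j] <- accv(bbv + MR[cbind(ss + 1L, j)])
        N2[i, j] <- accv(bbv + N1[cbind(ss + 1L, j)])
        bodyN[i, j] <- accv(bbv + N2[cbind(ss + 1L, j)])
      }
    }
    # motif chain tables -------------------------------------------------
    if (nmv && len >= 5L) for (t in seq_len(nmv)) {
      mv <- E$mv[[t]]; m <- mv$m
      for (k in seq_len(m)) {
        lk <- min(mv$caps[k], len - 5L)
        if (lk >= 0L)
          A[[t]][[k]][i, j] <- accv(mv$G[[k]][i, 1:(lk + 1L)] +
                                    F0[cbind(i + 0:lk, j)])
      }
      tmax <- min(mv$caps[m + 1L], len - 5L)
      if (tmax >= 0L) {
        tv <- 0:tmax
        Tt[[t]][[m]][i, j] <- accv(A[[t]][[m]][cbind(i, j - tv)] +
                                   mv$G[[m + 1L]][cbind(j - tv + 1L, tv + 1L)])
      }
      if (m > 1L) for (k in (m - 1L):1L) {
        ss <- if (j - 5L >= i + 4L) (i + 4L):(j - 5L) else integer(0)
        if (length(ss))
          Tt[[t]][[k]][i, j] <- accv(A[[t]][[k]][cbind(i, ss)] +
                                     Tt[[t]][[k + 1L]][cbind(ss + 1L, j)])
      }
    }
    # junction nonterminals ----------------------------------------------
    if (len >= 10L) {
      jc <- rp$J3$gen + body3[i, j]
      for (w in seq_along(E$slotIdx$J3))
        jc <- c(jc, rp$J3$motif[w] + Tt[[E$slotIdx$J3[w]]][[1L]][i, j])
      J3t[i, j] <- accv(jc)
      jc <- rp$J4$gen + body4[i, j]
      for (w in seq_along(E$slotIdx$J4))
        jc <- c(jc, rp$J4$motif[w] + Tt[[E$slotIdx$J4[w]]][[1L]][i, j])
      J4t[i, j] <- accv(jc)
    }
    # loop nonterminal P --------------------------------------------------
    if (len >= 3L) {
      cand <- rp$hairpin$gen + E$runScore(i, j, "hairpin")
      if (length(E$hl)) for (h in seq_along(E$hl))
        if (len <= E$hl[[h]]$cap)
          cand <- c(cand, rp$hairpin$motif[h] + E$hl[[h]]$G[i, len + 1L])
      if (len >= 6L) {
        lmax <- min(opts$maxBulge, len - 5L)
        lv <- seq_len(lmax)
        cand <- c(cand,
          rp$bulgeL$gen + accv(E$runVec(i, lmax, "bulge")[-1L] +
                               F0[cbind(i + lv, j)]),
          rp$bulgeR$gen + accv(E$runVecRight(j, lmax, "bulge") +
                               F0[cbind(i, j - lv)]))
      }
      if (len >= 7L) {
        l1max <- min(opts$maxIntLoop, len - 6L)
        intc <- rep(-Inf, l1max)
        for (l1 in seq_len(l1max)) {
          left <- E$runVec(i, l1, "internal")[l1 + 1L]
          if (!is.finite(left)) next
          l2max <- min(opts$maxIntLoop, len - 5L - l1)
          l2v <- seq_len(l2max)
          intc[l1] <- accv(left + E$runVecRight(j, l2max, "internal") +
                           F0[cbind(i + l1, j - l2v)])
        }
        cand <- c(cand, rp$internal$gen + accv(intc))
      }
      if (len >= 5L) {
        for (w in seq_along(E$slotIdx$BLleft))
          cand <- c(cand, rp$bulgeL$motif[w] +
                    Tt[[E$slotIdx$BLleft[w]]][[1L]][i, j])
        for (w in seq_along(E$slotIdx$BLright))
          cand <- c(cand, rp$bulgeR$motif[w] +
                    Tt[[E$slotIdx$BLright[w]]][[1L]][i, j])
        for (w in seq_along(E$slotIdx$IL))
          cand <- c(cand, rp$internal$motif[w] +
                    Tt[[E$slotIdx$IL[w]]][[1L]][i, j])
      }
      if (len >= 10L)
        cand <- c(cand, rp$PJ3 + J3t[i, j], rp$PJ4 + J4t[i, j],
                  rp$PJN + bodyN[i, j])
      P[i, j] <- accv(cand)
    }
    # top-level S ---------------------------------------------------------
    sc <- if (E$unpairFree[i])
      rp$S[["aS"]] + E$w1[i] + (if (i == j) Sempty else S[i + 1L, j])
      else -Inf
    if (len >= 5L) {
      ks <- (i + 4L):j
      rest <- c(if (j > i + 4L) S[cbind(ks[-length(ks)] + 1L, j)], Sempty)
      sc <- c(sc, rp$S[["F0S"]] + F0[cbind(i, ks)] + rest)
    }
    S[i, j] <- accv(sc)
  }
  E$S <- S; E$F0 <- F0; E$F5 <- F5; E$P <- P
  E$BB <- BB; E$BT <- BT; E$Rt <- Rt
  E$T2g <- T2g; E$body3 <- body3; E$body4 <- body4
  E$MR <- MR; E$N1 <- N1; E$N2 <- N2; E$bodyN <- bodyN
  E$J3t <- J3t; E$J4t <- J4t
  E$A <- A; E$Tt <- Tt
  invisible(E)
}

#' Inside log probability of an alignment under a grammar
#'
#' Sum over all derivations respecting the constraints; always at least the
#' CYK (maximum derivation) score.
#'
#' @param pa a \linkS4class{ProbAlignment}
#' @param grammar a \linkS4class{FoldGrammar} of type rbgj3j4 or r3d
#' @param constraints optional \code{foldConstraints()}
#' @return log total probability
#' @export
insideLogProb <- function(pa, grammar, constraints = NULL) {
  if (grammar@type == "layer") .stopf("use foldLayer for layer grammars")
  E <- .engineContext(pa, grammar, constraints, mode = "sum")
  .fillTables(E)
  E$S[1L, E$n]
}

#' Maximum-probability constrained fold with motif calls
#'
#' Runs the CYK recursion over the probabilistic alignment and traces back
#' the optimal derivation. Ties are broken deterministically by a fixed rule
#' order (generic loop before motif, unpaired before paired, shortest run /
#' leftmost split first).
#'
#' @param pa a \linkS4class{ProbAlignment}
#' @param grammar a \linkS4class{FoldGrammar} of type rbgj3j4 or r3d
#' @param constraints optional \code{foldConstraints()}
#' @return a \linkS4class{ParseResult} (single layer); the parse tree is
#'   attached as attribute \code{"tree"}
#' @export
foldCYK <- function(pa, grammar, constraints = NULL) {
  if (grammar@type == "layer") .stopf("use foldLayer for layer grammars")
  E <- .engineContext(pa, grammar, constraints, mode = "max")
  .fillTables(E)
  top <- E$S[1L, E$n]
  if (!is.finite(top))
    .stopf("constraints are unsatisfiable: no derivation has finite probability")
  tb <- .traceback(E)
  pairsKept <- tb$pairs
  orig <- function(x) E$kept[x]
  pm <- if (length(pairsKept)) {
    m <- do.call(rbind, pairsKept)
    m <- m[order(m[, 1]), , drop = FALSE]
    cbind(orig(m[, 1]), orig(m[, 2]))
  } else matrix(integer(0), 0, 2)
  colnames(pm) <- c("i", "j")
  calls <- .motifCallFrame(tb$motifs, E)
  res <- new("ParseResult", layers = list(pm), motifCalls = calls,
             logProb = top, L = length(pa@gapFraction),
             keptColumns = E$kept)
  attr(res, "tree") <- tb$tree
  res
}

.motifCallFrame <- function(motifList, E) {
  orig <- function(x) E$kept[x]
  if (!length(motifList))
    return(data.frame(name = character(0), class = character(0),
                      variant = integer(0), start = integer(0),
                      end = integer(0), logScore = numeric(0),
                      supported = logical(0), segments = character(0),
                      bounding = I(list())))
  rows <- lapply(motifList, function(m) {
    segs <- paste(vapply(m$groupSpans, function(sp) {
      if (sp[1] > sp[2]) "-" else paste0(orig(sp[1]), "-", orig(sp[2]))
    }, character(1)), collapse = ";")
    bnd <- m$bounding
    if (length(bnd)) bnd <- lapply(bnd, function(p) c(orig(p[1]), orig(p[2])))
    data.frame(name = m$name, class = m$class, variant = m$variant,
               start = orig(m$i), end = orig(m$j), logScore = m$logScore,
               supported = NA, segments = segs,
               bounding = I(list(bnd)))
  })
  do.call(rbind, rows)
}
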