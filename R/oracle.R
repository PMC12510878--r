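# Brute-force enumeration oracle: exhaustively lists every derivation of
# the grammar for a (small) input and scores each one directly, without any
# shared dynamic programming tables. Used to validate the CYK maximum, the
# inside sum, and the grammar's unambiguity on inputs of modest length.
#
# A "derivation" is an outer parse tree: rule applications, run lengths,
# helix placements and motif placements. Segmentation within a motif group
# and profile-HMM state paths are part of the emission model, not the
# derivation; their max/sum is folded into the group score tables.

#' Enumerate all derivations of an alignment under a grammar
#'
#' Exponential in input length; intended for lengths up to ~10. Each row of
#' the result is one derivation with its log probability under max-mode
#' motif-group scoring (\code{lpMax}, comparable to CYK) and sum-mode
#' scoring (\code{lpSum}; their log-sum-exp equals the inside probability),
#' the base-pair set and the motif annotation.
#'
#' @param pa a \linkS4class{ProbAlignment}
#' @param grammar a \linkS4class{FoldGrammar} (rbgj3j4 or r3d)
#' @param constraints optional \code{foldConstraints()}
#' @return data.frame with columns pairs, motifs, lpMax, lpSum
#' @export
enumerateDerivations <- function(pa, grammar, constraints = NULL) {
  Emax <- .engineContext(pa, grammar, constraints, mode = "max")
  Esum <- .engineContext(pa, grammar, constraints, mode = "sum")
  E <- Emax; n <- E$n
  rp <- E$rp; opts <- E$opts
  memo <- new.env(parent = emptyenv())

  alt <- function(lpMax, lpSum, pairs = character(0), motifs = character(0))
    list(lpMax = lpMax, lpSum = lpSum, pairs = pairs, motifs = motifs)
  lift <- function(alts, dMax, dSum = dMax) {
    lapply(alts, function(a)
      alt(a$lpMax + dMax, a$lpSum + dSum, a$pairs, a$motifs))
  }
  cross <- function(as, bs) {
    out <- list()
    for (a in as) for (b in bs)
      out[[length(out) + 1L]] <- alt(a$lpMax + b$lpMax, a$lpSum + b$lpSum,
                                     c(a$pairs, b$pairs),
                                     c(a$motifs, b$motifs))
    out
  }
  getMemo <- function(key, producer) {
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- producer()
    assign(key, val, envir = memo)
    val
  }

  eS <- function(i, j) getMemo(paste0("S:", i, ":", j), function() {
    if (i > j) return(list(alt(rp$S[["end"]], rp$S[["end"]])))
    out <- list()
    if (E$unpairFree[i])
      out <- c(out, lift(eS(i + 1L, j), rp$S[["aS"]] + E$w1[i]))
    if (j >= i + 4L) for (k in (i + 4L):j)
      out <- c(out, lift(cross(eF0(i, k, "F0"), eS(k + 1L, j)),
                         rp$S[["F0S"]]))
    out
  })

  eF0 <- function(i, j, nt) getMemo(paste0(nt, ":", i, ":", j), function() {
    len <- j - i + 1L
    if (len < 5L || !E$allowed[i, j]) return(list())
    base <- if (nt == "F0") E$WP[i, j] else E$WPS[i, j]
    if (!is.finite(base)) return(list())
    pk <- paste0(i, "-", j)
    out <- c(lift(eF0(i + 1L, j - 1L, "F5"), rp[[nt]][["pairF5"]]),
             lift(eP(i + 1L, j - 1L), rp[[nt]][["pairP"]]))
    lapply(out, function(a) alt(a$lpMax + base, a$lpSum + base,
                                c(pk, a$pairs), a$motifs))
  })

  mkey <- function(v, i, j)
    sprintf("%s:%s:%d:%d-%d", v@descriptor@name, v@descriptor@motifClass,
            v@topologyIndex, i, j)

  eP <- function(i, j) getMemo(paste0("P:", i, ":", j), function() {
    len <- j - i + 1L
    out <- list()
    hp <- E$runScore(i, j, "hairpin")
    if (is.finite(hp)) out <- c(out, list(alt(rp$hairpin$gen + hp,
                                              rp$hairpin$gen + hp)))
    for (h in seq_along(E$hl))
      if (len <= E$hl[[h]]$cap) {
        gm <- E$hl[[h]]$G[i, len + 1L]
        gsum <- Esum$hl[[h]]$G[i, len + 1L]
        if (is.finite(gm))
          out <- c(out, list(alt(rp$hairpin$motif[h] + gm,
                                 rp$hairpin$motif[h] + gsum,
                                 motifs = mkey(E$hl[[h]]$v, i, j))))
      }
    if (len >= 6L) {
      lmax <- min(opts$maxBulge, len - 5L)
      for (l in seq_len(lmax)) {
        rl <- E$runVec(i, l, "bulge")[l + 1L]
        if (is.finite(rl))
          out <- c(out, lift(eF0(i + l, j, "F0"), rp$bulgeL$gen + rl))
        rr <- E$runVecRight(j, l, "bulge")[l]
        if (is.finite(rr))
          out <- c(out, lift(eF0(i, j - l, "F0"), rp$bulgeR$gen + rr))
      }
    }
    if (len >= 7L) {
      l1max <- min(opts$maxIntLoop, len - 6L)
      for (l1 in seq_len(l1max)) {
        rl <- E$runVec(i, l1, "internal")[l1 + 1L]
        if (!is.finite(rl)) next
        l2max <- min(opts$maxIntLoop, len - 5L - l1)
        for (l2 in seq_len(l2max)) {
          rr <- E$runVecRight(j, l2, "internal")[l2]
          if (is.finite(rr))
            out <- c(out, lift(eF0(i + l1, j - l2, "F0"),
                               rp$internal$gen + rl + rr))
        }
      }
    }
    if (len >= 10L) {
      out <- c(out, lift(eJ3(i, j), rp$PJ3))
      out <- c(out, lift(eJ4(i, j), rp$PJ4))
      out <- c(out, lift(eJN(i, j), rp$PJN))
    }
    for (w in seq_along(E$slotIdx$BLleft))
      out <- c(out, lift(eChain(E$slotIdx$BLleft[w], i, j),
                         rp$bulgeL$motif[w]))
    for (w in seq_along(E$slotIdx$BLright))
      out <- c(out, lift(eChain(E$slotIdx$BLright[w], i, j),
                         rp$bulgeR$motif[w]))
    for (w in seq_along(E$slotIdx$IL))
      out <- c(out, lift(eChain(E$slotIdx$IL[w], i, j),
                         rp$internal$motif[w]))
    out
  })

  eBB <- function(i, j) getMemo(paste0("BB:", i, ":", j), function() {
    len <- j - i + 1L
    if (len < 5L) return(list())
    out <- list()
    lmax <- min(opts$maxMlRun, len - 5L)
    rv <- E$runVec(i, lmax, "ml")
    for (l in 0:lmax)
      if (is.finite(rv[l + 1L]))
        out <- c(out, lift(eF0(i + l, j, "F0"), rp$BB$gen + rv[l + 1L]))
    for (b in seq_along(E$bs)) {
      lb <- min(E$bs[[b]]$cap, len - 5L)
      for (l in 0:lb) {
        gm <- E$bs[[b]]$G[i, l + 1L]; gs <- Esum$bs[[b]]$G[i, l + 1L]
        if (!is.finite(gm)) next
        sub <- lift(eF0(i + l, j, "F0"), rp$BB$motif[b] + gm,
                    rp$BB$motif[b] + gs)
        key <- mkey(E$bs[[b]]$v, i, i + l - 1L)
        sub <- lapply(sub, function(a) { a$motifs <- c(key, a$motifs); a })
        out <- c(out, sub)
      }
    }
    out
  })

  eBT <- function(i, j) getMemo(paste0("BT:", i, ":", j), function() {
    out <- list()
    if (i > j) {
      out <- c(out, list(alt(rp$BT$gen + E$geom$ml[1L],
                             rp$BT$gen + E$geom$ml[1L])))
      for (b in seq_along(E$bs))
        out <- c(out, list(alt(rp$BT$motif[b] + E$bs[[b]]$empty,
                               rp$BT$motif[b] + Esum$bs[[b]]$empty,
                               motifs = mkey(E$bs[[b]]$v, i, j))))
      return(out)
    }
    len <- j - i + 1L
    rs <- E$runScore(i, j, "ml")
    if (is.finite(rs)) out <- c(out, list(alt(rp$BT$gen + rs, rp$BT$gen + rs)))
    for (b in seq_along(E$bs))
      if (len <= E$bs[[b]]$cap && is.finite(E$bs[[b]]$G[i, len + 1L]))
        out <- c(out, list(alt(rp$BT$motif[b] + E$bs[[b]]$G[i, len + 1L],
                               rp$BT$motif[b] + Esum$bs[[b]]$G[i, len + 1L],
                               motifs = mkey(E$bs[[b]]$v, i, j))))
    out
  })

  eR <- function(i, j) {
    if (i > j) return(list(alt(E$geom$ml[1L], E$geom$ml[1L])))
    rs <- E$runScore(i, j, "ml")
    if (is.finite(rs)) list(alt(rs, rs)) else list()
  }

  eJ3 <- function(i, j) getMemo(paste0("J3:", i, ":", j), function() {
    out <- list()
    if (j - 1L >= i + 9L) for (s1 in (i + 4L):(j - 5L))
      for (s2 in (s1 + 5L):j) {
        sub <- cross(cross(eBB(i, s1), eBB(s1 + 1L, s2)), eBT(s2 + 1L, j))
        out <- c(out, lift(sub, rp$J3$gen))
      }
    for (w in seq_along(E$slotIdx$J3))
      out <- c(out, lift(eChain(E$slotIdx$J3[w], i, j), rp$J3$motif[w]))
    out
  })

  eJ4 <- function(i, j) getMemo(paste0("J4:", i, ":", j), function() {
    out <- list()
    if (j >= i + 14L) for (s1 in (i + 4L):(j - 10L))
      for (s2 in (s1 + 5L):(j - 5L)) for (s3 in (s2 + 5L):j) {
        sub <- cross(cross(cross(eBB(i, s1), eBB(s1 + 1L, s2)),
                           eBB(s2 + 1L, s3)), eBT(s3 + 1L, j))
        out <- c(out, lift(sub, rp$J4$gen))
      }
    for (w in seq_along(E$slotIdx$J4))
      out <- c(out, lift(eChain(E$slotIdx$J4[w], i, j), rp$J4$motif[w]))
    out
  })

  eM1R <- function(i, j) getMemo(paste0("M1R:", i, ":", j), function() {
    out <- list()
    if (j >= i + 4L) for (s in (i + 4L):j) {
      out <- c(out, lift(cross(eBB(i, s), eR(s + 1L, j)), rp$M1[["last"]]))
      if (s < j)
        out <- c(out, lift(cross(eBB(i, s), eM1R(s + 1L, j)), rp$M1[["more"]]))
    }
    out
  })

  eJN <- function(i, j) getMemo(paste0("JN:", i, ":", j), function() {
    out <- list()
    if (j < i + 19L) return(out)
    for (s1 in (i + 4L):(j - 15L)) for (s2 in (s1 + 5L):(j - 10L))
      for (s3 in (s2 + 5L):(j - 5L)) {
        sub <- cross(cross(cross(eBB(i, s1), eBB(s1 + 1L, s2)),
                           eBB(s2 + 1L, s3)), eM1R(s3 + 1L, j))
        out <- c(out, sub)
      }
    out
  })

  # motif chain: groups interleaved with enclosed helices; group extents are
  # determined by the helix placements
  eChain <- function(t, i, j) {
    mv <- E$mv[[t]]; mvs <- Esum$mv[[t]]; m <- mv$m
    vkey <- function(a) { a$motifs <- c(mkey(mv$v, i, j), a$motifs); a }
    rec <- function(k, ci) {
      if (k == m + 1L) {
        len <- j - ci + 1L
        if (len < 0L || len > mv$caps[m + 1L]) return(list())
        st <- min(ci, n + 1L)
        gm <- mv$G[[m + 1L]][st, len + 1L]
        if (!is.finite(gm)) return(list())
        return(list(alt(gm, mvs$G[[m + 1L]][st, len + 1L])))
      }
      out <- list()
      lmaxk <- min(mv$caps[k], j - ci + 1L - 5L)
      if (lmaxk < 0L) return(out)
      for (l in 0:lmaxk) {
        gm <- mv$G[[k]][ci, l + 1L]
        if (!is.finite(gm)) next
        gs <- mvs$G[[k]][ci, l + 1L]
        hs <- ci + l
        for (e in (hs + 4L):j) {
          sub <- cross(eF0(hs, e, "F0"), rec(k + 1L, e + 1L))
          out <- c(out, lift(sub, gm, gs))
        }
      }
      out
    }
    lapply(rec(1L, i), vkey)
  }

  alts <- eS(1L, n)
  if (!length(alts))
    return(data.frame(pairs = character(0), motifs = character(0),
                      lpMax = numeric(0), lpSum = numeric(0)))
  data.frame(
    pairs = vapply(alts, function(a)
      paste(sort(a$pairs), collapse = ","), character(1)),
    motifs = vapply(alts, function(a)
      paste(sort(a$motifs), collapse = ","), character(1)),
    lpMax = vapply(alts, `[[`, 0, "lpMax"),
    lpSum = vapply(alts, `[[`, 0, "lpSum"))
}
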