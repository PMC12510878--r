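# Traceback of the CYK tables into a parse tree, base pairs and motif
# calls; independent rescoring of a parse tree; and the small-grammar engine
# used for pseudoknot layers.

.TB_TOL <- 1e-9

.tbClose <- function(a, b) {
  is.finite(a) & abs(a - b) <= .TB_TOL * pmax(1, abs(b))
}

.traceback <- function(E) {
  rp <- E$rp; opts <- E$opts; n <- E$n
  pairs <- list(); motifs <- list()
  addPair <- function(i, j) pairs[[length(pairs) + 1L]] <<- c(i, j)
  addMotif <- function(rec) motifs[[length(motifs) + 1L]] <<- rec
  node <- function(nt, rule, i, j, kids = list(), ...)
    c(list(nt = nt, rule = rule, i = i, j = j, kids = kids), list(...))
  fail <- function(nt, i, j)
    .stopf("traceback failed at %s[%d,%d] (internal error)", nt, i, j)

  tbS <- function(i, j) {
    if (i > j) return(node("S", "end", i, j))
    v <- E$S[i, j]
    if (E$unpairFree[i]) {
      cand <- rp$S[["aS"]] + E$w1[i] +
        (if (i == j) E$Sempty else E$S[i + 1L, j])
      if (.tbClose(cand, v))
        return(node("S", "aS", i, j, kids = list(tbS(i + 1L, j)), pos = i))
    }
    if (j >= i + 4L) for (k in (i + 4L):j) {
      cand <- rp$S[["F0S"]] + E$F0[i, k] +
        (if (k == j) E$Sempty else E$S[k + 1L, j])
      if (.tbClose(cand, v))
        return(node("S", "F0S", i, j,
                    kids = list(tbF0(i, k, "F0"), tbS(k + 1L, j))))
    }
    fail("S", i, j)
  }

  tbF0 <- function(i, j, nt) {
    v <- if (nt == "F0") E$F0[i, j] else E$F5[i, j]
    base <- if (nt == "F0") E$WP[i, j] else E$WPS[i, j]
    addPair(i, j)
    ii <- i + 1L; jj <- j - 1L
    if (.tbClose(base + rp[[nt]][["pairP"]] + E$P[ii, jj], v))
      return(node(nt, "pairP", i, j, kids = list(tbP(ii, jj, c(i, j))),
                  pair = c(i, j)))
    if (.tbClose(base + rp[[nt]][["pairF5"]] + E$F5[ii, jj], v))
      return(node(nt, "pairF5", i, j, kids = list(tbF0(ii, jj, "F5")),
                  pair = c(i, j)))
    fail(nt, i, j)
  }

  tbP <- function(i, j, closing) {
    v <- E$P[i, j]; len <- j - i + 1L
    if (.tbClose(rp$hairpin$gen + E$runScore(i, j, "hairpin"), v))
      return(node("P", "hairpin", i, j, run = c(i, j)))
    if (len >= 6L) {
      lmax <- min(opts$maxBulge, len - 5L)
      rv <- E$runVec(i, lmax, "bulge")
      for (l in seq_len(lmax))
        if (.tbClose(rp$bulgeL$gen + rv[l + 1L] + E$F0[i + l, j], v))
          return(node("P", "bulgeL", i, j,
                      kids = list(tbF0(i + l, j, "F0")), run = c(i, i + l - 1L)))
      rvr <- E$runVecRight(j, lmax, "bulge")
      for (l in seq_len(lmax))
        if (.tbClose(rp$bulgeR$gen + rvr[l] + E$F0[i, j - l], v))
          return(node("P", "bulgeR", i, j,
                      kids = list(tbF0(i, j - l, "F0")), run = c(j - l + 1L, j)))
    }
    if (len >= 7L) {
      l1max <- min(opts$maxIntLoop, len - 6L)
      for (l1 in seq_len(l1max)) {
        left <- E$runVec(i, l1, "internal")[l1 + 1L]
        if (!is.finite(left)) next
        l2max <- min(opts$maxIntLoop, len - 5L - l1)
        rvr <- E$runVecRight(j, l2max, "internal")
        for (l2 in seq_len(l2max))
          if (.tbClose(rp$internal$gen + left + rvr[l2] +
                       E$F0[i + l1, j - l2], v))
            return(node("P", "internal", i, j,
                        kids = list(tbF0(i + l1, j - l2, "F0")),
                        runL = c(i, i + l1 - 1L), runR = c(j - l2 + 1L, j)))
      }
    }
    if (len >= 10L) {
      if (.tbClose(rp$PJ3 + E$J3t[i, j], v))
        return(node("P", "J3", i, j, kids = list(tbJ3(i, j, closing))))
      if (.tbClose(rp$PJ4 + E$J4t[i, j], v))
        return(node("P", "J4", i, j, kids = list(tbJ4(i, j, closing))))
      if (.tbClose(rp$PJN + E$bodyN[i, j], v))
        return(node("P", "JN", i, j, kids = list(tbJN(i, j, closing))))
    }
    for (h in seq_along(E$hl))
      if (len <= E$hl[[h]]$cap &&
          .tbClose(rp$hairpin$motif[h] + E$hl[[h]]$G[i, len + 1L], v)) {
        vv <- E$hl[[h]]$v
        addMotif(list(name = vv@descriptor@name, class = "HL",
                      variant = vv@topologyIndex, i = i, j = j,
                      logScore = rp$hairpin$motif[h] + E$hl[[h]]$G[i, len + 1L],
                      groupSpans = list(c(i, j)),
                      bounding = .dropNull(list(closing))))
        return(node("P", "motifHL", i, j, variant = vv@uniqueId,
                    slot = "HL", groupSpans = list(c(i, j))))
      }
    for (w in seq_along(E$slotIdx$BLleft)) {
      t <- E$slotIdx$BLleft[w]
      if (.tbClose(rp$bulgeL$motif[w] + E$Tt[[t]][[1L]][i, j], v))
        return(tbChain(t, i, j, closing, rp$bulgeL$motif[w], "BLleft", "P"))
    }
    for (w in seq_along(E$slotIdx$BLright)) {
      t <- E$slotIdx$BLright[w]
      if (.tbClose(rp$bulgeR$motif[w] + E$Tt[[t]][[1L]][i, j], v))
        return(tbChain(t, i, j, closing, rp$bulgeR$motif[w], "BLright", "P"))
    }
    for (w in seq_along(E$slotIdx$IL)) {
      t <- E$slotIdx$IL[w]
      if (.tbClose(rp$internal$motif[w] + E$Tt[[t]][[1L]][i, j], v))
        return(tbChain(t, i, j, closing, rp$internal$motif[w], "IL", "P"))
    }
    fail("P", i, j)
  }

  tbJ3 <- function(i, j, closing) {
    v <- E$J3t[i, j]
    if (.tbClose(rp$J3$gen + E$body3[i, j], v)) {
      sp <- .findSplit2(E, E$BB, E$T2g, i, j)
      t2 <- .findT2(E, sp$s + 1L, j)
      return(node("J3", "generic", i, j, kids = list(
        tbBB(i, sp$s, closing),
        tbBB(t2$i, t2$s, closing),
        tbBTnode(t2$s + 1L, j, closing))))
    }
    for (w in seq_along(E$slotIdx$J3)) {
      t <- E$slotIdx$J3[w]
      if (.tbClose(rp$J3$motif[w] + E$Tt[[t]][[1L]][i, j], v))
        return(tbChain(t, i, j, closing, rp$J3$motif[w], "J3", "J3"))
    }
    fail("J3", i, j)
  }

  tbJ4 <- function(i, j, closing) {
    v <- E$J4t[i, j]
    if (.tbClose(rp$J4$gen + E$body4[i, j], v)) {
      sp <- .findSplit2(E, E$BB, E$body3, i, j)
      sp2 <- .findSplit2(E, E$BB, E$T2g, sp$s + 1L, j)
      t2 <- .findT2(E, sp2$s + 1L, j)
      return(node("J4", "generic", i, j, kids = list(
        tbBB(i, sp$s, closing),
        tbBB(sp$s + 1L, sp2$s, closing),
        tbBB(t2$i, t2$s, closing),
        tbBTnode(t2$s + 1L, j, closing))))
    }
    for (w in seq_along(E$slotIdx$J4)) {
      t <- E$slotIdx$J4[w]
      if (.tbClose(rp$J4$motif[w] + E$Tt[[t]][[1L]][i, j], v))
        return(tbChain(t, i, j, closing, rp$J4$motif[w], "J4", "J4"))
    }
    fail("J4", i, j)
  }

  tbJN <- function(i, j, closing) {
    s1 <- .findSplit2(E, E$BB, E$N2, i, j)$s
    s2 <- .findSplit2(E, E$BB, E$N1, s1 + 1L, j)$s
    s3 <- .findSplit2(E, E$BB, E$MR, s2 + 1L, j)$s
    mr <- tbMR(s3 + 1L, j, closing)
    node("JN", "generic", i, j, kids = list(
      tbBB(i, s1, closing), tbBB(s1 + 1L, s2, closing),
      tbBB(s2 + 1L, s3, closing), mr$chain, mr$rnode))
  }

  tbMR <- function(i, j, closing) {
    v <- E$MR[i, j]
    if (j - 5L >= i + 4L) for (s in (i + 4L):(j - 5L))
      if (.tbClose(rp$M1[["more"]] + E$BB[i, s] + E$MR[s + 1L, j], v)) {
        rest <- tbMR(s + 1L, j, closing)
        return(list(chain = node("M1", "more", i, j,
                                 kids = list(tbBB(i, s, closing), rest$chain)),
                    rnode = rest$rnode))
      }
    if (j - 1L >= i + 4L) for (s in (i + 4L):(j - 1L))
      if (.tbClose(rp$M1[["last"]] + E$BB[i, s] + E$Rt[s + 1L, j], v))
        return(list(chain = node("M1", "last", i, j,
                                 kids = list(tbBB(i, s, closing))),
                    rnode = node("R", "run", s + 1L, j, run = c(s + 1L, j))))
    if (.tbClose(rp$M1[["last"]] + E$BB[i, j] + E$Rempty, v))
      return(list(chain = node("M1", "last", i, j,
                               kids = list(tbBB(i, j, closing))),
                  rnode = node("R", "run", j + 1L, j)))
    fail("MR", i, j)
  }

  tbBB <- function(i, j, closing) {
    v <- E$BB[i, j]; len <- j - i + 1L
    lmax <- min(opts$maxMlRun, len - 5L)
    rv <- E$runVec(i, lmax, "ml")
    for (l in 0:lmax)
      if (.tbClose(rp$BB$gen + rv[l + 1L] + E$F0[i + l, j], v))
        return(node("BB", "generic", i, j, kids = list(tbF0(i + l, j, "F0")),
                    run = if (l > 0L) c(i, i + l - 1L) else NULL))
    for (b in seq_along(E$bs)) {
      lb <- min(E$bs[[b]]$cap, len - 5L)
      for (l in 0:lb)
        if (.tbClose(rp$BB$motif[b] + E$bs[[b]]$G[i, l + 1L] +
                     E$F0[i + l, j], v)) {
          vv <- E$bs[[b]]$v
          addMotif(list(name = vv@descriptor@name, class = "BS",
                        variant = vv@topologyIndex, i = i,
                        j = max(i, i + l - 1L),
                        logScore = rp$BB$motif[b] + E$bs[[b]]$G[i, l + 1L],
                        groupSpans = list(c(i, i + l - 1L)),
                        bounding = .dropNull(list(closing, c(i + l, j)))))
          return(node("BB", "motifBS", i, j,
                      kids = list(tbF0(i + l, j, "F0")),
                      variant = vv@uniqueId, slot = "BSBB",
                      groupSpans = list(c(i, i + l - 1L))))
        }
    }
    fail("BB", i, j)
  }

  tbBTnode <- function(i, j, closing) {
    if (i > j) {   # empty BT
      v <- E$BTempty
      if (.tbClose(rp$BT$gen + E$geom$ml[1L], v))
        return(node("BT", "generic", i, j))
      for (b in seq_along(E$bs))
        if (.tbClose(rp$BT$motif[b] + E$bs[[b]]$empty, v)) {
          vv <- E$bs[[b]]$v
          addMotif(list(name = vv@descriptor@name, class = "BS",
                        variant = vv@topologyIndex, i = i, j = j,
                        logScore = rp$BT$motif[b] + E$bs[[b]]$empty,
                        groupSpans = list(c(i, j)),
                        bounding = .dropNull(list(closing))))
          return(node("BT", "motifBS", i, j, variant = vv@uniqueId,
                      slot = "BSBT", groupSpans = list(c(i, j))))
        }
      fail("BTempty", i, j)
    }
    v <- E$BT[i, j]; len <- j - i + 1L
    if (.tbClose(rp$BT$gen + E$runScore(i, j, "ml"), v))
      return(node("BT", "generic", i, j, run = c(i, j)))
    for (b in seq_along(E$bs))
      if (len <= E$bs[[b]]$cap &&
          .tbClose(rp$BT$motif[b] + E$bs[[b]]$G[i, len + 1L], v)) {
        vv <- E$bs[[b]]$v
        addMotif(list(name = vv@descriptor@name, class = "BS",
                      variant = vv@topologyIndex, i = i, j = j,
                      logScore = rp$BT$motif[b] + E$bs[[b]]$G[i, len + 1L],
                      groupSpans = list(c(i, j)),
                      bounding = .dropNull(list(closing))))
        return(node("BT", "motifBS", i, j, variant = vv@uniqueId,
                    slot = "BSBT", groupSpans = list(c(i, j))))
      }
    fail("BT", i, j)
  }

  # walk a motif chain: groups interleaved with enclosed helices
  tbChain <- function(t, i, j, closing, ruleLog, slot, asNT) {
    mv <- E$mv[[t]]; m <- mv$m
    total <- ruleLog + E$Tt[[t]][[1L]][i, j]
    groupSpans <- list(); kids <- list(); bounding <- list(closing)
    ci <- i
    for (k in seq_len(m)) {
      vk <- E$Tt[[t]][[k]][ci, j]
      # end of this block (helix k ends at s; remainder is T_{k+1})
      found <- FALSE
      if (k < m) {
        if (j - 5L >= ci + 4L) for (s in (ci + 4L):(j - 5L)) {
          if (.tbClose(E$A[[t]][[k]][ci, s] + E$Tt[[t]][[k + 1L]][s + 1L, j], vk)) {
            e <- s; found <- TRUE; break
          }
        }
      } else {
        tmax <- min(mv$caps[m + 1L], j - ci + 1L - 5L)
        for (tl in 0:tmax) {
          if (.tbClose(E$A[[t]][[m]][ci, j - tl] +
                       mv$G[[m + 1L]][j - tl + 1L, tl + 1L], vk)) {
            e <- j - tl; found <- TRUE; break
          }
        }
      }
      if (!found) fail(paste0("chain-", slot), ci, j)
      # split A_k into group + helix
      av <- E$A[[t]][[k]][ci, e]
      lmax <- min(mv$caps[k], e - ci + 1L - 5L)
      gfound <- FALSE
      for (l in 0:lmax)
        if (.tbClose(mv$G[[k]][ci, l + 1L] + E$F0[ci + l, e], av)) {
          groupSpans[[k]] <- c(ci, ci + l - 1L)
          bounding[[length(bounding) + 1L]] <- c(ci + l, e)
          kids[[length(kids) + 1L]] <- tbF0(ci + l, e, "F0")
          gfound <- TRUE; break
        }
      if (!gfound) fail(paste0("chainA-", slot), ci, e)
      ci <- e + 1L
    }
    groupSpans[[m + 1L]] <- c(ci, j)
    vv <- mv$v
    addMotif(list(name = vv@descriptor@name, class = vv@descriptor@motifClass,
                  variant = vv@topologyIndex, i = i, j = j,
                  logScore = total, groupSpans = groupSpans,
                  bounding = .dropNull(bounding)))
    node(asNT, paste0("motif", slot), i, j, kids = kids,
         variant = vv@uniqueId, slot = slot, groupSpans = groupSpans)
  }

  tree <- tbS(1L, n)
  list(tree = tree, pairs = pairs, motifs = motifs)
}

.dropNull <- function(x) x[!vapply(x, is.null, TRUE)]

# best split s of X[i,s] + Y[s+1,j] (the argmax reproduces the stored
# combination value in max mode)
.findSplit2 <- function(E, X, Y, i, j) {
  best <- -Inf; sbest <- NA_integer_
  if (j - 1L >= i + 4L) for (s in (i + 4L):(j - 1L)) {
    tot <- X[i, s] + Y[s + 1L, j]
    if (tot > best + .TB_TOL) { best <- tot; sbest <- s }
  }
  if (!is.finite(best)) .stopf("split traceback failed (internal error)")
  list(s = sbest, val = best)
}

# decompose a T2g cell: BB then BT (possibly empty)
.findT2 <- function(E, i, j) {
  v <- E$T2g[i, j]
  if (j - 1L >= i + 4L) for (s in (i + 4L):(j - 1L))
    if (.tbClose(E$BB[i, s] + E$BT[s + 1L, j], v)) return(list(i = i, s = s))
  if (.tbClose(E$BB[i, j] + E$BTempty, v)) return(list(i = i, s = j))
  .stopf("T2 traceback failed (internal error)")
}

# ---- independent rescoring ---------------------------------------------

#' Rescore a parse tree
#'
#' Walks a parse tree (as returned in the \code{"tree"} attribute of
#' \code{foldCYK}) and recomputes its log probability from the grammar
#' parameters and emission mixtures; used to verify that the traceback
#' reproduces the CYK optimum.
#'
#' @param tree parse tree
#' @param pa the \linkS4class{ProbAlignment} that was folded
#' @param grammar the \linkS4class{FoldGrammar} used
#' @param constraints the constraints used for the fold, if any
#' @return log probability of the derivation
#' @export
rescoreParse <- function(tree, pa, grammar, constraints = NULL) {
  E <- .engineContext(pa, grammar, constraints, mode = "max")
  .scoreNode(E, tree)
}

.scoreNode <- function(E, node) {
  rp <- E$rp
  runSc <- function(run, ctx) {
    if (is.null(run) || run[1] > run[2]) E$geom[[ctx]][1L]
    else E$runScore(run[1], run[2], ctx)
  }
  kidSum <- sum(vapply(node$kids, function(k) .scoreNode(E, k), 0))
  nt <- node$nt; rule <- node$rule
  if (nt == "S")
    return(kidSum + switch(rule, end = rp$S[["end"]],
      aS = rp$S[["aS"]] + E$w1[node$pos], F0S = rp$S[["F0S"]]))
  if (nt %in% c("F0", "F5")) {
    base <- if (nt == "F0") E$WP[node$pair[1], node$pair[2]]
            else E$WPS[node$pair[1], node$pair[2]]
    return(kidSum + base + rp[[nt]][[rule]])
  }
  if (nt == "P") {
    if (rule == "hairpin")
      return(kidSum + rp$hairpin$gen + runSc(node$run, "hairpin"))
    if (rule == "bulgeL")
      return(kidSum + rp$bulgeL$gen + runSc(node$run, "bulge"))
    if (rule == "bulgeR")
      return(kidSum + rp$bulgeR$gen + runSc(node$run, "bulge"))
    if (rule == "internal")
      return(kidSum + rp$internal$gen + runSc(node$runL, "internal") +
             runSc(node$runR, "internal"))
    if (rule == "J3") return(kidSum + rp$PJ3)
    if (rule == "J4") return(kidSum + rp$PJ4)
    if (rule == "JN") return(kidSum + rp$PJN)
    if (rule == "motifHL") {
      w <- match(node$variant, vapply(E$hl, function(h) h$v@uniqueId, ""))
      sp <- node$groupSpans[[1L]]
      return(kidSum + rp$hairpin$motif[w] +
             E$hl[[w]]$G[sp[1], sp[2] - sp[1] + 2L])
    }
    if (rule == "motifBLleft")
      return(kidSum + .chainScore(E, node, rp$bulgeL$motif, "BLleft"))
    if (rule == "motifBLright")
      return(kidSum + .chainScore(E, node, rp$bulgeR$motif, "BLright"))
    if (rule == "motifIL")
      return(kidSum + .chainScore(E, node, rp$internal$motif, "IL"))
  }
  if (nt == "J3") {
    if (rule == "generic") return(kidSum + rp$J3$gen)
    return(kidSum + .chainScore(E, node, rp$J3$motif, "J3"))
  }
  if (nt == "J4") {
    if (rule == "generic") return(kidSum + rp$J4$gen)
    return(kidSum + .chainScore(E, node, rp$J4$motif, "J4"))
  }
  if (nt == "JN") return(kidSum)
  if (nt == "M1") return(kidSum + rp$M1[[rule]])
  if (nt == "BB") {
    if (rule == "generic")
      return(kidSum + rp$BB$gen + runSc(node$run, "ml"))
    b <- match(node$variant, vapply(E$bs, function(x) x$v@uniqueId, ""))
    sp <- node$groupSpans[[1L]]
    len <- max(0L, sp[2] - sp[1] + 1L)
    return(kidSum + rp$BB$motif[b] + E$bs[[b]]$G[sp[1], len + 1L])
  }
  if (nt == "BT") {
    if (rule == "generic") return(rp$BT$gen + runSc(node$run, "ml"))
    b <- match(node$variant, vapply(E$bs, function(x) x$v@uniqueId, ""))
    sp <- node$groupSpans[[1L]]
    if (sp[1] > sp[2]) return(rp$BT$motif[b] + E$bs[[b]]$empty)
    return(rp$BT$motif[b] + E$bs[[b]]$G[sp[1], sp[2] - sp[1] + 2L])
  }
  if (nt == "R") return(runSc(node$run, "ml"))
  .stopf("unknown node '%s/%s' in rescoring", nt, rule)
}

# motif-chain group emission score (the kids -- enclosed helices -- are
# scored by the caller); ruleLogVec is the per-motif rule log-prob vector of
# the slot
.chainScore <- function(E, node, ruleLogVec, slot) {
  idx <- E$slotIdx[[slot]]
  uids <- vapply(idx, function(t) E$mv[[t]]$v@uniqueId, "")
  w <- match(node$variant, uids)
  if (is.na(w)) .stopf("unknown motif variant '%s' in tree", node$variant)
  mv <- E$mv[[idx[w]]]
  gs <- 0
  for (k in seq_along(node$groupSpans)) {
    sp <- node$groupSpans[[k]]
    len <- max(0L, sp[2] - sp[1] + 1L)
    start <- min(sp[1], E$n + 1L)
    gs <- gs + mv$G[[k]][start, len + 1L]
  }
  ruleLogVec[w] + gs
}

# ---- pseudoknot layer grammar ------------------------------------------

#' Fold one pseudoknot layer with the small nested grammar
#'
#' CYK over the layer grammar (S -> L S | L; L -> a F a' | a;
#' F -> a F a' | L S) with forced and forbidden pairs; used for layers
#' beyond the first, whose helices are dictated by non-nested covarying
#' pairs.
#'
#' @param pa a \linkS4class{ProbAlignment}
#' @param grammar a \linkS4class{FoldGrammar} of type "layer"
#' @param constraints \code{foldConstraints()}; the layer's pairs forced,
#'   previously placed pairs forbidden
#' @return list with \code{pairs} (matrix, original columns) and
#'   \code{logProb}
#' @export
foldLayer <- function(pa, grammar, constraints = NULL) {
  if (grammar@type != "layer") .stopf("foldLayer needs a layer grammar")
  E <- .engineContext(pa, grammar, constraints, mode = "max")
  n <- E$n
  lt <- lapply(grammar@options$layerTransitions, log)
  Lt <- matrix(-Inf, n, n); Ft <- matrix(-Inf, n, n); St <- matrix(-Inf, n, n)
  for (len in seq_len(n)) for (i in seq_len(n - len + 1L)) {
    j <- i + len - 1L
    lc <- -Inf
    if (len == 1L && E$unpairFree[i]) lc <- lt$L[["single"]] + E$w1[i]
    if (len >= 3L && E$allowed[i, j])
      lc <- max(lc, lt$L[["pair"]] + E$WP[i, j] + Ft[i + 1L, j - 1L])
    Lt[i, j] <- lc
    sc <- lt$S[["L"]] + Lt[i, j]
    if (len >= 2L) for (s in i:(j - 1L))
      sc <- max(sc, lt$S[["LS"]] + Lt[i, s] + St[s + 1L, j])
    St[i, j] <- sc
    fc <- lt$F[["LS"]] + St[i, j]
    if (len >= 3L && E$allowed[i, j] && is.finite(E$WPS[i, j]))
      fc <- max(fc, lt$F[["pair"]] + E$WPS[i, j] + Ft[i + 1L, j - 1L])
    Ft[i, j] <- fc
  }
  top <- St[1L, n]
  if (!is.finite(top))
    .stopf("layer constraints are unsatisfiable")
  pairs <- list()
  tbL <- function(i, j) {
    v <- Lt[i, j]
    if (i == j) return(invisible(NULL))
    if (.tbClose(lt$L[["pair"]] + E$WP[i, j] + Ft[i + 1L, j - 1L], v)) {
      pairs[[length(pairs) + 1L]] <<- c(i, j)
      tbF(i + 1L, j - 1L)
      return(invisible(NULL))
    }
    .stopf("layer traceback failed at L[%d,%d]", i, j)
  }
  tbF <- function(i, j) {
    v <- Ft[i, j]
    if (j - i + 1L >= 3L && E$allowed[i, j] &&
        .tbClose(lt$F[["pair"]] + E$WPS[i, j] + Ft[i + 1L, j - 1L], v)) {
      pairs[[length(pairs) + 1L]] <<- c(i, j)
      tbF(i + 1L, j - 1L)
      return(invisible(NULL))
    }
    tbS(i, j)
  }
  tbS <- function(i, j) {
    v <- St[i, j]
    if (.tbClose(lt$S[["L"]] + Lt[i, j], v)) return(tbL(i, j))
    if (j > i) for (s in i:(j - 1L))
      if (.tbClose(lt$S[["LS"]] + Lt[i, s] + St[s + 1L, j], v)) {
        tbL(i, s); tbS(s + 1L, j)
        return(invisible(NULL))
      }
    .stopf("layer traceback failed at S[%d,%d]", i, j)
  }
  tbS(1L, n)
  pm <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    m <- m[order(m[, 1]), , drop = FALSE]
    cbind(i = E$kept[m[, 1]], j = E$kept[m[, 2]])
  } else matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  list(pairs = pm, logProb = top)
}
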