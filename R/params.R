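# Grammar parameters: construction, normalization, the motif probability
# split, training by counting from annotated structures, parameter file I/O,
# and sampling derivations from the grammar.
#
# Nonterminals of the helix/loop grammar and their rules:
#   S  -> a S | F0 S | end
#   F0 -> a F5 a' | a P a'            (pair emission)
#   F5 -> a F5 a' | a P a'            (stacked-pair emission)
#   P  -> m..m | m..m F0 | F0 m..m | m..m F0 m..m | J3 | J4 | JN
#   J3 -> BB BB BT     J4 -> BB BB BB BT     JN -> BB BB BB M1 R
#   M1 -> BB M1 | BB   BB -> m..m F0         BT, R -> m..m
# Unpaired runs m..m follow geometric length laws with context-specific
# minima: hairpin 3, bulge 1, internal 1 (per side), multiloop segments 0.

RUN_MIN <- c(hairpin = 3L, bulge = 1L, internal = 1L, ml = 0L)

#' Construct a grammar parameter set
#'
#' All probability vectors are normalized; defaults give a valid (uniform-ish)
#' parameter set useful for testing. \code{defaultFoldParams()} returns the
#' parameters trained on the bundled structure set.
#'
#' @param transitions named list with elements S, F0, F5, P, M1
#' @param eSingle,ePair,eStack emission tables (normalized internally;
#'   eStack rows are conditional on the outer pair)
#' @param runGeom geometric continuation probabilities per run context
#' @param classFractions motif mass fraction per class
#' @param epsilon profile HMM mismatch probability
#' @return a \linkS4class{FoldParams}
#' @export
foldParams <- function(transitions = NULL, eSingle = rep(1, 4),
                       ePair = NULL, eStack = NULL,
                       runGeom = c(hairpin = 0.3, bulge = 0.3,
                                   internal = 0.3, ml = 0.3),
                       classFractions = c(HL = 0.4, BL = 0.4, IL = 0.5,
                                          J3 = 0.2, J4 = 0.2, BS = 0.2),
                       epsilon = 1e-4) {
  if (is.null(transitions))
    transitions <- list(
      S = c(aS = 0.45, F0S = 0.45, end = 0.10),
      F0 = c(pairF5 = 0.5, pairP = 0.5),
      F5 = c(pairF5 = 0.5, pairP = 0.5),
      P = c(hairpin = 0.3475, bulgeL = 0.12, bulgeR = 0.12,
            internal = 0.25, J3 = 0.0834, J4 = 0.0523, J5plus = 0.0278),
      M1 = c(more = 0.5, last = 0.5))
  pNames <- c("hairpin", "bulgeL", "bulgeR", "internal", "J3", "J4", "JN")
  if (length(transitions$P) != 7L) .stopf("P needs 7 rule probabilities")
  if (all(pNames %in% names(transitions$P)))
    transitions$P <- transitions$P[pNames]
  else names(transitions$P) <- pNames
  transitions <- lapply(transitions, function(p) p / sum(p))
  if (is.null(ePair)) {
    ePair <- matrix(0.02 / 10, 4, 4, dimnames = list(NUCS, NUCS))
    wc <- rbind(c("A", "U"), c("U", "A"), c("C", "G"), c("G", "C"))
    wb <- rbind(c("G", "U"), c("U", "G"))
    for (k in 1:4) ePair[wc[k, 1], wc[k, 2]] <- 0.23
    for (k in 1:2) ePair[wb[k, 1], wb[k, 2]] <- 0.03
  }
  ePair <- ePair / sum(ePair)
  # default: stacking-neutral, every row repeats the plain pair table
  # (row-major flattening matches the pair-code layout (a-1)*4 + b)
  if (is.null(eStack)) eStack <- matrix(as.vector(t(ePair)), 16, 16,
                                        byrow = TRUE)
  eStack <- eStack / rowSums(eStack)
  obj <- new("FoldParams", transitions = transitions,
             eSingle = setNames(eSingle / sum(eSingle), NUCS), ePair = ePair,
             eStack = eStack, runGeom = runGeom,
             classFractions = classFractions[MOTIF_CLASSES],
             epsilon = epsilon)
  validObject(obj)
  obj
}

#' Split a generic loop probability between the generic rule and its motifs
#'
#' The trained probability of a generic loop rule is divided: the fraction
#' \code{fClass} goes to the motif class as a whole and, by maximum entropy,
#' is allocated equally over the class's motifs; the rest stays with the
#' generic rule. With no motifs in the class the whole mass stays generic.
#'
#' @param pGeneric trained generic-rule probability
#' @param fClass motif class fraction in [0, 1]
#' @param nMotifs number of motifs in the class (>= 0)
#' @return list with \code{generic} (kept probability) and \code{perMotif}
#' @examples
#' splitLoopProbability(0.3475, 0.4, 15)  # generic 0.2085, per motif 0.0093
#' @export
splitLoopProbability <- function(pGeneric, fClass, nMotifs) {
  stopifnot(fClass >= 0, fClass <= 1, nMotifs >= 0)
  if (nMotifs == 0L || fClass == 0)
    return(list(generic = pGeneric, perMotif = 0))
  list(generic = pGeneric * (1 - fClass),
       perMotif = pGeneric * fClass / nMotifs)
}

# ---- training by counting ----------------------------------------------

.pairCode <- function(a, b) (match(a, NUCS) - 1L) * 4L + match(b, NUCS)

# walk a parse tree accumulating rule and emission counts
.countTree <- function(node, chars, acc, outerPair = NULL) {
  nt <- node$nt; rule <- node$rule
  if (nt %in% names(acc$trans)) {
    if (!rule %in% names(acc$trans[[nt]]))
      .stopf("training with motif-annotated rule '%s' is not supported", rule)
    acc$trans[[nt]][rule] <- acc$trans[[nt]][rule] + 1L
  }
  countRun <- function(run, ctx) {
    len <- if (is.null(run)) 0L else run[2] - run[1] + 1L
    acc$runN[ctx] <- acc$runN[ctx] + 1L
    acc$runExtra[ctx] <- acc$runExtra[ctx] + (len - RUN_MIN[[ctx]])
    if (len > 0L) for (p in run[1]:run[2]) {
      a <- chars[p]; acc$single[a] <- acc$single[a] + 1L
    }
  }
  if (nt == "S" && rule == "aS") {
    a <- chars[node$pos]; acc$single[a] <- acc$single[a] + 1L
  }
  if (nt %in% c("F0", "F5")) {
    a <- chars[node$pair[1]]; b <- chars[node$pair[2]]
    if (nt == "F0" || is.null(outerPair)) {
      acc$pair[a, b] <- acc$pair[a, b] + 1L
    } else {
      oc <- .pairCode(chars[outerPair[1]], chars[outerPair[2]])
      ic <- .pairCode(a, b)
      acc$stack[oc, ic] <- acc$stack[oc, ic] + 1L
    }
    outerPair <- node$pair
  }
  if (nt == "P") {
    ctx <- switch(rule, hairpin = "hairpin", bulgeL = "bulge",
                  bulgeR = "bulge", internal = "internal", NULL)
    if (rule == "hairpin") countRun(node$run, "hairpin")
    if (rule %in% c("bulgeL", "bulgeR")) countRun(node$run, "bulge")
    if (rule == "internal") { countRun(node$runL, "internal")
                              countRun(node$runR, "internal") }
  }
  if (nt %in% c("BB", "BT", "R")) countRun(node$run, "ml")
  for (kid in node$kids) .countTree(kid, chars, acc, outerPair)
  invisible(NULL)
}

#' Train grammar parameters by counting rule usage
#'
#' The grammar is unambiguous, so an annotated secondary structure has a
#' unique derivation; maximum-likelihood transition estimates are rule-usage
#' frequencies. A +1 pseudocount is applied to every rule and emission cell,
#' so an empty training set yields the pseudocount-only (uniform) parameter
#' set with a warning.
#'
#' @param examples list of elements with \code{$seq} (character string) and
#'   \code{$tree} (a parse as produced by \code{structureToParse} or
#'   \code{sampleDerivation})
#' @param classFractions,epsilon carried into the returned parameter set
#' @return a \linkS4class{FoldParams}
#' @export
trainByCounting <- function(examples,
                            classFractions = c(HL = 0.4, BL = 0.4, IL = 0.5,
                                               J3 = 0.2, J4 = 0.2, BS = 0.2),
                            epsilon = 1e-4) {
  acc <- new.env()
  acc$trans <- list(
    S = c(aS = 0, F0S = 0, end = 0),
    F0 = c(pairF5 = 0, pairP = 0),
    F5 = c(pairF5 = 0, pairP = 0),
    P = c(hairpin = 0, bulgeL = 0, bulgeR = 0, internal = 0,
          J3 = 0, J4 = 0, JN = 0),
    M1 = c(more = 0, last = 0))
  acc$single <- setNames(numeric(4), NUCS)
  acc$pair <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  acc$stack <- matrix(0, 16, 16)
  acc$runN <- setNames(numeric(4), names(RUN_MIN))
  acc$runExtra <- setNames(numeric(4), names(RUN_MIN))
  if (!length(examples))
    .warnf("empty training set: returning pseudocount-only parameters")
  for (ex in examples) {
    chars <- strsplit(.normalizeRow(ex$seq), "")[[1]]
    .countTree(ex$tree, chars, acc)
  }
  trans <- lapply(acc$trans, function(cnt) (cnt + 1) / sum(cnt + 1))
  g <- (acc$runExtra + 1) / (acc$runExtra + acc$runN + 2)
  foldParams(transitions = trans, eSingle = acc$single + 1,
             ePair = acc$pair + 1,
             eStack = acc$stack + 1,
             runGeom = setNames(pmin(pmax(g, 1e-6), 1 - 1e-6), names(RUN_MIN)),
             classFractions = classFractions, epsilon = epsilon)
}

# ---- dot-bracket -> unique parse ---------------------------------------

.pairTable <- function(db) {
  chars <- strsplit(db, "")[[1]]
  open <- chars %in% c("(", "<", "[", "{")
  close <- chars %in% c(")", ">", "]", "}")
  pt <- integer(length(chars))
  stack <- integer(0)
  for (k in seq_along(chars)) {
    if (open[k]) stack <- c(stack, k)
    else if (close[k]) {
      if (!length(stack)) .stopf("unbalanced structure string")
      pt[k] <- stack[length(stack)]; pt[stack[length(stack)]] <- k
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) .stopf("unbalanced structure string")
  pt
}

# top-level pairs within [i, j] given a pair table
.topPairs <- function(pt, i, j) {
  out <- NULL; k <- i
  while (k <= j) {
    if (pt[k] > k) { out <- rbind(out, c(k, pt[k])); k <- pt[k] + 1L }
    else k <- k + 1L
  }
  out
}

#' Derive the unique parse of an annotated secondary structure
#'
#' Because the grammar is unambiguous, a (sequence, structure) pair has
#' exactly one derivation; this function constructs it directly, for use as
#' training input. Structures must respect the grammar's conventions
#' (hairpin loops of at least 3 residues).
#'
#' @param seq sequence string
#' @param db dot-bracket structure of the same length
#' @return parse tree (nested list of rule applications)
#' @export
structureToParse <- function(seq, db) {
  L <- nchar(db)
  if (nchar(seq) != L) .stopf("sequence and structure lengths differ")
  pt <- .pairTable(db)
  node <- function(nt, rule, i, j, kids = list(), ...)
    c(list(nt = nt, rule = rule, i = i, j = j, kids = kids), list(...))
  parseP <- function(i, j) {
    tp <- .topPairs(pt, i, j)
    nh <- if (is.null(tp)) 0L else nrow(tp)
    if (nh == 0L) {
      if (j - i + 1L < RUN_MIN[["hairpin"]])
        .stopf("hairpin loop shorter than %d at columns %d-%d",
               RUN_MIN[["hairpin"]], i, j)
      return(node("P", "hairpin", i, j, run = c(i, j)))
    }
    if (nh == 1L) {
      a <- tp[1, 1]; b <- tp[1, 2]
      lL <- a - i; lR <- j - b
      if (lL > 0L && lR == 0L)
        return(node("P", "bulgeL", i, j, kids = list(parseF0(a, b)),
                    run = c(i, a - 1L)))
      if (lL == 0L && lR > 0L)
        return(node("P", "bulgeR", i, j, kids = list(parseF0(a, b)),
                    run = c(b + 1L, j)))
      if (lL > 0L && lR > 0L)
        return(node("P", "internal", i, j, kids = list(parseF0(a, b)),
                    runL = c(i, a - 1L), runR = c(b + 1L, j)))
      .stopf("stacked pair reached loop parser (internal error)")
    }
    # multiloop: one BB per helix (preceding run + helix), trailing run
    bbs <- lapply(seq_len(nh), function(h) {
      st <- if (h == 1L) i else tp[h - 1L, 2] + 1L
      run <- if (tp[h, 1] > st) c(st, tp[h, 1] - 1L) else NULL
      node("BB", "generic", st, tp[h, 2],
           kids = list(parseF0(tp[h, 1], tp[h, 2])), run = run)
    })
    tail <- if (tp[nh, 2] < j) c(tp[nh, 2] + 1L, j) else NULL
    ts <- if (is.null(tail)) tp[nh, 2] + 1L else tail[1]
    if (nh == 2L)
      return(node("P", "J3", i, j, kids = list(
        node("J3", "generic", i, j, kids = c(bbs,
          list(node("BT", "generic", ts, j, run = tail)))))))
    if (nh == 3L)
      return(node("P", "J4", i, j, kids = list(
        node("J4", "generic", i, j, kids = c(bbs,
          list(node("BT", "generic", ts, j, run = tail)))))))
    # 5-way or higher: first three branches explicit, the rest in an M1 chain
    chain <- NULL
    for (h in rev(seq(4L, nh))) {
      rule <- if (h == nh) "last" else "more"
      kids <- if (h == nh) list(bbs[[h]]) else list(bbs[[h]], chain)
      chain <- node("M1", rule, bbs[[h]]$i, j, kids = kids)
    }
    node("P", "JN", i, j, kids = c(bbs[1:3], list(chain),
      list(node("R", "run", ts, j, run = tail))))
  }
  parseF0 <- function(i, j, nt = "F0") {
    if (pt[i] != j) .stopf("internal error: expected pair at (%d,%d)", i, j)
    if (i + 1L <= j - 1L && pt[i + 1L] == j - 1L)
      node(nt, "pairF5", i, j, kids = list(parseF0(i + 1L, j - 1L, "F5")),
           pair = c(i, j))
    else
      node(nt, "pairP", i, j, kids = list(parseP(i + 1L, j - 1L)),
           pair = c(i, j))
  }
  parseS <- function(i, j) {
    if (i > j) return(node("S", "end", i, j))
    if (pt[i] == 0L)
      node("S", "aS", i, j, kids = list(parseS(i + 1L, j)), pos = i)
    else
      node("S", "F0S", i, j,
           kids = list(parseF0(i, pt[i]), parseS(pt[i] + 1L, j)))
  }
  parseS(1L, L)
}

#' Parameters trained on the bundled structure set
#'
#' Trains by counting on the package's small set of literature-style
#' secondary structures, then imposes two anchors: the generic hairpin-loop
#' probability 0.3475 and the multiloop split 0.51/0.32/0.17 among three-way,
#' four-way and higher junctions (the remaining loop-rule mass is rescaled
#' proportionally). The result is cached for the session.
#'
#' @return a \linkS4class{FoldParams}
#' @export
defaultFoldParams <- function() {
  hit <- .pkgCache[["defaultParams"]]
  if (!is.null(hit)) return(hit)
  path <- system.file("extdata", "training_structures.txt",
                      package = "RNAMotifFold", mustWork = TRUE)
  lines <- grep("^#|^\\s*$", readLines(path), invert = TRUE, value = TRUE)
  examples <- lapply(strsplit(lines, "\t"), function(f)
    list(seq = f[2], tree = structureToParse(f[2], f[3])))
  p <- trainByCounting(examples)
  tP <- p@transitions$P
  hp <- 0.3475
  rest <- tP[-1] / sum(tP[-1]) * (1 - hp)
  mlMass <- sum(rest[c("J3", "J4", "JN")])
  rest[c("J3", "J4", "JN")] <- mlMass * c(0.51, 0.32, 0.17)
  p@transitions$P <- c(hairpin = hp, rest)
  validObject(p)
  .pkgCache[["defaultParams"]] <- p
  p
}

.pkgCache <- new.env(parent = emptyenv())

#' Write parameters to a JSON file (bit-exact round trip)
#' @param params a FoldParams
#' @param path output path
#' @export
writeParamsJSON <- function(params, path) {
  obj <- list(schema = "fold-params-1",
              transitions = lapply(params@transitions, as.list),
              eSingle = as.list(setNames(params@eSingle, NUCS)),
              ePair = params@ePair,
              eStack = params@eStack,
              runGeom = as.list(params@runGeom),
              classFractions = as.list(params@classFractions),
              epsilon = params@epsilon)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read parameters from a JSON file
#' @param path file written by \code{writeParamsJSON}
#' @export
readParamsJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fold-params-1"))
    .stopf("unrecognized parameter file schema")
  toMat <- function(m, d) { m <- as.matrix(m); dimnames(m) <- d; m }
  # constructed directly (no renormalization) so the round trip is bit-exact
  p <- new("FoldParams",
           transitions = lapply(obj$transitions, unlist),
           eSingle = unlist(obj$eSingle),
           ePair = toMat(obj$ePair, list(NUCS, NUCS)),
           eStack = toMat(obj$eStack, NULL),
           runGeom = unlist(obj$runGeom),
           classFractions = unlist(obj$classFractions),
           epsilon = obj$epsilon)
  validObject(p)
  p
}

# ---- sampling from the grammar -----------------------------------------

#' Sample a derivation (sequence, structure, parse tree) from the grammar
#'
#' Samples the helix/loop grammar without motif rules; used for
#' parameter-recovery simulations and for checks such as "a grammar with
#' zero four-way-junction probability never emits a four-way junction".
#'
#' @param params a \linkS4class{FoldParams}
#' @param seed optional seed (wraps the call in a fixed RNG scope)
#' @param maxLen guard against runaway derivations
#' @return list with \code{seq}, \code{db} (dot-bracket) and \code{tree};
#'   tree node coordinates are filled in post hoc
#' @export
sampleDerivation <- function(params, seed = NULL, maxLen = 5000L) {
  run <- function() .sampleS(params, maxLen)
  res <- if (is.null(seed)) run() else .withSeed(seed, run())
  res
}

.sampleS <- function(params, maxLen) {
  tr <- params@transitions
  chars <- character(0); struct <- character(0)
  pick <- function(p) sample(names(p), 1L, prob = p)
  emitSingle <- function() sample(NUCS, 1L, prob = params@eSingle)
  emitRun <- function(ctx) {
    len <- RUN_MIN[[ctx]] + stats::rgeom(1L, 1 - params@runGeom[[ctx]])
    replicate(len, emitSingle())
  }
  guard <- function(n) if (n > maxLen)
    .stopf("sampled derivation exceeds maxLen = %d", maxLen)
  sampS <- function() {
    rule <- pick(tr$S)
    if (rule == "end") return(list(nt = "S", rule = "end", txt = "",
                                   db = "", kids = list()))
    if (rule == "aS") {
      a <- emitSingle(); rest <- sampS()
      return(list(nt = "S", rule = "aS", txt = paste0(a, rest$txt),
                  db = paste0(".", rest$db), kids = list(rest)))
    }
    h <- sampF0("F0", NULL); rest <- sampS()
    guard(nchar(h$txt) + nchar(rest$txt))
    list(nt = "S", rule = "F0S", txt = paste0(h$txt, rest$txt),
         db = paste0(h$db, rest$db), kids = list(h, rest))
  }
  sampF0 <- function(nt, outer) {
    rule <- pick(tr[[nt]])
    pairChars <- if (nt == "F0" || is.null(outer)) {
      k <- sample.int(16L, 1L, prob = as.vector(params@ePair))
      c(NUCS[(k - 1L) %% 4L + 1L], NUCS[(k - 1L) %/% 4L + 1L])
    } else {
      oc <- .pairCode(outer[1], outer[2])
      k <- sample.int(16L, 1L, prob = params@eStack[oc, ])
      c(NUCS[(k - 1L) %/% 4L + 1L], NUCS[(k - 1L) %% 4L + 1L])
    }
    kid <- if (rule == "pairF5") sampF0("F5", pairChars) else sampP()
    guard(nchar(kid$txt) + 2L)
    list(nt = nt, rule = rule,
         txt = paste0(pairChars[1], kid$txt, pairChars[2]),
         db = paste0("(", kid$db, ")"), kids = list(kid),
         pairChars = pairChars)
  }
  sampBB <- function() {
    run <- emitRun("ml"); h <- sampF0("F0", NULL)
    list(nt = "BB", rule = "generic",
         txt = paste0(paste(run, collapse = ""), h$txt),
         db = paste0(strrep(".", length(run)), h$db),
         kids = list(h), runLen = length(run))
  }
  sampTail <- function(nt) {
    run <- emitRun("ml")
    list(nt = nt, rule = if (nt == "R") "run" else "generic",
         txt = paste(run, collapse = ""), db = strrep(".", length(run)),
         kids = list(), runLen = length(run))
  }
  sampM1 <- function() {
    rule <- pick(tr$M1)
    if (rule == "last") { bb <- sampBB()
      return(list(nt = "M1", rule = "last", txt = bb$txt, db = bb$db,
                  kids = list(bb))) }
    bb <- sampBB(); rest <- sampM1()
    list(nt = "M1", rule = "more", txt = paste0(bb$txt, rest$txt),
         db = paste0(bb$db, rest$db), kids = list(bb, rest))
  }
  sampP <- function() {
    rule <- pick(tr$P)
    if (rule == "hairpin") {
      run <- emitRun("hairpin")
      return(list(nt = "P", rule = "hairpin", txt = paste(run, collapse = ""),
                  db = strrep(".", length(run)), kids = list(),
                  runLen = length(run)))
    }
    if (rule %in% c("bulgeL", "bulgeR")) {
      run <- emitRun("bulge"); h <- sampF0("F0", NULL)
      txt <- if (rule == "bulgeL") paste0(paste(run, collapse = ""), h$txt)
             else paste0(h$txt, paste(run, collapse = ""))
      db <- if (rule == "bulgeL") paste0(strrep(".", length(run)), h$db)
            else paste0(h$db, strrep(".", length(run)))
      return(list(nt = "P", rule = rule, txt = txt, db = db, kids = list(h),
                  runLen = length(run)))
    }
    if (rule == "internal") {
      rl <- emitRun("internal"); h <- sampF0("F0", NULL)
      rr <- emitRun("internal")
      return(list(nt = "P", rule = "internal",
                  txt = paste0(paste(rl, collapse = ""), h$txt,
                               paste(rr, collapse = "")),
                  db = paste0(strrep(".", length(rl)), h$db,
                              strrep(".", length(rr))),
                  kids = list(h), runLenL = length(rl), runLenR = length(rr)))
    }
    nBB <- switch(rule, J3 = 2L, J4 = 3L, JN = 3L)
    bbs <- replicate(nBB, sampBB(), simplify = FALSE)
    kids <- bbs
    if (rule == "JN") { m1 <- sampM1(); kids <- c(kids, list(m1)) }
    tail <- sampTail(if (rule == "JN") "R" else "BT")
    kids <- c(kids, list(tail))
    inner <- list(nt = switch(rule, J3 = "J3", J4 = "J4", JN = "JN"),
                  rule = "generic",
                  txt = paste(vapply(kids, `[[`, "", "txt"), collapse = ""),
                  db = paste(vapply(kids, `[[`, "", "db"), collapse = ""),
                  kids = kids)
    list(nt = "P", rule = rule, txt = inner$txt, db = inner$db,
         kids = list(inner))
  }
  root <- sampS()
  tree <- .fillCoords(root, 1L)
  list(seq = root$txt, db = root$db, tree = tree)
}

# convert a sampled (txt/db) tree into the coordinate-based node format
# consumed by trainByCounting
.fillCoords <- function(node, i) {
  len <- nchar(node$txt)
  j <- i + len - 1L
  out <- list(nt = node$nt, rule = node$rule, i = i, j = j)
  kids <- list()
  pos <- i
  if (node$nt == "S" && node$rule == "aS") { out$pos <- i; pos <- i + 1L }
  if (node$nt %in% c("F0", "F5")) { out$pair <- c(i, j); pos <- i + 1L }
  if (node$nt == "P" && node$rule == "hairpin")
    out$run <- if (node$runLen > 0L) c(i, i + node$runLen - 1L) else NULL
  if (node$nt == "P" && node$rule == "bulgeL") {
    out$run <- if (node$runLen > 0L) c(i, i + node$runLen - 1L) else NULL
    pos <- i + node$runLen
  }
  if (node$nt == "P" && node$rule == "internal") {
    out$runL <- if (node$runLenL > 0L) c(i, i + node$runLenL - 1L) else NULL
    pos <- i + node$runLenL
  }
  if (node$nt == "BB") {
    out$run <- if (node$runLen > 0L) c(i, i + node$runLen - 1L) else NULL
    pos <- i + node$runLen
  }
  if (node$nt %in% c("BT", "R"))
    out$run <- if (node$runLen > 0L) c(i, j) else NULL
  for (kid in node$kids) {
    fk <- .fillCoords(kid, pos)
    kids <- c(kids, list(fk))
    pos <- pos + nchar(kid$txt)
  }
  if (node$nt == "P" && node$rule == "bulgeR") {
    out$run <- if (node$runLen > 0L) c(pos, j) else NULL
  }
  if (node$nt == "P" && node$rule == "internal") {
    out$runR <- if (node$runLenR > 0L) c(pos, j) else NULL
  }
  out$kids <- kids
  out
}

#' Count junction rule usages in a parse tree
#'
#' @param tree a parse tree
#' @return named integer vector with counts of J3, J4 and higher junctions
#' @export
countJunctions <- function(tree) {
  cnt <- c(J3 = 0L, J4 = 0L, JN = 0L)
  walk <- function(node) {
    if (node$nt == "P" && node$rule %in% names(cnt))
      cnt[node$rule] <<- cnt[node$rule] + 1L
    for (kid in node$kids) walk(kid)
  }
  walk(tree)
  cnt
}
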