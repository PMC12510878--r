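# Grammar construction: the helix/loop grammar, its motif-extended form, and
# the small nested grammar used for pseudoknot layers.

.defaultOptions <- function() {
  list(minHairpin = 3L,   # canonical minimum hairpin loop length
       maxBulge = 30L,    # generic bulge run cap
       maxIntLoop = 30L,  # generic internal loop cap per side
       maxMlRun = 30L,    # multiloop unpaired run cap
       segSlack = 8L)     # extra columns a motif segment may absorb
}

#' Build the helix/loop grammar (no motifs)
#'
#' @param params a \linkS4class{FoldParams} (default: trained defaults)
#' @param options list of engine options overriding the defaults
#'   (minHairpin, maxBulge, maxIntLoop, maxMlRun, segSlack)
#' @return a \linkS4class{FoldGrammar} of type "rbgj3j4"
#' @export
buildRbgj3j4 <- function(params = defaultFoldParams(), options = list()) {
  validObject(params)
  opts <- utils::modifyList(.defaultOptions(), options)
  new("FoldGrammar", type = "rbgj3j4", params = params, variants = list(),
      phmms = list(), options = opts)
}

#' Extend the helix/loop grammar with motif nonterminals
#'
#' Every loop-bearing rule gains motif alternatives: the hairpin rule gains
#' one alternative per hairpin motif, the bulge rules per left/right bulge
#' variant, the internal-loop rule per internal-loop variant; the three- and
#' four-way junction nonterminals gain one alternative per junction variant,
#' and branch segments extend the multiloop branch rules. Motif rule
#' probabilities come from \code{splitLoopProbability}, so the total mass
#' leaving each loop rule is unchanged. A profile HMM is built for every
#' consensus segment of every variant.
#'
#' @param variants list of \linkS4class{MotifVariant} (see
#'   \code{expandVariants}); an empty list gives a grammar scoring
#'   identically to the motif-free one
#' @param params a \linkS4class{FoldParams}
#' @param options engine options, as in \code{buildRbgj3j4}
#' @return a \linkS4class{FoldGrammar} of type "r3d"
#' @export
buildR3dGrammar <- function(variants, params = defaultFoldParams(),
                            options = list()) {
  validObject(params)
  opts <- utils::modifyList(.defaultOptions(), options)
  phmms <- lapply(variants, function(v) {
    lapply(v@elements, function(el) {
      if (el == "&") NULL else buildPHMM(el, epsilon = params@epsilon)
    })
  })
  names(phmms) <- vapply(variants, function(v) v@uniqueId, character(1))
  new("FoldGrammar", type = "r3d", params = params, variants = variants,
      phmms = phmms, options = opts)
}

#' Build the simple nested grammar used for pseudoknot layers
#'
#' A small unambiguous grammar (S -> L S | L; L -> a F a' | a;
#' F -> a F a' | L S) with stacking-aware pair emissions, used to fold
#' layers beyond the first, where structure is essentially dictated by the
#' forced covarying pairs.
#'
#' @param params a \linkS4class{FoldParams} (only the emission tables are used)
#' @param transitions optional named list with elements S, L, F
#' @return a \linkS4class{FoldGrammar} of type "layer"
#' @export
buildLayerGrammar <- function(params = defaultFoldParams(),
                              transitions = NULL) {
  if (is.null(transitions))
    transitions <- list(S = c(LS = 0.3, L = 0.7),
                        L = c(pair = 0.12, single = 0.88),
                        F = c(pair = 0.75, LS = 0.25))
  transitions <- lapply(transitions, function(p) p / sum(p))
  g <- new("FoldGrammar", type = "layer", params = params, variants = list(),
           phmms = list(), options = c(.defaultOptions(),
                                       list(layerTransitions = transitions)))
  g
}

#' Number of grammar nonterminals
#'
#' The helix/loop grammar has 11 nonterminals (S, F0, F5, P, J3, J4, JN, BB,
#' BT, M1, R); the motif-extended grammar adds one per unique variant.
#'
#' @param grammar a \linkS4class{FoldGrammar}
#' @export
nonterminalCount <- function(grammar) {
  switch(grammar@type,
         layer = 3L,
         rbgj3j4 = 11L,
         r3d = 11L + length(grammar@variants))
}

#' Motif variants of a grammar
#' @param grammar a FoldGrammar
#' @export
grammarVariants <- function(grammar) grammar@variants

# Effective rule probabilities after the motif split, in log space.
# Returns a list used by the folding engine and the enumeration oracle.
.effectiveRuleProbs <- function(grammar) {
  p <- grammar@params
  tr <- p@transitions
  grp <- .groupVariants(grammar@variants)
  cf <- p@classFractions
  sp <- function(pGen, cls, vars) {
    s <- splitLoopProbability(pGen, cf[[cls]], length(vars))
    list(gen = log(s$generic),
         motif = if (length(vars)) rep(log(s$perMotif), length(vars))
                 else numeric(0))
  }
  list(
    S = log(tr$S), F0 = log(tr$F0), F5 = log(tr$F5), M1 = log(tr$M1),
    PJ3 = log(tr$P[["J3"]]), PJ4 = log(tr$P[["J4"]]), PJN = log(tr$P[["JN"]]),
    hairpin = sp(tr$P[["hairpin"]], "HL", grp$HL),
    bulgeL = sp(tr$P[["bulgeL"]], "BL", grp$BLleft),
    bulgeR = sp(tr$P[["bulgeR"]], "BL", grp$BLright),
    internal = sp(tr$P[["internal"]], "IL", grp$IL),
    J3 = sp(1, "J3", grp$J3),
    J4 = sp(1, "J4", grp$J4),
    BB = sp(1, "BS", grp$BS),
    BT = sp(1, "BS", grp$BS),
    groups = grp)
}

# Split a variant's elements into alternating segment-groups and helix
# placeholders: list of list(kind = "seg" (character vector of consensus
# strings + their pHMMs) or "helix").
.variantLayout <- function(variant, phmms, slack = 8L) {
  els <- variant@elements
  out <- list(); cur <- integer(0)
  for (k in seq_along(els)) {
    if (els[k] == "&") {
      out[[length(out) + 1L]] <- list(kind = "seg", idx = cur)
      out[[length(out) + 1L]] <- list(kind = "helix")
      cur <- integer(0)
    } else cur <- c(cur, k)
  }
  out[[length(out) + 1L]] <- list(kind = "seg", idx = cur)
  # attach pHMMs and caps
  for (g in seq_along(out)) {
    if (out[[g]]$kind == "seg") {
      hm <- phmms[out[[g]]$idx]
      out[[g]]$phmms <- hm
      caps <- vapply(hm, function(h) {
        Lc <- nchar(h@consensus)
        if (Lc == 0L) max(2L, slack %/% 2L) else Lc + slack
      }, integer(1))
      out[[g]]$cap <- sum(caps)
      out[[g]]$segCaps <- caps
    }
  }
  out
}
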