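# End-to-end pipeline: alignment (+ optional pair list, descriptor file)
# -> annotated Stockholm, motif table, run log.

#' Consensus structure string of a multilayer parse
#'
#' Layer-1 pairs in angle brackets, pseudoknot layers in bracket alphabets
#' (Aa, Bb, ...), unpaired columns as dots.
#'
#' @param parse a \linkS4class{ParseResult}
#' @return character string of length \code{L}
#' @export
ssConsString <- function(parse) {
  ss <- rep(".", parse@L)
  ly <- parse@layers
  if (length(ly) && nrow(ly[[1]])) {
    ss[ly[[1]][, 1]] <- "<"; ss[ly[[1]][, 2]] <- ">"
  }
  if (length(ly) > 1L) for (k in 2:length(ly)) {
    if (!nrow(ly[[k]])) next
    op <- LETTERS[k - 1L]; clch <- letters[k - 1L]
    ss[ly[[k]][, 1]] <- op; ss[ly[[k]][, 2]] <- clch
  }
  paste(ss, collapse = "")
}

# per-column motif annotation line: one marker character per call
.motifGCLine <- function(parse) {
  marks <- c(as.character(1:9), LETTERS)
  out <- rep(".", parse@L)
  calls <- parse@motifCalls
  if (nrow(calls)) for (r in seq_len(nrow(calls))) {
    mk <- marks[((r - 1L) %% length(marks)) + 1L]
    out[calls$start[r]:calls$end[r]] <- mk
  }
  paste(out, collapse = "")
}

#' Run the full prediction pipeline
#'
#' Reads an alignment (Stockholm, or FASTA for single sequences), obtains
#' covariation evidence (external TSV, the built-in approximate statistic,
#' or none), decomposes positive pairs into layers, folds, flags motif
#' support, and writes three artifacts into \code{outDir}: an annotated
#' Stockholm file (\code{SS_cons} plus a \code{R3D} motif-span line), a
#' motif TSV and a run log.
#'
#' @param input alignment path
#' @param r3dfile motif descriptor path (default: bundled library); an
#'   empty-library file yields structure-only output
#' @param pairs path to a covarying-pair TSV (columns i, j, E, class)
#' @param standinCovariation compute the approximate covariation statistic
#'   instead (ignored when \code{pairs} is given)
#' @param gapMax column gap-fraction threshold
#' @param evalue E-value cutoff for positive pairs
#' @param seed RNG seed (stand-in statistic shuffles)
#' @param params optional parameter JSON path
#' @param outDir output directory (created if needed)
#' @param quiet suppress progress messages
#' @return the \linkS4class{ParseResult}, invisibly
#' @export
runPipeline <- function(input, r3dfile = NULL, pairs = NULL,
                        standinCovariation = FALSE, gapMax = 0.75,
                        evalue = 0.05, seed = 42L, params = NULL,
                        outDir = ".", quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  logit <- function(...) {
    ln <- sprintf(...)
    logLines <<- c(logLines, ln)
    say(ln)
  }
  firstLine <- readLines(input, n = 1L, warn = FALSE)
  msa <- if (grepl("^# STOCKHOLM", firstLine)) readStockholm(input)
         else readFastaMSA(input)
  logit("input: %s (%d sequences x %d columns)", input, nSeq(msa),
        alnLength(msa))
  descriptors <- if (is.null(r3dfile)) builtinMotifLibrary()
                 else parseDescriptor(r3dfile)
  logit("motif library: %d descriptors (%s)", length(descriptors),
        if (is.null(r3dfile)) "bundled" else r3dfile)
  variants <- suppressMessages(expandVariants(descriptors))
  logit("total nonredundant motif variants: %d", length(variants))
  pm <- if (is.null(params)) {
    logit("parameters: bundled defaults")
    defaultFoldParams()
  } else {
    logit("parameters: %s", params)
    readParamsJSON(params)
  }
  pa <- buildProbAlignment(msa, gapMax = gapMax)
  logit("gap filter (gapMax = %g): kept %d of %d columns", gapMax,
        length(keptColumns(pa)), alnLength(msa))
  pset <- if (!is.null(pairs)) {
    logit("covariation: external pair list %s", pairs)
    readPairsTSV(pairs, pa, threshold = evalue)
  } else if (standinCovariation) {
    logit("covariation: built-in stand-in statistic (approximate)")
    suppressMessages(covariationStandin(msa, pa, seed = seed,
                                        threshold = evalue))
  } else {
    logit("covariation: none (unconstrained fold)")
    pairSet(NULL, NULL, evalue)
  }
  pos <- pset@positives
  pos <- pos[pos[, 3] <= evalue, , drop = FALSE]
  layers <- if (nrow(pos)) decomposeLayers(pos[, 1:2, drop = FALSE])
            else list()
  logit("positive pairs: %d in %d layer(s); negative pairs: %d",
        nrow(pos), length(layers), nrow(pset@negatives))
  grammar <- buildR3dGrammar(variants, pm)
  res <- foldMultilayer(pa, grammar, layers = layers,
                        negatives = pset@negatives)
  res <- annotateSupport(res, pset)
  logit("fold: log probability %.4f; %d pair(s) in layer 1; %d motif call(s)",
        parseLogProb(res), nrow(pairLayers(res)[[1]]),
        nrow(motifCalls(res)))
  # artifacts
  stoPath <- file.path(outDir, "annotated.sto")
  msaOut <- methods::initialize(msa, ssCons = ssConsString(res))
  writeStockholm(msaOut, stoPath, extraGC = list(R3D = .motifGCLine(res)))
  tsvPath <- file.path(outDir, "motifs.tsv")
  calls <- motifCalls(res)
  utils::write.table(
    calls[, c("name", "class", "variant", "start", "end", "logScore",
              "supported", "segments")],
    tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  logPath <- file.path(outDir, "run.log")
  writeLines(logLines, logPath)
  invisible(res)
}

#' Run the pipeline from a configuration file
#'
#' The JSON configuration mirrors the arguments of \code{runPipeline}
#' (\code{input}, \code{r3dfile}, \code{pairs}, \code{standinCovariation},
#' \code{gapMax}, \code{evalue}, \code{seed}, \code{params}, \code{outDir}).
#'
#' @param path JSON configuration file
#' @param ... overrides applied on top of the file
#' @return the \linkS4class{ParseResult}, invisibly
#' @export
runPipelineConfig <- function(path, ...) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(runPipeline))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) .stopf("unknown configuration key '%s'", bad[1])
  cfg <- utils::modifyList(cfg, list(...))
  do.call(runPipeline, cfg)
}
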