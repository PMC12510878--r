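# Alignment input/output: Stockholm 1.0 (with #=GC annotation lines) and
# FASTA (single sequences treated as an S = 1 alignment). Residues are
# normalized on ingest: upper case, T -> U, any of '-', '.', '_', '~' -> '-'.

.normalizeRow <- function(x) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  gsub("[._~]", "-", x)
}

#' Construct an RnaMSA from id and row vectors
#'
#' @param ids sequence identifiers
#' @param rows aligned strings (equal length)
#' @param ssCons optional consensus structure line
#' @param gc optional named list of further per-column annotation lines
#' @return an \linkS4class{RnaMSA}
#' @export
rnaMSA <- function(ids, rows, ssCons = NA_character_, gc = list()) {
  obj <- new("RnaMSA", ids = as.character(ids),
             rows = .normalizeRow(as.character(rows)),
             ssCons = ssCons, gc = gc)
  validObject(obj)
  obj
}

#' Read a Stockholm 1.0 alignment
#'
#' Handles interleaved (multi-block) files; captures \code{#=GC SS_cons} into
#' the \code{ssCons} slot and any other \code{#=GC} line into \code{gc}.
#' Per-sequence (\code{#=GS}/\code{#=GR}) annotations are ignored.
#'
#' @param path file path
#' @return an \linkS4class{RnaMSA}
#' @export
readStockholm <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    .stopf("not a Stockholm 1.0 file (missing '# STOCKHOLM' header): %s", path)
  seqs <- list(); gc <- list(); order <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || ln == "//") next
    if (startsWith(ln, "#=GC")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) >= 3) {
        tag <- f[2]
        gc[[tag]] <- paste0(if (is.null(gc[[tag]])) "" else gc[[tag]], f[3])
      }
      next
    }
    if (startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 2)
      .stopf("malformed Stockholm sequence line: '%s'", ln)
    id <- f[1]
    if (is.null(seqs[[id]])) { seqs[[id]] <- ""; order <- c(order, id) }
    seqs[[id]] <- paste0(seqs[[id]], f[2])
  }
  if (!length(seqs)) .stopf("Stockholm file contains no sequences: %s", path)
  rows <- unlist(seqs[order], use.names = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    .stopf("ragged Stockholm alignment: rows differ in length")
  ss <- if (!is.null(gc[["SS_cons"]])) gc[["SS_cons"]] else NA_character_
  gc[["SS_cons"]] <- NULL
  rnaMSA(order, rows, ssCons = ss, gc = gc)
}

#' Write an RnaMSA as Stockholm 1.0
#'
#' @param msa an RnaMSA
#' @param path output file
#' @param extraGC optional named list of additional per-column annotation
#'   lines (e.g. a motif-span line) appended as \code{#=GC} records
#' @export
writeStockholm <- function(msa, path, extraGC = list()) {
  w <- max(nchar(msa@ids), 12L)
  out <- c("# STOCKHOLM 1.0", "")
  out <- c(out, sprintf("%-*s %s", w, msa@ids, msa@rows))
  gcs <- msa@gc
  if (!is.na(msa@ssCons)) gcs[["SS_cons"]] <- msa@ssCons
  for (tag in names(extraGC)) gcs[[tag]] <- extraGC[[tag]]
  for (tag in names(gcs))
    out <- c(out, sprintf("%-*s %s", w, paste("#=GC", tag), gcs[[tag]]))
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file as an alignment
#'
#' A single sequence becomes an S = 1 alignment; multiple sequences are
#' accepted if already aligned (equal lengths). Uses Biostrings when it is
#' available, with a plain-text fallback parser otherwise.
#'
#' @param path file path
#' @return an \linkS4class{RnaMSA}
#' @export
readFastaMSA <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    rows <- as.character(ss)
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (!length(hdr)) .stopf("not a FASTA file: %s", path)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    to <- c(hdr[-1] - 1L, length(lines))
    rows <- vapply(seq_along(hdr), function(k) {
      paste(lines[seq(hdr[k] + 1L, to[k])][!grepl("^>", lines[seq(hdr[k] + 1L, to[k])])],
            collapse = "")
    }, character(1))
  }
  if (length(unique(nchar(rows))) != 1L)
    .stopf("FASTA sequences have unequal lengths; not an alignment")
  rnaMSA(ids, rows)
}

#' Shuffle each alignment column independently
#'
#' Permutes the residues within every column independently of the others,
#' preserving each column's residue multiset exactly. This destroys
#' covariation between columns while keeping per-column base composition (and
#' hence any purely sequence-based motif signal), and is the null used for
#' control alignments and the approximate covariation statistic.
#'
#' @param msa an RnaMSA
#' @param seed integer seed; the same seed reproduces the same output
#' @return a column-shuffled \linkS4class{RnaMSA}
#' @export
shuffleColumns <- function(msa, seed) {
  m <- .charMatrix(msa)
  S <- nrow(m)
  .withSeed(seed, {
    for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(S), j]
  })
  rnaMSA(msa@ids, apply(m, 1, paste, collapse = ""),
         ssCons = msa@ssCons, gc = msa@gc)
}

# S x L character matrix of an alignment
.charMatrix <- function(msa) {
  do.call(rbind, strsplit(msa@rows, ""))
}
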