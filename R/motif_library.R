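# Motif descriptor format, bundled library, and variant expansion.
#
# Descriptor dialect: one record per line,
#     CLASS NAME key=value key=value ...
# '#' starts a comment; an empty value means an empty segment. Required keys:
#   HL : Loop, plus matched L1..Lk / R1..Rk (k <= 3; values may be empty)
#   BL : Loop, plus optional matched L1..Lk / R1..Rk
#   IL : Lo Loop1 Li Ri Loop2 Ro (all six, values may be empty)
#   J3 : S1 S2 S3        J4 : S1 S2 S3 S4        BS : S1

.MAX_HL_PAIRS <- 3L

.requiredKeys <- function(cls, keys) {
  ls <- grep("^L[0-9]$", keys, value = TRUE)
  rs <- grep("^R[0-9]$", keys, value = TRUE)
  switch(cls,
    HL = , BL = {
      if (!"Loop" %in% keys) return("missing segment Loop")
      if (cls == "HL" && !length(ls)) return("HL needs at least L1/R1")
      if (!setequal(sub("L", "", ls), sub("R", "", rs)))
        return("unmatched L/R correlated segments")
      if (length(ls) > .MAX_HL_PAIRS)
        return(sprintf("at most %d correlated pairs supported", .MAX_HL_PAIRS))
      extra <- setdiff(keys, c("Loop", ls, rs))
      if (length(extra)) return(paste("unknown key:", extra[1]))
      NULL
    },
    IL = {
      need <- c("Lo", "Loop1", "Li", "Ri", "Loop2", "Ro")
      miss <- setdiff(need, keys)
      if (length(miss)) return(paste("missing segment", miss[1]))
      extra <- setdiff(keys, need)
      if (length(extra)) return(paste("unknown key:", extra[1]))
      NULL
    },
    J3 = , J4 = , BS = {
      n <- switch(cls, J3 = 3L, J4 = 4L, BS = 1L)
      need <- paste0("S", seq_len(n))
      miss <- setdiff(need, keys)
      if (length(miss)) return(paste("missing segment", miss[1]))
      extra <- setdiff(keys, need)
      if (length(extra)) return(paste("unknown key:", extra[1]))
      NULL
    })
}

#' Parse a motif descriptor file
#'
#' @param path descriptor file in the line-based dialect above
#' @return list of \linkS4class{MotifDescriptor}
#' @export
parseDescriptor <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (k in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[k])
    if (!nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2)
      .stopf("line %d: expected 'CLASS NAME key=value ...'", k)
    cls <- f[1]; name <- f[2]
    if (!cls %in% MOTIF_CLASSES)
      .stopf("line %d: unknown motif class '%s'", k, cls)
    kv <- f[-(1:2)]
    if (length(kv) && !all(grepl("^[A-Za-z0-9]+=", kv)))
      .stopf("line %d: malformed key=value token", k)
    keys <- sub("=.*$", "", kv)
    vals <- toupper(sub("^[A-Za-z0-9]+=", "", kv))
    if (anyDuplicated(keys)) .stopf("line %d: duplicate segment key", k)
    err <- .requiredKeys(cls, keys)
    if (!is.null(err)) .stopf("line %d: %s", k, err)
    segs <- setNames(vals, keys)
    bad <- setdiff(unlist(strsplit(vals, "")), names(IUPAC))
    if (length(bad))
      .stopf("line %d: invalid IUPAC character '%s'", k, bad[1])
    if (name %in% vapply(out, function(d) d@name, character(1)))
      .stopf("line %d: duplicate motif name '%s'", k, name)
    d <- new("MotifDescriptor", name = name, motifClass = cls,
             segments = segs)
    validObject(d)
    out[[length(out) + 1L]] <- d
  }
  out
}

#' Bundled motif library
#'
#' Parses the descriptor file shipped with the package. It covers the motifs
#' whose consensus segments are documented in the file's header comments;
#' the library is freely extensible through \code{parseDescriptor}.
#'
#' @return list of \linkS4class{MotifDescriptor}
#' @export
builtinMotifLibrary <- function() {
  parseDescriptor(system.file("extdata", "motifs_builtin.r3d",
                              package = "RNAMotifFold", mustWork = TRUE))
}

# ordered element tuples per class; "&" marks an enclosed helix
.hlElements <- function(segs) {
  ks <- sort(grep("^L[0-9]$", names(segs), value = TRUE))
  c(setNames(segs[ks], ks), Loop = unname(segs[["Loop"]]),
    setNames(segs[rev(sub("L", "R", ks))], rev(sub("L", "R", ks))))
}

.variantsOf <- function(d) {
  segs <- d@segments
  mk <- function(idx, els) {
    new("MotifVariant", descriptor = d, topologyIndex = as.integer(idx),
        elements = unname(els), segNames = names(els),
        uniqueId = sprintf("%s.%s.%d", d@name, d@motifClass, idx))
  }
  switch(d@motifClass,
    HL = list(mk(1, .hlElements(segs))),
    BL = {
      e <- .hlElements(segs)
      list(mk(1, c(e, "&" = "&")),   # left bulge: strand then enclosed helix
           mk(2, c("&" = "&", e)))   # right bulge
    },
    IL = {
      a <- segs[c("Lo", "Loop1", "Li")]; b <- segs[c("Ri", "Loop2", "Ro")]
      list(mk(1, c(a, "&" = "&", b)),
           mk(2, c(b, "&" = "&", a)))
    },
    J3 = {
      s <- segs[c("S1", "S2", "S3")]
      lapply(1:3, function(r) {
        ord <- ((seq(r, r + 2) - 1) %% 3) + 1
        e <- s[ord]
        mk(r, c(e[1], "&" = "&", e[2], "&" = "&", e[3]))
      })
    },
    J4 = {
      s <- segs[c("S1", "S2", "S3", "S4")]
      lapply(1:4, function(r) {
        ord <- ((seq(r, r + 3) - 1) %% 4) + 1
        e <- s[ord]
        mk(r, c(e[1], "&" = "&", e[2], "&" = "&", e[3], "&" = "&", e[4]))
      })
    },
    BS = list(mk(1, segs["S1"])))
}

#' Expand motif descriptors into topological variants
#'
#' Every motif bounded by more than one helix is modeled in all its
#' attachments: 1 variant for HL and BS, 2 for BL (left/right bulge) and IL,
#' 3 for J3 and 4 for J4. Variants whose (class, ordered element tuple) are
#' identical are redundant and merged; the surviving count is reported via
#' \code{message()}.
#'
#' @param descriptors list of \linkS4class{MotifDescriptor}
#' @param quiet suppress the unique-variant count message
#' @return list of unique \linkS4class{MotifVariant}
#' @export
expandVariants <- function(descriptors, quiet = FALSE) {
  all <- unlist(lapply(descriptors, .variantsOf), recursive = FALSE)
  if (!length(all)) {
    if (!quiet) message("0 nonredundant motif variants")
    return(list())
  }
  keys <- vapply(all, function(v)
    paste(v@descriptor@motifClass, paste(v@elements, collapse = "|"),
          sep = ":"), character(1))
  uniq <- all[!duplicated(keys)]
  if (!quiet)
    message(length(uniq), " nonredundant motif variants (from ",
            length(all), " before redundancy elimination)")
  uniq
}

# variants grouped by the grammar slot they occupy
.variantClass <- function(v) v@descriptor@motifClass

.groupVariants <- function(variants) {
  cls <- vapply(variants, .variantClass, character(1))
  topo <- vapply(variants, function(v) v@topologyIndex, integer(1))
  list(
    HL = variants[cls == "HL"],
    BLleft = variants[cls == "BL" & topo == 1L],
    BLright = variants[cls == "BL" & topo == 2L],
    IL = variants[cls == "IL"],
    J3 = variants[cls == "J3"],
    J4 = variants[cls == "J4"],
    BS = variants[cls == "BS"])
}
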