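# Core annotated-sequence operations: accessors, coordinate-safe edits,
# motif scanning and transcript splicing. All coordinates are 0-based
# half-open internally; GenBank/GFF3 conversion happens at the I/O boundary.

#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
NULL

#' @describeIn AnnSeq-class sequence length in nucleotides
#' @param x An `AnnSeq`.
#' @export
annLength <- function(x) nchar(x@residues)

#' @describeIn AnnSeq-class residues as a character string
#' @export
residues <- function(x) x@residues

#' @describeIn AnnSeq-class topology accessor
#' @export
topology <- function(x) x@topology

#' @describeIn AnnSeq-class feature table accessor
#' @export
annFeatures <- function(x) x@features

#' @describeIn AnnSeq-class replace the feature table
#' @param value New feature table.
#' @export
`annFeatures<-` <- function(x, value) {
  x@features <- value
  validObject(x)
  x
}

sortFeatures <- function(f) f[order(f$start, f$end, f$label), , drop = FALSE]

shiftFeatures <- function(f, by) {
  if (nrow(f)) {
    f$start <- f$start + as.integer(by)
    f$end <- f$end + as.integer(by)
  }
  f
}

# Features of `x` fully inside [start, end), remapped to the window origin.
# Features partially overlapping the window are dropped and logged.
windowFeatures <- function(x, start, end, what = "edit") {
  f <- x@features
  if (!nrow(f)) return(f)
  f <- f[!f$wrap, , drop = FALSE]
  inside <- f$start >= start & f$end <= end
  spans <- (f$start < start & f$end > start) | (f$start < end & f$end > end)
  if (any(spans & !inside))
    tfLog("info", "dropping feature(s) spanning a ", what, " boundary: ",
          paste(f$label[spans & !inside], collapse = ", "))
  shiftFeatures(f[inside, , drop = FALSE], -start)
}

# Linear sub-sequence [start, end) of x with remapped features.
annSubseq <- function(x, start, end, id = x@id) {
  AnnSeq(substr(x@residues, start + 1L, end),
         id = id, topology = "linear",
         features = sortFeatures(windowFeatures(x, start, end)))
}

# Concatenate AnnSeq pieces into one linear (or circular) sequence,
# remapping every feature.
annConcat <- function(pieces, id, topology = "linear") {
  res <- paste(vapply(pieces, function(p) p@residues, character(1)),
               collapse = "")
  off <- 0L
  feats <- list()
  for (p in pieces) {
    feats[[length(feats) + 1L]] <- shiftFeatures(p@features, off)
    off <- off + annLength(p)
  }
  AnnSeq(res, id = id, topology = topology,
         features = sortFeatures(do.call(rbind, c(list(emptyFeatures()),
                                                  feats))))
}

# Insert a (linear) AnnSeq at position pos of x; features of x spanning pos
# are dropped with a log line.
annInsert <- function(x, pos, insert, id = x@id) {
  stopifnot(pos >= 0L, pos <= annLength(x))
  out <- annConcat(list(annSubseq(x, 0L, pos),
                        insert,
                        annSubseq(x, pos, annLength(x))),
                   id = id, topology = x@topology)
  out
}

# Rotate a circular sequence so that `origin` becomes position 0. Features
# are remapped modulo length; a feature that now spans the junction gains the
# wrap flag.
rotateCirc <- function(x, origin) {
  stopifnot(x@topology == "circular")
  L <- annLength(x)
  origin <- origin %% L
  res <- paste0(substr(x@residues, origin + 1L, L),
                substr(x@residues, 1L, origin))
  f <- x@features
  if (nrow(f)) {
    len <- ifelse(f$wrap, (f$end - f$start) %% L, f$end - f$start)
    f$start <- (f$start - origin) %% L
    f$end <- f$start + len
    f$wrap <- f$end > L
    f$end <- ifelse(f$wrap, f$end %% L, f$end)
  }
  AnnSeq(res, id = x@id, topology = "circular", features = sortFeatures(f))
}

setMethod("reverseComplement", "AnnSeq", function(x, ...) {
  L <- annLength(x)
  f <- x@features
  if (nrow(f)) {
    ns <- L - f$end
    ne <- L - f$start
    f$start <- as.integer(ns)
    f$end <- as.integer(ne)
    f$strand <- ifelse(f$strand == "+", "-", "+")
  }
  AnnSeq(revcompChar(x@residues), id = x@id, topology = x@topology,
         features = sortFeatures(f))
})

iupacOK <- function(motif) {
  !grepl(paste0("[^", paste(names(Biostrings::IUPAC_CODE_MAP),
                            collapse = ""), "]"), motif)
}

#' Scan a sequence for an IUPAC-degenerate motif
#'
#' Finds every occurrence of `motif` (IUPAC codes allowed) on the top strand
#' and, optionally, the bottom strand. Circular sequences are scanned across
#' the origin. Palindromic motifs are reported once per position when both
#' strands are requested.
#'
#' @param x An [AnnSeq-class].
#' @param motif IUPAC DNA motif, length >= 4.
#' @param bothStrands Scan the reverse strand as well?
#' @return data.frame with 0-based half-open `start`, `end` and `strand`,
#'   ascending by start. Starts are given modulo the sequence length for hits
#'   crossing a circular origin.
#' @examples
#' scanMotif(AnnSeq("AAGTTTAAACTT"), "GTTTAAAC")
#' @export
scanMotif <- function(x, motif, bothStrands = FALSE) {
  motif <- toupper(motif)
  if (!iupacOK(motif)) stop("invalid motif: non-IUPAC character in '",
                            motif, "'")
  if (nchar(motif) < 4L) stop("motif length must be >= 4")
  L <- annLength(x)
  m <- nchar(motif)
  subject <- x@residues
  if (x@topology == "circular" && L > m)
    subject <- paste0(subject, substr(x@residues, 1L, m - 1L))
  hitsOf <- function(pat) {
    mp <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                   Biostrings::DNAString(subject),
                                   fixed = FALSE)
    s <- BiocGenerics::start(mp) - 1L
    s[s < L]
  }
  fwd <- hitsOf(motif)
  out <- data.frame(start = fwd, end = fwd + m, strand = rep("+",
                                                             length(fwd)))
  if (bothStrands) {
    rc <- revcompChar(motif)
    if (!identical(rc, motif)) {  # palindromes already reported once
      rev <- hitsOf(rc)
      rev <- setdiff(rev, fwd)
      if (length(rev))
        out <- rbind(out, data.frame(start = rev, end = rev + m,
                                     strand = "-"))
    }
  }
  out$end <- ifelse(out$end > L & x@topology == "circular", out$end %% L,
                    out$end)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cut a sequence at two offsets
#'
#' Double cut yielding a remainder and an excised segment. Lengths are
#' conserved: `annLength(remainder) + annLength(excised)` equals the input
#' length. Features wholly inside one product are retained with remapped
#' coordinates; features spanning a cut are dropped and logged. On circular
#' input the cut pair may wrap the origin and both products are circular.
#'
#' @param x An [AnnSeq-class].
#' @param cutLeft,cutRight 0-based cut offsets (`cutLeft != cutRight`).
#' @return list with elements `remainder` and `excised`.
#' @export
exciseSegment <- function(x, cutLeft, cutRight) {
  L <- annLength(x)
  cutLeft <- as.integer(cutLeft); cutRight <- as.integer(cutRight)
  if (cutLeft == cutRight) stop("degenerate cut: cutLeft == cutRight")
  if (x@topology == "linear") {
    if (cutLeft > cutRight) stop("cutLeft must precede cutRight on a ",
                                 "linear sequence")
    stopifnot(cutLeft >= 0L, cutRight <= L)
    excised <- annSubseq(x, cutLeft, cutRight, id = paste0(x@id,
                                                           "_excised"))
    remainder <- annConcat(list(annSubseq(x, 0L, cutLeft),
                                annSubseq(x, cutRight, L)),
                           id = x@id, topology = "linear")
    # features spanning either cut were dropped by windowFeatures
    return(list(remainder = remainder, excised = excised))
  }
  # circular: rotate so cutLeft is the origin, then cut linearly
  rot <- rotateCirc(x, cutLeft)
  k <- (cutRight - cutLeft) %% L
  excised <- annSubseq(rot, 0L, k, id = paste0(x@id, "_excised"))
  excised@topology <- "circular"
  remainder <- annSubseq(rot, k, L, id = x@id)
  remainder@topology <- "circular"
  list(remainder = remainder, excised = excised)
}

# Trap cassettes (cassette features with a TRUE `trap` qualifier) on a
# sequence, sorted by start.
trapCassetteFeatures <- function(x) {
  f <- x@features
  if (!nrow(f)) return(f)
  keep <- f$kind == "cassette" &
    vapply(f$quals, function(q) isTRUE(q$trap), logical(1))
  sortFeatures(f[keep, , drop = FALSE])
}

exonFeatures <- function(x) {
  f <- x@features
  sortFeatures(f[f$kind %in% c("exon", "critical_exon"), , drop = FALSE])
}

#' Splice the primary transcript of an annotated locus
#'
#' Concatenates exon residues in transcription order. If a gene-trap cassette
#' (splice acceptor + marker ORF + polyA) lies in an intron between two
#' retained exons, splicing terminates at the cassette: the message is the
#' upstream exons followed by the cassette coding region. Exons and CDS
#' segments (and any appended cassette) are remapped into mRNA coordinates.
#'
#' @param x Locus [AnnSeq-class] with exon features.
#' @param strand Coding strand; `"-"` loci are reverse-complemented first.
#' @return mRNA as a linear [AnnSeq-class]. The attribute `"trapped"` is TRUE
#'   when a trap cassette terminated the message.
#' @export
spliceTranscript <- function(x, strand = "+") {
  if (strand == "-") x <- reverseComplement(x)
  ex <- exonFeatures(x)
  if (!nrow(ex)) stop("empty transcript: no exon features on '", x@id, "'")
  traps <- trapCassetteFeatures(x)
  nKeep <- nrow(ex)
  trapRow <- NULL
  if (nrow(traps)) {
    t0 <- traps$start[1]
    if (t0 < ex$start[1])
      stop("trap cassette upstream of the first exon is not a splice ",
           "substrate")
    nKeep <- sum(ex$end <= t0)
    trapRow <- traps[1, , drop = FALSE]
  }
  pieces <- lapply(seq_len(nKeep), function(i)
    annSubseq(x, ex$start[i], ex$end[i]))
  if (!is.null(trapRow)) {
    cs <- featQual(trapRow, "coding_start")
    ce <- featQual(trapRow, "coding_end")
    block <- annSubseq(x, trapRow$start + cs, trapRow$start + ce)
    tr <- trapRow
    tr$start <- 0L; tr$end <- as.integer(ce - cs)
    block@features <- sortFeatures(rbind(block@features, tr))
    pieces <- c(pieces, list(block))
  }
  out <- annConcat(pieces, id = paste0(x@id, "_mRNA"))
  attr(out, "trapped") <- !is.null(trapRow)
  out
}
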