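#' @import methods
NULL

ALLELE_STATES <- c("wt", "tm1a", "tm1b", "tm1c", "tm1d", "tm2")

FEATURE_KINDS <- c("exon", "cds_segment", "critical_exon", "homology_arm",
                   "recomb_site", "restriction_site", "cassette",
                   "primer_site", "promoter", "polyA", "splice_acceptor",
                   "origin", "marker")

emptyFeatures <- function() {
  data.frame(label = character(), kind = character(),
             start = integer(), end = integer(), strand = character(),
             wrap = logical(), quals = I(list()),
             stringsAsFactors = FALSE)
}

#' Build a one-row feature table
#'
#' Features use 0-based half-open intervals on the carrying sequence. Extra
#' named arguments become qualifiers (e.g. `site_subtype`, `marker_name`,
#' `frame_phase`, `trap`).
#'
#' @param label Feature label (text).
#' @param kind One of the supported feature kinds (exon, cds_segment,
#'   critical_exon, homology_arm, recomb_site, restriction_site, cassette,
#'   primer_site, promoter, polyA, splice_acceptor, origin, marker).
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param wrap Logical; `TRUE` for a circular feature spanning the origin.
#' @param ... Qualifiers (named scalars).
#' @return A one-row `data.frame` suitable for `rbind()` into a feature table.
#' @export
annFeature <- function(label, kind, start, end, strand = "+", wrap = FALSE,
                       ...) {
  stopifnot(kind %in% FEATURE_KINDS)
  q <- list(...)
  if (kind == "recomb_site" && is.null(q$site_subtype))
    stop("recomb_site features must carry a 'site_subtype' qualifier")
  if (kind == "cassette" && is.null(q$marker_name))
    stop("cassette features must carry a 'marker_name' qualifier")
  data.frame(label = label, kind = kind,
             start = as.integer(start), end = as.integer(end),
             strand = strand, wrap = wrap, quals = I(list(q)),
             stringsAsFactors = FALSE)
}

featQual <- function(featureRow, key) featureRow$quals[[1]][[key]]

#' Annotated DNA sequence
#'
#' The universal substrate of every operation in the package: a linear or
#' circular DNA sequence carrying typed, stranded features with 0-based
#' half-open coordinates. Feature coordinates are remapped through every edit;
#' features destroyed by an edit are dropped with a logged reason rather than
#' silently truncated.
#'
#' @slot residues DNA text over A, C, G, T, N.
#' @slot topology `"linear"` or `"circular"`.
#' @slot features Feature table (see [annFeature()]).
#' @slot id Sequence identifier.
#' @aliases AnnSeq-class
#' @exportClass AnnSeq
setClass("AnnSeq", representation(residues = "character",
                                  topology = "character",
                                  features = "data.frame",
                                  id = "character"))

setValidity("AnnSeq", function(object) {
  if (length(object@residues) != 1L) return("residues must be a single string")
  if (grepl("[^ACGTN]", object@residues))
    return("residues must be over {A,C,G,T,N}")
  if (!object@topology %in% c("linear", "circular"))
    return("topology must be 'linear' or 'circular'")
  f <- object@features
  L <- nchar(object@residues)
  if (nrow(f)) {
    if (any(f$start < 0L | f$end > L))
      return("feature interval outside sequence bounds")
    bad <- !f$wrap & f$start >= f$end
    if (any(bad)) return("non-wrapping features need start < end")
    if (any(f$wrap) && object@topology != "circular")
      return("wrapping features require a circular sequence")
  }
  TRUE
})

#' Construct an AnnSeq
#'
#' @param residues DNA string (A/C/G/T/N).
#' @param id Sequence id.
#' @param topology `"linear"` (default) or `"circular"`.
#' @param features Feature table built with [annFeature()].
#' @return An [AnnSeq-class] object.
#' @examples
#' AnnSeq("ACGTACGT", id = "toy")
#' @export
AnnSeq <- function(residues, id = "seq", topology = "linear",
                   features = emptyFeatures()) {
  new("AnnSeq", residues = toupper(as.character(residues)),
      topology = topology, features = features, id = id)
}

#' Gene model for a target locus
#'
#' Exon/CDS structure on a locus sequence plus the ES-cell expression level
#' (percent of the transferrin-receptor housekeeping reference) and the
#' ground-truth essentiality flag consumed by viability logic.
#'
#' @slot geneID Gene symbol.
#' @slot strand Coding strand on the locus.
#' @slot exons,cds data.frames of 0-based half-open intervals, transcription
#'   order.
#' @slot expressionPctTrfr Expression as percent of the Trfr reference.
#' @slot essentialInES Ground-truth essentiality flag.
#' @aliases GeneModel-class
#' @exportClass GeneModel
setClass("GeneModel", representation(geneID = "character",
                                     strand = "character",
                                     exons = "data.frame",
                                     cds = "data.frame",
                                     expressionPctTrfr = "numeric",
                                     essentialInES = "logical"))

setValidity("GeneModel", function(object) {
  if (object@expressionPctTrfr < 0) return("expression must be non-negative")
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  ex <- object@exons; cd <- object@cds
  if (nrow(cd)) {
    inside <- vapply(seq_len(nrow(cd)), function(i) {
      any(ex$start <= cd$start[i] & cd$end[i] <= ex$end)
    }, logical(1))
    if (!all(inside)) return("cds segments must lie within exons")
  }
  TRUE
})

#' @rdname GeneModel-class
#' @param geneID,strand,exons,cds,expressionPctTrfr,essentialInES See slots.
#' @export
GeneModel <- function(geneID, strand = "+", exons, cds,
                      expressionPctTrfr = 10, essentialInES = FALSE) {
  new("GeneModel", geneID = geneID, strand = strand, exons = exons, cds = cds,
      expressionPctTrfr = expressionPctTrfr, essentialInES = essentialInES)
}

#' Gene-trap cassette in a fixed reading frame
#'
#' One member of the three-frame hygromycin-GFP trap library (or the single
#' beta-geo trap). `framePhase` is the exon end phase (cumulative coding
#' length mod 3) the cassette is designed to splice onto in frame.
#'
#' @slot framePhase 0, 1 or 2.
#' @slot markerName `"hygro_gfp"` or `"betageo"`.
#' @slot seq Cassette payload as an [AnnSeq-class] (splice acceptor, ORF,
#'   polyA and, for the hygro-GFP trap, plasmid origin and kanR).
#' @aliases TrapCassette-class
#' @exportClass TrapCassette
setClass("TrapCassette", representation(framePhase = "integer",
                                        markerName = "character",
                                        seq = "AnnSeq"))

#' Intermediate Vector geometry for one gene
#'
#' Records, in locus coordinates, the recombineering boundaries of an
#' IKMC-style Intermediate Vector: G5/G3 delimit the genomic homology, U3/D5
#' delimit the loxP-flanked critical-exon region.
#'
#' @slot geneID Gene symbol.
#' @slot g5,u3,d5,g3 0-based locus offsets with g5 < u3 < d5 < g3.
#' @aliases IVSpec-class
#' @exportClass IVSpec
setClass("IVSpec", representation(geneID = "character", g5 = "integer",
                                  u3 = "integer", d5 = "integer",
                                  g3 = "integer"))

setValidity("IVSpec", function(object) {
  if (!(object@g5 < object@u3 && object@u3 < object@d5 &&
        object@d5 < object@g3))
    return("require G5 < U3 < D5 < G3 on the coding strand")
  TRUE
})

#' One chromosomal allele of the target locus
#'
#' An annotated locus sequence plus the symbolic allele state and an event
#' provenance log. The state census (which recombination sites and cassettes
#' each state must carry) is checked by [validateAllele()].
#'
#' @slot seq Locus sequence with flanks ([AnnSeq-class]).
#' @slot state One of wt, tm1a, tm1b, tm1c, tm1d, tm2.
#' @slot provenance Character vector of applied events.
#' @aliases AlleleMap-class
#' @exportClass AlleleMap
setClass("AlleleMap", representation(seq = "AnnSeq", state = "character",
                                     provenance = "character"))

setValidity("AlleleMap", function(object) {
  if (!object@state %in% ALLELE_STATES)
    return(paste("unknown allele state:", object@state))
  TRUE
})

AlleleMap <- function(seq, state, provenance = character()) {
  new("AlleleMap", seq = seq, state = state, provenance = provenance)
}

#' An ES cell line: two alleles plus unlinked transgenes
#'
#' @slot gene The target-locus [GeneModel-class].
#' @slot alleleA,alleleB The two chromosomal [AlleleMap-class]s.
#' @slot transgenes Character vector of unlinked transgenes (e.g.
#'   `"CreERT2"`).
#' @slot extras Unlinked carrier sequences (e.g. random integrants), a list of
#'   [AnnSeq-class].
#' @slot leakRate Per-cell probability of Cre recombination without induction.
#' @slot escaperRate Per-cell probability of failing induced recombination.
#' @slot seed RNG seed for the line's stochastic draws.
#' @aliases CellLine-class
#' @exportClass CellLine
setClass("CellLine", representation(gene = "GeneModel",
                                    alleleA = "AlleleMap",
                                    alleleB = "AlleleMap",
                                    transgenes = "character",
                                    extras = "list",
                                    leakRate = "numeric",
                                    escaperRate = "numeric",
                                    seed = "integer"))

setValidity("CellLine", function(object) {
  if (object@leakRate < 0 || object@leakRate > 1 ||
      object@escaperRate < 0 || object@escaperRate > 1)
    return("leakRate and escaperRate must lie in [0, 1]")
  TRUE
})

#' A genotyping primer
#'
#' Primers are exact-match 5'->3' sequences; a forward primer binds where its
#' sequence occurs on the template top strand, a reverse primer where the
#' reverse complement of its sequence occurs. No thermodynamics are modelled.
#'
#' @slot name Primer name (gf3, LAR_3, ex5, hygro_1R, LR, R1_amp_F2, ...).
#' @slot seq Primer sequence, 5'->3'.
#' @aliases Primer-class
#' @exportClass Primer
setClass("Primer", representation(name = "character", seq = "character"))

#' @rdname Primer-class
#' @param name,seq See slots.
#' @export
Primer <- function(name, seq) new("Primer", name = name, seq = toupper(seq))

#' A screening PCR assay
#'
#' @slot name Assay name.
#' @slot fwd,rev The [Primer-class] pair.
#' @slot maxLen Maximum amplifiable span (nt).
#' @slot expected Named numeric of expected product size per allele state
#'   (`NA` where the assay yields no band).
#' @aliases Assay-class
#' @exportClass Assay
setClass("Assay", representation(name = "character", fwd = "Primer",
                                 rev = "Primer", maxLen = "numeric",
                                 expected = "numeric"))

## ---- show methods -----------------------------------------------------

setMethod("show", "AnnSeq", function(object) {
  cat(sprintf("AnnSeq '%s': %d nt, %s, %d feature(s)\n", object@id,
              nchar(object@residues), object@topology,
              nrow(object@features)))
  if (nrow(object@features)) {
    f <- object@features
    n <- min(nrow(f), 12L)
    for (i in seq_len(n))
      cat(sprintf("  %-16s %-14s [%d, %d) %s\n", f$label[i], f$kind[i],
                  f$start[i], f$end[i], f$strand[i]))
    if (nrow(f) > n) cat(sprintf("  ... and %d more\n", nrow(f) - n))
  }
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf(
    "GeneModel '%s' (%s): %d exons, CDS %d nt, expression %.1f%% Trfr%s\n",
    object@geneID, object@strand, nrow(object@exons),
    sum(object@cds$end - object@cds$start), object@expressionPctTrfr,
    if (object@essentialInES) ", essential in ES cells" else ""))
})

setMethod("show", "AlleleMap", function(object) {
  cat(sprintf("AlleleMap [%s]: %d nt, %d feature(s)\n", object@state,
              nchar(object@seq@residues), nrow(object@seq@features)))
})

setMethod("show", "CellLine", function(object) {
  cat(sprintf("CellLine %s (%s)%s\n", genotypeString(object),
              object@gene@geneID,
              if (length(object@transgenes))
                paste0(" + ", paste(object@transgenes, collapse = ", "))
              else ""))
})

setMethod("show", "TrapCassette", function(object) {
  cat(sprintf("TrapCassette %s, frame phase %d, %d nt\n", object@markerName,
              object@framePhase, nchar(object@seq@residues)))
})

setMethod("show", "Assay", function(object) {
  cat(sprintf("Assay %s: %s + %s, max %d nt\n", object@name,
              object@fwd@name, object@rev@name, as.integer(object@maxLen)))
})
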