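# The insertion-vector construction pipeline: PmeI suitability screening,
# reading-frame selection, three-way Gateway assembly, bacterial Cre
# recovery with kan/strep counter-selection, linearization, and panel-level
# vector classification.

#' Screen a vector design for extra PmeI sites
#'
#' A design is suitable iff the genomic homology region (arm5 + critical
#' exon region + arm3, i.e. G5..G3) is free of the linearization motif: the
#' adaptor supplies the single intended site, and any extra site means the
#' vector cannot be linearized intact.
#'
#' @param spec An [IVSpec-class].
#' @param genome Locus [AnnSeq-class] the arms resolve against.
#' @param motif Linearization motif (default PmeI, GTTT/AAAC).
#' @return list with `suitable` (flag) and `extraSites` (data.frame of
#'   occurrences in locus coordinates).
#' @export
checkPmeISuitability <- function(spec, genome, motif = PMEI_MOTIF) {
  if (spec@g5 < 0L || spec@g3 > annLength(genome))
    stop("coordinate error: homology arms outside genome bounds")
  region <- annSubseq(genome, spec@g5, spec@g3)
  if (grepl("N", region@residues))
    stop("homology region contains N residues; arms must support exact ",
         "homology matching")
  hits <- scanMotif(region, motif)
  hits$start <- hits$start + spec@g5
  hits$end <- hits$end + spec@g5
  list(suitable = nrow(hits) == 0L, extraSites = hits)
}

#' Select the trap cassette matching the homology end phase
#'
#' The reading frame is set by the end phase of the most 3' exon within the
#' genomic homology region (see [endPhase()]).
#'
#' @param gene A [GeneModel-class].
#' @param homology Numeric pair, the G5..G3 interval.
#' @param library Cassette library from [makeTrapCassetteLibrary()].
#' @return The matching [TrapCassette-class].
#' @export
selectFrameCassette <- function(gene, homology, library) {
  phase <- endPhase(gene, homology)
  hit <- Filter(function(cs) identical(cs@framePhase, phase), library)
  if (!length(hit)) stop("no cassette with frame phase ", phase,
                         " in the library")
  hit[[1]]
}

#' Build and linearize an insertion-type targeted-trapping vector
#'
#' Full pipeline: suitability gate, frame selection, three-way Gateway
#' exchange, bacterial Cre excision of the floxed critical-exon/rpsL region
#' (creating the gap in the genomic homology), verification that
#' counter-selection would pass, and PmeI linearization.
#'
#' @param spec An [IVSpec-class].
#' @param genome Locus [AnnSeq-class].
#' @param gene The [GeneModel-class].
#' @param iv Circular Intermediate Vector ([AnnSeq-class]).
#' @param adaptor Adaptor plasmid from [makeAdaptorPlasmid()].
#' @param library Trap cassette library.
#' @param motif Linearization motif.
#' @return list with `vector` (linear [AnnSeq-class]) and `report` (frame
#'   chosen, gap interval and length, product lengths).
#' @export
buildInsertionVector <- function(spec, genome, gene, iv, adaptor, library,
                                 motif = PMEI_MOTIF) {
  suit <- checkPmeISuitability(spec, genome, motif)
  if (!suit$suitable)
    stop("unsuitable vector: ", nrow(suit$extraSites), " extra ", motif,
         " site(s) in the homology arms; cannot be linearized intact")
  cassette <- selectFrameCassette(gene, c(spec@g5, spec@g3), library)
  donor <- makeTrapDonorPlasmid(cassette)
  gw <- gatewayThreeWay(iv, adaptor, donor)
  cre <- ssrExcise(gw$product, "loxP")
  post <- cre$main
  markers <- post@features$label[post@features$kind == "marker"]
  if ("rpsL" %in% markers)
    stop("assembly-logic error: rpsL survived the bacterial Cre step")
  if (!simulateBacterialSelection(post, c("kan", "strep")))
    stop("assembly-logic error: post-Cre vector fails kan/strep recovery")
  vec <- linearizeVector(post, motif)
  report <- list(gene = gene@geneID, framePhase = cassette@framePhase,
                 gapInterval = c(spec@u3, spec@d5),
                 gapLength = spec@d5 - spec@u3,
                 assembledLength = annLength(gw$product),
                 excisedLength = annLength(cre$excisedCircle),
                 finalLength = annLength(vec))
  list(vector = vec, report = report)
}

MEDIA_MARKER <- c(kan = "kanR", chloramphenicol = "cat", amp = "bla",
                  zeo = "zeoR", clonNAT = "natR")

#' Simulate bacterial plating of a construct on selective media
#'
#' A construct grows iff it carries a replication origin, carries the
#' resistance marker for every drug in the media, and — for streptomycin on
#' an rpsL-mutant host — does NOT carry the dominant rpsL
#' streptomycin-sensitivity counter-selection marker.
#'
#' @param construct An [AnnSeq-class] with marker/origin features.
#' @param media Character set from kan, strep, chloramphenicol, amp, zeo,
#'   clonNAT.
#' @return Logical: does the host grow?
#' @export
simulateBacterialSelection <- function(construct, media) {
  known <- c(names(MEDIA_MARKER), "strep")
  if (length(setdiff(media, known)))
    stop("unknown media component: ",
         paste(setdiff(media, known), collapse = ", "))
  f <- construct@features
  markers <- f$label[f$kind == "marker"]
  if (!any(f$kind == "origin")) return(FALSE)
  for (m in media) {
    if (m == "strep") {
      if ("rpsL" %in% markers) return(FALSE)
    } else if (!(MEDIA_MARKER[[m]] %in% markers)) return(FALSE)
  }
  TRUE
}

#' Classify a panel of vector designs by PmeI suitability
#'
#' @param panel list of designs from [makeVectorPanel()] (each with `spec`,
#'   `locus`, `gene`).
#' @param motif Linearization motif.
#' @return list with `table` (gene, design, suitable, extra_site_count) and
#'   `unsuitableFraction` (NA with a flag for an empty panel).
#' @export
screenVectorPanel <- function(panel, motif = PMEI_MOTIF) {
  if (!length(panel))
    return(list(table = data.frame(gene = character(),
                                   design = character(),
                                   suitable = logical(),
                                   extra_site_count = integer()),
                unsuitableFraction = NA_real_, empty = TRUE))
  rows <- lapply(seq_along(panel), function(i) {
    d <- panel[[i]]
    s <- checkPmeISuitability(d$spec, d$locus, motif)
    data.frame(gene = d$gene@geneID, design = sprintf("design%04d", i),
               suitable = s$suitable,
               extra_site_count = nrow(s$extraSites))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, unsuitableFraction = mean(!tab$suitable),
       empty = FALSE)
}
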