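# Recombination engine: three-way Gateway exchange, Cre/loxP and Flp/FRT
# excision, PmeI linearization, single-crossover insertion targeting with gap
# repair, and random integration. Site-specific recombination operates on
# typed recomb_site features, not on raw motifs; every event conserves
# residues up to the bookkeeping stated in each operation's contract.

siteFeatures <- function(x, subtype) {
  f <- x@features
  if (!nrow(f)) return(f[0, ])
  keep <- f$kind == "recomb_site" &
    vapply(f$quals, function(q) identical(q$site_subtype, subtype),
           logical(1))
  sortFeatures(f[keep, , drop = FALSE])
}

requireOneSite <- function(x, subtype, who) {
  s <- siteFeatures(x, subtype)
  if (nrow(s) == 0L) stop("missing site: ", who, " carries no ", subtype)
  if (nrow(s) > 1L) stop("ambiguous site: ", who, " carries ", nrow(s),
                         " copies of ", subtype)
  s
}

relabelSite <- function(row, newSubtype) {
  row$label <- newSubtype
  row$quals <- I(list(modifyList(row$quals[[1]],
                                 list(site_subtype = newSubtype))))
  row
}

# Extract [from, to) of a circular AnnSeq as a linear piece (no wrap of the
# window itself).
circPiece <- function(x, from, to) annSubseq(x, from, to)

#' Three-way Gateway exchange
#'
#' Models the in vitro LR exchange assembling an insertion vector precursor:
#' the segment of the Intermediate Vector between attR1 and attR2 is replaced
#' by the adaptor payload (between its attL1/attL2), the segment between
#' attR3 and attR4 (the plasmid backbone) is replaced by the trap payload
#' (between attL3/attL4). All att sites in the product are relabelled
#' attB1..attB4; the two byproduct circles carry the displaced segments
#' joined to the donor backbones (attP1..attP4).
#'
#' @param intermediate Circular [AnnSeq-class] with attR1..attR4 sites.
#' @param adaptor Circular [AnnSeq-class] with attL1/attL2 flanking the
#'   payload.
#' @param trap Circular [AnnSeq-class] with attL3/attL4 flanking the payload.
#' @return list with `product` (circular AnnSeq, no attL/attR sites left) and
#'   `byproducts` (list of two circular AnnSeq).
#' @export
gatewayThreeWay <- function(intermediate, adaptor, trap) {
  stopifnot(intermediate@topology == "circular",
            adaptor@topology == "circular", trap@topology == "circular")
  for (st in paste0("attR", 1:4)) requireOneSite(intermediate, st,
                                                 "intermediate")
  for (st in c("attL1", "attL2")) requireOneSite(adaptor, st, "adaptor")
  for (st in c("attL3", "attL4")) requireOneSite(trap, st, "trap")

  iv <- rotateCirc(intermediate, siteFeatures(intermediate,
                                              "attR1")$start[1])
  r <- lapply(paste0("attR", 1:4), function(st)
    requireOneSite(iv, st, "intermediate"))
  names(r) <- paste0("attR", 1:4)
  ord <- vapply(r, function(s) s$start[1], numeric(1))
  if (is.unsorted(ord)) stop("attR1..attR4 are not in circular order on ",
                             "the intermediate vector")
  for (i in 1:4) {
    lname <- paste0("attL", i)
    src <- if (i <= 2) adaptor else trap
    ls <- siteFeatures(src, lname)
    if (!identical(ls$strand[1], r[[i]]$strand[1]))
      stop("orientation mismatch between attR", i, " and attL", i)
  }

  ad <- rotateCirc(adaptor, siteFeatures(adaptor, "attL1")$start[1])
  tp <- rotateCirc(trap, siteFeatures(trap, "attL3")$start[1])
  l1 <- siteFeatures(ad, "attL1"); l2 <- siteFeatures(ad, "attL2")
  l3 <- siteFeatures(tp, "attL3"); l4 <- siteFeatures(tp, "attL4")

  sitePiece <- function(x, row, newSub) {
    p <- annSubseq(x, row$start[1], row$end[1])
    p@features <- relabelSite(row, newSub)
    p@features$start <- 0L
    p@features$end <- as.integer(row$end[1] - row$start[1])
    p
  }

  adPayload <- circPiece(ad, l1$end[1], l2$start[1])
  tpPayload <- circPiece(tp, l3$end[1], l4$start[1])
  product <- annConcat(list(
    sitePiece(iv, r$attR1, "attB1"), adPayload,
    sitePiece(iv, r$attR2, "attB2"),
    circPiece(iv, r$attR2$end[1], r$attR3$start[1]),
    sitePiece(iv, r$attR3, "attB3"), tpPayload,
    sitePiece(iv, r$attR4, "attB4"),
    circPiece(iv, r$attR4$end[1], annLength(iv))),
    id = paste0(iv@id, "_gw"), topology = "circular")

  byp1 <- annConcat(list(
    sitePiece(ad, l1, "attP1"),
    circPiece(iv, r$attR1$end[1], r$attR2$start[1]),
    sitePiece(ad, l2, "attP2"),
    circPiece(ad, l2$end[1], annLength(ad))),
    id = "byproduct_adaptor", topology = "circular")
  byp2 <- annConcat(list(
    sitePiece(tp, l3, "attP3"),
    circPiece(iv, r$attR3$end[1], r$attR4$start[1]),
    sitePiece(tp, l4, "attP4"),
    circPiece(tp, l4$end[1], annLength(tp))),
    id = "byproduct_trap_backbone", topology = "circular")

  logRecombination("gateway_three_way",
                   inputs = c(intermediate@id, adaptor@id, trap@id),
                   product = product@id)
  list(product = product, byproducts = list(byp1, byp2))
}

#' Site-specific recombinase excision (Cre/loxP, Flp/FRT)
#'
#' Excises the segment between two directly repeated recombination sites,
#' retaining a single hybrid site in the main product. With zero or one site
#' the input is returned unchanged with a warning; more than two cognate
#' sites is an ambiguity error; inverted repeats are unsupported.
#'
#' @param x An [AnnSeq-class].
#' @param siteSubtype `"loxP"` or `"FRT"`.
#' @return list with `main` (input topology) and `excisedCircle` (circular
#'   excision product, or `NULL` for the no-op case).
#' @export
ssrExcise <- function(x, siteSubtype = c("loxP", "FRT")) {
  siteSubtype <- match.arg(siteSubtype)
  s <- siteFeatures(x, siteSubtype)
  if (nrow(s) < 2L) {
    tfLog("warn", "ssrExcise: ", nrow(s), " ", siteSubtype,
          " site(s) on '", x@id, "'; returning input unchanged")
    return(list(main = x, excisedCircle = NULL))
  }
  if (nrow(s) > 2L) stop("ambiguous substrate: ", nrow(s), " ",
                         siteSubtype, " sites on '", x@id, "'")
  if (s$strand[1] != s$strand[2])
    stop("unsupported orientation: inverted ", siteSubtype,
         " repeats on '", x@id, "'")
  cut <- exciseSegment(x, s$end[1], s$end[2])
  excised <- cut$excised
  excised@topology <- "circular"
  logRecombination(paste0("ssr_excise_", siteSubtype), inputs = x@id,
                   cutPoints = c(s$end[1], s$end[2]),
                   product = cut$remainder@id)
  list(main = cut$remainder, excisedCircle = excised)
}

#' Linearize a plasmid at a unique restriction motif
#'
#' Opens a circular sequence with a blunt cut in the middle of the single
#' occurrence of `motif` (GTTT/AAAC for PmeI). Vectors carrying extra sites
#' cannot be linearized intact and raise a multiple-site error.
#'
#' @param x Circular [AnnSeq-class].
#' @param motif Recognition motif (IUPAC), default the PmeI site.
#' @return Linear [AnnSeq-class] of identical length.
#' @export
linearizeVector <- function(x, motif = "GTTTAAAC") {
  if (x@topology != "circular") stop("linearize: input is not circular")
  hits <- scanMotif(x, motif)
  if (nrow(hits) == 0L) stop("no ", motif, " site on '", x@id, "'")
  if (nrow(hits) > 1L) stop("multiple ", motif, " sites on '", x@id,
                            "': cannot be linearized intact")
  cut <- hits$start[1] + nchar(motif) %/% 2L
  out <- rotateCirc(x, cut)
  f <- out@features
  if (any(f$wrap)) {
    tfLog("info", "linearize drops feature(s) spanning the cut: ",
          paste(f$label[f$wrap], collapse = ", "))
    f <- f[!f$wrap, , drop = FALSE]
  }
  out@features <- f
  out@topology <- "linear"
  logRecombination("linearize", inputs = x@id, cutPoints = cut,
                   product = out@id)
  out
}

armSeqOf <- function(x, label) {
  f <- x@features
  row <- f[f$kind == "homology_arm" & f$label == label, , drop = FALSE]
  if (!nrow(row)) stop("no '", label, "' homology feature on '", x@id, "'")
  row[1, , drop = FALSE]
}

#' Integrate a linearized insertion vector by single crossover with gap repair
#'
#' The vector (linearized within its homology region) inserts in one
#' crossover, duplicating the genomic homology around the trap cassette. The
#' critical-exon region deleted from the vector (the gap) is restored from
#' the chromosomal template, so the product carries it twice: once in the
#' repaired vector-derived copy (with the adaptor loxP at the repair
#' junction) and once in the chromosomal copy. Product length equals
#' allele + vector + gap.
#'
#' @param allele Target [AlleleMap-class] (wt, tm1a or tm1c; the gap-repair
#'   template region must be present).
#' @param vector Linear [AnnSeq-class] from [buildInsertionVector()].
#' @return The targeted [AlleleMap-class], state `"tm2"`.
#' @export
integrateInsertionVector <- function(allele, vector) {
  if (vector@topology != "linear")
    stop("must linearize: insertion vectors integrate as linear DNA")
  aseq <- allele@seq
  arm5 <- armSeqOf(vector, "arm5")
  arm3 <- armSeqOf(vector, "arm3")
  arm5seq <- substr(vector@residues, arm5$start + 1L, arm5$end)
  arm3seq <- substr(vector@residues, arm3$start + 1L, arm3$end)
  if (!grepl(arm5seq, aseq@residues, fixed = TRUE) ||
      !grepl(arm3seq, aseq@residues, fixed = TRUE))
    stop("no integration: vector homology does not match the allele")
  g <- aseq@features
  g <- g[g$label == "gap_region", , drop = FALSE]
  if (!nrow(g))
    stop("no integration: allele lacks the gap-repair template region")
  g0 <- g$start[1]
  gapSeq <- annSubseq(aseq, g$start[1], g$end[1])
  # Reassemble the insert: vector downstream-of-cut, vector upstream-of-cut
  # (reconstituting the PmeI half-sites), the repaired gap, then the cassette
  # side of the vector through the duplicated arm.
  p1 <- arm3$start[1]
  p2 <- arm5$end[1]
  block <- annConcat(list(annSubseq(vector, p2, annLength(vector)),
                          annSubseq(vector, 0L, p1),
                          gapSeq,
                          annSubseq(vector, p1, p2)),
                     id = "insert")
  product <- annConcat(list(annSubseq(aseq, 0L, g0), block,
                            annSubseq(aseq, g0, annLength(aseq))),
                       id = paste0(aseq@id, "_tm2"),
                       topology = aseq@topology)
  logRecombination("integrate_insertion_vector",
                   inputs = c(aseq@id, vector@id), product = product@id)
  AlleleMap(product, state = "tm2",
            provenance = c(allele@provenance,
                           sprintf("integrate(%s) into %s", vector@id,
                                   allele@state)))
}

#' Random (non-homologous) integration of a vector
#'
#' Blunt end-to-end insertion at a seeded-random position of a carrier
#' sequence, without gap repair: the gap region (and hence the ex5 primer
#' site) is absent from the inserted copy, which is what makes random
#' integrants PCR-negative in the ex5/hygro_1R screen.
#'
#' @param genomeFlank Carrier [AnnSeq-class].
#' @param vector Linear [AnnSeq-class].
#' @param seed Integer seed (same seed, same insertion offset).
#' @return The carrier with the vector inserted.
#' @export
randomIntegrate <- function(genomeFlank, vector, seed) {
  pos <- withSeed(seed, sample.int(annLength(genomeFlank) + 1L, 1L) - 1L)
  out <- annInsert(genomeFlank, pos, vector,
                   id = paste0(genomeFlank@id, "_randint"))
  logRecombination("random_integrate", inputs = c(genomeFlank@id,
                                                  vector@id),
                   cutPoints = pos, product = out@id)
  out
}

# JSON-lines event log, kept in a session option so CLI runs can persist it.
logRecombination <- function(op, inputs, product, cutPoints = NULL) {
  entry <- list(op = op, inputs = as.character(inputs),
                product = product)
  if (!is.null(cutPoints)) entry$cut_points <- as.integer(cutPoints)
  log <- getOption("trapforge.eventlog", list())
  log[[length(log) + 1L]] <- entry
  options(trapforge.eventlog = log)
  tfLog("info", op, ": ", paste(inputs, collapse = " + "), " -> ", product)
  invisible(entry)
}

#' Retrieve and clear the recombination event log
#'
#' @param clear Reset the log after reading?
#' @return list of event records (operation, inputs, cut points, product id).
#' @export
recombinationLog <- function(clear = FALSE) {
  log <- getOption("trapforge.eventlog", list())
  if (clear) options(trapforge.eventlog = list())
  log
}
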