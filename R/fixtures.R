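# Seeded synthetic-data generators: gene loci with a designated critical
# exon, trap cassette libraries, adaptor and Intermediate Vector plasmids,
# cell lines and screening tally tables. Every generator is deterministic
# given its seed and produces objects whose ground truth (planted PmeI
# sites, constructed reading-frame phase, essentiality) is known to tests.

LOXP_SEQ <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"   # canonical 34 nt loxP
FRT_SEQ  <- "GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC"   # minimal 34 nt FRT
PMEI_MOTIF <- "GTTTAAAC"

siteSeq <- function(subtype) {
  switch(subtype,
         loxP = LOXP_SEQ,
         FRT = FRT_SEQ,
         # 25 nt placeholder cores for att sites (sequences are not part of
         # the recombination contract, which is typed-feature based)
         withSeed(sum(utf8ToInt(subtype)) * 7919L, guardedDNA(25L)))
}

# A recombination site as a standalone AnnSeq block.
siteBlock <- function(subtype, label = subtype) {
  s <- siteSeq(subtype)
  AnnSeq(s, id = label,
         features = annFeature(label, "recomb_site", 0L, nchar(s),
                               site_subtype = subtype))
}

markerBlock <- function(name, len, seed) {
  AnnSeq(withSeed(seed, guardedDNA(len)), id = name,
         features = annFeature(name, "marker", 0L, len))
}

originBlock <- function(len = 400L, seed = 11L) {
  AnnSeq(withSeed(seed, guardedDNA(len)), id = "ori",
         features = annFeature("ori", "origin", 0L, len))
}

plainBlock <- function(len, seed) {
  AnnSeq(withSeed(seed, guardedDNA(len)), id = "spacer")
}

#' Hygromycin-GFP trap cassette library in three reading frames
#'
#' Builds the three-frame targeted-trapping payload: splice acceptor, a
#' frame-adapting pad, a single ORF carrying 2A-hygromycin-2A-GFP, a stop and
#' polyA, followed by the plasmid origin and kanR that become the backbone of
#' the assembled vector. The ORF begins with a sequence that is stop-free
#' in the design frame and contains stop codons in both shifted frames, so a
#' mis-chosen cassette yields a premature stop immediately after the splice
#' junction.
#'
#' @param seed Integer seed for the shared cassette body.
#' @return list of three [TrapCassette-class], frame phases 0, 1, 2.
#' @export
makeTrapCassetteLibrary <- function(seed = 9001L) {
  body <- withSeed(seed, list(
    sa = guardedDNA(150L),
    p2a_1 = randomORF(20L), hyg = randomORF(240L),
    p2a_2 = randomORF(20L), gfp = randomORF(200L),
    pa = guardedDNA(250L), spacer = guardedDNA(100L)
  ))
  lapply(0:2, function(phase) {
    pad <- strrep("C", (3L - phase) %% 3L)
    orf <- scrubMotif(paste0("CTAACTAGC", body$p2a_1, body$hyg,
                             body$p2a_2, body$gfp, "TAA"))
    codingStart <- 150L
    codingEnd <- codingStart + nchar(pad) + nchar(orf)
    paStart <- codingEnd
    hygOff <- codingStart + nchar(pad) + 9L + nchar(body$p2a_1) + 400L
    feats <- rbind(
      annFeature("hygGFP_trap", "cassette", 0L,
                 paStart + 250L, marker_name = "hygro_gfp", trap = TRUE,
                 frame_phase = as.integer(phase),
                 coding_start = codingStart, coding_end = codingEnd),
      annFeature("SA", "splice_acceptor", 0L, 150L),
      annFeature("hygGFP_orf", "cds_segment", codingStart, codingEnd),
      annFeature("hygro_1R_site", "primer_site", hygOff, hygOff + 20L,
                 strand = "-"),
      annFeature("pA", "polyA", paStart, paStart + 250L))
    payload <- paste0(body$sa, pad, orf, body$pa, body$spacer)
    ori <- originBlock(seed = seed + 1L)
    kan <- markerBlock("kanR", 800L, seed + 2L)
    seq <- annConcat(list(AnnSeq(payload, id = "trap_payload",
                                 features = feats), ori, kan),
                     id = sprintf("hygGFP_frame%d", phase))
    new("TrapCassette", framePhase = as.integer(phase),
        markerName = "hygro_gfp", seq = seq)
  })
}

#' Beta-geo (lacZ-neo) trapping cassette
#'
#' The promoterless splice-trap of the knockout-first allele: splice
#' acceptor, lacZ-neo fusion ORF, polyA and stuffer, 5.0 kb in total.
#' Reporting from this cassette is modelled frame-independent.
#'
#' @param seed Integer seed.
#' @return A [TrapCassette-class], marker `"betageo"`.
#' @export
makeBetageoCassette <- function(seed = 9101L) {
  parts <- withSeed(seed, list(
    sa = guardedDNA(150L),
    orf = scrubMotif(paste0("CTAACTAGC", randomORF(996L), "TAA")),
    pa = guardedDNA(250L)))
  used <- 150L + nchar(parts$orf) + 250L
  stuffer <- withSeed(seed + 1L, guardedDNA(5000L - used))
  larOff <- 150L + 800L
  feats <- rbind(
    annFeature("betageo_trap", "cassette", 0L, 150L + nchar(parts$orf) +
                 250L, marker_name = "betageo", trap = TRUE,
               coding_start = 150L, coding_end = 150L + nchar(parts$orf)),
    annFeature("SA", "splice_acceptor", 0L, 150L),
    annFeature("betageo_orf", "cds_segment", 150L,
               150L + nchar(parts$orf)),
    annFeature("LAR_3_site", "primer_site", larOff, larOff + 20L,
               strand = "-"),
    annFeature("pA", "polyA", 150L + nchar(parts$orf),
               150L + nchar(parts$orf) + 250L))
  seq <- annConcat(list(AnnSeq(paste0(parts$sa, parts$orf, parts$pa),
                               id = "betageo_payload", features = feats),
                        AnnSeq(stuffer, id = "stuffer")),
                   id = "betageo_cassette")
  new("TrapCassette", framePhase = NA_integer_, markerName = "betageo",
      seq = seq)
}

#' Adaptor plasmid: PmeI linearization site plus one loxP
#'
#' Circular donor whose attL1/attL2 payload introduces the rare PmeI site
#' and the single loxP that ends up upstream of the critical exon in the
#' assembled insertion vector.
#'
#' @param seed Integer seed.
#' @return Circular [AnnSeq-class].
#' @export
makeAdaptorPlasmid <- function(seed = 9201L) {
  pad1 <- plainBlock(154L, seed)
  pmei <- AnnSeq(PMEI_MOTIF, id = "PmeI",
                 features = annFeature("PmeI", "restriction_site", 0L, 8L,
                                       site_subtype = "PmeI"))
  pad2 <- plainBlock(154L, seed + 1L)
  annConcat(list(siteBlock("attL1"), pad1, pmei, pad2, siteBlock("loxP"),
                 siteBlock("attL2"), originBlock(seed = seed + 2L),
                 markerBlock("natR", 600L, seed + 3L),
                 plainBlock(200L, seed + 4L)),
            id = "adaptor_RloxP", topology = "circular")
}

#' Trap-cassette donor plasmid (one reading frame)
#'
#' Wraps a [TrapCassette-class] payload in attL3/attL4 plus a donor backbone
#' carrying its own origin, kanR and cat markers.
#'
#' @param cassette A [TrapCassette-class].
#' @param seed Integer seed for the backbone.
#' @return Circular [AnnSeq-class].
#' @export
makeTrapDonorPlasmid <- function(cassette, seed = 9301L) {
  annConcat(list(siteBlock("attL3"), cassette@seq, siteBlock("attL4"),
                 originBlock(seed = seed), markerBlock("kanR", 800L,
                                                       seed + 1L),
                 markerBlock("cat", 650L, seed + 2L),
                 plainBlock(150L, seed + 3L)),
            id = sprintf("trap_donor_frame%s", cassette@framePhase),
            topology = "circular")
}

## ---- gene locus -------------------------------------------------------

#' Generate a synthetic expressed gene locus
#'
#' Builds a multi-exon locus with a designated critical exon, homology-arm
#' landmarks (G5/U3/D5/G3), gf3 and ex5 primer sites, and a CDS that is
#' stop-free in frame 0 only. The critical exon length is not a multiple of
#' three, so its deletion frameshifts the message. Intron sizes around the
#' critical exon are fixed so that homology arms and the gap land in the
#' size classes the genotyping assays expect (~3.7 kb arm5, ~1.6 kb gap,
#' ~4.7 kb arm3); other exons and introns draw from the given ranges.
#'
#' @param seed Integer seed (mandatory; generation is deterministic).
#' @param nExons Number of exons (>= 5 for the canonical layout).
#' @param criticalExonIndex Index of the critical exon (strictly internal,
#'   with at least one exon on either side inside the homology).
#' @param phaseTarget Optional end phase (0/1/2) to engineer at the most-3'
#'   exon inside the homology region.
#' @param expressionPctTrfr ES-cell expression, percent of Trfr.
#' @param essential Ground-truth essentiality flag.
#' @param exonLenRange,intronLenRange Ranges for unconstrained exons/introns.
#' @param geneID Gene name.
#' @return list with `gene` ([GeneModel-class]), `locus` ([AnnSeq-class],
#'   the wild-type allele sequence) and `landmarks` (g5/u3/d5/g3 offsets).
#' @export
makeGeneLocus <- function(seed, nExons = 5L, criticalExonIndex = 3L,
                          phaseTarget = NULL, expressionPctTrfr = 10,
                          essential = FALSE, exonLenRange = c(110L, 150L),
                          intronLenRange = c(500L, 900L),
                          geneID = sprintf("synth%d", seed)) {
  if (nExons < 5L) stop("generation error: canonical layout needs >= 5 ",
                        "exons")
  ce <- as.integer(criticalExonIndex)
  if (ce < 3L || ce > nExons - 2L)
    stop("generation error: critical exon must be internal with flanking ",
         "exons inside the homology")
  withSeed(seed, {
    exonLen <- integer(nExons)
    exonLen[1] <- 120L
    exonLen[nExons] <- 200L
    mid <- setdiff(seq_len(nExons), c(1L, nExons))
    exonLen[mid] <- sample(seq(exonLenRange[1], exonLenRange[2]),
                           length(mid), replace = TRUE)
    # critical exon: force length = 1 mod 3 so deletion frameshifts
    exonLen[ce] <- exonLen[ce] + (1L - exonLen[ce] %% 3L) %% 3L
    # coding lengths per exon
    cdsLen <- exonLen
    cdsLen[1] <- 100L
    # engineer end phase at the frame exon (most 3' exon inside homology)
    frameExon <- ce + 1L
    if (!is.null(phaseTarget)) {
      cumToFrame <- sum(cdsLen[seq_len(frameExon)])
      exonLen[frameExon] <- exonLen[frameExon] +
        (as.integer(phaseTarget) - cumToFrame) %% 3L
      cdsLen[frameExon] <- exonLen[frameExon]
    }
    cumLast <- sum(cdsLen[seq_len(nExons - 1L)])
    lastCore <- 90L - (cumLast + 90L) %% 3L
    cdsLen[nExons] <- lastCore + 3L        # includes the stop codon
    totalCds <- sum(cdsLen)
    stopifnot(totalCds %% 3L == 0L)

    intronLen <- integer(nExons - 1L)
    other <- setdiff(seq_len(nExons - 1L), c(1L, ce - 1L, ce, ce + 1L))
    if (length(other))
      intronLen[other] <- sample(seq(intronLenRange[1], intronLenRange[2]),
                                 length(other), replace = TRUE)
    intronLen[1L] <- 2000L        # G5 at offset 1000
    intronLen[ce - 1L] <- 3600L   # U3 1000 nt upstream of the critical exon
    intronLen[ce] <- 900L         # D5 450 nt downstream of it
    intronLen[ce + 1L] <- 4400L   # G3 at offset 4200

    # CDS residues: ATG, a 9 nt block that plants stops in shifted frames,
    # random sense codons, terminal TAA
    coding <- paste0("ATG", "CTAACTAGC", randomORF((totalCds - 15L) %/% 3L),
                     "TAA")
    stopifnot(nchar(coding) == totalCds)

    # intermediate pieces are left unscrubbed; one final pass over the
    # assembled locus removes every spurious motif, including any formed at
    # piece junctions
    flank5 <- randomDNA(450L)
    flank3 <- randomDNA(350L)
    utr5 <- randomDNA(20L)
    utr3 <- randomDNA(exonLen[nExons] - cdsLen[nExons])

    feats <- list(annFeature("promoter", "promoter", 330L, 390L))
    res <- flank5
    pos <- nchar(flank5)
    exTab <- data.frame(start = integer(), end = integer())
    cdTab <- data.frame(start = integer(), end = integer())
    cdsUsed <- 0L
    exonEnds <- integer(nExons)
    for (i in seq_len(nExons)) {
      exStart <- pos
      body <- substr(coding, cdsUsed + 1L, cdsUsed + cdsLen[i])
      if (i == 1L) {
        exRes <- paste0(utr5, body)
        cdStart <- exStart + 20L
      } else if (i == nExons) {
        exRes <- paste0(body, utr3)
        cdStart <- exStart
      } else {
        exRes <- body
        cdStart <- exStart
      }
      cdsUsed <- cdsUsed + cdsLen[i]
      stopifnot(nchar(exRes) == exonLen[i])
      res <- paste0(res, exRes)
      kind <- if (i == ce) "critical_exon" else "exon"
      feats[[length(feats) + 1L]] <-
        annFeature(sprintf("exon%d", i), kind, exStart, exStart +
                     exonLen[i])
      feats[[length(feats) + 1L]] <-
        annFeature(sprintf("cds%d", i), "cds_segment", cdStart,
                   cdStart + cdsLen[i])
      exTab <- rbind(exTab, data.frame(start = exStart,
                                       end = exStart + exonLen[i]))
      cdTab <- rbind(cdTab, data.frame(start = cdStart,
                                       end = cdStart + cdsLen[i]))
      pos <- pos + exonLen[i]
      exonEnds[i] <- pos
      if (i < nExons) {
        res <- paste0(res, randomDNA(intronLen[i]))
        pos <- pos + intronLen[i]
      }
    }
    res <- paste0(res, flank3)
    # final pass: no spurious PmeI anywhere in the assembled locus (the
    # substituted base is a C, which cannot create an in-frame stop codon)
    res <- scrubMotif(res)

    g5 <- exonEnds[1L] + 1000L
    u3 <- exonEnds[ce - 1L] + intronLen[ce - 1L] - 1000L
    d5 <- exonEnds[ce] + 450L
    g3 <- exonEnds[ce + 1L] + 4200L
    ceStart <- exTab$start[ce]
    feats <- c(feats, list(
      annFeature("arm5", "homology_arm", g5, u3),
      annFeature("gap_region", "homology_arm", u3, d5),
      annFeature("arm3", "homology_arm", d5, g3),
      annFeature("gf3", "primer_site", exonEnds[1L] + 700L,
                 exonEnds[1L] + 720L),
      annFeature("ex5", "primer_site", ceStart + 10L, ceStart + 30L)))

    locus <- AnnSeq(res, id = geneID,
                    features = sortFeatures(do.call(rbind, feats)))
    gene <- GeneModel(geneID, strand = "+", exons = exTab, cds = cdTab,
                      expressionPctTrfr = expressionPctTrfr,
                      essentialInES = essential)
    list(gene = gene, locus = locus,
         landmarks = list(g5 = g5, u3 = u3, d5 = d5, g3 = g3))
  })
}

## ---- intermediate vector ----------------------------------------------

#' Assemble an IKMC-style Intermediate Vector for a synthetic locus
#'
#' Circular plasmid: genomic homology G5..G3 with the attR1/attR2 exchange
#' pair replacing the intron segment at U3, the rpsL counter-selection
#' marker and a loxP inserted in the critical-exon region, and an
#' attR3/backbone/attR4 cassette. Optionally plants extra PmeI sites in the
#' homology arms of the locus (returned alongside, so genome and plasmid
#' agree) to emulate designs that cannot be linearized intact.
#'
#' @param fixture Output of [makeGeneLocus()].
#' @param extraPmeI Number of extra PmeI sites to plant in the arms.
#' @param seed Integer seed for planting positions.
#' @return list with `spec` ([IVSpec-class]), `plasmid` (circular
#'   [AnnSeq-class]), `locus` (the possibly modified genome) and
#'   `plantedAt` (locus offsets of planted sites).
#' @export
makeIntermediateVector <- function(fixture, extraPmeI = 0L, seed = 1L) {
  locus <- fixture$locus
  lm <- fixture$landmarks
  plantedAt <- integer(0)
  if (extraPmeI > 0L) {
    # plant inside arm interiors, away from exon/primer features
    slots <- withSeed(seed, sample(c(
      seq(lm$g5 + 50L, lm$u3 - 550L, by = 10L),
      seq(lm$d5 + 600L, lm$g3 - 50L, by = 10L)), extraPmeI))
    res <- locus@residues
    for (p in slots) substr(res, p + 1L, p + 8L) <- PMEI_MOTIF
    locus@residues <- res
    plantedAt <- sort(as.integer(slots))
  }
  spec <- new("IVSpec", geneID = fixture$gene@geneID,
              g5 = as.integer(lm$g5), u3 = as.integer(lm$u3),
              d5 = as.integer(lm$d5), g3 = as.integer(lm$g3))
  arm5 <- annSubseq(locus, lm$g5, lm$u3)
  gap <- annSubseq(locus, lm$u3, lm$d5)
  arm3 <- annSubseq(locus, lm$d5, lm$g3)
  plasmid <- annConcat(list(
    arm5, siteBlock("attR1"), plainBlock(300L, seed + 10L),
    siteBlock("attR2"), gap, markerBlock("rpsL", 500L, seed + 11L),
    siteBlock("loxP"), arm3, siteBlock("attR3"),
    originBlock(seed = seed + 12L), markerBlock("bla", 800L, seed + 13L),
    markerBlock("zeoR", 400L, seed + 14L), plainBlock(200L, seed + 15L),
    siteBlock("attR4")),
    id = sprintf("IV_%s", fixture$gene@geneID), topology = "circular")
  sz <- annLength(plasmid)
  if (abs(sz - 15000) / 15000 > 0.30)
    tfLog("warn", "Intermediate Vector size ", sz,
          " bp outside the ~15 kb QC window")
  list(spec = spec, plasmid = plasmid, locus = locus,
       plantedAt = plantedAt)
}

## ---- bundles, cell lines, screen tables --------------------------------

#' One-stop fixture bundle for a target gene
#'
#' Generates the locus, cassette library, adaptor and trap donor plasmids,
#' Intermediate Vector and the final linearized insertion vector, all from
#' one seed. Used by tests and examples.
#'
#' @param seed Integer seed.
#' @param ... Passed to [makeGeneLocus()].
#' @return list with components `gene`, `locus`, `landmarks`, `spec`,
#'   `iv`, `adaptor`, `cassettes`, `betageo`, `vector` (linear AnnSeq) and
#'   `buildReport`.
#' @export
makeTargetFixture <- function(seed, ...) {
  fx <- makeGeneLocus(seed, ...)
  iv <- makeIntermediateVector(fx, seed = seed + 1L)
  adaptor <- makeAdaptorPlasmid(seed + 2L)
  cassettes <- makeTrapCassetteLibrary(seed + 3L)
  built <- buildInsertionVector(iv$spec, fx$locus, fx$gene, iv$plasmid,
                                adaptor, cassettes)
  c(fx, list(spec = iv$spec, iv = iv$plasmid, adaptor = adaptor,
             cassettes = cassettes, betageo = makeBetageoCassette(seed +
                                                                    4L),
             vector = built$vector, buildReport = built$report))
}

reachableStatePair <- function(a, b) {
  s <- c(a, b)
  if (!all(s %in% ALLELE_STATES)) return(FALSE)
  # any pair with a wt allele is reachable (including wt/wt); otherwise the
  # only routes to double mutants run through exactly one tm2 allele
  any(s == "wt") || sum(s == "tm2") == 1L
}

#' Construct a cell line in a given pair of allele states
#'
#' Alleles are built by running the actual event chain (knockout-first
#' construction, Flp/Cre conversion, insertion-vector targeting), so every
#' requested state carries the sequence structure the state machine
#' produces. Unreachable pairs (e.g. tm1d/tm1d, which no in-scope protocol
#' creates) are a construction error.
#'
#' @param fixture A [makeTargetFixture()] bundle.
#' @param states Character pair of allele states (e.g. `c("tm1a", "wt")`).
#' @param transgenes Character vector (e.g. `"CreERT2"`).
#' @param leakRate,escaperRate Stochastic Cre parameters in `[0, 1]`.
#' @param seed Integer seed for the line.
#' @return A [CellLine-class].
#' @export
makeCellLine <- function(fixture, states, transgenes = character(),
                         leakRate = 0, escaperRate = 0, seed = 1L) {
  stopifnot(length(states) == 2L)
  if (!reachableStatePair(states[1], states[2]))
    stop("construction error: allele pair ", states[1], "/", states[2],
         " is not reachable by any in-scope protocol")
  mk <- function(state) buildAllele(fixture, state)
  new("CellLine", gene = fixture$gene, alleleA = mk(states[1]),
      alleleB = mk(states[2]), transgenes = transgenes, extras = list(),
      leakRate = leakRate, escaperRate = escaperRate,
      seed = as.integer(seed))
}

#' Screening tally table with known ground truth
#'
#' Draws per-row positive-colony counts binomially from per-gene targeting
#' probabilities. Essential genes are forced to zero positives in their
#' heterozygous (tm1a/+) rows while their wild-type control rows draw
#' normally, reproducing the operational essentiality signal.
#'
#' @param truth data.frame with columns `gene`, `p_target` (probability of a
#'   screened colony being targeted) and `essential` (logical).
#' @param coloniesPerExperiment Colonies screened per electroporation.
#' @param seed Integer seed.
#' @return data.frame with columns `gene`, `line_genotype`,
#'   `colonies_screened`, `colonies_positive`; the input truth is attached
#'   as attribute `"truth"`.
#' @export
makeScreenTable <- function(truth, coloniesPerExperiment = 24L, seed = 1L) {
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      n <- coloniesPerExperiment
      wtPos <- rbinom(1L, n, truth$p_target[i])
      hetPos <- if (truth$essential[i]) 0L else rbinom(1L, n,
                                                       truth$p_target[i])
      data.frame(gene = rep(truth$gene[i], 2L),
                 line_genotype = c("wt", "tm1a/+"),
                 colonies_screened = c(n, n),
                 colonies_positive = c(wtPos, hetPos))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- truth
    out
  })
}

#' Panel of vector designs with planted PmeI ground truth
#'
#' Generates `n` synthetic loci and Intermediate Vector specs; each design
#' independently receives one extra PmeI site in its homology arms with
#' probability `plantProb`. The planted indicator is the ground truth that
#' [screenVectorPanel()] must recover exactly.
#'
#' @param n Panel size.
#' @param plantProb Per-design planting probability.
#' @param seed Integer seed.
#' @return list of per-design lists (`spec`, `locus`, `gene`, `planted`).
#' @export
makeVectorPanel <- function(n, plantProb = 0.115, seed = 1L) {
  planted <- withSeed(seed, runif(n) < plantProb)
  lapply(seq_len(n), function(i) {
    fx <- makeGeneLocus(seed + 1000L + i)
    iv <- makeIntermediateVector(fx, extraPmeI = if (planted[i]) 1L else 0L,
                                 seed = seed + 2000L + i)
    list(spec = iv$spec, locus = iv$locus, gene = fx$gene,
         planted = planted[i])
  })
}
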