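# Allele construction, the tm-state machine, expression/selection outcome
# logic, truncation prediction and multi-step workflow simulation.
#
# State transitions (direct-repeat excisions, one hybrid site retained):
#   tm1a --Flp--> tm1c --Cre--> tm1d      (conditional route)
#   tm1a --Cre--> tm1b --Flp--> tm1d      (commutes residue-identically)
#   wt  --insertion vector--> tm2         (second-allele targeted trap)

# Universal vector-derived primer tags: R1_amp_F2 binds between the 3' FRT
# and the 5' loxP of the knockout-first cassette region (survives both Flp
# and Cre); LR binds just 3' of the 3' loxP. Both are absent from wild-type
# loci and from pI_hygGFP-derived sequence.
tagR1F2 <- function() {
  s <- withSeed(77001L, guardedDNA(40L))
  AnnSeq(s, id = "R1F2_tag",
         features = annFeature("R1_amp_F2_site", "primer_site", 10L, 30L))
}

tagLR <- function() {
  s <- withSeed(77002L, guardedDNA(50L))
  AnnSeq(s, id = "LR_tag",
         features = annFeature("LR_site", "primer_site", 15L, 35L,
                               strand = "-"))
}

#' Genotype shorthand for a cell line
#'
#' Renders the allele-state pair in the conventional shorthand, wild type as
#' `+` and the non-wild-type allele first (e.g. `"tm1a/tm2"`, `"tm1d/+"`).
#'
#' @param cells A [CellLine-class] (or a character pair of states).
#' @return Character scalar.
#' @export
genotypeString <- function(cells) {
  s <- if (is(cells, "CellLine")) c(cells@alleleA@state, cells@alleleB@state)
       else cells
  s <- s[order(match(s, c(setdiff(ALLELE_STATES, "wt"), "wt")))]
  paste(ifelse(s == "wt", "+", s), collapse = "/")
}

#' Construct the knockout-first (tm1a) allele for a fixture locus
#'
#' Inserts the FRT-flanked beta-geo trapping cassette (with its own splice
#' acceptor and polyA) in the intron upstream of the critical exon, followed
#' by the loxP pair flanking the critical-exon region, reproducing the
#' knockout-first architecture: FRT - betageo - FRT - loxP ... critical exon
#' ... loxP.
#'
#' @param fixture A [makeTargetFixture()] bundle (or any list with `locus`,
#'   `landmarks`, `betageo`).
#' @return An [AlleleMap-class] in state `"tm1a"`.
#' @export
buildTm1a <- function(fixture) {
  locus <- fixture$locus
  lm <- fixture$landmarks
  if (is.null(lm)) stop("construction error: fixture carries no homology ",
                        "landmarks (no qualifying intron)")
  u3block <- annConcat(list(siteBlock("FRT"), fixture$betageo@seq,
                            siteBlock("FRT"), tagR1F2(),
                            siteBlock("loxP")), id = "tm1a_cassette")
  d5block <- annConcat(list(siteBlock("loxP"), tagLR()), id = "tm1a_3p")
  s1 <- annInsert(locus, lm$u3, u3block)
  s2 <- annInsert(s1, lm$d5 + annLength(u3block), d5block,
                  id = paste0(locus@id, "_tm1a"))
  AlleleMap(s2, "tm1a", provenance = "build_tm1a")
}

TRANSITIONS <- list(tm1a = c(Flp = "tm1c", Cre = "tm1b"),
                    tm1b = c(Flp = "tm1d"),
                    tm1c = c(Cre = "tm1d"))

#' Apply a site-specific recombinase to an allele
#'
#' Delegates to [ssrExcise()] (loxP for Cre, FRT for Flp) and updates the
#' symbolic state by the transition table. Alleles without two cognate sites
#' are returned unchanged with a warning.
#'
#' @param allele An [AlleleMap-class].
#' @param enzyme `"Cre"` or `"Flp"`.
#' @return The converted [AlleleMap-class].
#' @export
applyRecombinase <- function(allele, enzyme = c("Cre", "Flp")) {
  enzyme <- match.arg(enzyme)
  subtype <- if (enzyme == "Cre") "loxP" else "FRT"
  res <- ssrExcise(allele@seq, subtype)
  if (is.null(res$excisedCircle)) return(allele)
  newState <- TRANSITIONS[[allele@state]][[enzyme]]
  if (is.null(newState))
    stop("no transition defined for ", enzyme, " on state ", allele@state)
  AlleleMap(res$main, newState,
            provenance = c(allele@provenance,
                           sprintf("%s(%s -> %s)", enzyme, allele@state,
                                   newState)))
}

alleleCensus <- function(allele) {
  x <- allele@seq
  f <- x@features
  cassOf <- function(name) {
    sum(f$kind == "cassette" &
          vapply(f$quals, function(q) identical(q$marker_name, name),
                 logical(1)))
  }
  list(frt = nrow(siteFeatures(x, "FRT")),
       loxp = nrow(siteFeatures(x, "loxP")),
       betageo = cassOf("betageo"),
       hyg = cassOf("hygro_gfp"),
       ce = sum(f$kind == "critical_exon"),
       ex5 = sum(f$label == "ex5"),
       arm5 = sum(f$label == "arm5"))
}

CENSUS <- list(
  wt   = list(frt = 0, loxp = 0, betageo = 0, hyg = 0, ce = 1, ex5 = 1,
              arm5 = 1),
  tm1a = list(frt = 2, loxp = 2, betageo = 1, hyg = 0, ce = 1, ex5 = 1,
              arm5 = 1),
  tm1b = list(frt = 2, loxp = 1, betageo = 1, hyg = 0, ce = 0, ex5 = 0,
              arm5 = 1),
  tm1c = list(frt = 1, loxp = 2, betageo = 0, hyg = 0, ce = 1, ex5 = 1,
              arm5 = 1),
  tm1d = list(frt = 1, loxp = 1, betageo = 0, hyg = 0, ce = 0, ex5 = 0,
              arm5 = 1),
  tm2  = list(frt = 0, loxp = 1, betageo = 0, hyg = 1, ce = 2, ex5 = 2,
              arm5 = 2))

#' Validate an allele's state-specific feature census
#'
#' Checks that the allele carries exactly the recombination sites, trap
#' cassettes, critical-exon copies and gap-derived primer sites its symbolic
#' state requires (e.g. tm1c: one FRT, loxP-critical exon-loxP; tm2: two
#' homology copies flanking the hygro-GFP cassette with the ex5 site twice).
#'
#' @param allele An [AlleleMap-class].
#' @param state State to validate against (defaults to the allele's own).
#' @return `TRUE` invisibly, or an error describing the census mismatch.
#' @export
validateAllele <- function(allele, state = allele@state) {
  want <- CENSUS[[state]]
  if (is.null(want)) stop("unknown allele state: ", state)
  have <- alleleCensus(allele)
  for (k in names(want)) {
    if (have[[k]] != want[[k]])
      stop("census mismatch for ", state, ": ", k, " = ", have[[k]],
           ", expected ", want[[k]])
  }
  invisible(TRUE)
}

#' End phase of the most 3' exon inside a homology region
#'
#' Cumulative coding nucleotides from the CDS start through the end of the
#' most 3' exon lying wholly inside the homology interval, modulo 3. This is
#' the quantity that selects the trap cassette reading frame.
#'
#' @param gene A [GeneModel-class].
#' @param homology Numeric pair (0-based half-open locus interval).
#' @return 0, 1 or 2.
#' @export
endPhase <- function(gene, homology) {
  ex <- gene@exons; cd <- gene@cds
  inside <- which(ex$start >= homology[1] & ex$end <= homology[2])
  hasCds <- vapply(seq_len(nrow(ex)), function(i)
    any(cd$start >= ex$start[i] & cd$end <= ex$end[i]), logical(1))
  inside <- inside[hasCds[inside]]
  if (!length(inside)) stop("no coding exon within the homology region")
  k <- max(inside)
  cum <- sum(pmax(0L, pmin(cd$end, ex$end[k]) - cd$start)[cd$start <
                                                            ex$end[k]])
  as.integer(cum %% 3L)
}

## ---- expression and selection outcomes ---------------------------------

#' Expression outcome of one allele
#'
#' Walks the transcript from the promoter: the first splice-acceptor trap
#' cassette with a polyA terminates the message. Beta-geo reporters (lacZ,
#' neo) require gene expression at or above the trapping threshold and are
#' modelled frame-independent; hygro/GFP additionally require the cassette
#' frame phase to match the end phase of the last spliced exon. Full-length
#' protein requires an untrapped transcript with the critical exon (and all
#' CDS segments) present.
#'
#' @param allele An [AlleleMap-class].
#' @param gene The [GeneModel-class] (expression level, CDS layout).
#' @param threshold Minimum expression for trap-marker survival, percent of
#'   the Trfr reference (default 1).
#' @return list with `fullProtein`, `markers` (subset of lacZ, neo, hygro,
#'   GFP), `trapped`, `upstreamCodingNt` and `truncation` (see
#'   [predictTruncation()]; `NULL` when untrapped).
#' @export
expressionOutcome <- function(allele, gene, threshold = 1) {
  x <- allele@seq
  mrna <- spliceTranscript(x, strand = gene@strand)
  trapped <- isTRUE(attr(mrna, "trapped"))
  f <- mrna@features
  expressed <- gene@expressionPctTrfr >= threshold
  markers <- character()
  truncation <- NULL
  if (trapped) {
    cass <- f[f$kind == "cassette", , drop = FALSE][1, , drop = FALSE]
    upstream <- f[f$kind == "cds_segment" & f$end <= cass$start, ,
                  drop = FALSE]
    upNt <- sum(upstream$end - upstream$start)
    marker <- featQual(cass, "marker_name")
    if (identical(marker, "betageo")) {
      if (expressed) markers <- c("lacZ", "neo")
    } else if (identical(marker, "hygro_gfp")) {
      phase <- featQual(cass, "frame_phase")
      if (expressed && identical(as.integer(phase),
                                 as.integer(upNt %% 3L)))
        markers <- c("hygro", "GFP")
    }
    truncation <- list(aaLength = upNt %/% 3L,
                       approxMassKda = truncationMass(upNt %/% 3L))
    fullProtein <- FALSE
  } else {
    upNt <- sum(f$end - f$start)
    nCds <- sum(f$kind == "cds_segment")
    fullProtein <- sum(f$kind == "critical_exon") >= 1L &&
      nCds == nrow(gene@cds)
  }
  list(fullProtein = fullProtein, markers = markers, trapped = trapped,
       upstreamCodingNt = if (trapped) upNt else NA_integer_,
       truncation = truncation)
}

#' Approximate mass of a truncation product from its residue count
#'
#' Uses the 110.5 Da average residue mass, reported in kDa at nearest
#' integer (353 aa -> 39 kDa; 97 aa -> 11 kDa).
#'
#' @param aaLength Residue count.
#' @return Integer kDa.
#' @export
truncationMass <- function(aaLength) as.integer(round(aaLength * 110.5 /
                                                        1000))

#' Predict the truncation product of a trapped allele
#'
#' The product length is the floor of the coding nucleotides upstream of the
#' trap junction divided by three (the 2A elements release the endogenous
#' moiety from the marker fusion); a trap upstream of the CDS start yields a
#' zero-length product rather than an error.
#'
#' @param allele A trapped [AlleleMap-class].
#' @param gene The [GeneModel-class].
#' @return list with `aaLength` and `approxMassKda` (nearest-integer kDa).
#' @export
predictTruncation <- function(allele, gene) {
  out <- expressionOutcome(allele, gene)
  if (!out$trapped) stop("allele carries no trap cassette on its ",
                         "transcript")
  out$truncation
}

## ---- targeting and workflow simulation ---------------------------------

cellAlleles <- function(cells) list(A = cells@alleleA, B = cells@alleleB)

cellMarkers <- function(cells, threshold = 1) {
  unique(c(expressionOutcome(cells@alleleA, cells@gene, threshold)$markers,
           expressionOutcome(cells@alleleB, cells@gene,
                             threshold)$markers))
}

cellViable <- function(cells, threshold = 1) {
  if (!cells@gene@essentialInES) return(TRUE)
  any(vapply(cellAlleles(cells), function(a)
    expressionOutcome(a, cells@gene, threshold)$fullProtein, logical(1)))
}

DRUG_MARKER <- c(hygromycin = "hygro", G418 = "neo")

#' Simulate one electroporation + drug-selection step
#'
#' Enumerates the possible integration targets (each chromosomal allele plus
#' random integration into an unlinked carrier) and classifies each outcome:
#' a genotype is recoverable iff the selection marker is expressed from the
#' resulting cell and the genotype is viable (an essential gene with no
#' full-protein allele is not). Re-targeting a trapped knockout-first allele
#' in cis is enumerated but never hygromycin-recoverable, and random
#' integrants never trap the locus transcript.
#'
#' @param cells Starting [CellLine-class].
#' @param vector Linearized insertion vector ([AnnSeq-class]).
#' @param selection Drug name (`"hygromycin"` or `"G418"`).
#' @param threshold Trap expression threshold (percent Trfr).
#' @return list with `table` (one row per enumerated outcome) and
#'   `recoverable` (named list of [CellLine-class], by genotype string).
#' @export
simulateTargetingStep <- function(cells, vector, selection = "hygromycin",
                                  threshold = 1) {
  if (!selection %in% names(DRUG_MARKER))
    stop("configuration error: unknown selection drug '", selection, "'")
  marker <- DRUG_MARKER[[selection]]
  outcomes <- list()
  recoverable <- list()
  consider <- function(target, newCells, class) {
    expressedHere <- marker %in% cellMarkers(newCells, threshold)
    viable <- cellViable(newCells, threshold)
    rec <- expressedHere && viable
    gt <- genotypeString(newCells)
    outcomes[[length(outcomes) + 1L]] <<-
      data.frame(target = target, genotype = gt, class = class,
                 markerExpressed = expressedHere, viable = viable,
                 recoverable = rec)
    if (rec) recoverable[[gt]] <<- newCells
  }
  for (which in c("A", "B")) {
    allele <- if (which == "A") cells@alleleA else cells@alleleB
    cand <- tryCatch(suppressWarnings(
      integrateInsertionVector(allele, vector)), error = function(e) NULL)
    if (is.null(cand)) next
    newCells <- cells
    if (which == "A") newCells@alleleA <- cand else newCells@alleleB <- cand
    consider(paste0("allele", which), newCells, "targeted")
  }
  carrier <- AnnSeq(withSeed(cells@seed + 31L, guardedDNA(2000L)),
                    id = "unlinked_carrier")
  rnd <- randomIntegrate(carrier, vector, seed = cells@seed + 32L)
  newCells <- cells
  newCells@extras <- c(cells@extras, list(rnd))
  consider("random", newCells, "random")
  tab <- do.call(rbind, outcomes)
  list(table = tab, recoverable = recoverable)
}

#' Binomially simulate induced Cre conversion over a cell population
#'
#' @param nCells Number of plated cells.
#' @param escaperRate Per-cell probability of failing induced recombination.
#' @param seed Integer seed.
#' @return list with `escapers` (count of non-recombined cells) and
#'   `fraction`.
#' @export
simulateInduction <- function(nCells, escaperRate, seed) {
  k <- withSeed(seed, rbinom(1L, as.integer(nCells), escaperRate))
  list(escapers = k, fraction = k / nCells)
}

applyToLine <- function(line, enzyme) {
  line@alleleA <- suppressWarnings(applyRecombinase(line@alleleA, enzyme))
  line@alleleB <- suppressWarnings(applyRecombinase(line@alleleB, enzyme))
  line
}

induceLine <- function(line) applyToLine(line, "Cre")

hasState <- function(line, state) {
  state %in% c(line@alleleA@state, line@alleleB@state)
}

#' Simulate a multi-step engineering protocol on a cell population
#'
#' Runs an ordered list of steps (`electroporate`, `select`, `flp`,
#' `knockin_creert2`, `induce_4oht`, `subclone`) over a population of
#' genotype fractions starting from one cell line. Deterministic allele
#' transitions are applied per step; 4'OHT induction converts tm1c-carrying
#' fractions with probability `1 - escaperRate`, and once CreERT2 is present
#' every uninduced step converts with the line's `leakRate`. Selection keeps
#' the recoverable genotypes from [simulateTargetingStep()]; when both a cis
#' and a second-allele event survive selection, the second-allele (wild-type
#' target) clones are retained, mirroring the cis/trans PCR triage.
#'
#' @param steps list of steps; each is either a character scalar or a list
#'   whose first element is the step name, e.g.
#'   `list("electroporate", vector = v)`, `list("select",
#'   drug = "hygromycin")`, `list("induce_4oht", hours = 48)`.
#' @param start Starting [CellLine-class].
#' @return list with `trajectory` (one population snapshot per step),
#'   `population` (final genotype fractions) and `lines` (genotype ->
#'   [CellLine-class]).
#' @export
simulateProtocol <- function(steps, start) {
  lines <- setNames(list(start), genotypeString(start))
  population <- setNames(1, genotypeString(start))
  pendingVector <- NULL
  creOn <- length(start@transgenes) > 0 && "CreERT2" %in% start@transgenes
  trajectory <- list()
  leak <- start@leakRate
  esc <- start@escaperRate

  shiftFraction <- function(p) {
    # convert a fraction p of every tm1c-carrying genotype by Cre
    for (gt in names(population)) {
      line <- lines[[gt]]
      if (!hasState(line, "tm1c") || population[[gt]] <= 0) next
      conv <- induceLine(line)
      cgt <- genotypeString(conv)
      moved <- population[[gt]] * p
      population[[gt]] <<- population[[gt]] - moved
      population[cgt] <<- (if (cgt %in% names(population))
        population[[cgt]] else 0) + moved
      lines[[cgt]] <<- conv
    }
  }

  for (step in steps) {
    if (is.character(step)) step <- as.list(step)
    name <- step[[1]]
    args <- step[-1]
    if (creOn && leak > 0 && name != "induce_4oht") shiftFraction(leak)
    if (name == "electroporate") {
      pendingVector <- args$vector %||% args[[1]]
    } else if (name == "select") {
      drug <- args$drug %||% args[[1]]
      if (is.null(pendingVector))
        stop("protocol error: select() without a preceding electroporate()")
      newPop <- numeric(); newLines <- list()
      for (gt in names(population)) {
        res <- simulateTargetingStep(lines[[gt]], pendingVector, drug)
        rec <- res$recoverable
        if (!length(rec)) next
        # prefer second-allele (wild-type target) events over cis events
        tab <- res$table
        wtTargets <- tab$recoverable & tab$target != "random" &
          vapply(tab$target, function(t) {
            a <- if (t == "alleleA") lines[[gt]]@alleleA
                 else lines[[gt]]@alleleB
            a@state == "wt"
          }, logical(1))
        keep <- if (any(wtTargets)) tab$genotype[wtTargets]
                else tab$genotype[tab$recoverable]
        for (g2 in unique(keep)) {
          newPop[g2] <- (if (g2 %in% names(newPop)) newPop[[g2]] else 0) +
            population[[gt]] / length(unique(keep))
          newLines[[g2]] <- rec[[g2]]
        }
      }
      if (!length(newPop))
        tfLog("warn", "selection recovered no clones (essentiality signal)")
      population <- if (length(newPop)) newPop / sum(newPop) else newPop
      lines <- newLines
      pendingVector <- NULL
    } else if (name == "flp") {
      newPop <- numeric(); newLines <- list()
      for (gt in names(population)) {
        conv <- applyToLine(lines[[gt]], "Flp")
        g2 <- genotypeString(conv)
        newPop[g2] <- (if (g2 %in% names(newPop)) newPop[[g2]] else 0) +
          population[[gt]]
        newLines[[g2]] <- conv
      }
      population <- newPop; lines <- newLines
    } else if (name == "knockin_creert2") {
      lines <- lapply(lines, function(l) {
        l@transgenes <- unique(c(l@transgenes, "CreERT2")); l
      })
      creOn <- TRUE
    } else if (name == "induce_4oht") {
      if (!creOn)
        stop("protocol error: 4'OHT induction without a CreERT2 transgene")
      shiftFraction(1 - esc)
    } else if (name == "subclone") {
      top <- names(population)[which.max(population)]
      population <- setNames(1, top)
      lines <- lines[top]
    } else stop("unknown protocol step: ", name)
    trajectory[[length(trajectory) + 1L]] <-
      list(step = name, population = population)
  }
  list(trajectory = trajectory, population = population, lines = lines)
}

#' Build a reference allele in a given symbolic state
#'
#' Runs the actual event chain producing the requested state: knockout-first
#' construction for tm1a, Flp/Cre conversions for tm1b/tm1c/tm1d, and
#' insertion-vector targeting of the wild-type allele for tm2.
#'
#' @param fixture A [makeTargetFixture()] bundle.
#' @param state One of wt, tm1a, tm1b, tm1c, tm1d, tm2.
#' @return An [AlleleMap-class].
#' @export
buildAllele <- function(fixture, state) {
  switch(state,
         wt = AlleleMap(fixture$locus, "wt", provenance = "wild_type"),
         tm1a = buildTm1a(fixture),
         tm1b = applyRecombinase(buildTm1a(fixture), "Cre"),
         tm1c = applyRecombinase(buildTm1a(fixture), "Flp"),
         tm1d = applyRecombinase(applyRecombinase(buildTm1a(fixture),
                                                  "Flp"), "Cre"),
         tm2 = integrateInsertionVector(
           AlleleMap(fixture$locus, "wt"), fixture$vector),
         stop("unknown allele state: ", state))
}
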