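# Genotyping: assay design following the published primer placement rules,
# in-silico long-range PCR by exact-site lookup, blue/white X-gal screening,
# cis/trans discrimination, clone genotype calling and screening-efficiency
# summaries.

allOccurrences <- function(subject, pattern) {
  i <- as.integer(gregexpr(pattern, subject, fixed = TRUE)[[1]])
  i[i > 0] - 1L
}

#' Extract a primer from a primer_site feature
#'
#' @param x An [AnnSeq-class] carrying the feature.
#' @param label Feature label.
#' @param name Primer name (defaults to the label without `_site`).
#' @return A [Primer-class]; reverse-strand sites yield the reverse
#'   complement (the primer as synthesized, 5'->3').
#' @export
primerFromFeature <- function(x, label, name = sub("_site$", "", label)) {
  f <- x@features
  row <- f[f$label == label & f$kind == "primer_site", , drop = FALSE]
  if (!nrow(row)) stop("no primer_site feature '", label, "' on '", x@id,
                       "'")
  s <- substr(x@residues, row$start[1] + 1L, row$end[1])
  if (row$strand[1] == "-") s <- revcompChar(s)
  Primer(name, s)
}

#' In-silico PCR by exact primer-site lookup
#'
#' One product is reported for every convergent forward/reverse site pair
#' with span at most `maxLen`; an empty result is "no band". Primer binding
#' is exact string matching (both orientations of the pair are considered);
#' no thermodynamics are modelled.
#'
#' @param template An [AnnSeq-class].
#' @param fwd,rev [Primer-class] pair.
#' @param maxLen Maximum amplifiable span in nt.
#' @return data.frame of products (`start`, `end`, `size`), ascending size.
#' @export
inSilicoPCR <- function(template, fwd, rev, maxLen = 15000) {
  res <- template@residues
  pairsFor <- function(p1, p2) {
    f <- allOccurrences(res, p1@seq)
    r <- allOccurrences(res, revcompChar(p2@seq))
    if (!length(f) || !length(r)) return(NULL)
    grid <- expand.grid(f = f, r = r)
    grid$end <- grid$r + nchar(p2@seq)
    grid$size <- grid$end - grid$f
    ok <- grid$size >= nchar(p1@seq) + nchar(p2@seq) & grid$size <= maxLen
    grid[ok, c("f", "end", "size")]
  }
  hits <- rbind(pairsFor(fwd, rev), pairsFor(rev, fwd))
  if (is.null(hits) || !nrow(hits))
    return(data.frame(start = integer(), end = integer(),
                      size = integer()))
  out <- data.frame(start = hits$f, end = hits$end, size = hits$size)
  out <- unique(out[order(out$size), , drop = FALSE])
  rownames(out) <- NULL
  out
}

REACHABLE_PAIRS <- rbind(
  expand.grid(a = setdiff(ALLELE_STATES, "wt"), b = "wt",
              stringsAsFactors = FALSE),
  expand.grid(a = c("tm1a", "tm1b", "tm1c", "tm1d"), b = "tm2",
              stringsAsFactors = FALSE))

#' Design the canonical four-assay genotyping panel for a fixture gene
#'
#' Emits the four screening assays: (1) gf3 + LAR_3 confirms the
#' knockout-first allele; (2) ex5 + hygro_1R detects the gap-repaired tm2
#' allele (random integrants are PCR-negative); (3) gf3 + LR distinguishes
#' tm1a from tm1c by the beta-geo cassette size shift and is silent on tm2;
#' (4) R1_amp_F2 + hygro_1R is the cis/trans junction test. Expected band
#' sizes per allele state are computed by running the assays on reference
#' alleles constructed for every reachable state. The external-primer rule
#' (at least one primer outside the vector homology or inside the gap) is
#' verified for every assay.
#'
#' @param fixture A [makeTargetFixture()] bundle.
#' @param maxLen Maximum LR-PCR span.
#' @param cisMaxLen Maximum span for the cis/trans junction assay.
#' @return Named list of four [Assay-class] objects; reference alleles are
#'   attached as attribute `"references"`.
#' @export
designPanel <- function(fixture, maxLen = 15000, cisMaxLen = 8000) {
  locus <- fixture$locus
  lm <- fixture$landmarks
  tm1aRef <- buildTm1a(fixture)
  gf3 <- primerFromFeature(locus, "gf3", "gf3")
  ex5 <- primerFromFeature(locus, "ex5", "ex5")
  lar3 <- primerFromFeature(fixture$betageo@seq, "LAR_3_site")
  hyg1r <- primerFromFeature(fixture$cassettes[[1]]@seq, "hygro_1R_site")
  lr <- primerFromFeature(tm1aRef@seq, "LR_site")
  r1f2 <- primerFromFeature(tm1aRef@seq, "R1_amp_F2_site")

  # external-primer rule: gf3 external to the 5' arm, ex5 inside the gap
  gf3pos <- locus@features[locus@features$label == "gf3", ]$start[1]
  ex5pos <- locus@features[locus@features$label == "ex5", ]$start[1]
  if (gf3pos >= lm$g5 && gf3pos < lm$g3)
    stop("design error: gf3 is not external to the vector homology")
  if (ex5pos < lm$u3 || ex5pos >= lm$d5)
    stop("design error: ex5 does not bind inside the gap region")

  refs <- lapply(setNames(ALLELE_STATES, ALLELE_STATES), function(s)
    buildAllele(fixture, s))
  mkAssay <- function(name, fwd, rev, max) {
    exp <- vapply(refs, function(a) {
      pr <- inSilicoPCR(a@seq, fwd, rev, max)
      if (nrow(pr)) pr$size[1] else NA_real_
    }, numeric(1))
    new("Assay", name = name, fwd = fwd, rev = rev, maxLen = max,
        expected = exp)
  }
  panel <- list(tm1a_confirm = mkAssay("tm1a_confirm", gf3, lar3, maxLen),
                tm2_gap = mkAssay("tm2_gap", ex5, hyg1r, maxLen),
                flp_revert = mkAssay("flp_revert", gf3, lr, maxLen),
                cis_trans = mkAssay("cis_trans", r1f2, hyg1r, cisMaxLen))
  attr(panel, "references") <- refs
  panel
}

#' Band pattern of a cell line under an assay panel
#'
#' @param cells A [CellLine-class].
#' @param panel Panel from [designPanel()].
#' @return Named list of numeric size vectors (empty = no band), covering
#'   both alleles and any unlinked integrants.
#' @export
bandPattern <- function(cells, panel) {
  templates <- c(list(cells@alleleA@seq, cells@alleleB@seq), cells@extras)
  lapply(panel, function(as) {
    sizes <- unlist(lapply(templates, function(t)
      inSilicoPCR(t, as@fwd, as@rev, as@maxLen)$size))
    sort(unique(sizes))
  })
}

matchBands <- function(observed, predicted, tol = 0.10) {
  observed <- sort(observed); predicted <- sort(predicted)
  if (length(observed) != length(predicted)) return(FALSE)
  if (!length(observed)) return(TRUE)
  all(abs(observed - predicted) <= tol * predicted)
}

#' Call a clone genotype from an observed band pattern
#'
#' Finds the allele-state pairs reachable by in-scope protocols whose
#' expected band multiset is consistent with every observed and absent band
#' (within the size tolerance). The wt/wt pair is not a candidate: a clone
#' with no bands at all is reported as a conflict, not a call. When the
#' cis/trans junction assay is part of the pattern, the configuration is
#' reported alongside the call.
#'
#' @param pattern Named list of observed sizes per assay (numeric vectors;
#'   empty or missing = no band). Keys must be a subset of the panel names.
#' @param panel Panel from [designPanel()].
#' @param tol Relative band-size tolerance (default 0.10).
#' @return list with `genotype` (string or NA), `confidence` (`"unique"`,
#'   `"ambiguous"` or `"none"`), `candidates`, `conflicts` and
#'   `configuration` (`"cis"`, `"trans"` or NA).
#' @export
callGenotype <- function(pattern, panel, tol = 0.10) {
  if (length(setdiff(names(pattern), names(panel))))
    stop("pattern keys not in panel: ",
         paste(setdiff(names(pattern), names(panel)), collapse = ", "))
  stateAssays <- setdiff(names(panel), "cis_trans")
  fits <- character()
  for (i in seq_len(nrow(REACHABLE_PAIRS))) {
    a <- REACHABLE_PAIRS$a[i]; b <- REACHABLE_PAIRS$b[i]
    ok <- TRUE
    for (nm in intersect(stateAssays, names(pattern))) {
      exp <- panel[[nm]]@expected[c(a, b)]
      exp <- exp[!is.na(exp)]
      if (!matchBands(pattern[[nm]], exp, tol)) { ok <- FALSE; break }
    }
    if (ok) fits <- c(fits, genotypeString(c(a, b)))
  }
  fits <- unique(fits)
  conflicts <- character()
  if (!length(fits)) {
    for (nm in intersect(stateAssays, names(pattern)))
      conflicts <- c(conflicts,
                     sprintf("%s: observed [%s] matches no reachable pair",
                             nm, paste(pattern[[nm]], collapse = ", ")))
  }
  configuration <- NA_character_
  if ("cis_trans" %in% names(pattern)) {
    if (length(pattern$cis_trans)) configuration <- "cis"
    else if (length(fits) == 1L && grepl("tm2", fits) &&
             grepl("tm1[a-d]", fits)) configuration <- "trans"
  }
  list(genotype = if (length(fits) == 1L) fits else NA_character_,
       confidence = c("none", "unique", "ambiguous")[
         min(length(fits), 2L) + 1L],
       candidates = fits, conflicts = conflicts,
       configuration = configuration)
}

#' cis/trans discrimination for doubly targeted lines
#'
#' `"cis"` iff the junction assay (R1_amp_F2 + hygro_1R) amplifies from a
#' single allele sequence; `"trans"` iff no product on either allele while
#' both the knockout-first-derived structure and the hygro-GFP cassette are
#' present across the two alleles; `"not_applicable"` otherwise.
#'
#' @param cells A [CellLine-class].
#' @param panel Panel from [designPanel()].
#' @return `"cis"`, `"trans"` or `"not_applicable"`.
#' @export
cisTransTest <- function(cells, panel) {
  as <- panel$cis_trans
  alleles <- list(cells@alleleA@seq, cells@alleleB@seq)
  products <- vapply(alleles, function(t)
    nrow(inSilicoPCR(t, as@fwd, as@rev, as@maxLen)) > 0, logical(1))
  if (any(products)) return("cis")
  hasTag <- any(vapply(alleles, function(t)
    grepl(as@fwd@seq, t@residues, fixed = TRUE), logical(1)))
  hasHyg <- any(vapply(alleles, function(t) {
    f <- t@features
    any(f$kind == "cassette" &
          vapply(f$quals, function(q) identical(q$marker_name,
                                                "hygro_gfp"), logical(1)))
  }, logical(1)))
  if (hasTag && hasHyg) "trans" else "not_applicable"
}

#' X-gal blue/white screen of a cell line
#'
#' Blue iff any allele expresses lacZ from an intact beta-geo trap; a
#' low-expression caveat is flagged when the gene sits below the trapping
#' threshold, in which case the visual screen may be insufficiently
#' sensitive and genomic genotyping should be used instead.
#'
#' @param cells A [CellLine-class].
#' @param threshold Trap expression threshold (percent Trfr).
#' @return list with `stain` (`"blue"`/`"white"`) and
#'   `lowExpressionCaveat`.
#' @export
xgalScreen <- function(cells, threshold = 1) {
  blue <- "lacZ" %in% cellMarkers(cells, threshold)
  hasBetageo <- any(vapply(cellAlleles(cells), function(a) {
    f <- a@seq@features
    any(f$kind == "cassette" &
          vapply(f$quals, function(q) identical(q$marker_name, "betageo"),
                 logical(1)))
  }, logical(1)))
  list(stain = if (blue) "blue" else "white",
       lowExpressionCaveat = hasBetageo &&
         cells@gene@expressionPctTrfr < threshold)
}

## ---- screening summaries ----------------------------------------------

#' Summarize a screening tally table
#'
#' Per-row targeting percents (one decimal), per-gene percents within each
#' line class (duplicate lines for a gene are averaged), unweighted
#' mean/min/max over the per-gene values, and the operational essentiality
#' tally: genes whose every experimental (non wild-type) row has zero
#' positive colonies.
#'
#' @param table data.frame with columns `gene`, `line_genotype`,
#'   `colonies_screened`, `colonies_positive`.
#' @return list with `perRow`, `perGene`, `summary` (one row per line
#'   class), `genesWithClones`, `genesWithoutClones` and `empty`.
#' @export
summarizeScreen <- function(table) {
  need <- c("gene", "line_genotype", "colonies_screened",
            "colonies_positive")
  if (length(setdiff(need, names(table))))
    stop("screen table must have columns: ", paste(need, collapse = ", "))
  if (!nrow(table))
    return(list(perRow = table, perGene = table,
                summary = data.frame(), genesWithClones = character(),
                genesWithoutClones = character(), empty = TRUE))
  if (any(table$colonies_positive > table$colonies_screened) ||
      any(table$colonies_positive < 0) || any(table$colonies_screened < 0))
    stop("data error: positives must lie in [0, colonies screened]")
  perRow <- table
  perRow$pct <- ifelse(perRow$colonies_screened > 0,
                       round(100 * perRow$colonies_positive /
                               perRow$colonies_screened, 1), NA_real_)
  perGene <- aggregate(pct ~ gene + line_genotype, data = perRow,
                       FUN = mean, na.action = stats::na.omit)
  perGene$pct <- round(perGene$pct, 1)
  summary <- do.call(rbind, lapply(split(perGene, perGene$line_genotype),
                                   function(g)
    data.frame(line_genotype = g$line_genotype[1],
               mean_pct = round(mean(g$pct), 1),
               min_pct = min(g$pct), max_pct = max(g$pct),
               n_genes = length(unique(g$gene)))))
  rownames(summary) <- NULL
  exp <- perRow[perRow$line_genotype != "wt", , drop = FALSE]
  genesWithout <- character(); genesWith <- character()
  if (nrow(exp)) {
    byGene <- split(exp, exp$gene)
    genesWithout <- names(byGene)[vapply(byGene, function(g)
      all(g$colonies_positive == 0), logical(1))]
    genesWith <- setdiff(names(byGene), genesWithout)
  }
  list(perRow = perRow, perGene = perGene, summary = summary,
       genesWithClones = sort(genesWith),
       genesWithoutClones = sort(genesWithout), empty = FALSE)
}

#' Read a screening tally table from TSV
#'
#' @param path TSV path with the [summarizeScreen()] columns.
#' @return data.frame.
#' @export
readScreenTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "line_genotype", "colonies_screened",
            "colonies_positive")
  if (length(setdiff(need, names(tab))))
    stop("malformed screen table '", path, "': need columns ",
         paste(need, collapse = ", "))
  tab
}

#' Bundled second-allele targeting screen tallies
#'
#' Colony tallies from a published bi-allelic targeting screen of 14
#' epigenetic-regulator genes in JM8 mouse ES cells: wild-type control
#' electroporations and heterozygous knockout-first (tm1a/+) lines screened
#' by long-range PCR after hygromycin selection.
#'
#' @return data.frame in [summarizeScreen()] format (plus `clone_id`).
#' @export
biallelicScreenExample <- function() {
  readScreenTable(system.file("extdata", "biallelic_screen.tsv",
                              package = "trapforge", mustWork = TRUE))
}
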