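# Genotyping: in-silico PCR, panel design, clone calling, cis/trans and
# X-gal screening, and screening-efficiency summaries.

test_that("in-silico PCR matches the all-pairs brute-force oracle", {
  fwd <- Primer("f", "ACGTACGTACGTACGTACGT")
  rev <- Primer("r", "TTGGCCAATTGGCCAATTGG")
  for (i in 1:20) {
    base <- withr::with_seed(500L + i,
                             paste(sample(c("A", "C", "G", "T"), 3000,
                                          replace = TRUE), collapse = ""))
    # plant forward and reverse sites at seeded positions
    slots <- withr::with_seed(600L + i, sample(seq(1, 2900, by = 40), 4))
    substr(base, slots[1], slots[1] + 19) <- fwd@seq
    substr(base, slots[2], slots[2] + 19) <- fwd@seq
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    substr(base, slots[3], slots[3] + 19) <- rc(rev@seq)
    substr(base, slots[4], slots[4] + 19) <- rc(rev@seq)
    got <- inSilicoPCR(AnnSeq(base), fwd, rev, 2500)$size
    expect_equal(sort(got), brutePCR(base, fwd@seq, rev@seq, 2500))
  }
})

test_that("PCR product sizes shift by exact cassette-length deltas", {
  panel <- tfPanel()
  exp <- panel$flp_revert@expected
  betageo <- tfFixture()$betageo
  expect_equal(exp[["tm1a"]] - exp[["tm1c"]],
               annLength(betageo@seq) + 34)     # cassette + one FRT
  gapLen <- tfFixture()$buildReport$gapLength
  expect_equal(exp[["tm1c"]] - exp[["tm1d"]], gapLen + 34)
})

test_that("panel design follows the published primer rules", {
  panel <- tfPanel()
  expect_named(panel, c("tm1a_confirm", "tm2_gap", "flp_revert",
                        "cis_trans"))
  e <- function(nm) panel[[nm]]@expected
  # gf3+LAR_3 detects the knockout-first cassette
  expect_false(is.na(e("tm1a_confirm")[["tm1a"]]))
  expect_true(is.na(e("tm1a_confirm")[["wt"]]))
  expect_true(is.na(e("tm1a_confirm")[["tm2"]]))
  # ex5+hygro_1R detects the gap-repaired tm2 allele only
  expect_false(is.na(e("tm2_gap")[["tm2"]]))
  expect_true(all(is.na(e("tm2_gap")[setdiff(names(e("tm2_gap")),
                                             "tm2")])))
  expect_gt(e("tm2_gap")[["tm2"]], 4000)   # long-range product class
  # gf3+LR distinguishes tm1a (~12 kb class) from tm1c (~7 kb class),
  # silent on wt and tm2 (the LR site does not bind those templates)
  expect_true(is.na(e("flp_revert")[["wt"]]))
  expect_true(is.na(e("flp_revert")[["tm2"]]))
  expect_gt(e("flp_revert")[["tm1a"]], e("flp_revert")[["tm1c"]] * 1.5)
  # each state assay distinguishes at least two allele states, and the
  # size-discriminating assay separates its four classes by >10%
  for (nm in c("tm1a_confirm", "tm2_gap", "flp_revert")) {
    v <- e(nm)
    expect_true(any(is.na(v)) && any(!is.na(v)), info = nm)
  }
  sizes <- sort(e("flp_revert")[!is.na(e("flp_revert"))],
                decreasing = TRUE)
  expect_true(all(diff(sizes) < -0.1 * sizes[-length(sizes)]))
})

test_that("band generation followed by calling is the identity", {
  fx <- tfFixture()
  panel <- tfPanel()
  pairs <- rbind(expand.grid(a = setdiff(c("wt", "tm1a", "tm1b", "tm1c",
                                           "tm1d", "tm2"), "wt"),
                             b = "wt", stringsAsFactors = FALSE),
                 expand.grid(a = c("tm1a", "tm1b", "tm1c", "tm1d"),
                             b = "tm2", stringsAsFactors = FALSE))
  for (i in seq_len(nrow(pairs))) {
    cl <- makeCellLine(fx, c(pairs$a[i], pairs$b[i]), seed = i)
    call <- callGenotype(bandPattern(cl, panel), panel)
    expect_equal(call$genotype, genotypeString(cl),
                 info = paste(pairs$a[i], pairs$b[i]))
    expect_equal(call$confidence, "unique")
  }
})

test_that("an all-absent pattern yields conflicts, not a call", {
  panel <- tfPanel()
  pat <- list(tm1a_confirm = numeric(), tm2_gap = numeric(),
              flp_revert = numeric())
  call <- callGenotype(pat, panel)
  expect_true(is.na(call$genotype))
  expect_equal(call$confidence, "none")
  expect_gt(length(call$conflicts), 0L)
  expect_error(callGenotype(list(bogus = 1), panel), "not in panel")
})

test_that("cis/trans discrimination follows the junction assay", {
  fx <- tfFixture()
  panel <- tfPanel()
  trans <- makeCellLine(fx, c("tm1c", "tm2"), seed = 1L)
  expect_equal(cisTransTest(trans, panel), "trans")
  cisAllele <- integrateInsertionVector(buildAllele(fx, "tm1c"),
                                        fx$vector)
  cisLine <- new("CellLine", gene = fx$gene, alleleA = cisAllele,
                 alleleB = buildAllele(fx, "wt"),
                 transgenes = character(), extras = list(), leakRate = 0,
                 escaperRate = 0, seed = 1L)
  expect_equal(cisTransTest(cisLine, panel), "cis")
  # the junction product sits in the ~6 kb class
  pr <- inSilicoPCR(cisAllele@seq, panel$cis_trans@fwd,
                    panel$cis_trans@rev, panel$cis_trans@maxLen)
  expect_gt(pr$size[1], 5000)
  expect_lt(pr$size[1], 8000)
  expect_equal(cisTransTest(makeCellLine(fx, c("tm1a", "wt")), panel),
               "not_applicable")
  # calling a trans clone reports the configuration
  call <- callGenotype(bandPattern(trans, panel), panel)
  expect_equal(call$genotype, "tm1c/tm2")
  expect_equal(call$configuration, "trans")
})

test_that("X-gal screening reports trap activity and its sensitivity", {
  fx <- tfFixture()
  expect_equal(xgalScreen(makeCellLine(fx, c("tm1a", "wt")))$stain,
               "blue")
  expect_equal(xgalScreen(makeCellLine(fx, c("tm1c", "wt")))$stain,
               "white")
  lowFx <- tfFixture(seed = 44L, expressionPctTrfr = 0.5)
  low <- xgalScreen(makeCellLine(lowFx, c("tm1a", "wt")))
  expect_equal(low$stain, "white")
  expect_true(low$lowExpressionCaveat)
})

test_that("screen summaries reproduce the published arithmetic", {
  row <- data.frame(gene = "Cbx1", line_genotype = "tm1a/+",
                    colonies_screened = 24, colonies_positive = 11)
  expect_equal(summarizeScreen(row)$perRow$pct, 45.8)

  tab <- biallelicScreenExample()
  res <- summarizeScreen(tab)
  wt <- res$summary[res$summary$line_genotype == "wt", ]
  expect_equal(round(wt$mean_pct), 80)
  expect_equal(wt$min_pct, 50)
  expect_equal(wt$max_pct, 100)
  expect_length(res$genesWithClones, 11L)
  expect_equal(res$genesWithoutClones, c("Ddx27", "Phf20", "Setdb1"))
  # duplicate lines are averaged before gene-level summaries
  perGene <- res$perGene
  expect_equal(perGene$pct[perGene$gene == "Jarid2" &
                             perGene$line_genotype == "tm1a/+"], 62.5)
  expect_true(summarizeScreen(tab[0, ])$empty)
  bad <- row; bad$colonies_positive <- 30
  expect_error(summarizeScreen(bad), "data error")
})
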