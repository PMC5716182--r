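# Allele state machine, census validation, expression/selection logic,
# truncation prediction and workflow simulation.

test_that("end phase follows cumulative coding length mod 3", {
  mk <- function(lens) {
    starts <- c(0L, 1000L)
    GeneModel("toy",
              exons = data.frame(start = starts, end = starts + lens),
              cds = data.frame(start = starts, end = starts + lens))
  }
  expect_equal(endPhase(mk(c(60L, 90L)), c(-1, 2000)), 0L)
  expect_equal(endPhase(mk(c(60L, 91L)), c(-1, 2000)), 1L)
  # only the exons wholly inside the homology count
  expect_equal(endPhase(mk(c(60L, 91L)), c(-1, 500)), 0L)
  expect_error(endPhase(mk(c(60L, 90L)), c(5000, 6000)), "no coding exon")
})

test_that("state transitions produce census-valid alleles", {
  tm1a <- tfAllele("tm1a")
  expect_true(validateAllele(tm1a))
  tm1c <- applyRecombinase(tm1a, "Flp")
  expect_equal(tm1c@state, "tm1c")
  expect_true(validateAllele(tm1c))
  tm1b <- applyRecombinase(tm1a, "Cre")
  expect_true(validateAllele(tm1b))
  tm1d <- applyRecombinase(tm1c, "Cre")
  expect_equal(tm1d@state, "tm1d")
  expect_true(validateAllele(tm1d))
  expect_true(validateAllele(tfAllele("tm2")))
  expect_true(validateAllele(tfAllele("wt")))
})

test_that("Flp and Cre commute on tm1a, both yielding tm1d", {
  tm1a <- tfAllele("tm1a")
  viaC <- applyRecombinase(applyRecombinase(tm1a, "Flp"), "Cre")
  viaB <- applyRecombinase(applyRecombinase(tm1a, "Cre"), "Flp")
  expect_equal(viaC@state, "tm1d")
  expect_equal(viaB@state, "tm1d")
  expect_identical(residues(viaC@seq), residues(viaB@seq))
})

test_that("census validator rejects every cross-state claim", {
  alleles <- lapply(setNames(c("wt", "tm1a", "tm1b", "tm1c", "tm1d",
                               "tm2"), c("wt", "tm1a", "tm1b", "tm1c",
                                         "tm1d", "tm2")), tfAllele)
  for (built in names(alleles)) for (claimed in names(alleles)) {
    if (built == claimed) {
      expect_true(validateAllele(alleles[[built]], claimed))
    } else {
      expect_error(validateAllele(alleles[[built]], claimed),
                   "census mismatch", info = paste(built, "as", claimed))
    }
  }
})

test_that("expression outcomes follow the transcript walk", {
  fx <- tfFixture()
  # knockout-first: trapped by beta-geo, reporters on, no full protein
  out1a <- expressionOutcome(tfAllele("tm1a"), fx$gene)
  expect_setequal(out1a$markers, c("lacZ", "neo"))
  expect_false(out1a$fullProtein)
  # frame-matched second-allele trap expresses hygro and GFP
  out2 <- expressionOutcome(tfAllele("tm2"), fx$gene)
  expect_setequal(out2$markers, c("hygro", "GFP"))
  # wt and tm1c make full-length protein; tm1d is frameshifted null
  expect_true(expressionOutcome(tfAllele("wt"), fx$gene)$fullProtein)
  expect_true(expressionOutcome(tfAllele("tm1c"), fx$gene)$fullProtein)
  out1d <- expressionOutcome(tfAllele("tm1d"), fx$gene)
  expect_false(out1d$fullProtein)
  expect_equal(out1d$markers, character(0))
  # below the trapping threshold no reporter survives selection
  low <- fx$gene
  low@expressionPctTrfr <- 0.5
  expect_equal(expressionOutcome(tfAllele("tm1a"), low)$markers,
               character(0))
  # in-cis integration downstream of an intact beta-geo trap leaves
  # hygro silent
  cis <- integrateInsertionVector(tfAllele("tm1a"), fx$vector)
  expect_setequal(expressionOutcome(cis, fx$gene)$markers,
                  c("lacZ", "neo"))
})

test_that("truncation products reproduce printed residue arithmetic", {
  expect_equal(truncationMass(353), 39L)   # Setdb1-class product
  expect_equal(truncationMass(97), 11L)    # Jarid2-class product
  fx <- tfFixture()
  tr <- predictTruncation(tfAllele("tm2"), fx$gene)
  cd <- fx$gene@cds
  upstreamNt <- sum((cd$end - cd$start)[seq_len(4)])
  expect_equal(tr$aaLength, upstreamNt %/% 3L)
  expect_equal(tr$approxMassKda, truncationMass(tr$aaLength))
  expect_error(predictTruncation(tfAllele("wt"), fx$gene), "no trap")
})

test_that("targeting step recovers only marker-positive viable genotypes", {
  fx <- tfFixture()
  het <- makeCellLine(fx, c("tm1a", "wt"), seed = 5L)
  res <- simulateTargetingStep(het, fx$vector, "hygromycin")
  expect_equal(names(res$recoverable), "tm1a/tm2")
  cisRow <- res$table[res$table$target == "alleleA", ]
  expect_false(cisRow$markerExpressed)   # re-targeting selected against
  expect_false(res$table[res$table$target == "random", ]$recoverable)

  wtLine <- makeCellLine(fx, c("wt", "wt"), seed = 5L)
  resW <- simulateTargetingStep(wtLine, fx$vector, "hygromycin")
  expect_equal(names(resW$recoverable), "tm2/+")

  ess <- tfFixture(seed = 43L, essential = TRUE)
  hetE <- makeCellLine(ess, c("tm1a", "wt"), seed = 5L)
  expect_length(simulateTargetingStep(hetE, ess$vector,
                                      "hygromycin")$recoverable, 0L)
  wtE <- makeCellLine(ess, c("wt", "wt"), seed = 5L)
  expect_equal(names(simulateTargetingStep(wtE, ess$vector,
                                           "hygromycin")$recoverable),
               "tm2/+")
  expect_error(simulateTargetingStep(het, fx$vector, "ampicillin"),
               "configuration error")
})

test_that("the conditional-ablation route reaches tm1d/tm2 majority", {
  fx <- tfFixture()
  start <- makeCellLine(fx, c("tm1a", "wt"), escaperRate = 1e-3,
                        seed = 7L)
  steps <- list("flp", list("electroporate", vector = fx$vector),
                list("select", drug = "hygromycin"), "knockin_creert2",
                list("induce_4oht", hours = 48))
  res <- suppressWarnings(simulateProtocol(steps, start))
  stepNames <- vapply(res$trajectory, `[[`, character(1), "step")
  pops <- lapply(res$trajectory, `[[`, "population")
  expect_equal(names(pops[[which(stepNames == "select")]]), "tm1c/tm2")
  final <- res$population
  expect_equal(names(which.max(final)), "tm1d/tm2")
  expect_equal(unname(final["tm1c/tm2"]), 1e-3, tolerance = 1e-9)
  # leak 0: no tm1d anywhere before induction
  for (i in which(stepNames != "induce_4oht"))
    expect_false(any(grepl("tm1d", names(pops[[i]]))))
  # induction requires the CreERT2 transgene
  expect_error(suppressWarnings(simulateProtocol(
    list(list("induce_4oht", hours = 48)), start)), "protocol error")
})

test_that("observed escaper fractions recover the simulated rate", {
  n <- 1e5L
  for (r in c(1e-2, 1e-3)) {
    obs <- simulateInduction(n, r, seed = 11L)$fraction
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / n))
  }
  # rare escapers: <1 expected per 1000-cell plating at the working rate
  plated <- simulateInduction(1000L, 1e-3, seed = 3L)
  expect_lte(plated$escapers, 3L)
})

test_that("genotype strings follow the published shorthand", {
  fx <- tfFixture()
  expect_equal(genotypeString(makeCellLine(fx, c("tm1a", "wt"))), "tm1a/+")
  expect_equal(genotypeString(c("wt", "tm2")), "tm2/+")
  expect_equal(genotypeString(c("tm1a", "tm2")), "tm1a/tm2")
  expect_error(makeCellLine(fx, c("tm1d", "tm1d")), "construction error")
})
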