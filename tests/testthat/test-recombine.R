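# Recombination engine: Gateway exchange, Cre/Flp excision, linearization,
# gap-repair insertion targeting and random integration.

test_that("three-way Gateway exchange obeys length bookkeeping", {
  fx <- tfFixture()
  donor <- makeTrapDonorPlasmid(fx$cassettes[[fx$buildReport$framePhase +
                                               1L]])
  gw <- gatewayThreeWay(fx$iv, fx$adaptor, donor)
  sitePos <- function(x, st) {
    f <- annFeatures(x)
    f[f$kind == "recomb_site" &
        vapply(f$quals, function(q) identical(q$site_subtype, st),
               logical(1)), c("start", "end")]
  }
  r1 <- sitePos(fx$iv, "attR1"); r2 <- sitePos(fx$iv, "attR2")
  r3 <- sitePos(fx$iv, "attR3"); r4 <- sitePos(fx$iv, "attR4")
  l1 <- sitePos(fx$adaptor, "attL1"); l2 <- sitePos(fx$adaptor, "attL2")
  l3 <- sitePos(donor, "attL3"); l4 <- sitePos(donor, "attL4")
  stuffer <- r2$start - r1$end
  backbone <- r4$start - r3$end
  adPayload <- l2$start - l1$end
  trapPayload <- l4$start - l3$end
  expect_equal(annLength(gw$product),
               annLength(fx$iv) - stuffer - backbone + adPayload +
                 trapPayload)
  # displaced segments are conserved in the byproduct circles
  total <- annLength(gw$product) + sum(vapply(gw$byproducts, annLength,
                                              numeric(1)))
  expect_equal(total, annLength(fx$iv) + annLength(fx$adaptor) +
                 annLength(donor))
})

test_that("Gateway product census: attB only, PmeI, loxP, trap cassette", {
  fx <- tfFixture()
  donor <- makeTrapDonorPlasmid(fx$cassettes[[1]])
  gw <- gatewayThreeWay(fx$iv, fx$adaptor, donor)
  f <- annFeatures(gw$product)
  subs <- vapply(f$quals[f$kind == "recomb_site"],
                 function(q) q$site_subtype, character(1))
  expect_equal(sum(grepl("^att[RL]", subs)), 0L)
  expect_equal(sort(subs[grepl("^attB", subs)]), paste0("attB", 1:4))
  expect_equal(sum(subs == "loxP"), 2L)
  expect_true(any(f$kind == "restriction_site" & f$label == "PmeI"))
  expect_true(any(f$kind == "cassette" &
                    vapply(f$quals, function(q)
                      identical(q$marker_name, "hygro_gfp"), logical(1))))
})

test_that("Gateway precondition violations raise named errors", {
  fx <- tfFixture()
  donor <- makeTrapDonorPlasmid(fx$cassettes[[1]])
  drop2 <- fx$adaptor
  f <- annFeatures(drop2)
  annFeatures(drop2) <- f[f$label != "attL2", ]
  expect_error(gatewayThreeWay(fx$iv, drop2, donor), "missing site.*attL2")
  dup <- fx$adaptor
  extra <- f[f$label == "attL2", ]
  annFeatures(dup) <- rbind(f, extra)
  expect_error(gatewayThreeWay(fx$iv, dup, donor), "ambiguous")
  flip <- fx$adaptor
  f2 <- annFeatures(flip)
  f2$strand[f2$label == "attL1"] <- "-"
  annFeatures(flip) <- f2
  expect_error(gatewayThreeWay(fx$iv, flip, donor), "orientation")
})

loxFeat <- function(start) {
  annFeature("loxP", "recomb_site", start, start + 34L,
             site_subtype = "loxP")
}

test_that("ssrExcise removes the inter-site segment, keeping one site", {
  x <- AnnSeq(strrep("A", 1000),
              features = rbind(loxFeat(100L), loxFeat(500L)))
  res <- ssrExcise(x, "loxP")
  expect_equal(annLength(res$main), 600L)          # 1 kb - 400 nt
  expect_equal(nrow(annFeatures(res$main)), 1L)    # one hybrid site kept
  expect_equal(annLength(res$excisedCircle), 400L)
  expect_equal(topology(res$excisedCircle), "circular")
  # residue conservation up to the shared site copy
  expect_equal(annLength(res$main) + annLength(res$excisedCircle),
               annLength(x))
})

test_that("ssrExcise handles degenerate substrates per contract", {
  one <- AnnSeq(strrep("A", 200), features = loxFeat(50L))
  expect_warning(res <- ssrExcise(one, "loxP"), "returning input")
  expect_identical(residues(res$main), residues(one))
  expect_null(res$excisedCircle)
  expect_warning(res2 <- ssrExcise(one, "FRT"), "0 FRT")
  three <- AnnSeq(strrep("A", 1000),
                  features = rbind(loxFeat(100L), loxFeat(400L),
                                   loxFeat(700L)))
  expect_error(suppressWarnings(ssrExcise(three, "loxP")), "ambiguous")
  inv <- AnnSeq(strrep("A", 1000),
                features = rbind(loxFeat(100L), {
                  f <- loxFeat(500L); f$strand <- "-"; f
                }))
  expect_error(ssrExcise(inv, "loxP"), "unsupported orientation")
})

test_that("ssrExcise is idempotent once one site remains", {
  a <- tfAllele("tm1a")
  flp1 <- ssrExcise(a@seq, "FRT")
  expect_warning(flp2 <- ssrExcise(flp1$main, "FRT"), "1 FRT")
  expect_identical(residues(flp2$main), residues(flp1$main))
})

test_that("linearize opens blunt mid-motif and enforces site uniqueness", {
  ad <- tfFixture()$adaptor
  lin <- linearizeVector(ad)
  expect_equal(annLength(lin), annLength(ad))
  expect_equal(topology(lin), "linear")
  expect_equal(substr(residues(lin), 1, 4), "AAAC")   # GTTT/AAAC cut
  expect_equal(substr(residues(lin), annLength(lin) - 3, annLength(lin)),
               "GTTT")
  two <- AnnSeq(paste0(strrep("A", 50), "GTTTAAAC", strrep("C", 50),
                       "GTTTAAAC", strrep("G", 50)),
                topology = "circular")
  expect_error(linearizeVector(two), "cannot be linearized intact")
  none <- AnnSeq(strrep("ACGG", 30), topology = "circular")
  expect_error(linearizeVector(none), "no GTTTAAAC")
  expect_error(linearizeVector(AnnSeq("GTTTAAACAA")), "not circular")
})

test_that("insertion targeting satisfies the gap-repair contract", {
  fx <- tfFixture()
  wt <- buildAllele(fx, "wt")
  tm2 <- integrateInsertionVector(wt, fx$vector)
  expect_equal(tm2@state, "tm2")
  expect_equal(annLength(tm2@seq),
               annLength(wt@seq) + annLength(fx$vector) +
                 fx$buildReport$gapLength)
  # ex5 occurs exactly twice: repaired copy + chromosomal copy
  ex5 <- primerFromFeature(fx$locus, "ex5")
  expect_equal(length(gregexpr(ex5@seq, residues(tm2@seq),
                               fixed = TRUE)[[1]]), 2L)
  # cassette strictly between the two homology copies
  f <- annFeatures(tm2@seq)
  arm5s <- sort(f$start[f$label == "arm5"])
  cass <- f[f$kind == "cassette", ]
  expect_equal(length(arm5s), 2L)
  expect_true(cass$start > arm5s[1] && cass$end < max(f$end[f$label ==
                                                              "arm3"]))
})

test_that("integration rejects mismatched homology and circular vectors", {
  fx <- tfFixture()
  wt <- buildAllele(fx, "wt")
  bad <- fx$vector
  f <- annFeatures(bad)
  arm <- f[f$label == "arm5", ]
  pos <- arm$start[1] + 100L
  r <- residues(bad)
  substr(r, pos + 1L, pos + 1L) <- if (substr(r, pos + 1L, pos + 1L) ==
                                         "A") "C" else "A"
  bad@residues <- r
  expect_error(integrateInsertionVector(wt, bad), "no integration")
  circ <- fx$vector
  circ@topology <- "circular"
  expect_error(integrateInsertionVector(wt, circ), "must linearize")
  # no gap-repair template on a critical-exon-deleted allele
  expect_error(integrateInsertionVector(tfAllele("tm1b"), fx$vector),
               "gap-repair template")
})

test_that("random integration is seeded, conservative and gap-free", {
  fx <- tfFixture()
  flank <- AnnSeq(strrep("ACGG", 500), id = "flank")
  r1 <- randomIntegrate(flank, fx$vector, seed = 9L)
  r2 <- randomIntegrate(flank, fx$vector, seed = 9L)
  expect_identical(residues(r1), residues(r2))
  expect_equal(annLength(r1), annLength(flank) + annLength(fx$vector))
  # the inserted copy lacks the ex5 site, so the gap-repair PCR is negative
  ex5 <- primerFromFeature(fx$locus, "ex5")
  hyg <- primerFromFeature(fx$cassettes[[1]]@seq, "hygro_1R_site")
  expect_equal(nrow(inSilicoPCR(r1, ex5, hyg, 15000)), 0L)
})
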