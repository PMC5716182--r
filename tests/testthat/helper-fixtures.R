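# Shared fixtures, cached per test run (construction is deterministic).

tfCache <- new.env(parent = emptyenv())

tfFixture <- function(seed = 42L, ...) {
  key <- paste("fx", seed, ..., sep = "_")
  if (is.null(tfCache[[key]]))
    tfCache[[key]] <- makeTargetFixture(seed, ...)
  tfCache[[key]]
}

tfPanel <- function() {
  if (is.null(tfCache$panel)) tfCache$panel <- designPanel(tfFixture())
  tfCache$panel
}

tfAllele <- function(state, seed = 42L) {
  key <- paste("al", state, seed, sep = "_")
  if (is.null(tfCache[[key]]))
    tfCache[[key]] <- buildAllele(tfFixture(seed), state)
  tfCache[[key]]
}

# Position-by-position brute-force IUPAC scan: the independent oracle for
# scanMotif.
IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "GC", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

bruteScan <- function(seqchar, motif) {
  n <- nchar(seqchar); m <- nchar(motif)
  cls <- strsplit(IUPAC_CLASS[strsplit(motif, "")[[1]]], "")
  hits <- integer()
  if (n >= m) for (i in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!substr(seqchar, i + j, i + j) %in% cls[[j]]) { ok <- FALSE
        break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Brute-force amplicon oracle: all convergent site pairs by direct string
# positions, independent of inSilicoPCR's implementation.
brutePCR <- function(seqchar, fwdSeq, revSeq, maxLen) {
  occ <- function(p) {
    i <- as.integer(gregexpr(p, seqchar, fixed = TRUE)[[1]]); i[i > 0] - 1L
  }
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  sizes <- integer()
  for (f in occ(fwdSeq)) for (r in occ(rc(revSeq))) {
    s <- r + nchar(revSeq) - f
    if (s >= nchar(fwdSeq) + nchar(revSeq) && s <= maxLen)
      sizes <- c(sizes, s)
  }
  for (f in occ(revSeq)) for (r in occ(rc(fwdSeq))) {
    s <- r + nchar(fwdSeq) - f
    if (s >= nchar(fwdSeq) + nchar(revSeq) && s <= maxLen)
      sizes <- c(sizes, s)
  }
  sort(unique(sizes))
}

# Translate a fusion mRNA from its CDS start; returns the aa string up to
# the first stop and whether a stop occurred.
fusionTranslate <- function(allele) {
  m <- spliceTranscript(allele@seq)
  f <- annFeatures(m)
  cds0 <- min(f$start[f$kind == "cds_segment"])
  s <- substr(residues(m), cds0 + 1L, nchar(residues(m)))
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)))
  stopAt <- regexpr("*", aa, fixed = TRUE)
  list(aa = aa, stopAt = as.integer(stopAt),
       upstreamAA = sum(f$end - f$start)[1])
}

# Assemble a pI_hygGFP-style vector with an arbitrary (possibly mismatched)
# cassette, bypassing the frame-selection gate.
buildVectorWithCassette <- function(fx, cassette) {
  donor <- makeTrapDonorPlasmid(cassette)
  gw <- gatewayThreeWay(fx$iv, fx$adaptor, donor)
  post <- suppressWarnings(ssrExcise(gw$product, "loxP"))$main
  linearizeVector(post)
}
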