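---
title: "Modelling second-allele targeted trapping in mouse ES cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling second-allele targeted trapping in mouse ES cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapforge)
```

## What the package models

trapforge is a nucleotide-level simulator of bi-allelic gene ablation in
mouse ES cells by *targeted trapping* of the second allele. Its substrate
is the `AnnSeq` class: a linear or circular DNA sequence carrying typed,
stranded features (exons, recombination sites, cassettes, primer sites,
markers) on 0-based half-open coordinates. Every operation — restriction,
Gateway exchange, Cre/loxP and Flp/FRT excision, single-crossover
insertion with gap repair, random integration — edits residues and
remaps features together, so downstream logic (transcript walks, PCR,
census validation) always reads the current molecular state rather than
a symbolic summary. Features destroyed by an edit are dropped with a
logged reason; they are never silently truncated, because a truncated
feature would misrepresent the biology it stands for.

The cast of molecules:

* **Intermediate Vector** (circular, ~12–15 kb): genomic homology
  G5..G3 with an attR1/attR2 exchange pair in the intron upstream of the
  critical exon, the critical-exon region carrying the rpsL
  counter-selection marker and the downstream loxP, and an
  attR3/backbone/attR4 cassette.
* **Adaptor module**: attL1/attL2 donor whose payload introduces the
  single PmeI linearization site and the upstream loxP.
* **Trap cassette library**: three attL3/attL4 donors whose payloads are
  the splice acceptor – 2A – hygromycin – 2A – GFP – polyA trap in
  reading-frame phases 0/1/2, followed by the plasmid origin and kanR
  that become the backbone of the assembled vector.
* **Knockout-first (tm1a) allele**: FRT–betageo–FRT–loxP upstream of the
  critical exon, loxP downstream.

## The state machine and its invariants

Direct-repeat excision retains a single hybrid site (the segment from
the end of the first site through the end of the second site is
removed). This convention makes the two conversion routes commute
residue-identically:

```
tm1a --Flp--> tm1c --Cre--> tm1d
tm1a --Cre--> tm1b --Flp--> tm1d
```

`validateAllele()` checks a per-state census (counts of FRT, loxP,
betageo, hygro-GFP, critical-exon copies, ex5 sites and homology-arm
copies); the test suite verifies that each constructed state passes its
own census and fails all five others. Inverted-repeat substrates raise
an error rather than inverting: all in-scope constructs use direct
repeats, and a silent inversion would mask fixture bugs.

Gateway exchange operates on typed att features, not sequence motifs;
att cores are 25 nt placeholders (the recombination contract is feature
identity and orientation, and real att sequences are not part of the
model). Product sites are relabelled attB1..attB4, byproduct sites
attP1..attP4, and residues are conserved across the three circles.

## Insertion targeting and gap repair

The assembled vector is recovered through Cre-expressing bacteria: the
floxed critical-exon region (including rpsL) is excised, creating the
gap in the genomic homology, and growth on kanamycin + streptomycin
works only after that excision because loss of rpsL restores
streptomycin resistance in an rpsL-mutant host. Linearization opens the
plasmid with a blunt cut in the middle of the single GTTT/AAAC site;
any extra site in the homology arms is a hard error ("cannot be
linearized intact"), which is exactly what the panel-screening module
classifies.

Integration models the single-crossover outcome directly: the vector
inserts at the gap-template position of the target allele, duplicating
the homology region around the trap cassette, with the gap restored
once from the chromosomal template and the adaptor loxP left at the
repair junction. This yields the auditable contracts

* `length(tm2) = length(allele) + length(vector) + length(gap)`,
* the ex5 primer site (inside the gap) occurs exactly twice in tm2 and
  once in a cell carrying only a random integrant,

both exercised over 100 seeded fixtures. Junction microstructure beyond
the retained loxP (and the re-joined PmeI half-sites) is deliberately
not modelled; nothing observable in the workflow depends on it. A cis
re-target of a tm1a or tm1c allele inserts downstream of the existing
cassette elements; its symbolic state is rendered `tm2` with the event
recorded in the allele's provenance log, and the cis/trans junction
assay is the tool that distinguishes it.

## Expression, selection and essentiality

`expressionOutcome()` walks the transcript from the promoter and
terminates at the first splice-acceptor trap cassette. Reporter logic:

* betageo (lacZ, neo) is modelled **frame-independent**. Whether real
  promoterless betageo reporting depends on frame is an open modelling
  question; the frame requirement is only asserted for the hygro-GFP
  cassette, where the design states it.
* hygro/GFP require the cassette `frame_phase` to equal the end phase
  (cumulative CDS length mod 3) of the last spliced exon, and gene
  expression at or above the trapping threshold — default 1% of the
  transferrin-receptor reference, configurable, the minimum reported
  for targeted trapping to work.
* full-length protein requires an untrapped transcript with the
  critical exon present. This is a structural rule rather than a
  translation of the frameshifted message: a random frameshifted tail
  has a few-percent chance of lacking a stop codon in a short 3' CDS,
  and a simulator should not let that lottery decide nullness.

A genotype is *recoverable* from a selection step iff the drug's marker
is expressed from the resulting cell and the cell is viable; viability
fails only for a ground-truth-essential gene with no full-protein
allele. Essentiality is a fixture-level flag consumed by viability — it
is never inferred from sequence — because the method itself infers
essentiality operationally, from the failure to recover bi-allelic
clones while the same vector targets wild-type cells efficiently. The
simulator reproduces that inference direction.

Truncation products: the released endogenous moiety is
`floor(upstream coding nt / 3)` residues (the 2A elements separate it
from the marker), and count-only masses use the 110.5 Da average
residue mass rounded to integer kDa — which maps 353 aa to 39 kDa and
97 aa to 11 kDa.

## Genotyping model

Primer binding is exact-site lookup in both orientations; no
thermodynamics. The four canonical assays follow the published
placement rules: gf3 lies external (5') to the homology, ex5 inside the
gap, LAR_3 and hygro_1R inside the two trap cassettes, and LR /
R1_amp_F2 are vector-derived sites near the 3' and 5' cassette-region
junctions of the knockout-first allele. The exact sequences and offsets
of the latter two are synthetic stand-ins satisfying the stated binding
rules (R1_amp_F2 between the 3' FRT and the 5' loxP so it survives both
Flp and Cre; LR just 3' of the 3' loxP so it is absent from wild-type
and tm2 templates). Expected band sizes are not hard-coded: the panel
runs each assay on reference alleles built for every state, so the
expected map always matches the fixture geometry. On the default
fixtures the gap assay lands at ~6 kb and the gf3/LR classes at ~10.8
kb (tm1a) versus ~5.8 kb (tm1c), separated by exactly the betageo
cassette plus one FRT.

Clone calling matches the observed band multiset against all
protocol-reachable allele pairs with a ±10% size tolerance (long-range
PCR sizes are approximate). The wild-type/wild-type pair is not a
candidate: an all-absent pattern is reported as a conflict, not a call,
since a screen without a single positive control band is uninformative.
Screening summaries round per-row percents to one decimal and average
duplicate lines per gene before computing unweighted mean/min/max, so a
gene contributes once regardless of how many clones were run.

## The synthetic-data generator

`makeGeneLocus()` emulates an expressed multi-exon locus: by default
five exons over ~12 kb, a promoter-bearing 5' region, a critical exon
whose length is forced to 1 mod 3 (so its deletion frameshifts), and
fixed intron sizes around the critical exon giving a ~3.7 kb 5' arm, a
~1.6 kb gap and a ~4.7 kb 3' arm. These sizes were chosen once so that
the gap assay sits in the published ~6–7 kb class and the gf3/LR size
classes are cleanly separated, while a locus still generates in ~0.1 s;
they are deliberately larger than a minimal toy but far below real
mouse loci. The CDS is stop-free in frame 0 only: a planted 9 nt block
immediately after the ATG carries stop codons in both shifted frames,
and the same guard starts every cassette ORF, so 3-frame translation is
a sharp oracle for the frame rule. The `phaseTarget` argument adjusts
the exon downstream of the critical exon so the end phase at the
homology boundary takes any requested value.

Two numerical safeguards keep motif arithmetic exact at every seed:
assembled genomic sequences are scrubbed of spurious GTTT/AAAC
occurrences (the substituted base is a C, which can never create a stop
codon), and every synthetic building block starts with G and ends with
C — since the PmeI motif has its only G first and its only C last, no
junction between blocks can assemble the motif across a boundary. Extra
PmeI sites are therefore exactly the planted ones, which is what makes
the planted-truth panel recovery exact rather than approximate.

What the generator does **not** emulate: real mouse sequence
composition, repeat structure, splice-site motifs, crossover-position
variability within arms, or partial/imperfect recombination products.
Passing tests therefore demonstrate that the workflow logic is
internally consistent and faithful to the stated contracts — not that
any particular wet-lab efficiency would be reproduced on real loci. In
the same spirit, per-gene targeting percentages in generated screen
tables are binomial draws around user-supplied probabilities, and the
published 11.5% unsuitable-vector fraction is used only as the default
planting probability of the panel generator, not as a number the
simulation claims to derive.

## Stochastic model

Cre leak and escaper behaviour are per-cell Bernoulli events:
`induce_4oht` converts tm1c-carrying cells with probability
1 − escaper_rate, and once CreERT2 is present every uninduced step
converts with the leak rate. Population trajectories in
`simulateProtocol()` propagate exact fractions; `simulateInduction()`
draws binomial counts under the given seed for finite platings, and the
suite checks that observed escaper fractions over 1e5 cells sit within
three binomial standard deviations of rates 1e-2 and 1e-3. When a
selection step recovers both a cis event and the desired second-allele
event (possible for tm1c/+ lines), the protocol keeps the second-allele
clones, mirroring the cis/trans PCR triage a bench scientist performs.

All generator and simulation entry points take explicit seeds; RNG
state is scoped with an internal `withSeed()` so library calls never
disturb the caller's stream.

## Problem sizes and limitations

The shipped tests run the motif-scan oracle on dozens of seeded
sequences, the recombinase algebra on 50 loci, the gap-repair contract
on 100 full fixtures, the planted-PmeI screen on a 1000-design panel,
and the end-to-end pipeline round trip on three fixtures × three
starting genotypes; `scripts/acceptance.R` recomputes the same
quantities (with a 200-design panel) under a caller-supplied seed.

Known limitations: recombination efficiency and kinetics are not
modelled (events either happen or are enumerated as alternatives);
double-crossover replacement targeting is out of scope (the tm1a allele
is consumed pre-built); GenBank I/O covers the package's own dialect
(standard keys plus typed qualifier tags) rather than the full flat-file
grammar; and bacterial selection is a marker-presence truth table, not
a growth model.
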