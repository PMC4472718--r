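---
title: "Methods: multiplex panel screening and artificial positive control design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex panel screening and artificial positive control design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apctools)
```

This vignette records the models, conventions and design decisions behind
`apctools`, in the spirit of a lab notebook for maintainers: what each
computation assumes, which knobs matter, and what the shipped tests do and
do not demonstrate.

## Oligo thermodynamics

**Melting temperature.** `nn_tm()` implements the unified nearest-neighbor
duplex model: enthalpy and entropy are summed over the oligo's dinucleotide
stacks plus terminal-pair initiation terms, with a symmetry correction for
self-complementary sequences, and

$$T_m = \frac{\Delta H}{\Delta S + R\,\ln(C_T/x)} - 273.15,$$

where $C_T$ is total oligo concentration and $x$ is 4 for
non-self-complementary duplexes. Salt enters through the entropy correction
$\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$, with divalent
cations folded into an effective monovalent concentration as
$120\sqrt{[\mathrm{Mg}^{2+}]\,(\mathrm{mM})}$. Defaults — 50 nM oligo,
50 mM monovalent, no divalent — approximate common primer-design software
settings. Published oligo tables rarely state the exact software version
and ionic settings behind their printed Tm column, so the shipped panel's
Tm values are carried as metadata and compared only loosely; the package's
own tests validate `nn_tm()` against a hand-summed stack ledger and
structural properties (reverse-complement symmetry, monotonicity in salt,
GC > AT stabilization) instead.

**Self- and cross-complementarity.** `self_any_score()`,
`self_end3_score()` and `cross_dimer_score()` count Watson–Crick pairs in
the best ungapped antiparallel alignment of two oligo copies; the 3'
variant restricts to alignments in which one copy's 3'-terminal base is
inside the paired window (the configurations that can self-prime). G:T
wobbles never count. These are deliberately transparent integer scores:
commercial "ANY"/"3'" columns use version-dependent alignment weights, so
the package verifies its scores against brute-force enumeration rather
than against any printed table. For intuition, random 20-mers typically
score 6–9; the compatibility report's flag threshold defaults to 12, the
same length as the "extensive match" spacer screen below, and a primer
paired with its own reverse complement scores its full length.

**Hairpins.** `hairpin_dg()` enumerates every *single* stem-loop fold
(stem of at least two contiguous pairs, loop of at least three bases) and
returns the most negative sum of nearest-neighbor stack free energies at
37 °C plus a loop-length penalty (3.5/3.5/3.3/4.0/4.2/4.3/4.5 kcal/mol for
loops of 3–9 nt, Jacobson–Stockmayer extrapolation beyond). It reports
nothing when no fold is stabilizing. This is a screening surrogate: no
bulges, internal loops, coaxial stacks or multibranch folds, so its values
are not numerically comparable to full folding programs — only the sign
and ranking are meant to be used.

## In-silico PCR

Coordinates are 1-based inclusive on the plus strand, and an amplicon
includes both primer footprints: length = reverse-site end − forward-site
start + 1. Binding sites accept `max_mismatch` mismatches but require a
perfect match over the `clamp3` 3'-terminal bases (defaults 0 and 3: the
specificity semantics of a validated diagnostic panel are exact-match;
the mismatch budget exists for exploring near-neighbor decoys).
Amplicon prediction is strand-symmetric — a plus-strand forward hit
upstream of a minus-strand reverse hit, or the mirror configuration —
because PCR cannot tell which strand a construct designer called "plus".
All productive pairings are reported; being single-product is a design
property to verify, not an assumption. Circular templates are searched on
the doubled sequence with site starts confined to the first copy, and
origin-spanning products are recovered by letting the downstream partner
sit in the second copy; products are capped at the template length, so
doubling never duplicates a product. Probes never act as extension
primers; `locate_probe()` demands a unique exact site strictly inside the
amplicon and (by default) clear of both primer footprints. The virtual gel
simply orders sizes and flags adjacent bands closer than `min_separation`
(default 20 bp, a conservative agarose resolution at these sizes).

## APC construct layout

Each target contributes one block carrying its endpoint ("outer") pair
and, when present, its qPCR ("inner") pair and probe. Five geometries
cover the cases a real oligo set produces:

* **single** — one pair serves both reactions (forward … probe … reverse);
* **shared_rev / shared_fwd** — inner and outer pairs share one primer,
  so the shared site serves both amplicons;
* **nested** — fully distinct pairs, inner amplicon strictly inside;
* **staggered** — the outer forward primer's sequence is contained in the
  reverse complement of the inner reverse primer. Planting both sites
  separately would give the outer forward two exact matches (and a second,
  spurious endpoint product), so the two sites are merged: the outer
  amplicon starts inside the inner-reverse footprint. The shipped panel's
  *L. bostrychophila* assays force exactly this case.

Spacer lengths are solved exactly so every requested size is hit to the
base; the minimum spacer between functional elements is 2 nt. Requested
sizes must be pairwise distinct per reaction type, with a minimum gap of
20 bp for endpoint sets (gel discrimination) and 0 for qPCR sets
(channel-discriminated). Probes are embedded on the plus strand as written
(a flag allows minus-strand embedding); either way the probe hybridizes to
one strand of the amplicon, which is all hydrolysis chemistry needs.

**Spacers and barcodes.** Spacer fill is GC-balanced (40–60%) random
sequence screened, on both strands, against every panel oligo's
3'-terminal 8-mer and every 12-mer window of every panel oligo — the two
mispriming routes that matter (extension from a seeded 3' end; stable
annealing anywhere). Each block's longest spacer carries a 12-nt barcode,
pairwise Hamming distance ≥ 4, so every amplicon has a unique identifiable
interior even when its size equals the genomic product (the shipped panel's
*L. brunnea* assay is 140 bp on both; verification flags this
informationally, since the barcode — not the size — provides the
discrimination). Screens cannot see element–spacer junctions, so the
designer loops: synthesize, assemble, verify, and re-synthesize spacers
(deterministically, seed + attempt × 7919) until verification passes.

**Cross-assay products and block ordering.** On a single molecule, some
convergent pairing between primers of different assays always exists —
whatever the orientation pattern, a rightward-extending site lies upstream
of some leftward-extending site. "No cross-assay product" is therefore
enforced up to a length ceiling, defaulting to the largest designed size
in the reaction: any cross product at or below that length would be
confusable with a designed band (endpoint) or compete efficiently (qPCR),
while longer ones amplify poorly under short-cycle protocols and are
reported informationally. To push cross products above the ceiling the
assembler alternates block orientation (adjacent blocks meet
divergently) and chooses the block order — exhaustively for up to eight
blocks — maximizing the shortest possible cross product, computed from
each block's primer-site margins per reaction tube (including merged
staggered sites). Verification is per reaction tube: endpoint-use and
qPCR-use primers never share a reaction, which is also what makes the
*L. bostrychophila* staggered geometry sound (its 8F×7R combination never
co-occurs). For the shipped panel the shortest possible cross product is
408 bp against the 322-bp endpoint ceiling and 246 bp against the 140-bp
qPCR ceiling.

Verification then asserts, from the assembled sequence alone: exactly one
product per assay at its designed size; every probe strictly between its
primers; no cross product at or below the ceiling; exactly one exact-match
site per multiplex oligo (the uniqueness scan covers only the multiplex
set — the panel's single-PCR primers may legitimately overlap probe
complements, e.g. BruCo6R inside the BruCo5P complement); and pairwise
distinct amplicon interiors.

## Channels and compatibility

Dyes are assigned to the acquisition channel nearest their emission; the
assignment must be injective and all emissions pairwise ≥ 25 nm apart —
below the smallest gap in the shipped dye set (520/554/602/667/705 nm,
minimum gap 34 nm) but far above instrument bandwidth. The five channel
centers (green 470/510, yellow 530/555, orange 585/610, red 625/660,
crimson 680/712 nm) are instrument constants shipped as an editable table.
Primer Tm uniformity is checked against a ±3 °C window around the shared
annealing temperature (60 °C), matching the spread a single-annealing-step
multiplex tolerates.

Compatibility findings are prompts for human review, not automatic
failures: the shipped panel itself trips the cross-dimer flag because
BosCo7F is complementary to BosCo8R over its full 21 bases — a deliberate
consequence of the two assays overlapping the same genomic locus, and the
same containment that forces the staggered APC geometry above.

## qPCR standard curves

Fits are ordinary least squares of Ct on log10(template amount in ng),
on per-dilution replicate means by default because published tables print
means; `per_replicate = TRUE` fits all replicates (identical slope on
balanced designs, slightly different R²). Efficiency is
$10^{-1/\mathrm{slope}} - 1$, reported as a fraction. Replicate SD uses
the sample (n−1) convention and is absent for single replicates. The
detection limit is the smallest amount at which all (default) or any
replicates report a finite Ct; non-template controls are rows without an
amount. Refitting printed means reproduces printed slopes only to the
rounding of those means — the shipped reference table's second master-mix
slopes differ in the third significant figure from their printed values
for exactly this reason, while the efficiencies still agree at two
decimals — so only mean-level agreement at ±0.01 is asserted.

## Synthetic fixtures: what they do and do not show

The generators produce GC-balanced random backgrounds with verbatim
planted primer sites (`make_planted_template()`), near-neighbor decoys
derived from them by transversions at chosen positions counted from the
3' end (`make_decoy_template()`), an exclusivity set of five targets,
eight decoys, an out-group and a host analogue, and Gaussian-noise Ct
series (`simulate_ct_series()`, Ct = intercept + slope·log10(amount) +
N(0, σ)). All are deterministic under a mandatory seed.

These fixtures emulate the *logic* of a validation panel — site presence,
3'-clamp failures, dilution linearity — not real genomes: they have no
phylogenetic structure (real near-neighbors differ by scattered
substitutions, not designed ones), no secondary targets, no mitochondrial
copy-number effects, and Ct noise is homoscedastic whereas real low-copy
dilutions show inflated variance and stochastic dropout near the detection
limit. A diagonal fixture matrix therefore demonstrates that the search
and verdict machinery is correct, not that any particular wet panel is
specific; that evidence can only come from the corresponding laboratory
exclusivity panel. Simulation sizes used in the tests (σ = 0.15 cycles,
3 replicates, 7 ten-fold dilutions, 200 seeds; ~500 fuzzed oracle
instances; ≤ 2 kb fuzz templates) were chosen to estimate the relevant
statistics comfortably — e.g. the theoretical slope SE at those settings
is σ/√(replicates × Σ(x−x̄)²) ≈ 0.016 cycles per decade, so a mean
absolute error bound of 0.05 is a wide, stable margin.

## Numerical and degenerate-input conventions

* GC% is reported to one decimal, the precision oligo tables print.
* Scores are integers; ties among equally good alignments are irrelevant
  because only the maximum is reported.
* `hairpin_dg()` returns `NA` (rather than a positive number) when no
  stabilizing fold exists, keeping the "present implies ≤ 0" invariant.
* Templates shorter than the oligo yield an empty hit list, not an error;
  an empty FASTA yields an empty template list.
* Fits require ≥ 3 distinct amounts and finite Ct values; a non-negative
  fitted slope is an error, not a silent efficiency > 10.
* Auto APC sizing lays outer sizes on an even grid over the configured
  range (largest feasible block gets the largest size) with inner blocks
  at their minimal feasible size; explicit size requests are validated per
  reaction type.

## Known limitations

* The hairpin model is a single-stem screen, not a folding algorithm.
* Tm reproduction of any particular software's printed values is
  approximate by nature (version- and settings-dependent).
* Cross-dimer scores ignore position-dependent weighting (a 3'-anchored
  cross score is available only through the self 3' variant).
* The APC designer guarantees "no cross product up to the ceiling", not
  the physical impossibility of longer products; the ceiling and the
  verification report make that trade-off explicit.
* Amplification kinetics, electrophoretic mobility and fluorescence
  crosstalk are out of scope throughout: sizes, sites and Ct values are
  the modeled observables.
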