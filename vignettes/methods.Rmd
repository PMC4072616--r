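---
title: "Free-energy screening of SNPs in pre-miRNA hairpins: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy screening of SNPs in pre-miRNA hairpins: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnpscan)
```

## The biological model

A canonical miRNA matures in two cuts: Drosha excises the hairpin
precursor from the primary transcript, and Dicer trims it to the ~22-nt
mature duplex.  Two structural properties of the hairpin gate the first,
rate-limiting cut: a large, unstructured terminal loop and a stable
double-stranded stem around the Drosha cleavage sites.  A third property
gates function after maturation: stable base pairing between the mature
miRNA and the 3'UTRs of its targets.

A single-nucleotide substitution can break any of the three.  The package
therefore splits each hairpin into three segment classes and scores a
variant by the free-energy change, ddG = dG(mutant) − dG(wild type), of
its own segment:

* **terminal loop** — the loop sequence is folded alone
  (`dg_terminal_loop()`).  A substitution that lets loop bases pair
  shrinks the loop, which is read as *lower* free energy, so causal loop
  variants have **ddG < 0**.
* **extension duplex** — the ~25-nt arms flanking the mature duplex are
  joined by the linker `GGCGGGG` into one strand and folded
  (`dg_extension_duplex()`).  The linker is a folding trick that lets a
  single-strand engine score a two-strand duplex; it is excluded from
  mutagenesis and loop accounting.  Causal variants break stem pairs:
  **ddG > 0**.
* **mature duplex** — the mutated arm is hybridized against each target
  gene's 3'UTRs; per gene the best (minimum-energy) isoform counts and
  the per-gene minima are averaged (`dg_mature()`).  Causal variants
  weaken target binding: **ddG > 0**.

Every position covered by a segment is substituted with all three
non-reference bases (`enumerate_artificial()`), and known SNPs are merged
into that universe so that known and artificial variants are scored on an
equal footing.  A base in the overlap of two segments belongs to both and
is scored once per class.

## Segmentation details

Arm coordinates come from the annotation when available.  When only one
arm is annotated, the star arm is placed by an ungapped complementarity
scan under the 2-nt 3'-overhang geometry of Drosha/Dicer processing
(`infer_star_arm()`): a Watson–Crick pair scores 1, a G·U wobble 0.5, and
ties prefer the placement with the larger terminal loop (large loops favor
processing), then the most 3' placement.  This is the simplest testable
reading of "good complementarity"; a gapped alignment would add parameters
without changing where near-perfect stems place the arm, and on perfectly
complementary synthetic stems the scan recovers a hidden arm exactly.

The loop is the interval strictly between the arms.  When an annotation
leaves no such interval (arms abut), the loop is taken from the predicted
MFE structure of the whole hairpin — the 3'-most hairpin loop — because
annotation and structure are the two sources of loop evidence and the
second is always available.  Extension arms are capped at 25 nt per side
(configurable `ext_size`); the cap reflects the approximate span of the
Drosha cleavage context, and the exact value matters little because distal
extension bases contribute little to the linked fold.

## Thermodynamic backends

All energies flow through a two-function contract (`fold_mfe()`,
`hybridize_mfe()`), with two adapters:

* **vienna** (default): ViennaRNA's `RNAfold` and `RNAduplex` at 37 °C,
  minimum hairpin loop 3, the full nearest-neighbor parameter set.  The
  engine version is echoed into every run manifest because MFE structures
  of marginal sequences can move between parameter sets.  `RNAduplex`
  implements exactly the intended hybridization model: intermolecular
  pairs only, no intramolecular structure in either strand.
* **basic**: a built-in Nussinov-style scorer with coarse pair energies
  (G-C −3, A-U −2, G·U −1 kcal/mol, stacking bonus −1, minimum loop 3) and
  a matching intermolecular duplex dynamic program.  Its absolute energies
  are uncalibrated, but it preserves what the screening logic consumes —
  the sign and ordering of pair gain/loss — and it keeps the unit-test
  suite fast.  Sign-level conclusions are checked on both adapters.

Both adapters apply an open-chain floor: a sequence (or hybrid) whose best
structure is not stabilizing scores exactly 0 with an all-unpaired
structure.  This makes "the variant decreases free energy" well defined
for loops that are unstructured in the wild type.  `loop_size()` reads the
number of unpaired bases enclosed by the innermost pair of the 3'-most
hairpin loop; an unpaired chain counts its full length.

## Candidate calling

Within each class, variants passing the direction filter (loop ddG < 0;
mature/extension ddG > 0; zeros dropped) are ranked by |ddG|, ties broken
by (hairpin, position, alt) for determinism.  The cumulative fraction of
the total ddG is computed along the ranking, and the cutoff is the knee of
that curve: the rank with maximum perpendicular distance from the chord
joining the first point to (N, 1), first rank on ties.  The knee rule is
parameter-free, deterministic, and scale-invariant (multiplying all ddG by
a constant changes nothing); a marginal-contribution threshold would need
a tuned constant instead.  A Welch t-test (`compare_known_artificial()`)
summarizes whether known and artificial candidates differ in effect size;
"t-test" admits both pooled and unpooled variants and Welch is the safer
default under unequal group sizes.

## Burden ranking

Candidates are re-ranked by population impact, score = frequency × ddG,
with frequencies resampled per round: a known variant with a recorded
minor allele frequency keeps it; a known variant without one draws
Uniform(f_min, f_max) over the recorded range; an artificial variant draws
Uniform(0, f_min) on the open interval — never having been observed, it
should be rarer than anything observed.  Per round and per class, the
variants are sorted by |score| and the minimal prefix covering 50% of the
class's score mass is selected (class totals are sign-segregated: loop
scores are negative, duplex scores positive).  After 1000 rounds a variant
selected in at least 95% of them (`1 − alpha`) is a burden variant.  The
50% threshold is applied per class, matching the sign-segregated totals; a
pooled variant is available through the class labels.  The selection
frequency across resamples is the operational reading of selection
"significance": it uses all 1000 rounds and needs no distributional
assumption.

## Synthetic data: what it emulates and what it does not

`make_hairpin()` builds `5'ext + arm + loop + revcomp(arm) + 3'ext` with
perfectly complementary arms at a chosen GC fraction (default 0.5, a
typical precursor composition), an A/C-only loop (unpairable by
construction, emulating the unstructured loop of a good Drosha substrate;
default 16 nt, a realistic large loop), 25-nt extension arms that are
mutual reverse complements, and the annotated 3p arm shifted 2 nt
downstream of the exact complement — the 2-nt 3' overhang — so star-arm
inference is testable against ground truth.  Default stem length is 22 nt,
the canonical mature-arm length.  `make_target_utrs()` plants a
(optionally degraded) reverse-complement binding site in 200–600-nt random
UTR isoforms, 1–3 per gene.  `make_planted_scenario()` assembles three
hairpins with variants of known effect direction: a loop-shrinker that
completes a 4-bp stem inside the loop, an extension pair-breaker (a stem
G or C flipped to its own complement), a mature seed-breaker against
perfect-match targets, and neutral substitutions inside unpaired A-runs.
`make_burden_benchmark()` plants 5 high-maf/high-ddG variants among 195
noise variants whose worst planted score (0.15 × 6) still exceeds the best
achievable noise score (0.3 × 2), so recovery is expected and deviations
indicate implementation faults, not luck.

Real data differ in ways the generator does not model: imperfect stems
with bulges and internal loops, wobble-rich duplexes (available only via
`wobble_rate`), annotation errors, dbSNP-like frequency spectra (the
generator draws uniform mafs), and UTR base composition.  Passing tests
therefore establish the correctness of the machinery and the qualitative
behavior of the scores, not quantitative performance on real precursors.

## Numerical choices and degenerate inputs

* Energies are kept at the engine's printed precision (0.01 kcal/mol);
  no further rounding happens before report formatting (2 decimals for
  percentages and per-kb rates, 1 for ddG summaries).
* The knee and the half-mass prefix use exact comparisons except for a
  1e-9 tolerance when locating the knee's maximum, which absorbs
  floating-point noise on perfectly linear curves.
* Identity substitutions are rejected outright (`alt == ref` is an
  error), so ddG = 0 rows can only arise from genuinely neutral variants.
* A hairpin with no annotated arm, arms that overlap, or an arm flush
  with the hairpin end (empty extension) is a hard error: each indicates
  a broken annotation rather than a scorable record.
* A run with no known-frequency variant has no sampling range; burden
  ranking stops with an error unless a fallback `freq_range` is
  configured.
* Monte-Carlo rounds draw frequencies independently; with
  all-known-frequency inputs the procedure is deterministic and selection
  frequencies are exactly 0 or 1.

## Problem sizes and reproducibility

The shipped tests and examples run on 3-hairpin bundles (~110 nt each,
~600 variants end-to-end), where a full pipeline run with the ViennaRNA
backend takes a few seconds; the burden benchmark uses 200 variants × 1000
rounds × 20 seeds.  These sizes exercise every code path while keeping the
suite quick; the machinery itself is linear in the number of variants and
target UTRs.  Every stochastic step takes a seed, and a pipeline run
writes a manifest (backend and engine version, linker, extension size,
iterations, alpha, seed, input checksums) sufficient to reproduce its
outputs byte for byte.

## Known limitations

* Loop sizes predicted by MFE folding are often smaller than the loops
  observed in vivo, so loop-class screening is conservative; this is a
  property of MFE prediction, not of the implementation.
* The hybridization model scores the best site only; it ignores site
  accessibility, multiple-site synergy, and seed-centric weighting that
  dedicated target predictors apply.
* Counts of candidates (knee cutoffs) depend on the folding engine's
  parameter set; the manifest pins the version for that reason.
* No multiple-testing correction is applied at the calling stage; the
  burden stage's stability criterion is the only error control.
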