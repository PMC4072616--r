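# mirsnpscan

Free-energy screening of single-nucleotide variants in pre-miRNA
hairpins.

## The problem

Single-nucleotide substitutions in a miRNA precursor can be pathogenic in
two ways: by blocking maturation (Drosha needs a large unstructured
terminal loop and a stable stem around its cleavage sites) or by weakening
the mature miRNA's binding to its target 3'UTRs.  Both mechanisms are
structural, so both leave a thermodynamic footprint.  `mirsnpscan` screens
every possible substitution in a set of disease-associated hairpins — plus
any catalog of known SNPs — by the free-energy change of the segment the
variant falls in, and ranks the results down to a short list of putative
causal variants and a shorter list of variants likely responsible for most
affected cases in a population.  It is aimed at analysts who have a list
of disease-associated miRNAs and want candidate variants without
case–control data or assays.

## The method

Each hairpin is segmented into **terminal loop**, **mature duplex** (5p +
3p arms), and **extension duplex** (≤ 25 nt flanking each arm); a missing
arm is placed by a complementarity scan under the canonical 2-nt 3'
overhang.  For every variant *v* in segment *S*,

> ΔΔG(v, S) = ΔG(S with v) − ΔG(S),

where ΔG is: the MFE of the loop folded alone (loop class); the MFE of the
two extension arms joined by the linker `GGCGGGG` (extension class); or
the mean over target genes of the minimum RNAduplex-style hybridization
energy over each gene's 3'UTR isoforms (mature class).  Causal directions
are ΔΔG < 0 for loops (the loop shrinks) and ΔΔG > 0 for duplexes (pairs
break).  Direction-filtered variants are ranked by |ΔΔG| per class and cut
at the knee of the cumulative-contribution curve (max distance to chord).
Candidates are then re-scored 1000 times as `frequency × ΔΔG` with minor
allele frequencies resampled by origin category (recorded maf kept; known
variants without one drawn in the recorded range; artificial variants
drawn below the smallest recorded maf); variants inside the top-50%-of-score-mass
set in ≥ 95% of rounds are burden calls.

Folding runs through ViennaRNA (`RNAfold`/`RNAduplex`, the default
backend) or a built-in simplified Nussinov-with-stacking scorer used by
the fast tests.

## Worked example

Everything below is generated in code — no downloads:

```r
library(mirsnpscan)

sc <- make_planted_scenario(seed = 1)   # 3 hairpins, planted causal SNPs
en <- compute_energy_changes(sc$hairpins, sc$segments, sc$snps,
                             sc$target_map, backend = "vienna")
dplyr::select(en, snp_id, segment_class, dg_wt, dg_mut, ddg)
#>   snp_id         segment_class dg_wt dg_mut   ddg
#> 1 planted_loop   loop            0     -5.1  -5.1
#> 2 neutral_1      loop            0      0     0
#> 3 planted_ext    extension     -47.6  -44     3.6
#> 4 neutral_2      loop            0      0     0
#> 5 planted_mature mature        -46    -40     6
```

The planted loop-shrinker stabilizes its loop by 5.1 kcal/mol (negative,
causal for the loop class), the extension pair-breaker and the seed-breaker
destabilize their duplexes by 3.6 and 6.0 kcal/mol (positive, causal), and
the neutral substitutions change nothing.  Calling and burden ranking:

```r
calls <- select_inflection(direction_filter(en))
b <- monte_carlo_burden(calls, iterations = 1000, seed = 42)
tidy(b)[, c("snp_id", "segment_class", "ddg", "maf", "selection_frequency", "burden")]
#>   snp_id         segment_class   ddg   maf selection_frequency burden
#> 1 planted_ext    extension       3.6 0.113                   1 TRUE
#> 2 planted_loop   loop           -5.1 0.183                   1 TRUE
#> 3 planted_mature mature          6   0.245                   1 TRUE
```

All three planted variants are selected in 100% of the 1000 resampling
rounds.  `autoplot(calls)` draws the cumulative-contribution curves with
the knee cutoffs; `autoplot(b)` the selection-frequency stability plot.
`run_pipeline()` (or the `inst/cli/mirsnpscan` script) chains the whole
thing from a YAML config and writes TSVs plus a manifest that reproduces
the run byte for byte.

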