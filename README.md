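# sievepool

Downstream analysis of DNA metabarcoding data from **size-sorted bulk
arthropod samples**, such as Malaise trap catches.

Bulk invertebrate samples mix specimens spanning several orders of magnitude
in body mass. Because read abundance loosely tracks biomass, a handful of
large specimens can swamp a sequencing library and leave many small taxa
undetected. A common remedy is to sieve the dried sample into size fractions
(S < 2 mm, M > 2 mm, L > 4 mm, XL > 8 mm), lyse each fraction separately and
pool the lysates in proportions that *enrich* the small fractions before one
DNA extraction. `sievepool` implements the quantitative machinery for
evaluating such designs:

- **OTU-table quality filtering** — subtract the per-OTU maximum read count
  observed in negative controls; zero counts strictly below a per-sample
  relative-abundance threshold (default 0.01 %); zero counts not present in
  both extraction replicates; merge replicate pairs by summation.
- **In silico pooling** — mix per-fraction compositions under named lysate
  strategies (`g` dry-weight-proportional, reconstructing an unsorted
  sample; `equ` equal; small-enriching `invg`, `fibo`, `4x`, `log`), sweep
  the S+M : L+XL mixing ratio in 5 % steps at 10,000 reads, and pool the
  four fractions at quarter depth (0.04 % per-fraction threshold).
- **Threshold-based rarefaction** — simulate a sequencing depth *d* by
  keeping OTUs with relative abundance ≥ 100/*d* percent (no resampling
  noise), and derive **depth-equivalence factors**: how much more deeply an
  unsorted sample must be sequenced to match a size-sorted strategy's
  richness.
- **Community summaries** — per-OTU size-class assignment (argmax of the
  relative read abundances combined across samples per fraction), size-class
  spectra, fraction-sharing histograms, Jaccard / Bray–Curtis dissimilarity
  with UPGMA dendrograms (Newick export).
- **A forward simulator** of the whole experiment — lognormal rank
  abundances, lognormal body lengths, allometric dry weights
  (w = 0.0305·L^2.62 mg), sieving with an effective-width retention rule and
  fragment carryover between fractions, biomass-proportional multinomial
  read generation with fixed per-species primer bias, extraction replicates
  and Poisson-contaminated negative controls — yielding OTU tables with
  known ground truth for validating every analysis stage.

## Worked example

```r
library(sievepool)

scen <- simulate_scenario(sim_config(), seed = 1)
scen
#> sim_scenario (seed 1): 300 species, 69 libraries

filtered <- quality_filter(scen$table)
attr(filtered, "filter_log")
#>         step reads_removed otus_removed
#> 1  negatives          2884           14
#> 2  threshold             0            0
#> 3 replicates          1304           22

ev <- evaluate_scenario(scen)
aggregate(richness ~ strategy, ev$richness, mean)
#>   strategy richness
#> 1       4x 185.3333
#> 2      equ 168.3333
#> 3     fibo 185.6667
#> 4        g 124.6667
#> 5     invg 179.3333
#> 6      log 167.6667
```

The dry-weight-proportional pool `g` — the reconstruction of an unsorted
sample — recovers far fewer OTUs (125) than equal pooling (168) or the
small-enriching strategies (180–186): the biomass of a few large specimens
crowds small taxa below the detection threshold.

```r
ev$sweep
#>    source best_pct_small best_pct_large interior
#> L1     L1             95              5     TRUE
#> L2     L2             80             20     TRUE
#> L3     L3             80             20     TRUE
```

Splitting each sample into just two composites (S+M vs L+XL) and mixing them
in silico, recovery peaks when 5–20 % of the large composite is added to the
small one — an interior optimum: neither pure composite is best.

```r
round(ev$spectrum, 2)
#>          S          M          L         XL unassigned
#>      58.50      24.11       9.88       1.98       5.53
ev$recovery_pct
#> [1] 95.8
```

Most OTUs are assigned to the small size classes, a few percent only appear
in pooled libraries (unassigned), and the assignment recovers the
simulation's ground-truth size class for ~96 % of detected species.

A complete run — filtering, pooling, rarefaction, summaries, manifest — can
be driven from one YAML file with `run_pipeline()`, or from a shell via the
thin front end `inst/cli/sievepool.R` (`run` and `simulate` subcommands).

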