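---
title: "sievepool: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sievepool: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sievepool` analyses OTU tables from size-sorted bulk arthropod samples and
ships a forward simulator of the full experiment so that every analysis
stage can be validated against known ground truth. This vignette documents
the underlying models, the parameters that matter, the numerical rules, and
what the simulation does and does not establish about real data.

## The quality-filtering model

An OTU table holds integer read counts (OTUs × libraries) with each library
labelled as a size-fraction library (S, M, L or XL), a pooled-lysate library
(one of six pooling strategies), or a negative control. Cleanup runs in a
fixed order:

1. **Negative-control subtraction.** For each OTU the maximum count over all
   control libraries is subtracted from every other library, flooring at
   zero; controls are then dropped. The maximum (not the mean) is used so a
   single badly contaminated control is enough to discount an OTU's signal
   at that level everywhere.
2. **Relative-abundance threshold.** Within each library, counts whose share
   of the library total is *strictly below* the threshold (default 0.01 %)
   are zeroed. Column totals are computed once, before any zeroing: the
   filter is a single pass. Recomputing totals iteratively would let
   removals cascade unpredictably; with totals frozen the filter is
   idempotent. A count sitting exactly at the threshold survives — the same
   boundary convention is used everywhere in the package.
3. **Replicate consistency and merging.** Each library is extracted twice;
   an OTU count present in only one replicate is treated as unreliable and
   zeroed in both. Surviving replicate pairs are merged by summation, which
   preserves depth semantics.

OTU rows left empty are dropped only at the end, so the per-step log of
reads and OTUs removed remains interpretable. The step order can be
permuted via an argument, but only for sensitivity analysis; the default
order is the one the pipeline is specified and tested for. At a library
depth of exactly 10,000 reads the 0.01 % cut equals one read, so step 2
removes nothing that sampling has not already removed — detection is then
governed by the multinomial sampling and the replicate-consistency rule,
which is the intended regime.

## In silico pooling

Per-fraction libraries are converted to relative abundances and mixed over
the union of their OTU ids (absent = 0):

- `pool_by_scheme()` computes `profile_i = Σ_f scheme_f · relabund_{f,i}`
  for a proportion vector over fractions summing to 1.
- `pool_by_weight()` uses dry-weight shares `w_f / Σ w`, reconstructing the
  composition an unsorted sample would have produced: the lysis buffer
  volume tracks tissue weight, so DNA concentration is uniform across
  lysates and volume shares weight fractions directly.
- `two_fraction_sweep()` mixes a small (S+M) and a large (L+XL) composite
  from 100 % small to 0 % small in 5 % steps, thresholds the mixture at
  0.01 % (0.01 % of 10,000 expected reads is exactly one read) and records
  surviving richness per ratio. Thresholding operates on fractional
  expected counts — no rounding — to avoid arbitrary integer ties.
- `equal_quarter_pool()` filters each of the four fractions at 0.04 % of
  its own total (the 0.01 % cut at quarter depth) and counts the union of
  survivors.

Built-in strategy proportions: `g` = dry-weight shares, `equ` = ¼ each,
`4x` = (64,16,4,1)/85 (each smaller fraction four times the next larger),
`log` = (1000,100,10,1)/1111, `invg` = normalised reciprocals of the
dry-weight shares, and `fibo` = Fibonacci shares (5,3,2,1)/11. Only `g` and
`equ` follow from first principles; the other vectors are conventional
small-enriching defaults and are freely overridable — analyses relying on
exact proportions should supply their own `pooling_scheme()`.

## Threshold-based rarefaction

A simulated sequencing depth *d* is realised by the deterministic cut
`threshold_for_depth(d) = 100/d` percent (one expected read at depth *d*):
an OTU survives iff its relative abundance reaches the cut. This replaces
resampling-based rarefaction, removing its stochastic noise entirely;
survivor sets are nested in depth by construction, so recovery curves are
monotone. Curves are computed on a log-spaced grid (19 points from 500 to
50,000 reads by default).

The **depth-equivalence factor** of a strategy is `reference_depth / d*`,
where `d*` is the smallest *grid* depth at which the strategy matches the
reference strategy's richness at the reference depth (default: `g` at
50,000 reads). Lookup is deliberately grid-based, not interpolated:
interpolation would imply precision the discrete curves do not have. A
strategy that never reaches the target is reported as "not reached" rather
than extrapolated.

Two upstream preparations are supported and recorded in provenance,
because they answer different questions: `"fig3"` mode sums replicate pairs
directly (no consistency rule, no 0.01 % filter), maximising the dynamic
range of the curves; `"filtered"` mode rarefies the quality-filtered
tables. The package default for strategy comparisons is `"fig3"`.

## Size-class assignment and summaries

For every OTU, its relative read abundances in the individually sequenced
fraction libraries are summed across source samples, per fraction
("combined"), giving a four-component evidence vector; the assigned class
is the argmax. Summation (rather than averaging) of relative abundances is
scale-free across libraries of different depth and gives the same argmax
whenever all sources contributed a library. OTUs with all-zero evidence —
typically low-abundance taxa seen only in pooled lysates — are labelled
`unassigned`, and the size-class spectrum includes them in its denominator.
Exact argmax ties are broken towards the smaller class, deterministically,
and flagged in the output; the small-ward direction reflects the package's
focus on small-taxon detection and is an explicit, documented convention
rather than a claim about the specimen.

Jaccard (presence/absence) and Bray–Curtis (relative abundance)
dissimilarities are computed with `vegan::vegdist` behind a thin, validated
interface; dendrograms use average linkage (UPGMA) by default — a neutral,
widely used choice for community matrices — and serialise to Newick via
`ape`.

## The forward simulator

`sim_config()` collects the generative model:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 300 | regional species pool (one OTU per species) |
| `mu_a`, `sigma_a` | 1.5, 1.2 | lognormal rank abundance; expected specimens per species per sample ≈ 9, heavy-tailed |
| `mu_L`, `sigma_L` | log 2.5, 0.9 | per-species mean body length (mm): median 2.5 mm with a long right tail |
| `length_cv` | 0.1 | within-species log-sd of individual length |
| `length_bounds` | 0.5–30 mm | truncation of body length |
| `allometry_a`, `allometry_b` | 0.0305 mg, 2.62 | dry weight = a·L^b, a widely used general-insect fit |
| `mesh_diameters_mm` | 8, 4, 2 | sieve holes; fractions XL/L/M/S |
| `retention_k` | 0.5 | effective width factor: retained when k·L ≥ mesh |
| `carryover_prob`, `carryover_mass_frac` | 0.05, 0.02 | fragment shedding into a uniformly chosen smaller fraction |
| `bias_sigma` | 0.5 | sd of per-species log10 amplification efficiency |
| `depth` | 10,000 | reads per library (the depth the 0.01 % filter corresponds to) |
| `n_replicates`, `n_negatives` | 2, 9 | extraction replicates; negative controls |
| `contamination_lambda` | 0.05 | Poisson stray reads per OTU per control |

A scenario draws one species pool (abundance, mean length, efficiency) and,
per bulk sample (default three: L1–L3), realises specimens (Poisson counts,
lognormal individual lengths), sieves them with the retention rule, and
sequences the four fractions and all six pooled lysates in duplicate, plus
nine negative controls — everything from a single seed, bit-reproducibly.

Modelling commitments worth stating explicitly:

- **Lengths are community-realistic, not taxon-specific.** The defaults
  place roughly 70 % of species in S, 20 % in M, and a thin tail in L/XL,
  with total biomass nonetheless dominated by the large classes — the
  regime in which size sorting matters. No taxonomy is simulated.
- **Retention uses an effective width** `k·length` against round sieve
  holes, since elongate specimens pass by cross-section, not length.
- **Fragment carryover is a mass transfer**: a retained specimen sheds a
  fixed mass fraction into one smaller fraction; total dry weight is
  conserved exactly. This single channel stands in for both broken-off body
  parts and small specimens clinging to large ones.
- **Primer bias is a species property**: efficiency `10^N(0, bias_sigma)`
  is drawn once per species and reused in every library, as sequence-
  determined bias should be. It multiplies the *pooled* template: lysate
  DNA composition within a fraction is biomass-proportional, and efficiency
  acts at PCR, after lysates are mixed. Under this formulation, dry-weight-
  proportional pooling reproduces the unsorted sample's read distribution
  exactly — the identity the pooled-lysate design relies on — which would
  not hold if efficiency were folded into each fraction's composition
  before mixing.
- **Ground truth**: a species' true size class is the fraction holding the
  majority of its *intact* (pre-fragment) biomass; per-fraction dry weights
  handed to the dry-weight pooling scheme are the *realised* (post-
  fragment) weights, as a balance would measure them.

What the simulator does **not** emulate: sequence errors, chimeras and OTU
clustering artifacts (one OTU ≡ one species, the analysis operates
downstream of clustering); PCR cycle dynamics; tag jumping;
compositionality beyond the multinomial; spatial or temporal structure
among the three bulk samples (they share one species pool and differ only
by sampling noise). Passing simulation-based tests therefore shows that the
analysis chain is *self-consistent* under a biomass-dominated,
size-structured community with primer bias and leakage — not that any
particular field data satisfy those assumptions.

## Validation strategy and problem sizes

The test suite checks exact hand-computed oracles (a five-OTU three-step
filtering fixture; mixture arithmetic; agglomeration orders), exhaustive
brute-force equivalences (the ratio sweep against an independent per-OTU
enumeration across all 21 ratios; fraction-sharing against direct presence
counting), cross-module identities (depth-10,000 rarefaction ≡ 0.01 %
filter), and distributional oracles (multinomial and Poisson means within
three standard errors). Directional claims — unsorted `g` recovering fewer
OTUs than `equ` and small-favouring strategies, depth-equivalence factors
above 1, interior sweep optima, ≥ 95 % ground-truth recovery of size
classes with carryover off — are evaluated on 20 independent scenarios at
the default configuration (300 species, three bulk samples, ~60 libraries
per scenario), a size chosen to make the ensemble means stable while a full
replication finishes in seconds. The exact-threshold boundary (retained, not
discarded) is asserted at every place it appears.

## Known limitations

- Strategy proportions other than `g`/`equ` are conventions, not
  measurements; comparisons among `invg`/`fibo`/`4x`/`log` depend on them.
- Threshold rarefaction is deterministic: it removes rarefaction noise but
  also ignores the binomial detection uncertainty near the cut; curves on
  real data will be smoother than resampling-based ones near the origin.
- With a single leakage channel, the simulator cannot distinguish
  fragment-driven from attachment-driven cross-fraction contamination.
- The depth-equivalence factor is a grid statistic; its resolution is the
  grid spacing (about 27 % between neighbouring points on the default
  19-point grid).
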