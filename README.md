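# mitohap

Forensic mitogenome haplotyping: threshold-based variant and
point-heteroplasmy (PHP) calling from aligned reads or pileups,
quantitative length-heteroplasmy assessment by spanning-read motif
counting, replicate/mixture/duplicate quality control, and
lineage-marker population statistics — random match probabilities,
haplotype diversity, pairwise Φst with permutation tests, and principal
coordinate analysis. A seeded synthetic mitogenome population and read
simulator stands in for specimen data throughout the test suite.

The package is for forensic and population geneticists who need
database-grade mitochondrial haplotypes and the statistics computed on
them, with every processing rule explicit and testable.

## The model in brief

A haplotype is a list of named differences from a 16,569 bp circular
reference (e.g. `A263G`, `315.1C`, `249DEL`), interpreted over a stated
range. Calling is per pileup column: no call below 100× filtered depth;
alleles at ≥ 5% variant frequency with ≥ 1% of their reads on each
strand are retained; one retained non-reference allele is a fixed call
and two are a PHP written with the two-base IUPAC code (a secondary 2%
screen flags nuclear-insert interference). Indels in nine catalogued
homopolymer regions are withheld and re-derived from the *major length
molecule* — the most-read motif among reads spanning the region.
For a sample set partitioned into haplotype classes of sizes *k&#8321;…k&#8342;*
(*n* = Σ*k&#7522;*, *p&#7522;* = *k&#7522;*/*n*):

- observed RMP = Σ *p&#7522;*²
- empirical RMP = Σ *k&#7522;*(*k&#7522;*−1) / (*n*(*n*−1))
- haplotype diversity = (*n*/(*n*−1)) (1 − Σ *p&#7522;*²)

Genetic distance between haplotypes is Kimura 2-parameter,
*d* = −½ ln((1−2P−Q)√(1−2Q)); pairwise Φst is the among-population
fraction of an AMOVA on squared K2P distances with a permutation test.

See the methods vignette (`vignettes/mitogenome-haplotyping.Rmd`) for
the full set of rules, defaults and design decisions.

## Worked example

Simulate one individual at 1000× on the synthetic reference, call its
profile, and compute summary statistics for a 112-sample set containing
two shared haplotype pairs:

```r
library(mitohap)

ref <- synthetic_reference()
cfg <- sim_config(seed = 7, n_individuals = 1, depth_mean = 1000)
pop <- simulate_population(cfg)

pl  <- simulate_pileup(pop$profiles[[1]], ref, cfg, seed = 7)
res <- call_profile(pl, ref, call_params(), range = c(1, 16569),
                    sample_id = "SIM0001")
res$profile
#> <mito_profile> SIM0001
#>   range: 1-16569
#>   variants (42): G288A C598T G617A C2681T C2945T A4034G T4361C G4497A ...
res$metrics
#> <call_metrics>
#>   average read depth:            1000.1
#>   avg major base freq:           0.9950
#>   avg major base freq (excl het):0.9950
#>   positions below min depth: 0

counts <- haplotype_counts(make_table6_fixture(112, c(2L, 2L), seed = 1))
summary_statistics(counts)[, 1:6]
#>     n total_haplotypes unique_haplotypes observed_rmp_pct empirical_rmp_pct
#> 1 112              110               108             0.92              0.03
#>   haplotype_diversity
#> 1              0.9997
```

The called profile lists the 42 substitutions of the simulated
haplotype; the metrics show full coverage with ~99.5% average major-base
frequency (the 0.5% simulated base error). The 112-sample set with 108
singletons and two doubleton classes gives an observed random match
probability of 0.92%, an empirical RMP of 0.03% and haplotype diversity
0.9997.

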